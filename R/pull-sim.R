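# ---- simulated micropipette-pull sequences with geometric ground truth

# distance-capped, angle-weighted tension response: the FRET-index drop of a
# tension-sensor punctum as a function of recoil distance and angle. A
# minimal monotone model (not a mechanistic claim): larger recoils and more
# junction-perpendicular recoils load the molecule more.
tension_response <- function(d_r, alpha_r_deg, gain = 1, angle_power = 2,
                             d_cap = 10) {
  gain * pmin(d_r, d_cap) * sin(alpha_r_deg * pi / 180)^angle_power
}

# acute angle (deg) between a vector and the nearest segment of a polyline
.angle_to_polyline <- function(pt, vec, polyline) {
  if (sqrt(sum(vec^2)) < 1e-12) return(0)
  best_d <- Inf; best_dir <- c(1, 0)
  for (s in seq_len(nrow(polyline) - 1)) {
    a <- polyline[s, ]; b <- polyline[s + 1, ]
    ab <- b - a
    tpar <- sum((pt - a) * ab) / sum(ab^2)
    tpar <- min(1, max(0, tpar))
    proj <- a + tpar * ab
    d <- sqrt(sum((pt - proj)^2))
    if (d < best_d) { best_d <- d; best_dir <- ab }
  }
  a1 <- atan2(vec[2], vec[1])
  a2 <- atan2(best_dir[2], best_dir[1])
  d <- abs(a1 - a2) %% pi
  if (d > pi / 2) d <- pi - d
  d * 180 / pi
}

#' Simulate a micropipette pull sequence with ground-truth recoil geometry
#'
#' Generates the three phases of a pull experiment as punctum point sets
#' (centres are warped and re-rendered, so no interpolation artefacts enter
#' the ground truth): pre = the base configuration; pull = pre warped by a
#' projective deformation, with each tension-sensor punctum's FRET index
#' reduced by the distance- and angle-dependent tension response; post =
#' partial recovery of the deformation by \code{recoil_fraction}. Exact
#' control-point pairs (>= 6) and the per-punctum ground truth (d_r,
#' alpha_r, delta I) are emitted for the downstream tracking and statistics
#' stages.
#'
#' @param puncta data.frame with columns \code{x_um}, \code{y_um},
#'   \code{base_index} (resting FRET index) and optionally
#'   \code{is_sensor} (logical; default all TRUE).
#' @param homography 3x3 projective matrix describing the pull deformation
#'   (micrometre coordinates).
#' @param recoil_fraction fraction of the deformation recovered post-pull,
#'   in [0, 1] (1 = full relaxation back to pre).
#' @param junction_polyline K x 2 matrix tracing the cell-cell contact.
#' @param gain,angle_power tension-response parameters: index drop per um of
#'   capped recoil, and the exponent on sin(alpha_r).
#' @param index_noise_sd per-punctum, per-phase Gaussian noise on measured
#'   indices (0 = noiseless).
#' @param dropout_pre fraction of puncta missing from the pre phase
#'   (emulates detection dropout; default 0).
#' @param control_grid number of control points along each image edge
#'   (yields >= 6 pairs).
#' @param seed integer seed.
#' @return list with \code{pre}, \code{pull}, \code{post} puncta tables
#'   (x_um, y_um, fret_index), \code{control_points} (exact pairs across the
#'   three phases), and \code{truth} (punctum, d_r_um, alpha_r_deg,
#'   delta_index, is_sensor).
#' @export
simulate_pull_sequence <- function(puncta, homography,
                                   recoil_fraction = 1,
                                   junction_polyline = NULL,
                                   gain = 1, angle_power = 2,
                                   index_noise_sd = 0,
                                   dropout_pre = 0,
                                   control_grid = 3L, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(all(c("x_um", "y_um", "base_index") %in% names(puncta)))
  if (!is.finite(recoil_fraction) || recoil_fraction < 0 ||
      recoil_fraction > 1)
    stop("recoil_fraction must lie in [0, 1]")
  H <- if (inherits(homography, "homography")) homography$H else homography
  if (abs(det(H)) < 1e-12) stop("degenerate homography")
  n <- nrow(puncta)
  is_sensor <- if ("is_sensor" %in% names(puncta)) puncta$is_sensor else
    rep(TRUE, n)
  pre_pos <- cbind(puncta$x_um, puncta$y_um)
  pull_pos <- apply_homography(H, pre_pos)
  post_pos <- pull_pos + recoil_fraction * (pre_pos - pull_pos)
  recoil <- post_pos - pull_pos
  d_r <- sqrt(rowSums(recoil^2))
  if (is.null(junction_polyline)) {
    rng <- range(puncta$x_um)
    junction_polyline <- cbind(c(rng[1] - 1, rng[2] + 1),
                               c(mean(puncta$y_um), mean(puncta$y_um)))
  }
  # the contact line deforms with the monolayer: the recoil angle is defined
  # against the junction as it lies in the pull configuration
  junction_pull <- apply_homography(H, junction_polyline)
  alpha <- vapply(seq_len(n), function(i)
    .angle_to_polyline(pull_pos[i, ], recoil[i, ], junction_pull),
    numeric(1))
  dI <- ifelse(is_sensor,
               tension_response(d_r, alpha, gain = gain,
                                angle_power = angle_power), 0)
  noise <- function() if (index_noise_sd > 0)
    stats::rnorm(n, 0, index_noise_sd) else numeric(n)
  mk <- function(pos, idx, keep = rep(TRUE, n)) {
    data.frame(x_um = pos[keep, 1], y_um = pos[keep, 2],
               fret_index = (idx + noise())[keep])
  }
  keep_pre <- if (dropout_pre > 0)
    stats::runif(n) >= dropout_pre else rep(TRUE, n)
  pre <- mk(pre_pos, puncta$base_index, keep_pre)
  pull <- mk(pull_pos, puncta$base_index - dI)
  post <- mk(post_pos, puncta$base_index)
  # exact control points on a grid spanning the punctum bounding box
  gx <- seq(min(puncta$x_um) - 2, max(puncta$x_um) + 2,
            length.out = control_grid)
  gy <- seq(min(puncta$y_um) - 2, max(puncta$y_um) + 2,
            length.out = control_grid)
  cp_pre <- as.matrix(expand.grid(x = gx, y = gy))
  cp_pull <- apply_homography(H, cp_pre)
  cp_post <- cp_pull + recoil_fraction * (cp_pre - cp_pull)
  control_points <- data.frame(x_pre = cp_pre[, 1], y_pre = cp_pre[, 2],
                               x_pull = cp_pull[, 1], y_pull = cp_pull[, 2],
                               x_post = cp_post[, 1], y_post = cp_post[, 2])
  truth <- data.frame(punctum = seq_len(n), d_r_um = d_r,
                      alpha_r_deg = alpha, delta_index = dI,
                      is_sensor = is_sensor, kept_pre = keep_pre)
  list(pre = pre, pull = pull, post = post,
       control_points = control_points, truth = truth)
}
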