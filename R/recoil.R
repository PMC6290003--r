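# ---- recoil tracking: registration, bipartite matching, junction geometry

#' Fit a projective map (homography) from control-point pairs
#'
#' Normalised direct linear transform: both point sets are translated to
#' their centroid and scaled to mean distance sqrt(2), the 2N x 9 DLT system
#' is solved by SVD, and the map is de-normalised and scaled to H[3,3] = 1.
#' Intended for the 6-10 manually selected control points that register the
#' pull-deformed monolayer.
#'
#' @param src,dst N x 2 matrices of corresponding points (micrometres),
#'   N >= 4 and non-degenerate.
#' @return object of class \code{homography}: list with the 3x3 matrix
#'   \code{H} and the reprojection \code{rms} (um).
#' @export
fit_projective_map <- function(src, dst) {
  src <- as.matrix(src); dst <- as.matrix(dst)
  stopifnot(ncol(src) == 2, identical(dim(src), dim(dst)))
  n <- nrow(src)
  if (n < 4) stop("at least 4 control-point pairs are required")
  norm_T <- function(p) {
    ctr <- colMeans(p)
    d <- sqrt(rowSums(sweep(p, 2, ctr)^2))
    s <- if (mean(d) > 0) sqrt(2) / mean(d) else 1
    matrix(c(s, 0, -s * ctr[1], 0, s, -s * ctr[2], 0, 0, 1), 3, 3,
           byrow = TRUE)
  }
  Ts <- norm_T(src); Td <- norm_T(dst)
  hp <- function(p, T) {
    q <- T %*% rbind(t(p), 1)
    t(q[1:2, , drop = FALSE] / rep(q[3, ], each = 2))
  }
  s <- hp(src, Ts); d <- hp(dst, Td)
  A <- matrix(0, 2 * n, 9)
  for (i in seq_len(n)) {
    x <- s[i, 1]; y <- s[i, 2]; u <- d[i, 1]; v <- d[i, 2]
    A[2 * i - 1, ] <- c(-x, -y, -1, 0, 0, 0, u * x, u * y, u)
    A[2 * i, ]     <- c(0, 0, 0, -x, -y, -1, v * x, v * y, v)
  }
  sv <- svd(A)
  if (sv$d[8] < 1e-10 * sv$d[1])
    stop("degenerate control-point configuration")
  Hn <- matrix(sv$v[, 9], 3, 3, byrow = TRUE)
  H <- solve(Td) %*% Hn %*% Ts
  if (abs(H[3, 3]) < 1e-12) stop("degenerate homography")
  H <- H / H[3, 3]
  proj <- apply_homography(H, src)
  rms <- sqrt(mean(rowSums((proj - dst)^2)))
  structure(list(H = H, rms = rms, n_points = n), class = "homography")
}

#' Apply a projective map to points
#'
#' @param H 3x3 matrix or a \code{homography}.
#' @param pts N x 2 matrix of points.
#' @return N x 2 matrix of mapped points.
#' @export
apply_homography <- function(H, pts) {
  if (inherits(H, "homography")) H <- H$H
  pts <- as.matrix(pts)
  q <- H %*% rbind(t(pts), 1)
  t(q[1:2, , drop = FALSE] / rep(q[3, ], each = 2))
}

# Shortest-augmenting-path (Jonker-Volgenant style) rectangular assignment.
# cost: n x m with n <= m; returns integer vector a, a[i] = column of row i.
solve_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, all(is.finite(cost)))
  u <- numeric(n)            # row potentials
  v <- numeric(m + 1)        # column potentials, v[1] is virtual column 0
  p <- integer(m + 1)        # p[j+1] = row assigned to column j (0 = none)
  way <- integer(m + 1)
  for (i in seq_len(n)) {
    p[1] <- i
    j0 <- 0L
    minv <- rep(Inf, m + 1)
    used <- rep(FALSE, m + 1)
    repeat {
      used[j0 + 1L] <- TRUE
      i0 <- p[j0 + 1L]
      free <- which(!used[-1])
      idx <- free + 1L
      cur <- cost[i0, free] - u[i0] - v[idx]
      upd <- cur < minv[idx]
      if (any(upd)) {
        minv[idx[upd]] <- cur[upd]
        way[idx[upd]] <- j0
      }
      k <- which.min(minv[idx])
      delta <- minv[idx][k]
      j1 <- free[k]
      us <- which(used)                    # 1-based positions = columns + 1
      rows_us <- p[us]
      u[rows_us] <- u[rows_us] + delta
      v[us] <- v[us] - delta
      minv[idx] <- minv[idx] - delta
      j0 <- j1
      if (p[j0 + 1L] == 0L) break
    }
    repeat {
      j1 <- way[j0 + 1L]
      p[j0 + 1L] <- p[j1 + 1L]
      j0 <- j1
      if (j0 == 0L) break
    }
  }
  a <- integer(n)
  for (j in seq_len(m)) if (p[j + 1L] > 0L) a[p[j + 1L]] <- j
  a
}

#' Minimum-total-displacement bipartite matching of two point sets
#'
#' One-to-one matching of puncta between time points minimising the total
#' Euclidean displacement, restricted to pairs closer than \code{max_disp}.
#' When the sets differ in size, the maximum feasible number of pairs is
#' matched first, then total displacement is minimised (infeasible edges
#' carry a prohibitive surrogate cost and are stripped from the result).
#'
#' @param A,B N x 2 and M x 2 point matrices (micrometres).
#' @param max_disp admissible displacement gate in micrometres (default 15).
#' @return object of class \code{matching}: list with \code{pairs} (two-column
#'   integer matrix: index in A, index in B), \code{total_displacement},
#'   \code{unmatched_A}, \code{unmatched_B}.
#' @export
match_puncta <- function(A, B, max_disp = 15) {
  A <- as.matrix(A); B <- as.matrix(B)
  stopifnot(max_disp > 0)
  nA <- nrow(A); nB <- nrow(B)
  empty <- function() structure(list(
    pairs = matrix(integer(0), 0, 2,
                   dimnames = list(NULL, c("i", "j"))),
    total_displacement = 0,
    unmatched_A = seq_len(nA), unmatched_B = seq_len(nB)),
    class = "matching")
  if (nA == 0 || nB == 0) return(empty())
  D <- sqrt(outer(A[, 1], B[, 1], `-`)^2 + outer(A[, 2], B[, 2], `-`)^2)
  feas <- D <= max_disp
  if (!any(feas)) return(empty())
  big <- (max(D[feas]) + 1) * (min(nA, nB) + 1)  # cardinality-first surrogate
  C <- D
  C[!feas] <- big
  flip <- nA > nB
  if (flip) C <- t(C)
  a <- solve_assignment(C)
  ii <- seq_along(a); jj <- a
  if (flip) { tmp <- ii; ii <- jj; jj <- tmp }
  keep <- feas[cbind(ii, jj)]
  pairs <- cbind(i = ii[keep], j = jj[keep])
  structure(list(pairs = pairs,
                 total_displacement =
                   if (nrow(pairs)) sum(D[pairs]) else 0,
                 unmatched_A = setdiff(seq_len(nA), pairs[, 1]),
                 unmatched_B = setdiff(seq_len(nB), pairs[, 2])),
            class = "matching")
}

#' @export
print.matching <- function(x, ...) {
  cat(sprintf("<matching> %d pairs, total displacement %.3f um\n",
              nrow(x$pairs), x$total_displacement))
  invisible(x)
}

#' Per-punctum recoil vectors and distances
#'
#' Given the pull-to-post matching, the recoil vector of a punctum is its
#' post-relaxation position minus its position at maximal pull; the recoil
#' distance d_r is the vector norm. Unmatched puncta yield no track.
#'
#' @param matching a \code{matching} from \code{\link{match_puncta}}
#'   (A = pull, B = post).
#' @param pull_pos,post_pos the point matrices that were matched.
#' @return data.frame: pull_id, post_id, x_pull, y_pull, x_post, y_post,
#'   recoil_dx, recoil_dy, d_r_um.
#' @export
compute_recoil <- function(matching, pull_pos, post_pos) {
  p <- matching$pairs
  dx <- post_pos[p[, 2], 1] - pull_pos[p[, 1], 1]
  dy <- post_pos[p[, 2], 2] - pull_pos[p[, 1], 2]
  data.frame(pull_id = p[, 1], post_id = p[, 2],
             x_pull = pull_pos[p[, 1], 1], y_pull = pull_pos[p[, 1], 2],
             x_post = post_pos[p[, 2], 1], y_post = post_pos[p[, 2], 2],
             recoil_dx = dx, recoil_dy = dy,
             d_r_um = sqrt(dx^2 + dy^2))
}

#' Robust local junction slope around a punctum
#'
#' Fits a line through a punctum and all neighbouring puncta within a radius
#' (default 4 um) by iteratively reweighted least squares with bisquare
#' weights, in a rotated frame chosen from the principal axis so vertical
#' contacts cause no infinities. The slope standard error is propagated to
#' angle units; fits with fewer than \code{min_points} points or SE above
#' \code{max_se_deg} are flagged unreliable.
#'
#' @param punctum length-2 numeric (x, y) in micrometres.
#' @param neighbors N x 2 matrix of candidate neighbour positions (may
#'   include the punctum itself; it is added if absent).
#' @param radius_um neighbourhood radius (default 4).
#' @param min_points minimal number of points (default 3).
#' @param max_se_deg maximal slope-angle standard error in degrees
#'   (default 9).
#' @return list with \code{m_c} (slope, may be +-Inf for vertical),
#'   \code{angle_deg} in (-90, 90], \code{se_deg}, \code{n_points},
#'   \code{reliable}.
#' @export
junction_slope <- function(punctum, neighbors, radius_um = 4,
                           min_points = 3L, max_se_deg = 9) {
  neighbors <- as.matrix(neighbors)
  d <- sqrt(colSums((t(neighbors) - punctum)^2))
  pts <- neighbors[d <= radius_um, , drop = FALSE]
  if (!any(d < 1e-9)) pts <- rbind(punctum, pts)
  n <- nrow(pts)
  if (n < min_points)
    return(list(m_c = NA_real_, angle_deg = NA_real_, se_deg = NA_real_,
                n_points = n, reliable = FALSE))
  ctr <- colMeans(pts)
  X <- sweep(pts, 2, ctr)
  ev <- eigen(crossprod(X) / n, symmetric = TRUE)
  theta0 <- atan2(ev$vectors[2, 1], ev$vectors[1, 1])
  R <- matrix(c(cos(-theta0), -sin(-theta0), sin(-theta0), cos(-theta0)),
              2, 2, byrow = TRUE)
  P <- X %*% t(R)                      # principal axis now ~horizontal
  xs <- P[, 1]; ys <- P[, 2]
  # bisquare IRLS for ys ~ a + b xs
  w <- rep(1, n)
  b <- 0; a <- 0
  for (it in 1:25) {
    sw <- sum(w); mx <- sum(w * xs) / sw; my <- sum(w * ys) / sw
    sxx <- sum(w * (xs - mx)^2)
    if (sxx < 1e-12) break
    b_new <- sum(w * (xs - mx) * (ys - my)) / sxx
    a_new <- my - b_new * mx
    conv <- abs(b_new - b) < 1e-10 && abs(a_new - a) < 1e-10 && it > 1
    b <- b_new; a <- a_new
    r <- ys - a - b * xs
    s <- stats::median(abs(r - stats::median(r))) / 0.6745
    if (s < 1e-9) { w <- rep(1, n) } else {
      u <- r / (4.685 * s)
      w <- ifelse(abs(u) < 1, (1 - u^2)^2, 0)
      if (sum(w > 0) < 2) w <- rep(1, n)
    }
    if (conv) break
  }
  sw <- sum(w); mx <- sum(w * xs) / sw
  sxx <- sum(w * (xs - mx)^2)
  r <- ys - a - b * xs
  dof <- max(1, sum(w > 0) - 2)
  s2 <- sum(w * r^2) / dof
  se_b <- if (sxx > 0) sqrt(s2 / sxx) else Inf
  angle <- theta0 + atan(b)
  # fold to (-90, 90]
  angle <- atan2(sin(angle), cos(angle))
  if (angle <= -pi / 2) angle <- angle + pi
  if (angle > pi / 2) angle <- angle - pi
  se_deg <- se_b / (1 + b^2) * 180 / pi
  m_c <- tan(angle)
  if (abs(abs(angle) - pi / 2) < 1e-9) m_c <- Inf
  list(m_c = m_c, angle_deg = angle * 180 / pi, se_deg = se_deg,
       n_points = n, reliable = n >= min_points && se_deg <= max_se_deg)
}

#' Acute angle between the recoil direction and the cell-cell contact
#'
#' The recoil angle alpha_r is the acute angle between the line of slope
#' \code{m_r} (the recoil vector) and the line of slope \code{m_c} (the
#' local junction). Algebraically \code{atan((m_r - m_c)/(1 + m_r m_c))},
#' but computed in angle space (atan of each slope, difference folded to
#' [0, 90] degrees) so vertical lines (infinite slope) are handled exactly:
#' junction-parallel recoil gives 0 degrees, perpendicular recoil 90.
#'
#' @param m_r recoil-vector slope (may be \code{Inf} for vertical).
#' @param m_c junction slope (may be \code{Inf}).
#' @return acute angle in degrees, in [0, 90] (vectorised).
#' @export
recoil_angle <- function(m_r, m_c) {
  a1 <- atan(m_r)   # atan(Inf) = pi/2
  a2 <- atan(m_c)
  d <- abs(a1 - a2) %% pi
  d <- ifelse(d > pi / 2, pi - d, d)
  d * 180 / pi
}

#' Classify recoil orientation relative to the junction
#'
#' @param alpha_r recoil angle(s) in degrees, within [0, 90].
#' @return \code{"parallel"} when alpha_r <= 45 degrees, else
#'   \code{"perpendicular"}.
#' @export
classify_orientation <- function(alpha_r) {
  stopifnot(all(alpha_r >= 0 & alpha_r <= 90, na.rm = TRUE))
  ifelse(alpha_r <= 45, "parallel", "perpendicular")
}

#' Apply the recoil-track inclusion and exclusion rules
#'
#' Flags tracks rather than deleting them: \code{small_recoil} when
#' d_r < \code{min_recoil_um} (only puncta that recoiled by at least 1 um are
#' analysed), \code{out_of_window} when d_r > \code{max_dr_um} (analysis
#' window 10 um), \code{isolated} when fewer than 2 neighbouring tracks lie
#' within \code{neighbor_radius_um}, and \code{direction_mismatch} when the
#' recoil direction deviates from the mean of neighbouring recoils by more
#' than \code{direction_tol_deg}. Summaries should use rows with
#' \code{included == TRUE}.
#'
#' @param tracks data.frame with x_pull, y_pull, recoil_dx, recoil_dy,
#'   d_r_um (from \code{\link{compute_recoil}}), plus any other columns.
#' @param min_recoil_um minimal recoil distance (default 1).
#' @param max_dr_um analysis-window upper bound (default 10).
#' @param neighbor_radius_um isolation / direction neighbourhood (default
#'   10).
#' @param direction_tol_deg mismatch tolerance (default 60).
#' @return the tracks with added \code{flags} and \code{included} columns.
#' @export
filter_tracks <- function(tracks, min_recoil_um = 1, max_dr_um = 10,
                          neighbor_radius_um = 10, direction_tol_deg = 60) {
  n <- nrow(tracks)
  flags <- vector("list", n)
  pos <- cbind(tracks$x_pull, tracks$y_pull)
  for (i in seq_len(n)) {
    fl <- character(0)
    if (tracks$d_r_um[i] < min_recoil_um) fl <- c(fl, "small_recoil")
    if (tracks$d_r_um[i] > max_dr_um) fl <- c(fl, "out_of_window")
    d <- sqrt(rowSums((pos - matrix(pos[i, ], n, 2, byrow = TRUE))^2))
    nb <- which(d > 1e-12 & d <= neighbor_radius_um)
    if (length(nb) < 2) fl <- c(fl, "isolated")
    else if (tracks$d_r_um[i] > 1e-9) {
      mdx <- mean(tracks$recoil_dx[nb]); mdy <- mean(tracks$recoil_dy[nb])
      if (mdx^2 + mdy^2 > 1e-18) {
        dot <- tracks$recoil_dx[i] * mdx + tracks$recoil_dy[i] * mdy
        cosang <- dot / (tracks$d_r_um[i] * sqrt(mdx^2 + mdy^2))
        ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
        if (ang > direction_tol_deg) fl <- c(fl, "direction_mismatch")
      }
    }
    flags[[i]] <- fl
  }
  tracks$flags <- vapply(flags, paste, character(1), collapse = ";")
  tracks$included <- lengths(flags) == 0
  tracks
}

#' Track puncta across a pre/pull/post micropipette-pull sequence
#'
#' End-to-end geometry pipeline: fits a projective registration map from the
#' manually supplied control points, matches pull puncta to post puncta in
#' the registered frame (the map absorbs the bulk deformation so residual
#' displacements are small), computes recoil vectors in the ORIGINAL
#' coordinates, performs the second post-to-pre matching to attach pre-phase
#' FRET values, fits the local junction slope at each punctum, evaluates the
#' recoil angle, classifies orientation and applies the track filters.
#'
#' @param pre,pull,post data.frames with columns \code{x_um}, \code{y_um}
#'   and optionally \code{fret_index}.
#' @param control_points data.frame with columns \code{x_pull},
#'   \code{y_pull}, \code{x_post}, \code{y_post} (and optionally
#'   \code{x_pre}, \code{y_pre} for the post-to-pre registration).
#' @param max_disp matching gate in micrometres.
#' @param slope_radius_um,min_slope_points,max_slope_se_deg junction-slope
#'   settings (defaults 4 um, 3 points, 9 degrees).
#' @param min_recoil_um,max_dr_um,neighbor_radius_um,direction_tol_deg track
#'   filter settings.
#' @return data.frame of tracks: ids and positions at each phase, recoil
#'   vector and d_r_um, junction slope and SE, alpha_r_deg, orientation,
#'   fret_pre/pull/post, flags, included.
#' @export
track_pull_sequence <- function(pre, pull, post, control_points,
                                max_disp = 15,
                                slope_radius_um = 4, min_slope_points = 3L,
                                max_slope_se_deg = 9,
                                min_recoil_um = 1, max_dr_um = 10,
                                neighbor_radius_um = 10,
                                direction_tol_deg = 60) {
  P <- function(tab) cbind(tab$x_um, tab$y_um)
  pull_pos <- P(pull); post_pos <- P(post); pre_pos <- P(pre)
  H_pp <- fit_projective_map(cbind(control_points$x_pull,
                                   control_points$y_pull),
                             cbind(control_points$x_post,
                                   control_points$y_post))
  pull_reg <- apply_homography(H_pp, pull_pos)
  m1 <- match_puncta(pull_reg, post_pos, max_disp = max_disp)
  tracks <- compute_recoil(m1, pull_pos, post_pos)
  if (!nrow(tracks)) return(tracks)
  # second matching: post back to pre (registration optional)
  post_reg <- post_pos
  if (all(c("x_pre", "y_pre") %in% names(control_points))) {
    H_post_pre <- fit_projective_map(cbind(control_points$x_post,
                                           control_points$y_post),
                                     cbind(control_points$x_pre,
                                           control_points$y_pre))
    post_reg <- apply_homography(H_post_pre, post_pos)
  }
  m2 <- match_puncta(post_reg, pre_pos, max_disp = max_disp)
  pre_of_post <- rep(NA_integer_, nrow(post_pos))
  if (nrow(m2$pairs)) pre_of_post[m2$pairs[, 1]] <- m2$pairs[, 2]
  tracks$pre_id <- pre_of_post[tracks$post_id]
  tracks$x_pre <- pre_pos[tracks$pre_id, 1]
  tracks$y_pre <- pre_pos[tracks$pre_id, 2]
  gi <- function(tab, col, id) {
    if (col %in% names(tab)) tab[[col]][id] else rep(NA_real_, length(id))
  }
  tracks$fret_pull <- gi(pull, "fret_index", tracks$pull_id)
  tracks$fret_post <- gi(post, "fret_index", tracks$post_id)
  tracks$fret_pre <- ifelse(is.na(tracks$pre_id), NA_real_,
                            gi(pre, "fret_index", tracks$pre_id))
  # junction slope at each tracked punctum, from pull-phase positions
  slopes <- lapply(seq_len(nrow(tracks)), function(i) {
    junction_slope(c(tracks$x_pull[i], tracks$y_pull[i]),
                   cbind(tracks$x_pull, tracks$y_pull),
                   radius_um = slope_radius_um,
                   min_points = min_slope_points,
                   max_se_deg = max_slope_se_deg)
  })
  tracks$m_c <- vapply(slopes, `[[`, numeric(1), "m_c")
  tracks$slope_se_deg <- vapply(slopes, `[[`, numeric(1), "se_deg")
  slope_ok <- vapply(slopes, `[[`, logical(1), "reliable")
  m_r <- ifelse(abs(tracks$recoil_dx) < 1e-12, Inf,
                tracks$recoil_dy / tracks$recoil_dx)
  tracks$alpha_r_deg <- ifelse(is.na(tracks$m_c), NA_real_,
                               recoil_angle(m_r, tracks$m_c))
  tracks$orientation <- ifelse(is.na(tracks$alpha_r_deg), NA_character_,
                               classify_orientation(tracks$alpha_r_deg))
  tracks <- filter_tracks(tracks, min_recoil_um = min_recoil_um,
                          max_dr_um = max_dr_um,
                          neighbor_radius_um = neighbor_radius_um,
                          direction_tol_deg = direction_tol_deg)
  extra <- ifelse(slope_ok, "", "slope_unreliable")
  unlink_f <- ifelse(is.na(tracks$pre_id), "unlinked_pre", "")
  comb <- function(a, b) {
    out <- paste(a, b, sep = ";")
    gsub("^;|;$", "", out)
  }
  tracks$flags <- comb(comb(tracks$flags, extra), unlink_f)
  tracks$included <- tracks$included & slope_ok
  tracks$track_id <- seq_len(nrow(tracks))
  tracks
}
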