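# ---- sensitized-emission ratiometric FRET: calibration, de-mixing, indices

#' Spectral cross-talk (mixing) matrix
#'
#' Builds the 3x3 forward mixing operator that maps true channel intensities
#' (D, F, A) to observed ones. Row/column order is (donor-exc/donor-em,
#' donor-exc/acceptor-em, acceptor-exc/acceptor-em). Off-diagonal entries are
#' the cross-talk correction factors epsilon_XY = contribution of true
#' channel Y into observed channel X; the diagonal is fixed to 1.
#'
#' @param eps_FD,eps_AD,eps_DF,eps_AF,eps_DA,eps_FA non-negative cross-talk
#'   coefficients.
#' @return object of class \code{mixing_matrix} (a 3x3 matrix with dimnames).
#' @export
mixing_matrix <- function(eps_FD, eps_AD, eps_DF, eps_AF, eps_DA, eps_FA) {
  eps <- c(eps_FD, eps_AD, eps_DF, eps_AF, eps_DA, eps_FA)
  if (any(!is.finite(eps)) || any(eps < 0))
    stop("all epsilon factors must be finite and >= 0")
  M <- matrix(c(1,      eps_FD, eps_AD,
                eps_DF, 1,      eps_AF,
                eps_DA, eps_FA, 1), 3, 3, byrow = TRUE,
              dimnames = list(c("D", "F", "A"), c("D", "F", "A")))
  if (abs(det(M)) < 1e-12) stop("mixing matrix is singular")
  structure(M, class = c("mixing_matrix", "matrix"))
}

#' Cross-talk presets for the two shipped FRET pairs
#'
#' Correction-factor sets measured from fluorophore-only samples for the
#' mTFP1/mEYFP pair (DPI constructs) and the YPet/mCherry pair (DPII
#' constructs). Fully overridable via \code{\link{mixing_matrix}}.
#'
#' @param pair \code{"mTFP1-mEYFP"} or \code{"YPet-mCherry"}.
#' @return a \code{mixing_matrix}.
#' @export
fret_pair_preset <- function(pair = c("mTFP1-mEYFP", "YPet-mCherry")) {
  pair <- match.arg(pair)
  switch(pair,
    "mTFP1-mEYFP" = mixing_matrix(eps_FD = 4.9e-3, eps_AD = 4.5e-4,
                                  eps_DF = 0.62,   eps_AF = 0.092,
                                  eps_DA = 2.4e-3, eps_FA = 3.8e-3),
    "YPet-mCherry" = mixing_matrix(eps_FD = 2.4e-3, eps_AD = 1.3e-4,
                                   eps_DF = 0.29,   eps_AF = 0.056,
                                   eps_DA = 0.038,  eps_FA = 0.13))
}

#' Three-channel acquisition container
#'
#' Holds the observed donor (donor-exc/donor-em), FRET (donor-exc/
#' acceptor-em) and acceptor (acceptor-exc/acceptor-em) images together with
#' calibration frames.
#'
#' @param D_obs,F_obs,A_obs 2-D intensity matrices, congruent shapes.
#' @param dark_frame dark-count calibration image (or scalar).
#' @param flat_frame flat-field calibration image (normalised to unit mean at
#'   correction time; or scalar 1).
#' @param pixel_size micrometres per pixel.
#' @return object of class \code{channel_triplet}.
#' @export
channel_triplet <- function(D_obs, F_obs, A_obs, dark_frame = 0,
                            flat_frame = 1, pixel_size = 0.16) {
  stopifnot(is.matrix(D_obs), identical(dim(D_obs), dim(F_obs)),
            identical(dim(D_obs), dim(A_obs)), pixel_size > 0)
  as_img <- function(x) if (is.matrix(x)) x else
    matrix(x, nrow(D_obs), ncol(D_obs))
  structure(list(D_obs = D_obs, F_obs = F_obs, A_obs = A_obs,
                 dark_frame = as_img(dark_frame),
                 flat_frame = as_img(flat_frame),
                 pixel_size = pixel_size),
            class = "channel_triplet")
}

#' @export
print.channel_triplet <- function(x, ...) {
  cat(sprintf("<channel_triplet> %d x %d px, pixel %.4f um\n",
              nrow(x$D_obs), ncol(x$D_obs), x$pixel_size))
  invisible(x)
}

#' Flat-field correction
#'
#' \code{(raw - dark) / flat_norm} elementwise, where \code{flat_norm} is the
#' calibration image from a uniformly fluorescent sample normalised to unit
#' mean. Negative results are permitted; downstream filters handle them.
#'
#' @param raw,dark,flat_norm congruent matrices (dark may be a scalar).
#' @return corrected image.
#' @export
flat_field_correct <- function(raw, dark, flat_norm) {
  if (any(flat_norm == 0)) stop("flat-field image contains zeros")
  (raw - dark) / flat_norm
}

# rolling-ball structuring function: height profile of a sphere of radius
# `r` px, zero at the apex and negative outward, truncated at the radius
.ball_profile <- function(diameter_px) {
  r <- diameter_px / 2
  half <- floor(r)
  d <- expand.grid(dr = -half:half, dc = -half:half)
  d2 <- d$dr^2 + d$dc^2
  keep <- d2 <= r^2
  list(dr = d$dr[keep], dc = d$dc[keep],
       h = sqrt(r^2 - d2[keep]) - r)
}

# grey erosion/dilation with a structuring function; borders use replicate
# padding so a constant image is invariant
.grey_morph <- function(img, prof, op = c("erode", "dilate")) {
  op <- match.arg(op)
  nr <- nrow(img); nc <- ncol(img)
  pad <- max(abs(c(prof$dr, prof$dc)))
  big <- matrix(NA_real_, nr + 2 * pad, nc + 2 * pad)
  big[pad + 1:nr, pad + 1:nc] <- img
  # replicate borders
  big[1:pad, ] <- big[rep(pad + 1L, pad), ]
  big[pad + nr + 1:pad, ] <- big[rep(pad + nr, pad), ]
  big[, 1:pad] <- big[, rep(pad + 1L, pad)]
  big[, pad + nc + 1:pad] <- big[, rep(pad + nc, pad)]
  acc <- matrix(if (op == "erode") Inf else -Inf, nr, nc)
  for (i in seq_along(prof$dr)) {
    sh <- big[pad + prof$dr[i] + 1:nr, pad + prof$dc[i] + 1:nc]
    if (op == "erode") acc <- pmin(acc, sh - prof$h[i])
    else acc <- pmax(acc, sh + prof$h[i])
  }
  acc
}

#' Rolling-ball background subtraction
#'
#' Estimates the smooth background as the grey-scale morphological opening of
#' the image with a spherical (ball) structuring element of the stated
#' diameter, and subtracts it. A constant image maps to (exactly) zero;
#' narrow spots ride on top of the ball and are retained.
#'
#' @param image numeric matrix.
#' @param diameter_px ball diameter in pixels (default 50, about 8 um at the
#'   epifluorescence pixel pitch this was designed for).
#' @return background-subtracted image (same dimensions).
#' @export
rolling_ball_subtract <- function(image, diameter_px = 50) {
  stopifnot(is.matrix(image), diameter_px >= 3)
  prof <- .ball_profile(diameter_px)
  bg <- .grey_morph(.grey_morph(image, prof, "erode"), prof, "dilate")
  image - bg
}

#' Linear spectral de-mixing of a three-channel acquisition
#'
#' Removes donor/acceptor cross-talk from flat-fielded, background-subtracted
#' channel images. The shipped epsilon matrix is interpreted as the FORWARD
#' mixing operator (observed = M x true), so de-mixing solves
#' \code{corrected = M^-1 x observed} per pixel — the physically sensible
#' reading, which is the default. \code{interpretation = "direct"} instead
#' applies M to the observations (the literal matrix product), provided only
#' for comparison.
#'
#' @param D,F_,A corrected-channel matrices (flat-fielded,
#'   background-subtracted), or a \code{channel_triplet} passed as \code{D}.
#' @param M a \code{mixing_matrix}.
#' @param interpretation \code{"inverse"} (default) or \code{"direct"}.
#' @return list with matrices \code{D_cor}, \code{F_cor}, \code{A_cor}.
#' @export
unmix_channels <- function(D, F_ = NULL, A = NULL, M,
                           interpretation = c("inverse", "direct")) {
  interpretation <- match.arg(interpretation)
  if (inherits(D, "channel_triplet")) {
    A <- D$A_obs; F_ <- D$F_obs; D <- D$D_obs
  }
  stopifnot(is.matrix(D), identical(dim(D), dim(F_)),
            identical(dim(D), dim(A)))
  Mm <- unclass(M)
  if (abs(det(Mm)) < 1e-12) stop("mixing matrix is singular")
  obs <- rbind(as.vector(D), as.vector(F_), as.vector(A))
  cor <- if (interpretation == "inverse") solve(Mm, obs) else Mm %*% obs
  shp <- dim(D)
  list(D_cor = matrix(cor[1, ], shp[1], shp[2]),
       F_cor = matrix(cor[2, ], shp[1], shp[2]),
       A_cor = matrix(cor[3, ], shp[1], shp[2]))
}

#' Ratiometric FRET index
#'
#' \code{I = 100 * F_cor / (D_cor + F_cor)}: the corrected sensitized
#' emission as a percentage of total donor-excited emission. A proxy for
#' FRET, not an absolute efficiency. No clamping; zero denominators yield
#' \code{NaN} (flagged downstream).
#'
#' @param d_cor,f_cor corrected donor and FRET intensities (vectorised).
#' @return FRET index in index units (0-100 for in-range signals).
#' @export
fret_index <- function(d_cor, f_cor) {
  100 * f_cor / (d_cor + f_cor)
}

#' Punctum segmentation from the corrected acceptor channel
#'
#' Thresholds \code{A_cor} at \code{mean + threshold_sd * SD} of a
#' user-supplied background region of the monolayer (default 4 SD), then
#' applies the same blur / nearest-local-maximum / minimum-area punctum
#' extraction as the FLIM pipeline.
#'
#' @param A_cor corrected acceptor image.
#' @param background_region logical matrix marking background pixels.
#' @param threshold_sd SD multiplier (default 4).
#' @param min_area minimal region size in px (default 9).
#' @param blur_sigma blur for the local-maximum assignment (px).
#' @return a \code{segmentation_map}.
#' @export
segment_from_acceptor <- function(A_cor, background_region, threshold_sd = 4,
                                  min_area = 9L, blur_sigma = 3) {
  stopifnot(is.matrix(A_cor), identical(dim(A_cor), dim(background_region)))
  bg <- A_cor[background_region > 0]
  if (!length(bg)) stop("background region is empty")
  thr <- mean(bg) + threshold_sd * stats::sd(bg)
  mask <- A_cor > thr
  labels <- if (any(mask)) {
    b <- gaussian_blur(A_cor, blur_sigma)
    drop_small_regions(assign_to_local_maxima(b, mask), min_area)
  } else matrix(0L, nrow(A_cor), ncol(A_cor))
  new_segmentation_map(labels, "acceptor-threshold",
                       list(threshold_sd = threshold_sd, min_area = min_area,
                            threshold = thr, blur_sigma = blur_sigma))
}

#' Full ratiometric FRET analysis of one acquisition
#'
#' Runs the fixed processing chain: flat-field correction of each channel,
#' rolling-ball background subtraction, spectral de-mixing, acceptor-channel
#' segmentation, and per-punctum FRET indices computed from SUMMED corrected
#' intensities over each punctum's pixels (photon weighting; matches the
#' total-intensity filter convention). Puncta with total corrected acceptor
#' signal below \code{min_total_A} are flagged \code{dim}; indices outside
#' [0, 100] are flagged \code{extreme_value}; a user-provided manual QC
#' column (\code{misaligned}) is honoured but never inferred.
#'
#' @param triplet a \code{channel_triplet} (raw observations + calibration).
#' @param M a \code{mixing_matrix}.
#' @param background_region logical background mask for segmentation.
#' @param min_total_A dim-punctum threshold on the summed corrected acceptor
#'   intensity (a.u.; presets: 5000 for DPI-TS, 2000 for DPII-TS).
#' @param rolling_ball_diameter background-filter ball diameter, px.
#' @param threshold_sd segmentation threshold in background-SD units.
#' @param min_area minimal punctum area, px.
#' @param misaligned optional logical vector (one per punctum label) marking
#'   manually identified channel-misalignment regions.
#' @return data.frame: image-punctum table with columns label, x_um, y_um,
#'   area_px, sumD, sumF, sumA, fret_index, flags, included.
#' @export
analyze_ratiometric_image <- function(triplet, M, background_region,
                                      min_total_A = 2000,
                                      rolling_ball_diameter = 50,
                                      threshold_sd = 4, min_area = 9L,
                                      misaligned = NULL) {
  stopifnot(inherits(triplet, "channel_triplet"))
  flat <- triplet$flat_frame / mean(triplet$flat_frame)
  ff <- function(ch) flat_field_correct(ch, triplet$dark_frame, flat)
  rb <- function(ch) rolling_ball_subtract(ch, rolling_ball_diameter)
  cor <- unmix_channels(rb(ff(triplet$D_obs)), rb(ff(triplet$F_obs)),
                        rb(ff(triplet$A_obs)), M = M)
  seg <- segment_from_acceptor(cor$A_cor, background_region,
                               threshold_sd = threshold_sd,
                               min_area = min_area)
  labels <- seg$labels
  K <- max(0L, max(labels))
  cent <- label_centroids_um(labels, triplet$pixel_size)
  rows <- vector("list", K)
  for (k in seq_len(K)) {
    pix <- labels == k
    sD <- sum(cor$D_cor[pix]); sF <- sum(cor$F_cor[pix])
    sA <- sum(cor$A_cor[pix])
    I <- fret_index(sD, sF)
    flags <- character(0)
    if (sA < min_total_A) flags <- c(flags, "dim")
    if (!is.finite(I) || I < 0 || I > 100)
      flags <- c(flags, "extreme_value")
    if (!is.null(misaligned) && isTRUE(misaligned[k]))
      flags <- c(flags, "misaligned")
    ci <- cent[cent$label == k, ]
    rows[[k]] <- data.frame(label = k, x_um = ci$x_um, y_um = ci$y_um,
                            area_px = ci$area_px, sumD = sD, sumF = sF,
                            sumA = sA, fret_index = I,
                            flags = paste(flags, collapse = ";"),
                            included = length(flags) == 0)
  }
  if (K == 0) {
    return(data.frame(label = integer(0), x_um = numeric(0),
                      y_um = numeric(0), area_px = integer(0),
                      sumD = numeric(0), sumF = numeric(0), sumA = numeric(0),
                      fret_index = numeric(0), flags = character(0),
                      included = logical(0)))
  }
  do.call(rbind, rows)
}

#' Simulate a three-channel sensitized-emission scene with ground truth
#'
#' Renders puncta with per-punctum true FRET index and brightness, builds the
#' true channel images (\code{D = S (1 - I/100)}, \code{F = S I/100},
#' \code{A = S * acceptor_ratio}), applies the forward mixing model
#' \code{observed = M x true}, multiplies by a vignette, adds a dark offset
#' and optional noise.
#'
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param puncta data.frame with columns row, col, sigma_px, peak (total
#'   donor-excited brightness S at the centre pixel) and \code{fret_index}
#'   (true index, 0-100).
#' @param M a \code{mixing_matrix} (forward operator).
#' @param vignette matrix (unit-mean flat-field shape) or 1 for flat.
#' @param dark scalar or matrix dark offset.
#' @param acceptor_ratio true acceptor-channel brightness per unit S.
#' @param background_level true background signal level.
#' @param noise_sd Gaussian read-noise SD (0 = noiseless).
#' @param pixel_size micrometres per pixel.
#' @param seed integer seed.
#' @return list with \code{triplet} (a \code{channel_triplet} carrying the
#'   dark and flat calibration frames) and \code{truth} (per-punctum table
#'   with true index and pixel ownership in \code{owner}).
#' @export
simulate_three_channel_scene <- function(shape = c(64L, 64L), puncta, M,
                                         vignette = 1, dark = 0,
                                         acceptor_ratio = 1,
                                         background_level = 0,
                                         noise_sd = 0,
                                         pixel_size = 0.16, seed = NULL) {
  if (!is.null(seed)) set.seed(as.integer(seed))
  stopifnot(all(c("row", "col", "sigma_px", "peak", "fret_index") %in%
                  names(puncta)))
  Mm <- unclass(M)
  if (abs(det(Mm)) < 1e-12) stop("mixing matrix is singular")
  sp <- render_spots(shape, puncta, allow_overlap = FALSE)
  S <- sp$intensity + background_level
  idx_map <- matrix(0, shape[1], shape[2])
  pos <- sp$owner > 0
  idx_map[pos] <- puncta$fret_index[sp$owner[pos]]
  D_true <- S * (1 - idx_map / 100)
  F_true <- S * idx_map / 100
  A_true <- S * acceptor_ratio
  obs <- Mm %*% rbind(as.vector(D_true), as.vector(F_true),
                      as.vector(A_true))
  vmat <- if (is.matrix(vignette)) vignette / mean(vignette) else
    matrix(1, shape[1], shape[2])
  dmat <- if (is.matrix(dark)) dark else matrix(dark, shape[1], shape[2])
  mk <- function(r) {
    img <- matrix(obs[r, ], shape[1], shape[2]) * vmat + dmat
    if (noise_sd > 0) img <- img + matrix(stats::rnorm(length(img), 0,
                                                       noise_sd),
                                          shape[1], shape[2])
    img
  }
  trip <- channel_triplet(mk(1), mk(2), mk(3), dark_frame = dmat,
                          flat_frame = vmat, pixel_size = pixel_size)
  truth <- data.frame(label = seq_len(nrow(puncta)),
                      x_um = (puncta$col - 0.5) * pixel_size,
                      y_um = (puncta$row - 0.5) * pixel_size,
                      fret_index = puncta$fret_index,
                      peak = puncta$peak)
  list(triplet = trip, truth = truth, owner = sp$owner)
}
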