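# ---- low-level image helpers shared by the FLIM and ratiometric pipelines ---
# Images are plain numeric matrices indexed [row, col]; pixel (1,1) is the
# top-left corner. Physical position of pixel (r, c) is ((c-0.5), (r-0.5)) *
# pixel_size in (x, y) micrometres.

gaussian_kernel_1d <- function(sigma) {
  stopifnot(sigma > 0)
  half <- max(1L, ceiling(3 * sigma))
  x <- seq(-half, half)
  k <- exp(-x^2 / (2 * sigma^2))
  k / sum(k)
}

#' Gaussian blur of an image matrix
#'
#' Separable Gaussian convolution with kernel truncated at 3 sigma. Image
#' borders are handled by renormalising the kernel mass that falls inside the
#' image, so a constant image stays exactly constant.
#'
#' @param img numeric matrix.
#' @param sigma standard deviation in pixels.
#' @return blurred matrix of the same dimensions.
#' @export
gaussian_blur <- function(img, sigma) {
  stopifnot(is.matrix(img))
  if (sigma <= 0) return(img)
  k <- gaussian_kernel_1d(sigma)
  blur_axis <- function(m, k) {
    # convolve each column of m with k, renormalised at the borders
    n <- nrow(m)
    half <- (length(k) - 1L) %/% 2L
    out <- matrix(0, n, ncol(m))
    wsum <- numeric(n)
    for (o in seq_along(k)) {
      off <- o - half - 1L
      src <- seq_len(n) + off
      ok <- src >= 1L & src <= n
      out[ok, ] <- out[ok, ] + k[o] * m[src[ok], , drop = FALSE]
      wsum[ok] <- wsum[ok] + k[o]
    }
    out / wsum
  }
  t(blur_axis(t(blur_axis(img, k)), k))
}

#' Difference-of-Gaussians band-pass filter
#'
#' Enhances features in a diameter range by subtracting a wide Gaussian blur
#' from a narrow one. Sigmas follow the FWHM convention
#' \code{sigma = diameter / 2.355}.
#'
#' @param img numeric matrix.
#' @param d_min,d_max feature diameter range in pixels.
#' @return filtered matrix (zero mean over flat regions; offsets removed).
#' @export
band_pass_dog <- function(img, d_min = 3, d_max = 10) {
  stopifnot(d_min > 0, d_min < d_max)
  gaussian_blur(img, d_min / 2.355) - gaussian_blur(img, d_max / 2.355)
}

#' Otsu threshold of a set of intensity values
#'
#' Histogram-based between-class variance maximisation over 256 levels.
#'
#' @param values numeric vector (e.g. the blurred pixels inside a mask).
#' @return scalar threshold on the input intensity scale.
#' @export
otsu_threshold <- function(values) {
  values <- values[is.finite(values)]
  stopifnot(length(values) > 1)
  rng <- range(values)
  if (diff(rng) == 0) return(rng[1])
  nb <- 256L
  h <- tabulate(pmin(nb, 1L + floor((values - rng[1]) / diff(rng) * nb)), nb)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(nb) - 0.5) / nb * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[nb]
  sb <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sb[!is.finite(sb)] <- -Inf
  mids[which.max(sb)]
}

# Assign every pixel of `mask` to the nearest local maximum of `guide` by
# deterministic hill-climbing (8-connectivity, pointer jumping). Ties between
# equal-valued neighbours are broken toward the smallest linear (column-major)
# index, so labelling is deterministic. Returns an integer matrix of labels
# (0 outside mask), labels renumbered 1..K in order of first (column-major)
# occurrence.
assign_to_local_maxima <- function(guide, mask) {
  stopifnot(is.matrix(guide), identical(dim(guide), dim(mask)))
  nr <- nrow(guide); nc <- ncol(guide); n <- nr * nc
  # pad with -Inf so border pixels never climb outside
  g <- matrix(-Inf, nr + 2L, nc + 2L)
  g[2:(nr + 1L), 2:(nc + 1L)] <- guide
  g[2:(nr + 1L), 2:(nc + 1L)][!mask] <- -Inf
  best_val <- guide
  best_val[!mask] <- -Inf
  ptr <- matrix(seq_len(n), nr, nc)        # linear index of best move target
  offs <- expand.grid(dr = -1:1, dc = -1:1)
  offs <- offs[!(offs$dr == 0 & offs$dc == 0), ]
  # visit neighbours in increasing linear-index order of the *target* so that
  # later strict '>' comparisons keep the smallest-index target on ties
  ord <- order(offs$dc, offs$dr)
  for (i in ord) {
    dr <- offs$dr[i]; dc <- offs$dc[i]
    nb <- g[(2 + dr):(nr + 1 + dr), (2 + dc):(nc + 1 + dc)]
    nb_idx <- matrix(seq_len(n), nr, nc) + dr + dc * nr
    upd <- nb > best_val
    # neighbours visited in increasing target index: strictly-greater keeps
    # the first (smallest-index) maximal neighbour
    best_val[upd] <- nb[upd]
    ptr[upd] <- nb_idx[upd]
  }
  p <- as.integer(ptr)
  p[!mask] <- which(!mask)  # background points to itself
  # pointer jumping until fixed point
  repeat {
    p2 <- p[p]
    if (identical(p2, p)) break
    p <- p2
  }
  lab <- integer(n)
  roots <- p[as.logical(mask)]
  uroots <- unique(roots)                # column-major first-occurrence order
  lab[as.logical(mask)] <- match(roots, uroots)
  matrix(lab, nr, nc)
}

# Drop labelled regions smaller than min_area pixels and renumber 1..K.
drop_small_regions <- function(labels, min_area) {
  if (!any(labels > 0)) return(labels)
  sizes <- tabulate(labels[labels > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(labels), ncol(labels))
  if (length(keep)) {
    remap <- integer(length(sizes))
    remap[keep] <- seq_along(keep)
    pos <- labels > 0
    out[pos] <- remap[labels[pos]]
  }
  out
}

# Render isotropic Gaussian spots (truncated at 3 sigma) onto a zero image.
# puncta: data.frame with columns row, col (pixel centres, 1-based, may be
# fractional), sigma_px, peak. Returns list(intensity, owner) where owner is
# the 1-based punctum index covering each pixel (0 = none). Overlap of two
# spots' 3-sigma supports raises an error when disallowed.
render_spots <- function(shape, puncta, allow_overlap = FALSE) {
  img <- matrix(0, shape[1], shape[2])
  owner <- matrix(0L, shape[1], shape[2])
  for (i in seq_len(nrow(puncta))) {
    r0 <- puncta$row[i]; c0 <- puncta$col[i]
    s <- puncta$sigma_px[i]; pk <- puncta$peak[i]
    rr <- max(1L, floor(r0 - 3 * s)):min(shape[1], ceiling(r0 + 3 * s))
    cc <- max(1L, floor(c0 - 3 * s)):min(shape[2], ceiling(c0 + 3 * s))
    d2 <- outer((rr - r0)^2, (cc - c0)^2, `+`)
    prof <- pk * exp(-d2 / (2 * s^2))
    prof[d2 > (3 * s)^2] <- 0
    hit <- prof > 0
    if (!allow_overlap && any(owner[rr, cc][hit] > 0))
      stop("puncta ", i, " overlaps an earlier punctum (ambiguous ground truth)")
    img[rr, cc] <- img[rr, cc] + prof
    ow <- owner[rr, cc]
    ow[hit] <- i
    owner[rr, cc] <- ow
  }
  list(intensity = img, owner = owner)
}

# Centroid of a label in physical micrometres (x = col, y = row convention).
label_centroids_um <- function(labels, pixel_size) {
  ks <- sort(unique(labels[labels > 0]))
  out <- data.frame(label = ks, x_um = rep(NA_real_, length(ks)),
                    y_um = rep(NA_real_, length(ks)),
                    area_px = rep(NA_integer_, length(ks)))
  for (j in seq_along(ks)) {
    idx <- which(labels == ks[j], arr.ind = TRUE)
    out$x_um[j] <- mean(idx[, 2] - 0.5) * pixel_size
    out$y_um[j] <- mean(idx[, 1] - 0.5) * pixel_size
    out$area_px[j] <- nrow(idx)
  }
  out
}
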