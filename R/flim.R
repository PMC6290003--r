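# ---- FLIM containers, punctum segmentation and lifetime/FRET analysis

#' Construct a FLIM image
#'
#' Container for a TCSPC-FLIM acquisition: a per-pixel photon-count histogram
#' stack plus calibration. The intensity image is the photon sum over time
#' bins and is recomputed (and cross-checked when supplied).
#'
#' @param photons 3-D integer array \code{[row, col, time_bin]} of counts.
#' @param bin_width time-bin width in ns (> 0).
#' @param pixel_size pixel pitch in micrometres (> 0).
#' @param intensity optional 2-D photon-sum image; validated if given.
#' @return object of class \code{flim_image}.
#' @export
flim_image <- function(photons, bin_width, pixel_size, intensity = NULL) {
  stopifnot(length(dim(photons)) == 3, bin_width > 0, pixel_size > 0)
  if (any(photons < 0)) stop("photon counts must be non-negative")
  isum <- apply(photons, c(1, 2), sum)
  if (!is.null(intensity) &&
      max(abs(intensity - isum)) > 1e-6 * max(1, max(isum)))
    stop("supplied intensity image does not equal the photon sum over bins")
  structure(list(photons = photons, bin_width = bin_width,
                 pixel_size = pixel_size, intensity = isum),
            class = "flim_image")
}

#' @export
print.flim_image <- function(x, ...) {
  d <- dim(x$photons)
  cat(sprintf(
    "<flim_image> %d x %d px, %d bins x %.4f ns, %.3g photons total\n",
    d[1], d[2], d[3], x$bin_width, sum(x$intensity)))
  invisible(x)
}

new_segmentation_map <- function(labels, provenance, params) {
  structure(list(labels = labels, provenance = provenance, params = params),
            class = "segmentation_map")
}

#' @export
print.segmentation_map <- function(x, ...) {
  cat(sprintf("<segmentation_map> %d puncta (%s)\n",
              max(0L, max(x$labels)), x$provenance))
  invisible(x)
}

#' Automatic punctum segmentation of an intensity image
#'
#' Band-pass filters the image (difference of Gaussians tuned to a feature
#' diameter range), thresholds at \code{mean + threshold_sd * SD} of the
#' filtered image, assigns connected supra-threshold pixels to the nearest
#' local intensity maximum by deterministic hill-climbing, and removes
#' regions smaller than \code{min_area} pixels. This is the whole-image mode
#' used for epithelial monolayers where junctional puncta dominate.
#'
#' @param intensity non-negative 2-D matrix (photon-sum image).
#' @param band_pass feature diameter range \code{c(d_min, d_max)} in px.
#' @param threshold_sd threshold in SD units above the mean of the filtered
#'   image (default 1).
#' @param min_area minimal region size in pixels (default 9).
#' @return a \code{segmentation_map}; an image with no supra-threshold
#'   features yields an empty (all-zero) map.
#' @export
segment_puncta_auto <- function(intensity, band_pass = c(3, 10),
                                threshold_sd = 1, min_area = 9L) {
  stopifnot(is.matrix(intensity), all(intensity >= 0))
  f <- band_pass_dog(intensity, band_pass[1], band_pass[2])
  thr <- mean(f) + threshold_sd * stats::sd(f)
  # a featureless (flat) image leaves only rounding noise after the DoG
  featureless <- diff(range(f)) <= 1e-9 * max(1, diff(range(intensity)))
  mask <- if (featureless) matrix(FALSE, nrow(f), ncol(f)) else f > thr
  labels <- if (any(mask)) {
    drop_small_regions(assign_to_local_maxima(f, mask), min_area)
  } else matrix(0L, nrow(intensity), ncol(intensity))
  new_segmentation_map(labels, "auto",
                       list(band_pass = band_pass, threshold_sd = threshold_sd,
                            min_area = min_area, threshold = thr))
}

#' Punctum segmentation within a manually drawn junction mask
#'
#' Restricts segmentation to a hand-drawn cell-cell junction mask: the image
#' is Gaussian-blurred (default sigma 3 px), bright connected regions inside
#' the mask are isolated (Otsu threshold on the blurred in-mask pixels —
#' exposed because the brightness criterion is a lab convention), pixels are
#' assigned to the nearest local maximum and small regions removed.
#'
#' @param intensity 2-D matrix.
#' @param manual_mask logical matrix of the same shape.
#' @param blur_sigma Gaussian blur sigma in px (default 3).
#' @param min_area minimal region size in pixels (default 9).
#' @param threshold optional explicit brightness threshold on the blurred
#'   image; default is Otsu within the mask.
#' @return a \code{segmentation_map} (empty when the mask is empty).
#' @export
segment_puncta_masked <- function(intensity, manual_mask, blur_sigma = 3,
                                  min_area = 9L, threshold = NULL) {
  stopifnot(is.matrix(intensity), identical(dim(intensity), dim(manual_mask)))
  mask0 <- manual_mask > 0
  if (!any(mask0)) {
    return(new_segmentation_map(matrix(0L, nrow(intensity), ncol(intensity)),
                                "manual-masked", list(blur_sigma = blur_sigma,
                                                      min_area = min_area)))
  }
  b <- gaussian_blur(intensity, blur_sigma)
  if (is.null(threshold)) threshold <- otsu_threshold(b[mask0])
  mask <- mask0 & (b > threshold)
  labels <- if (any(mask)) {
    drop_small_regions(assign_to_local_maxima(b, mask), min_area)
  } else matrix(0L, nrow(intensity), ncol(intensity))
  new_segmentation_map(labels, "manual-masked",
                       list(blur_sigma = blur_sigma, min_area = min_area,
                            threshold = threshold))
}

#' Simulate a FLIM scene with ground truth
#'
#' Renders Gaussian puncta (truncated at 3 sigma) with per-punctum true
#' lifetimes onto a uniform background, then draws a full TCSPC stack whose
#' per-pixel decay uses the lifetime of the covering punctum (the background
#' lifetime elsewhere). Overlapping puncta with different lifetimes are
#' rejected because their ground truth would be ambiguous.
#'
#' @param shape image dimensions \code{c(rows, cols)}.
#' @param puncta data.frame with columns \code{row}, \code{col} (pixel
#'   centres), \code{sigma_px}, \code{peak} (expected photons at the centre
#'   pixel) and \code{lifetime} (ns).
#' @param pixel_size micrometres per pixel; default matches a 512 px image
#'   spanning 70.85 um.
#' @param background_level expected background photons per pixel.
#' @param background_lifetime lifetime of background photons, ns.
#' @param n_bins,window time axis (defaults 256 bins over 12.5 ns).
#' @param noise \code{"poisson"} or \code{"none"} (expected values).
#' @param seed integer seed.
#' @return list with \code{image} (a \code{flim_image}) and \code{truth}
#'   (data.frame: label, x_um, y_um, area_px, lifetime, expected_photons).
#' @export
simulate_flim_scene <- function(shape = c(64L, 64L), puncta,
                                pixel_size = 70.85 / 512,
                                background_level = 0.5,
                                background_lifetime = 1.5,
                                n_bins = 256L, window = 12.5,
                                noise = c("poisson", "none"), seed = NULL) {
  noise <- match.arg(noise)
  if (!is.null(seed)) set.seed(as.integer(seed))
  if (missing(puncta) || is.null(puncta))
    puncta <- data.frame(row = numeric(0), col = numeric(0),
                         sigma_px = numeric(0), peak = numeric(0),
                         lifetime = numeric(0))
  stopifnot(all(c("row", "col", "sigma_px", "peak", "lifetime") %in%
                  names(puncta)) || nrow(puncta) == 0)
  if (nrow(puncta) > 0 &&
      (any(puncta$row < 1) || any(puncta$row > shape[1]) ||
       any(puncta$col < 1) || any(puncta$col > shape[2])))
    stop("all puncta centres must lie inside the image")
  sp <- render_spots(shape, puncta, allow_overlap = FALSE)
  intensity <- sp$intensity + background_level
  dt <- window / n_bins
  tc <- (seq_len(n_bins) - 0.5) * dt
  shape_of <- function(tau) { s <- exp(-tc / tau); s / sum(s) }
  photons <- array(0, dim = c(shape[1], shape[2], n_bins))
  taus <- c(background_lifetime, puncta$lifetime)
  zones <- sp$owner + 1L   # 1 = background, i+1 = punctum i
  npix <- shape[1] * shape[2]
  for (z in sort(unique(as.integer(zones)))) {
    pix <- which(zones == z)
    lam <- outer(intensity[pix], shape_of(taus[z]))   # npix_sel x nbins
    vals <- if (noise == "poisson") stats::rpois(length(lam), lam) else lam
    idx <- rep(pix, times = n_bins) +
      rep((seq_len(n_bins) - 1L) * npix, each = length(pix))
    photons[idx] <- vals
  }
  img <- flim_image(photons, bin_width = dt, pixel_size = pixel_size)
  truth <- if (nrow(puncta) > 0) {
    data.frame(label = seq_len(nrow(puncta)),
               x_um = (puncta$col - 0.5) * pixel_size,
               y_um = (puncta$row - 0.5) * pixel_size,
               area_px = as.integer(tabulate(sp$owner[sp$owner > 0],
                                             nrow(puncta))),
               lifetime = puncta$lifetime,
               expected_photons = vapply(seq_len(nrow(puncta)), function(i)
                 sum(intensity[sp$owner == i]), numeric(1)))
  } else {
    data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
               area_px = integer(0), lifetime = numeric(0),
               expected_photons = numeric(0))
  }
  list(image = img, truth = truth, owner = sp$owner)
}

#' Lifetime and FRET-efficiency analysis of a segmented FLIM image
#'
#' Fits the Poisson maximum-likelihood decay model to photon histograms and
#' converts lifetimes to FRET efficiencies against a matched donor-only
#' lifetime. In \code{per_punctum} mode each labelled region is fitted from
#' its summed decay and filtered: regions below the photon minimum are
#' flagged \code{low_photons}, efficiencies outside [0, 1] are flagged
#' \code{extreme_value}; flagged records carry their values but are marked
#' excluded. In \code{bulk} mode all photons under the segmentation mask are
#' pooled into a single fit and no exclusions apply.
#'
#' @param img a \code{flim_image}.
#' @param seg a \code{segmentation_map}.
#' @param tau_d donor-only lifetime in ns (see
#'   \code{\link{donor_lifetime_presets}}).
#' @param mode \code{"per_punctum"} or \code{"bulk"}.
#' @param min_photons per-punctum photon minimum (see
#'   \code{\link{photon_minimum_presets}}).
#' @param offset_ns fit-start offset after the peak bin, ns.
#' @return \code{per_punctum}: data.frame with one row per punctum (label,
#'   x_um, y_um, area_px, photons, tau_ns, fret_efficiency, flags,
#'   included). \code{bulk}: list with the pooled \code{decay_fit}, the
#'   efficiency and the photon count.
#' @export
analyze_flim_image <- function(img, seg, tau_d,
                               mode = c("per_punctum", "bulk"),
                               min_photons = 175L, offset_ns = 0.56) {
  mode <- match.arg(mode)
  stopifnot(inherits(img, "flim_image"), inherits(seg, "segmentation_map"))
  labels <- seg$labels
  stopifnot(identical(dim(labels), dim(img$intensity)))
  nb <- dim(img$photons)[3]
  pages <- matrix(img$photons, ncol = nb)   # pixels x bins
  sum_decay <- function(pix) colSums(pages[pix, , drop = FALSE])
  if (mode == "bulk") {
    pix <- which(labels > 0)
    if (!length(pix)) stop("empty segmentation: no photons for a bulk fit")
    fit <- fit_decay_ml(sum_decay(pix), offset_ns = offset_ns,
                        bin_width = img$bin_width)
    return(list(fit = fit, fret_efficiency = fret_efficiency(fit$tau, tau_d),
                photons = sum(pages[pix, ]), n_pixels = length(pix)))
  }
  ks <- seq_len(max(0L, max(labels)))
  cent <- label_centroids_um(labels, img$pixel_size)
  out <- data.frame(label = integer(0), x_um = numeric(0), y_um = numeric(0),
                    area_px = integer(0), photons = numeric(0),
                    tau_ns = numeric(0), fret_efficiency = numeric(0),
                    flags = character(0), included = logical(0))
  for (k in ks) {
    pix <- which(labels == k)
    dk <- sum_decay(pix)
    fit <- fit_decay_ml(dk, offset_ns = offset_ns, bin_width = img$bin_width)
    E <- if (is.na(fit$tau)) NA_real_ else fret_efficiency(fit$tau, tau_d)
    flags <- character(0)
    if (sum(dk) < min_photons) flags <- c(flags, "low_photons")
    if (!is.na(E) && (E < 0 || E > 1)) flags <- c(flags, "extreme_value")
    if (!fit$converged) flags <- c(flags, "no_convergence")
    ci <- cent[cent$label == k, ]
    out <- rbind(out, data.frame(
      label = k, x_um = ci$x_um, y_um = ci$y_um, area_px = ci$area_px,
      photons = sum(dk), tau_ns = fit$tau, fret_efficiency = E,
      flags = paste(flags, collapse = ";"),
      included = length(flags) == 0))
  }
  out
}
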