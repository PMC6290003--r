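# ---- image-grouped tension statistics (mixed models, KS, boxplot summary)

#' Simulate a grouped puncta FRET table
#'
#' Draws a two-arm (tension sensor vs truncated control) table with the
#' grouping structure the mixed model assumes: every image contributes a
#' normal random intercept, and puncta scatter around the arm mean plus
#' their image's intercept. The sensor arm mean is the control mean minus
#' \code{true_delta} (tension lowers sensor FRET), so the estimand
#' delta = ctrl - TS equals \code{true_delta}.
#'
#' @param n_images_per_arm images per arm (>= 1).
#' @param puncta_per_image puncta per image (>= 1).
#' @param true_delta true ctrl - TS difference, FRET-index units.
#' @param image_sd SD of the per-image random intercept.
#' @param punctum_sd residual (per-punctum) SD.
#' @param ctrl_mean control-arm mean index (default 50).
#' @param seed integer seed.
#' @return data.frame with columns \code{value}, \code{isTensionSensor}
#'   (0/1) and \code{imageNumber} (unique across arms).
#' @export
simulate_grouped_fret_table <- function(n_images_per_arm, puncta_per_image,
                                        true_delta, image_sd, punctum_sd,
                                        ctrl_mean = 50, seed = NULL) {
  stopifnot(n_images_per_arm >= 1, puncta_per_image >= 1,
            image_sd >= 0, punctum_sd >= 0)
  if (!is.null(seed)) set.seed(as.integer(seed))
  rows <- list()
  img <- 0L
  for (arm in c(0L, 1L)) {
    arm_mean <- if (arm == 1L) ctrl_mean - true_delta else ctrl_mean
    for (i in seq_len(n_images_per_arm)) {
      img <- img + 1L
      b <- stats::rnorm(1, 0, image_sd)
      rows[[img]] <- data.frame(
        value = stats::rnorm(puncta_per_image, arm_mean + b, punctum_sd),
        isTensionSensor = arm, imageNumber = img)
    }
  }
  do.call(rbind, rows)
}

.check_obs <- function(obs) {
  stopifnot(all(c("value", "isTensionSensor", "imageNumber") %in% names(obs)))
  if (any(!is.finite(obs$value))) stop("values must be finite")
  if (length(unique(obs$isTensionSensor)) < 2)
    stop("both arms (isTensionSensor = 0 and 1) must be present")
  invisible(obs)
}

#' Image-grouped sensor-vs-control FRET difference
#'
#' Fits \code{value ~ isTensionSensor + (1 | imageNumber)} by REML and
#' reports delta = ctrl - TS (the negative of the sensor coefficient), so
#' positive delta means molecular tension. Wald confidence intervals and
#' normal-approximation p-values are used on the fixed effect; the grouped
#' random intercept makes the interval wider — and honest — relative to
#' treating puncta as independent. With a single image the model is
#' degenerate and a pooled OLS fallback is used (flagged).
#'
#' @param obs data.frame with \code{value}, \code{isTensionSensor} (0/1) and
#'   \code{imageNumber}; extra columns are ignored.
#' @param ci_level confidence level (default 0.95).
#' @return object of class \code{grouped_difference}: list with
#'   \code{delta}, \code{ci_low}, \code{ci_high}, \code{p_value},
#'   \code{group_sd}, \code{residual_sd}, \code{n_puncta}, \code{n_images},
#'   \code{ci_level}, \code{flags}.
#' @export
fit_grouped_difference <- function(obs, ci_level = 0.95) {
  .check_obs(obs)
  n_img <- length(unique(obs$imageNumber))
  flags <- character(0)
  if (n_img < 2) {
    fit <- stats::lm(value ~ isTensionSensor, data = obs)
    co <- summary(fit)$coefficients
    est <- co["isTensionSensor", 1]; se <- co["isTensionSensor", 2]
    g_sd <- 0; r_sd <- summary(fit)$sigma
    flags <- c(flags, "pooled_ols")
    warning("single image: grouped variance is degenerate, ",
            "falling back to pooled OLS")
  } else {
    fit <- suppressMessages(lme4::lmer(
      value ~ isTensionSensor + (1 | imageNumber), data = obs, REML = TRUE))
    est <- lme4::fixef(fit)[["isTensionSensor"]]
    se <- unname(sqrt(diag(as.matrix(stats::vcov(fit))))[2])
    vc <- as.data.frame(lme4::VarCorr(fit))
    g_sd <- vc$sdcor[vc$grp == "imageNumber"]
    r_sd <- vc$sdcor[vc$grp == "Residual"]
    if (lme4::isSingular(fit)) flags <- c(flags, "boundary_variance")
  }
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  delta <- -est                           # ctrl - TS sign convention
  p <- 2 * stats::pnorm(-abs(est / se))
  structure(list(delta = delta, ci_low = delta - z * se,
                 ci_high = delta + z * se, p_value = p,
                 group_sd = g_sd, residual_sd = r_sd,
                 n_puncta = nrow(obs), n_images = n_img,
                 ci_level = ci_level, flags = flags),
            class = "grouped_difference")
}

#' @export
print.grouped_difference <- function(x, ...) {
  cat(sprintf(
    "<grouped_difference> delta = %.3f [%.3f, %.3f] (%.0f%% CI), p = %.3g\n",
    x$delta, x$ci_low, x$ci_high, 100 * x$ci_level, x$p_value))
  cat(sprintf("  %d puncta / %d images; image SD %.3f, residual SD %.3f%s\n",
              x$n_puncta, x$n_images, x$group_sd, x$residual_sd,
              if (length(x$flags)) paste0(" [", paste(x$flags,
                                                      collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Drug-interaction contrast for the grouped FRET model
#'
#' Fits \code{value ~ isTensionSensor * isDrugWell + (1 | imageNumber)} and
#' reports the interaction coefficient: the drug-induced change in the
#' sensor-vs-control difference (model scale; negate for the ctrl - TS
#' tension convention). All four arm-by-well cells must be populated.
#'
#' @param obs data.frame with \code{value}, \code{isTensionSensor},
#'   \code{isDrugWell} (0 = solvent control) and \code{imageNumber}.
#' @param ci_level confidence level (default 0.95).
#' @return list with \code{estimate} (interaction coefficient),
#'   \code{ci_low}, \code{ci_high}, \code{p_value}, \code{n_puncta},
#'   \code{n_images}, \code{flags}.
#' @export
fit_drug_interaction <- function(obs, ci_level = 0.95) {
  .check_obs(obs)
  if (!"isDrugWell" %in% names(obs)) stop("isDrugWell column is required")
  cells <- table(obs$isTensionSensor, obs$isDrugWell)
  for (a in c("0", "1")) for (w in c("0", "1")) {
    if (!a %in% rownames(cells) || !w %in% colnames(cells) ||
        cells[a, w] == 0)
      stop(sprintf("empty design cell: isTensionSensor = %s, isDrugWell = %s",
                   a, w))
  }
  flags <- character(0)
  fit <- suppressMessages(lme4::lmer(
    value ~ isTensionSensor * isDrugWell + (1 | imageNumber),
    data = obs, REML = TRUE))
  cn <- "isTensionSensor:isDrugWell"
  est <- lme4::fixef(fit)[[cn]]
  V <- as.matrix(stats::vcov(fit))
  se <- sqrt(V[cn, cn])
  if (lme4::isSingular(fit)) flags <- c(flags, "boundary_variance")
  z <- stats::qnorm(1 - (1 - ci_level) / 2)
  list(estimate = est, ci_low = est - z * se, ci_high = est + z * se,
       p_value = 2 * stats::pnorm(-abs(est / se)),
       n_puncta = nrow(obs), n_images = length(unique(obs$imageNumber)),
       ci_level = ci_level, flags = flags)
}

#' Distance- or angle-binned FRET differences against a pooled control
#'
#' Bins the tension-sensor tracks by recoil distance, recoil angle, or
#' distance crossed with orientation, and contrasts EACH bin's sensor puncta
#' against the entire (un-binned) control pool with the image-grouped model.
#' Per-bin intervals default to 68% (one SD equivalent); the control-pool
#' mean is reported with a 95% interval.
#'
#' @param ts data.frame of sensor observations: \code{value},
#'   \code{imageNumber}, and the binning variable (\code{d_r_um},
#'   \code{alpha_r_deg} and/or \code{orientation}).
#' @param ctrl_pool data.frame of control observations: \code{value},
#'   \code{imageNumber}.
#' @param bin_by \code{"d_r"}, \code{"alpha_r"} or \code{"d_r_x_orientation"}.
#' @param edges bin edges (um or degrees) for the continuous variable.
#' @param ci_level per-bin confidence level (default 0.68).
#' @return list with \code{bins} (data.frame: bin label, centre, n_ts,
#'   delta, ci_low, ci_high, p_value) and \code{ctrl} (pooled control mean
#'   with 95% CI). Empty bins are skipped and listed in \code{skipped}.
#' @export
binned_delta <- function(ts, ctrl_pool,
                         bin_by = c("d_r", "alpha_r", "d_r_x_orientation"),
                         edges = NULL, ci_level = 0.68) {
  bin_by <- match.arg(bin_by)
  stopifnot(all(c("value", "imageNumber") %in% names(ts)),
            all(c("value", "imageNumber") %in% names(ctrl_pool)))
  var <- switch(bin_by, d_r = "d_r_um", alpha_r = "alpha_r_deg",
                d_r_x_orientation = "d_r_um")
  if (!var %in% names(ts)) stop("ts lacks column ", var)
  if (is.null(edges))
    edges <- if (var == "d_r_um") seq(0, 10, by = 2.5) else
      seq(0, 90, by = 22.5)
  groups <- cut(ts[[var]], edges, include.lowest = TRUE)
  if (bin_by == "d_r_x_orientation") {
    if (!"orientation" %in% names(ts)) stop("ts lacks column orientation")
    groups <- interaction(groups, ts$orientation, drop = FALSE)
  }
  # distinct image ids across the two arms
  ctrl_pool$imageNumber <- paste0("ctrl_", ctrl_pool$imageNumber)
  ts$imageNumber <- paste0("ts_", ts$imageNumber)
  centres <- (utils::head(edges, -1) + utils::tail(edges, -1)) / 2
  out <- list(); skipped <- character(0)
  for (lv in levels(groups)) {
    sel <- which(groups == lv)
    if (!length(sel)) { skipped <- c(skipped, lv); next }
    dat <- rbind(
      data.frame(value = ts$value[sel], isTensionSensor = 1L,
                 imageNumber = ts$imageNumber[sel]),
      data.frame(value = ctrl_pool$value, isTensionSensor = 0L,
                 imageNumber = ctrl_pool$imageNumber))
    gd <- suppressWarnings(fit_grouped_difference(dat, ci_level = ci_level))
    ctr <- if (bin_by != "d_r_x_orientation")
      centres[match(lv, levels(cut(numeric(0), edges,
                                   include.lowest = TRUE)))] else NA_real_
    out[[lv]] <- data.frame(bin = lv, centre = ctr, n_ts = length(sel),
                            delta = gd$delta, ci_low = gd$ci_low,
                            ci_high = gd$ci_high, p_value = gd$p_value)
  }
  # pooled control mean with a 95% grouped CI
  if (length(unique(ctrl_pool$imageNumber)) > 1) {
    cf <- suppressMessages(lme4::lmer(value ~ 1 + (1 | imageNumber),
                                      data = ctrl_pool, REML = TRUE))
    cm <- lme4::fixef(cf)[[1]]
    cse <- sqrt(as.matrix(stats::vcov(cf))[1, 1])
  } else {
    cm <- mean(ctrl_pool$value)
    cse <- stats::sd(ctrl_pool$value) / sqrt(nrow(ctrl_pool))
  }
  z95 <- stats::qnorm(0.975)
  list(bins = if (length(out)) do.call(rbind, out) else NULL,
       ctrl = list(mean = cm, ci_low = cm - z95 * cse,
                   ci_high = cm + z95 * cse, ci_level = 0.95),
       skipped = skipped, ci_level = ci_level)
}

#' Two-sample two-sided Kolmogorov-Smirnov comparison
#'
#' @param sample_a,sample_b numeric vectors of length >= 2.
#' @return list with \code{statistic} (ECDF supremum distance) and
#'   \code{p_value} (asymptotic, two-sided).
#' @export
ks_compare <- function(sample_a, sample_b) {
  stopifnot(length(sample_a) >= 2, length(sample_b) >= 2)
  kt <- suppressWarnings(stats::ks.test(sample_a, sample_b,
                                        alternative = "two.sided",
                                        exact = FALSE))
  list(statistic = unname(kt$statistic), p_value = unname(kt$p.value))
}

#' Per-image boxplot summary
#'
#' Reduces puncta to one median per image, then summarises the per-image
#' medians with box statistics: median, 25th/75th percentiles, and whiskers
#' reaching to the last data point within 1.5 times the interquartile range
#' of the fences.
#'
#' @param values numeric vector of punctum values.
#' @param image grouping vector (image id per punctum).
#' @return list with \code{per_image} (data.frame image/median/n) and
#'   \code{box} (median, q25, q75, whisker_low, whisker_high, n_images).
#' @export
summarize_boxplot <- function(values, image) {
  stopifnot(length(values) == length(image), length(values) > 0)
  med <- tapply(values, image, stats::median)
  m <- as.numeric(med)
  q <- stats::quantile(m, c(0.25, 0.5, 0.75), names = FALSE)
  iqr <- q[3] - q[1]
  lo_fence <- q[1] - 1.5 * iqr
  hi_fence <- q[3] + 1.5 * iqr
  in_lo <- m[m >= lo_fence]
  in_hi <- m[m <= hi_fence]
  list(per_image = data.frame(image = names(med), median = m,
                              n = as.integer(table(image)[names(med)])),
       box = list(median = q[2], q25 = q[1], q75 = q[3],
                  whisker_low = min(in_lo), whisker_high = max(in_hi),
                  n_images = length(m)))
}
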