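# punctum segmentation and Poisson ML lifetime / FRET-efficiency analysis

make_spot_image <- function(shape, centres, sigma = 2, peak = 100,
                            background = 10) {
  sp <- render_spots_for_test(shape, centres, sigma, peak)
  sp + background
}

# local duplicate of the Gaussian-spot renderer (kept independent of the
# generator module so segmentation fixtures do not ride on it)
render_spots_for_test <- function(shape, centres, sigma, peak) {
  img <- matrix(0, shape[1], shape[2])
  for (i in seq_len(nrow(centres))) {
    rr <- seq_len(shape[1]); cc <- seq_len(shape[2])
    d2 <- outer((rr - centres[i, 1])^2, (cc - centres[i, 2])^2, `+`)
    img <- img + peak * exp(-d2 / (2 * sigma^2))
  }
  img
}

test_that("segment_puncta_auto: flat image, two spots, min-area rule", {
  flat <- matrix(7, 40, 40)
  expect_equal(max(segment_puncta_auto(flat)$labels), 0)

  two <- make_spot_image(c(48, 48), rbind(c(14, 14), c(34, 36)))
  seg <- segment_puncta_auto(two)
  expect_equal(max(seg$labels), 2)
  expect_true(all(tabulate(seg$labels[seg$labels > 0]) >= 9))

  # a region that segments at 12-13 px vanishes when min_area exceeds it
  one <- make_spot_image(c(40, 40), rbind(c(20, 20)), sigma = 1.2)
  seg_small <- segment_puncta_auto(one)
  area <- sum(seg_small$labels == 1)
  seg_gone <- segment_puncta_auto(one, min_area = area + 1L)
  expect_equal(max(seg_gone$labels), 0)
})

test_that("segmentation is invariant to a constant intensity offset", {
  img <- make_spot_image(c(48, 48), rbind(c(12, 30), c(36, 12)))
  s0 <- segment_puncta_auto(img)
  s1 <- segment_puncta_auto(img + 250)
  expect_identical(s0$labels, s1$labels)
})

test_that("segment_puncta_masked: mask logic and ridge splitting", {
  img <- make_spot_image(c(48, 48), rbind(c(14, 14), c(34, 36)))
  none <- matrix(FALSE, 48, 48)
  expect_equal(max(segment_puncta_masked(img, none)$labels), 0)

  mask <- matrix(FALSE, 48, 48)
  mask[6:22, 6:22] <- TRUE                 # covers only the first spot
  seg <- segment_puncta_masked(img, mask)
  expect_equal(max(seg$labels), 1)
  expect_true(all(mask[seg$labels == 1]))  # pixel set inside the mask

  # two maxima in one bright region, separated well beyond 2 sigma:
  # hill-climbing splits the region at the intensity ridge
  two_close <- make_spot_image(c(40, 60), rbind(c(20, 22), c(20, 40)))
  all_mask <- matrix(TRUE, 40, 60)
  seg2 <- segment_puncta_masked(two_close, all_mask, blur_sigma = 3)
  expect_equal(max(seg2$labels), 2)
})

test_that("fit_decay_ml: noiseless recovery and the printed lifetimes", {
  dn <- simulate_decay(2.0, 1e5, noise = "none")
  expect_lt(abs(fit_decay_ml(dn)$tau - 2.0) / 2.0, 0.005)

  d <- simulate_decay(2.52, 1e4, seed = 1)
  f <- fit_decay_ml(d)
  expect_lt(abs(f$tau - 2.52) / 2.52, 0.02)
  expect_true(f$converged)
  # the fit window starts at least 0.56 ns after the peak bin
  peak <- which.max(d$counts)
  expect_gte((f$fit_start_bin - peak) * d$bin_width, 0.56 - 1e-9)
})

test_that("fit_decay_ml equals the brute-force likelihood grid argmax", {
  for (s in c(2, 7, 19)) {
    d <- simulate_decay(2.52, 1e4, seed = s)
    f <- fit_decay_ml(d)
    oracle <- grid_search_lifetime(d$counts, d$bin_width)
    expect_lt(abs(f$tau - oracle), 0.001 + 1e-9)
  }
})

test_that("fit_decay_ml: precision improves with photon budget", {
  sd_at <- function(budget, n_rep, seed0) {
    taus <- vapply(seq_len(n_rep), function(i)
      fit_decay_ml(simulate_decay(2.5, budget, seed = seed0 + i))$tau,
      numeric(1))
    stats::sd(taus)
  }
  s2 <- sd_at(1e2, 60, 100)
  s3 <- sd_at(1e3, 60, 200)
  s4 <- sd_at(1e4, 60, 300)
  expect_gt(s2, s3)
  expect_gt(s3, s4)
  expect_lt(s4 / 2.5, 0.03)       # relative SD < 3% at 1e4 photons
})

test_that("fit_decay_ml: degenerate inputs are flagged, not fatal", {
  k <- rep(0, 64); k[3] <- 1
  f <- fit_decay_ml(k, bin_width = 0.05)
  expect_false(f$converged)
  expect_error(fit_decay_ml(rep(0, 64), bin_width = 0.05), "photons")
})

test_that("fret_efficiency: closed forms, monotonicity, validation", {
  expect_equal(fret_efficiency(2.94, 2.94), 0)
  expect_equal(fret_efficiency(0, 2.94), 1)
  expect_equal(fret_efficiency(1.26, 2.52), 0.5)
  taus <- seq(0.5, 3, by = 0.1)
  expect_true(all(diff(fret_efficiency(taus, 2.52)) < 0))
  expect_error(fret_efficiency(2, 0), "tau_d")
  # no clamping: out-of-range efficiencies pass through
  expect_lt(fret_efficiency(3.1, 2.94), 0)
})

test_that("analyze_flim_image: per-punctum filters and bulk consistency", {
  sc <- simulate_flim_scene(
    shape = c(48L, 48L),
    puncta = data.frame(row = c(12, 24, 36), col = c(12, 30, 40),
                        sigma_px = 1.6, peak = c(150, 200, 120),
                        lifetime = 2.2),
    background_level = 0, seed = 11)
  seg <- new_seg_from_owner(sc$owner)
  tab <- analyze_flim_image(sc$image, seg, tau_d = 2.94,
                            mode = "per_punctum", min_photons = 175)
  expect_equal(nrow(tab), 3)
  expect_true(all(tab$included))

  # bulk E equals the photon-weighted per-punctum mean on a uniform scene
  bulk <- analyze_flim_image(sc$image, seg, tau_d = 2.94, mode = "bulk")
  weighted <- sum(tab$fret_efficiency * tab$photons) / sum(tab$photons)
  expect_lt(abs(bulk$fret_efficiency - weighted) /
              max(abs(weighted), 1e-3), 0.01)

  # photon minimum: same scene analysed against a higher minimum
  hi <- analyze_flim_image(sc$image, seg, tau_d = 2.94,
                           mode = "per_punctum",
                           min_photons = max(tab$photons) + 1)
  expect_true(all(grepl("low_photons", hi$flags)))
  expect_false(any(hi$included))

  # tau-hat above tau_D gives E < 0 -> extreme_value
  lo_tau_d <- analyze_flim_image(sc$image, seg, tau_d = 2.0,
                                 mode = "per_punctum", min_photons = 175)
  expect_true(all(grepl("extreme_value", lo_tau_d$flags)))
})

test_that("analyze_flim_image: empty segmentation yields empty table", {
  sc <- simulate_flim_scene(shape = c(16L, 16L), puncta = NULL,
                            background_level = 1, seed = 1)
  seg <- new_seg_from_owner(matrix(0L, 16, 16))
  expect_equal(nrow(analyze_flim_image(sc$image, seg, tau_d = 2.94)), 0)
  expect_error(analyze_flim_image(sc$image, seg, tau_d = 2.94,
                                  mode = "bulk"), "empty")
})
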