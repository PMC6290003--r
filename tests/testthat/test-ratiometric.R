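# sensitized-emission chain: flat field, rolling ball, de-mixing, indices

test_that("flat_field_correct: trivial and forward-model inversion", {
  raw <- matrix(runif(100, 10, 20), 10, 10)
  dark <- matrix(10, 10, 10)
  expect_equal(flat_field_correct(raw, raw, matrix(1, 10, 10)),
               matrix(0, 10, 10))
  expect_equal(flat_field_correct(raw, dark, matrix(1, 10, 10)), raw - dark)

  # synthetic vignette v * S + dark recovers S
  set.seed(1)
  S <- matrix(runif(400, 50, 150), 20, 20)
  v <- outer(seq(0.8, 1.2, length.out = 20), seq(0.9, 1.1, length.out = 20))
  v <- v / mean(v)
  recovered <- flat_field_correct(v * S + 5, 5, v)
  expect_lt(max(abs(recovered - S)), 1e-10)
  expect_error(flat_field_correct(raw, dark, matrix(0, 10, 10)), "zero")
})

test_that("rolling_ball_subtract: flat, spot retention, broad gradient", {
  expect_lt(max(abs(rolling_ball_subtract(matrix(40, 60, 60), 50))), 1e-12)

  # 5-px-FWHM spot of height h on a constant offset: the ball cannot enter
  # the spot, so the peak is retained within 10%
  h <- 50
  d2 <- outer((1:60 - 30)^2, (1:60 - 30)^2, `+`)
  spot <- 20 + h * exp(-d2 / (2 * (5 / 2.355)^2))
  out <- rolling_ball_subtract(spot, 50)
  expect_lt(abs(max(out) - h) / h, 0.10)

  # broad 100-px-scale gradient with no spots is mostly removed
  grad <- outer(rep(1, 100), seq(0, 30, length.out = 100))
  res <- rolling_ball_subtract(grad, 50)
  expect_lt(max(res), 0.05 * 30)
})

test_that("unmix_channels: identity, pure donor, printed epsilon sets", {
  m1 <- function(x) matrix(x, 1, 1)
  Mi <- mixing_matrix(0, 0, 0, 0, 0, 0)
  um <- unmix_channels(m1(3), m1(4), m1(5), M = Mi)
  expect_equal(c(um$D_cor, um$F_cor, um$A_cor), c(3, 4, 5))

  for (pair in c("mTFP1-mEYFP", "YPet-mCherry")) {
    M <- fret_pair_preset(pair)
    obs <- unclass(M) %*% c(120, 0, 0)        # pure donor
    um <- unmix_channels(m1(obs[1]), m1(obs[2]), m1(obs[3]), M = M)
    expect_lt(abs(um$D_cor - 120), 1e-10)
    expect_lt(abs(um$F_cor), 1e-10)
    obs <- unclass(M) %*% c(100, 40, 200)
    um <- unmix_channels(m1(obs[1]), m1(obs[2]), m1(obs[3]), M = M)
    expect_lt(max(abs(c(um$D_cor - 100, um$F_cor - 40, um$A_cor - 200))),
              1e-8)
  }
  expect_error(mixing_matrix(1, 1, 1, 1, 1, 1), "singular")
})

test_that("per-pixel unmix then forward mixing reproduces observations", {
  set.seed(2)
  M <- fret_pair_preset("YPet-mCherry")
  obs <- list(D = matrix(runif(64, 10, 100), 8, 8),
              F = matrix(runif(64, 10, 100), 8, 8),
              A = matrix(runif(64, 10, 100), 8, 8))
  um <- unmix_channels(obs$D, obs$F, obs$A, M = M)
  fwd <- unclass(M) %*% rbind(as.vector(um$D_cor), as.vector(um$F_cor),
                              as.vector(um$A_cor))
  expect_lt(max(abs(fwd[1, ] - as.vector(obs$D))) / max(obs$D), 1e-8)
  expect_lt(max(abs(fwd[2, ] - as.vector(obs$F))) / max(obs$F), 1e-8)
})

test_that("fret_index: closed forms and scale invariance", {
  expect_equal(fret_index(25, 25), 50)
  expect_equal(fret_index(10, 0), 0)
  expect_equal(fret_index(25, 75), 75)
  set.seed(3)
  d <- runif(20, 1, 50); f <- runif(20, 1, 50)
  expect_equal(fret_index(3.7 * d, 3.7 * f), fret_index(d, f))
  expect_true(is.nan(fret_index(0, 0)))
})

test_that("segment_from_acceptor: threshold in background-SD units", {
  set.seed(4)
  bg_noise <- matrix(rnorm(48 * 48, 100, 5), 48, 48)
  bg_mask <- matrix(TRUE, 48, 48)
  expect_equal(max(segment_from_acceptor(bg_noise, bg_mask)$labels), 0)

  spot_at <- function(img, r, c, amp, sigma = 2) {
    d2 <- outer((1:48 - r)^2, (1:48 - c)^2, `+`)
    img + amp * exp(-d2 / (2 * sigma^2))
  }
  two <- spot_at(spot_at(bg_noise, 12, 12, 10 * 5), 36, 34, 10 * 5)
  seg <- segment_from_acceptor(two, bg_mask)
  expect_equal(max(seg$labels), 2)

  dim_spot <- spot_at(bg_noise, 24, 24, 3 * 5)
  expect_equal(max(segment_from_acceptor(dim_spot, bg_mask)$labels), 0)
  expect_error(segment_from_acceptor(bg_noise, matrix(FALSE, 48, 48)),
               "background")
})

test_that("analyze_ratiometric_image: noiseless index recovery across range", {
  M <- fret_pair_preset("mTFP1-mEYFP")
  truth_idx <- c(10, 30, 50, 70, 90)
  pu <- data.frame(row = c(10, 10, 24, 38, 38),
                   col = c(10, 38, 24, 10, 38),
                   sigma_px = 1.6, peak = 4000, fret_index = truth_idx)
  s <- simulate_three_channel_scene(shape = c(48L, 48L), pu, M,
                                    vignette = outer(
                                      seq(0.9, 1.1, length.out = 48),
                                      seq(0.95, 1.05, length.out = 48)),
                                    dark = 20, seed = 5)
  bg <- s$owner == 0
  tab <- analyze_ratiometric_image(s$triplet, M, bg, min_total_A = 10)
  expect_equal(nrow(tab), 5)
  got <- tab$fret_index[order(tab$x_um + 100 * tab$y_um)]
  want <- s$truth$fret_index[order(s$truth$x_um + 100 * s$truth$y_um)]
  expect_lt(max(abs(got - want)), 0.5)
})

test_that("analyze_ratiometric_image: dim and extreme filters, manual QC", {
  M <- fret_pair_preset("YPet-mCherry")
  pu <- data.frame(row = c(12, 36), col = c(12, 36), sigma_px = 1.6,
                   peak = c(100, 4000), fret_index = 60)
  s <- simulate_three_channel_scene(shape = c(48L, 48L), pu, M, seed = 6)
  bg <- s$owner == 0
  tab <- analyze_ratiometric_image(s$triplet, M, bg, min_total_A = 2000)
  dim_rows <- tab[tab$sumA < 2000, ]
  expect_true(all(grepl("dim", dim_rows$flags)))
  expect_false(any(dim_rows$included))
  bright <- tab[tab$sumA >= 2000, ]
  expect_true(all(bright$included))

  # manual misalignment QC is honoured, never inferred
  tab2 <- analyze_ratiometric_image(s$triplet, M, bg, min_total_A = 10,
                                    misaligned = c(TRUE,
                                                   rep(FALSE, nrow(tab))))
  expect_true(grepl("misaligned", tab2$flags[1]))
})

test_that("index estimates are unbiased under symmetric noise at SNR >= 10", {
  M <- fret_pair_preset("mTFP1-mEYFP")
  pu <- data.frame(row = 16, col = 16, sigma_px = 1.6, peak = 2000,
                   fret_index = 40)
  set.seed(7)
  est <- vapply(1:200, function(i) {
    s <- simulate_three_channel_scene(shape = c(32L, 32L), pu, M,
                                      noise_sd = 20, seed = 700 + i)
    um <- unmix_channels(s$triplet$D_obs, s$triplet$F_obs, s$triplet$A_obs,
                         M = M)
    pix <- s$owner == 1
    fret_index(sum(um$D_cor[pix]), sum(um$F_cor[pix]))
  }, numeric(1))
  expect_lt(abs(mean(est) - 40), 1)
})
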