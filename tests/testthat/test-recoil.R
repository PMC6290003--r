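# registration, matching, recoil geometry, junction slopes, track filters

test_that("fit_projective_map: identity, exact recovery, noise RMS", {
  set.seed(1)
  pts <- cbind(runif(6, 0, 50), runif(6, 0, 50))
  fid <- fit_projective_map(pts, pts)
  expect_lt(max(abs(fid$H - diag(3))), 1e-9)
  expect_lt(fid$rms, 1e-9)

  H <- matrix(c(1.1, 0.2, 3, -0.1, 0.95, -2, 1e-3, 2e-3, 1), 3, 3,
              byrow = TRUE)
  dst <- apply_homography(H, pts)
  fh <- fit_projective_map(pts, dst)
  expect_lt(max(abs(fh$H - H)) / max(abs(H)), 1e-8)

  set.seed(2)
  p8 <- cbind(runif(8, 0, 50), runif(8, 0, 50))
  d8 <- apply_homography(H, p8) + matrix(rnorm(16, 0, 0.1), 8, 2)
  expect_lte(fit_projective_map(p8, d8)$rms, 0.2)

  expect_error(fit_projective_map(pts[1:3, ], pts[1:3, ]), "4")
  coll <- cbind(1:5, 2 * (1:5))
  expect_error(fit_projective_map(coll, coll + 1), "degenerate")
})

test_that("match_puncta: identity, translation, gating", {
  set.seed(3)
  A <- cbind(runif(7, 0, 30), runif(7, 0, 30))
  m <- match_puncta(A, A, max_disp = 10)
  expect_equal(nrow(m$pairs), 7)
  expect_equal(m$total_displacement, 0)
  expect_equal(m$pairs[, 1], m$pairs[, 2])

  B <- sweep(A, 2, c(-3, -4))
  m2 <- match_puncta(A, B, max_disp = 10)
  d <- sqrt((B[m2$pairs[, 2], 1] - A[m2$pairs[, 1], 1])^2 +
              (B[m2$pairs[, 2], 2] - A[m2$pairs[, 1], 2])^2)
  expect_equal(d, rep(5, 7), tolerance = 1e-12)

  # gate excludes distant points; unequal sizes keep max cardinality
  C <- rbind(A, c(500, 500))
  m3 <- match_puncta(A, C, max_disp = 10)
  expect_equal(nrow(m3$pairs), 7)
  expect_true(8 %in% m3$unmatched_B)
})

test_that("match_puncta equals the brute-force permutation minimum", {
  for (s in 1:100) {
    set.seed(s)
    n <- sample(2:8, 1)
    A <- matrix(runif(2 * n, 0, 10), n)
    B <- matrix(runif(2 * n, 0, 10), n)
    m <- match_puncta(A, B, max_disp = 100)
    expect_equal(m$total_displacement, brute_force_matching_cost(A, B),
                 tolerance = 1e-9)
  }
})

test_that("compute_recoil: closed forms and simulator ground truth", {
  pull <- rbind(c(0, 0), c(10, 0))
  post <- rbind(c(0, 0), c(16, 8))
  m <- match_puncta(pull, post, max_disp = 50)
  rc <- compute_recoil(m, pull, post)
  expect_equal(sort(rc$d_r_um), c(0, 10))

  ps <- make_pull_scene(n = 25, seed = 9, recoil_fraction = 1)
  tr <- track_pull_sequence(ps$pre, ps$pull, ps$post, ps$control_points)
  mm <- match(round(tr$x_pull, 9), round(ps$pull$x_um, 9))
  expect_false(any(is.na(mm)))
  expect_lt(max(abs(tr$d_r_um - ps$truth$d_r_um[mm])), 0.05)
})

test_that("post-to-pre linking survives punctum dropout", {
  ps <- make_pull_scene(n = 40, seed = 13, dropout_pre = 0.10)
  tr <- track_pull_sequence(ps$pre, ps$pull, ps$post, ps$control_points)
  frac <- mean(!is.na(tr$pre_id))
  # binomial 99% band around 0.9 for n = 40
  expect_gt(frac, 0.9 - 2.6 * sqrt(0.9 * 0.1 / 40))
  expect_lte(frac, 1)
  expect_true(all(grepl("unlinked_pre", tr$flags[is.na(tr$pre_id)])))
})

test_that("junction_slope: collinear, insufficient points, outliers", {
  xs <- seq(-1.5, 1.5, length.out = 5)
  pts <- cbind(xs, xs)                          # slope exactly 1
  js <- junction_slope(c(0, 0), pts)
  expect_equal(js$m_c, 1, tolerance = 1e-9)
  expect_lt(js$se_deg, 1e-6)
  expect_true(js$reliable)

  # punctum plus a single neighbour: two points only, insufficient
  js2 <- junction_slope(c(0, 0), pts[1, , drop = FALSE])
  expect_false(js2$reliable)

  # vertical contact: no infinities escape, angle is 90 degrees
  vert <- cbind(rep(0, 5), seq(-1.5, 1.5, length.out = 5))
  jv <- junction_slope(c(0, 0), vert)
  expect_equal(abs(jv$angle_deg), 90, tolerance = 1e-6)

  # gross outlier: robust slope within 5% of the outlier-free OLS fit
  set.seed(5)
  xo <- seq(-2, 2, length.out = 9)
  yo <- 0.4 * xo + rnorm(9, 0, 0.02)
  clean_fit <- stats::coef(stats::lm(yo ~ xo))[2]
  pts_out <- rbind(cbind(xo, yo), c(1.0, 3.5))
  jr <- junction_slope(c(0, 0), pts_out, radius_um = 10)
  expect_lt(abs(jr$m_c - clean_fit) / abs(clean_fit), 0.05)
})

test_that("recoil_angle: closed forms, symmetry, rotation invariance", {
  expect_equal(recoil_angle(0.7, 0.7), 0)
  expect_equal(recoil_angle(Inf, 0), 90)
  expect_equal(recoil_angle(1, 0), 45)
  expect_equal(recoil_angle(0, Inf), 90)

  set.seed(6)
  for (i in 1:20) {
    m1 <- tan(runif(1, -pi / 2 + 0.01, pi / 2 - 0.01))
    m2 <- tan(runif(1, -pi / 2 + 0.01, pi / 2 - 0.01))
    expect_equal(recoil_angle(m1, m2), recoil_angle(m2, m1),
                 tolerance = 1e-9)
  }
  # invariance under global rotation of both lines
  for (i in 1:10) {
    a1 <- runif(1, -pi / 2, pi / 2); a2 <- runif(1, -pi / 2, pi / 2)
    th <- runif(1, 0, pi)
    base <- recoil_angle(tan(a1), tan(a2))
    rot <- recoil_angle(tan(a1 + th), tan(a2 + th))
    expect_equal(base, rot, tolerance = 1e-9)
  }
})

test_that("classify_orientation: 45-degree split", {
  expect_equal(classify_orientation(45.0), "parallel")
  expect_equal(classify_orientation(45.1), "perpendicular")
  expect_equal(classify_orientation(0), "parallel")
  expect_error(classify_orientation(95))
})

test_that("filter_tracks: every boundary has both sides exercised", {
  base <- data.frame(x_pull = c(0, 3, 6, 9, 12, 15),
                     y_pull = rep(0, 6),
                     recoil_dx = c(0.8, 1.2, 11, 9.9, 2, 2),
                     recoil_dy = 0)
  base$d_r_um <- abs(base$recoil_dx)
  ft <- filter_tracks(base)
  expect_true(grepl("small_recoil", ft$flags[1]))     # 0.8 < 1 um
  expect_false(grepl("small_recoil", ft$flags[2]))    # 1.2 >= 1 um
  expect_true(grepl("out_of_window", ft$flags[3]))    # 11 > 10 um
  expect_false(grepl("out_of_window", ft$flags[4]))   # 9.9 <= 10 um

  # isolation: a lone far-away punctum has < 2 neighbours within radius
  iso <- rbind(base, data.frame(x_pull = 500, y_pull = 0, recoil_dx = 2,
                                recoil_dy = 0, d_r_um = 2))
  expect_true(grepl("isolated", filter_tracks(iso)$flags[7]))

  # coherent field with one punctum recoiling opposite its neighbours
  fld <- data.frame(x_pull = seq(0, 10, by = 2), y_pull = 0,
                    recoil_dx = c(3, 3, -3, 3, 3, 3), recoil_dy = 0)
  fld$d_r_um <- abs(fld$recoil_dx)
  ff <- filter_tracks(fld)
  expect_true(grepl("direction_mismatch", ff$flags[3]))
  expect_false(any(grepl("direction_mismatch", ff$flags[-3])))
})

test_that("end-to-end geometry: (d_r, alpha_r) match simulator truth", {
  hits <- 0L; total <- 0L
  for (s in 1:5) {
    # a well-defined contact: transverse punctum scatter would add an
    # irreducible angle error not attributable to the estimator
    ps <- make_pull_scene(n = 30, seed = 20 + s, jitter = 0.02)
    tr <- track_pull_sequence(ps$pre, ps$pull, ps$post, ps$control_points)
    mm <- match(round(tr$x_pull, 9), round(ps$pull$x_um, 9))
    ok <- tr$included & !is.na(tr$alpha_r_deg)
    good <- abs(tr$d_r_um - ps$truth$d_r_um[mm]) <= 0.1 &
      abs(tr$alpha_r_deg - ps$truth$alpha_r_deg[mm]) <= 2
    hits <- hits + sum(good[ok])
    total <- total + sum(ok)
  }
  expect_gte(hits / total, 0.95)
})
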