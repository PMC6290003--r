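# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: brute-force enumeration, direct scans and
# closed-form evaluations against which the implementations are checked.

# all permutations of 1..n as a matrix (n! rows)
all_perms <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  p <- all_perms(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(k)
    cbind(k, ifelse(p >= k, p + 1L, p))))
}

# brute-force minimum total displacement over all one-to-one matchings of
# two equal-size point sets
brute_force_matching_cost <- function(A, B) {
  n <- nrow(A)
  D <- as.matrix(stats::dist(rbind(A, B)))[seq_len(n), n + seq_len(n),
                                           drop = FALSE]
  pm <- all_perms(n)
  min(apply(pm, 1, function(p) sum(D[cbind(seq_len(n), p)])))
}

# grid-search Poisson ML lifetime oracle: same tail window convention as the
# fitter (first-maximum peak bin, start offset), likelihood evaluated
# directly on a dense tau grid with the amplitude profiled out
grid_search_lifetime <- function(counts, bin_width, offset_ns = 0.56,
                                 grid = seq(0.5, 6, by = 0.001)) {
  peak <- which.max(counts)
  start <- peak + ceiling(offset_ns / bin_width - 1e-9)
  idx <- start:length(counts)
  tt <- (idx - 0.5) * bin_width
  k <- counts[idx]
  ll <- vapply(grid, function(tau) {
    e <- exp(-tt / tau)
    A <- sum(k) / sum(e)
    sum(k * log(A * e)) - A * sum(e)
  }, numeric(1))
  grid[which.max(ll)]
}

# ECDF-supremum two-sample KS statistic by direct evaluation
ecdf_ks_statistic <- function(a, b) {
  pts <- sort(unique(c(a, b)))
  Fa <- vapply(pts, function(x) mean(a <= x), numeric(1))
  Fb <- vapply(pts, function(x) mean(b <= x), numeric(1))
  max(abs(Fa - Fb))
}

# direct scan for the last datum within the 1.5 IQR fences
whisker_scan <- function(x) {
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE)
  iqr <- q[2] - q[1]
  list(low = min(x[x >= q[1] - 1.5 * iqr]),
       high = max(x[x <= q[2] + 1.5 * iqr]))
}

# wrap a ground-truth ownership matrix as a segmentation map, bypassing the
# segmentation stage when a test needs exact pixel sets
new_seg_from_owner <- function(owner) {
  tensionfret:::new_segmentation_map(matrix(as.integer(owner), nrow(owner),
                                            ncol(owner)),
                                     "manual-masked", list())
}

# a junction-like pull scene: puncta strung along a horizontal contact with
# small transverse jitter, sheared + translated by the pull
make_pull_scene <- function(n = 30, seed = 1, gain = 0.8,
                            recoil_fraction = 0.9, jitter = 0.1,
                            index_noise_sd = 0, dropout_pre = 0) {
  set.seed(seed)
  x <- sort(runif(n, 5, 45))
  y <- 25 + jitter * rnorm(n)
  H <- matrix(c(1, 0, 0, 0.08, 1, 4, 0, 0, 1), 3, 3, byrow = TRUE)
  simulate_pull_sequence(
    puncta = data.frame(x_um = x, y_um = y, base_index = 55),
    homography = H, recoil_fraction = recoil_fraction,
    junction_polyline = cbind(c(0, 50), c(25, 25)),
    gain = gain, index_noise_sd = index_noise_sd,
    dropout_pre = dropout_pre, seed = seed)
}
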