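# ---- plain-text serialisation, schemas, configuration and the pipeline
#
# FLIM stacks are stored as a plain-text page stack (one whitespace-separated
# row of counts per time bin) next to a JSON sidecar carrying bin width,
# pixel size and dimensions. TIFF would be the interoperable choice for real
# exports but no TIFF codec is available in this R stack, so the format is a
# documented text equivalent with the same page-per-bin structure.

#' Write a FLIM stack to a plain-text page file plus JSON sidecar
#'
#' @param img a \code{flim_image}.
#' @param path output path for the counts file; the sidecar is written to
#'   \code{paste0(path, ".json")}.
#' @return \code{path}, invisibly.
#' @export
write_flim_stack <- function(img, path) {
  stopifnot(inherits(img, "flim_image"))
  d <- dim(img$photons)
  con <- file(path, "w")
  on.exit(close(con))
  for (b in seq_len(d[3])) {
    writeLines(paste(as.integer(img$photons[, , b]), collapse = " "), con)
  }
  meta <- list(n_rows = d[1], n_cols = d[2], n_bins = d[3],
               bin_width_ns = img$bin_width, pixel_size_um = img$pixel_size,
               format = "tensionfret-flim-text", version = 1L)
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' Read a FLIM stack written by \code{\link{write_flim_stack}}
#'
#' Validates the sidecar metadata, checks the page count against the file
#' contents, and recomputes the intensity image from the pages.
#'
#' @param path counts-file path (sidecar expected at
#'   \code{paste0(path, ".json")}).
#' @return a \code{flim_image}.
#' @export
read_flim_stack <- function(path) {
  side <- paste0(path, ".json")
  if (!file.exists(path)) stop("missing FLIM stack file: ", path)
  if (!file.exists(side)) stop("missing sidecar metadata: ", side)
  meta <- jsonlite::read_json(side, simplifyVector = TRUE)
  for (f in c("n_rows", "n_cols", "n_bins", "bin_width_ns", "pixel_size_um"))
    if (is.null(meta[[f]])) stop("sidecar lacks field ", f)
  if (meta$bin_width_ns <= 0) stop("sidecar bin_width_ns must be > 0")
  if (meta$pixel_size_um <= 0) stop("sidecar pixel_size_um must be > 0")
  lines <- readLines(path)
  if (length(lines) != meta$n_bins)
    stop(sprintf("page-count mismatch: expected %d time-bin pages, found %d",
                 meta$n_bins, length(lines)))
  npix <- meta$n_rows * meta$n_cols
  photons <- array(0L, dim = c(meta$n_rows, meta$n_cols, meta$n_bins))
  for (b in seq_along(lines)) {
    v <- as.integer(strsplit(trimws(lines[b]), "\\s+")[[1]])
    if (length(v) != npix)
      stop(sprintf("page %d has %d values, expected %d", b, length(v), npix))
    photons[, , b] <- v
  }
  flim_image(photons, bin_width = meta$bin_width_ns,
             pixel_size = meta$pixel_size_um)
}

#' Write / read a channel image as plain text
#'
#' Single-channel intensity matrices round-trip through headerless
#' whitespace-separated text (one image row per line).
#'
#' @param img numeric matrix.
#' @param path file path.
#' @return \code{path} (write) or the matrix (read).
#' @export
write_channel_image <- function(img, path) {
  stopifnot(is.matrix(img))
  utils::write.table(img, path, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_channel_image
#' @export
read_channel_image <- function(path) {
  as.matrix(utils::read.table(path, header = FALSE))
}

# versioned column dictionaries shared by all writers/readers
.schemas <- list(
  puncta_v1 = list(
    required = c("image_id", "label", "x_um", "y_um", "area_px"),
    version = 1L),
  tracks_v1 = list(
    required = c("track_id", "x_pull", "y_pull", "x_post", "y_post",
                 "d_r_um", "alpha_r_deg", "flags"),
    version = 1L)
)

#' Validate a puncta or track table against its schema
#'
#' Checks required columns, basic types, and the field invariants that every
#' writer must maintain: finite coordinates, non-negative areas and
#' distances, recoil angles within [0, 90] degrees, and uniqueness of
#' (image_id, label) for puncta tables.
#'
#' @param tab data.frame, or a path to a CSV file.
#' @param schema \code{"puncta"} or \code{"tracks"}.
#' @return list with \code{ok} (logical) and \code{problems} (character
#'   vector, empty when clean).
#' @export
validate_table <- function(tab, schema = c("puncta", "tracks")) {
  schema <- match.arg(schema)
  if (is.character(tab)) {
    if (!file.exists(tab)) stop("unreadable file: ", tab)
    tab <- utils::read.csv(tab)
  }
  sc <- .schemas[[paste0(schema, "_v1")]]
  probs <- character(0)
  miss <- setdiff(sc$required, names(tab))
  if (length(miss))
    probs <- c(probs, paste("missing columns:", paste(miss, collapse = ", ")))
  if (!length(miss)) {
    if (schema == "puncta") {
      key <- paste(tab$image_id, tab$label)
      if (anyDuplicated(key))
        probs <- c(probs, "duplicated (image_id, label) keys")
      if (any(!is.finite(tab$x_um)) || any(!is.finite(tab$y_um)))
        probs <- c(probs, "non-finite coordinates")
      if (any(tab$area_px < 0)) probs <- c(probs, "negative area_px")
    } else {
      if (any(tab$d_r_um < 0, na.rm = TRUE))
        probs <- c(probs, "negative d_r_um")
      bad_a <- tab$alpha_r_deg < 0 | tab$alpha_r_deg > 90
      if (any(bad_a, na.rm = TRUE))
        probs <- c(probs, "alpha_r_deg outside [0, 90]")
    }
  }
  list(ok = length(probs) == 0, problems = probs)
}

#' Assemble a run configuration
#'
#' Bundles every tunable constant of the pipeline with validated defaults:
#' the fluorophore preset (cross-talk matrix + donor-only lifetime), photon
#' minimum, segmentation and recoil-filter settings, CI levels and the seed.
#' Round-trips losslessly through JSON.
#'
#' @param fluorophore_pair \code{"mTFP1-mEYFP"} or \code{"YPet-mCherry"}.
#' @param tau_d_preset name in \code{\link{donor_lifetime_presets}}.
#' @param min_photons per-punctum photon minimum.
#' @param min_total_A dim-punctum threshold (a.u.).
#' @param offset_ns decay fit-start offset (ns).
#' @param rolling_ball_diameter background ball diameter (px).
#' @param threshold_sd,min_area segmentation settings.
#' @param slope_radius_um,max_slope_se_deg,min_recoil_um,max_dr_um recoil
#'   settings.
#' @param ci_level,bin_ci_level inference settings.
#' @param seed integer seed.
#' @param out_dir artifact directory.
#' @return list of class \code{run_config}.
#' @export
run_config <- function(fluorophore_pair = "YPet-mCherry",
                       tau_d_preset = "YPet-F40-mCherry",
                       min_photons = 1000L, min_total_A = 2000,
                       offset_ns = 0.56, rolling_ball_diameter = 50,
                       threshold_sd = 1, min_area = 9L,
                       slope_radius_um = 4, max_slope_se_deg = 9,
                       min_recoil_um = 1, max_dr_um = 10,
                       ci_level = 0.95, bin_ci_level = 0.68,
                       seed = 1L, out_dir = tempfile("tfret_run_")) {
  taus <- donor_lifetime_presets()
  if (!tau_d_preset %in% names(taus))
    stop("unknown donor-lifetime preset: ", tau_d_preset)
  stopifnot(min_photons > 0, min_total_A > 0, offset_ns > 0,
            rolling_ball_diameter >= 3, min_area > 0, slope_radius_um > 0,
            max_slope_se_deg > 0, min_recoil_um > 0, max_dr_um > 0,
            ci_level > 0, ci_level < 1, bin_ci_level > 0, bin_ci_level < 1)
  cfg <- list(fluorophore_pair = fluorophore_pair,
              tau_d_preset = tau_d_preset,
              tau_d = unname(taus[tau_d_preset]),
              min_photons = as.integer(min_photons),
              min_total_A = min_total_A, offset_ns = offset_ns,
              rolling_ball_diameter = rolling_ball_diameter,
              threshold_sd = threshold_sd, min_area = as.integer(min_area),
              slope_radius_um = slope_radius_um,
              max_slope_se_deg = max_slope_se_deg,
              min_recoil_um = min_recoil_um, max_dr_um = max_dr_um,
              ci_level = ci_level, bin_ci_level = bin_ci_level,
              seed = as.integer(seed), out_dir = out_dir)
  class(cfg) <- "run_config"
  cfg
}

#' Write / read a run configuration as JSON
#'
#' @param cfg a \code{run_config}.
#' @param path JSON file path.
#' @return the path (write) or the configuration (read).
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  cfg$out_dir <- as.character(cfg$out_dir)
  do.call(run_config, cfg[setdiff(names(cfg), "tau_d")])
}

#' Run the synthetic end-to-end demonstration pipeline
#'
#' Chains the stages on internally generated synthetic data: \code{simulate}
#' (FLIM scene + grouped index tables + pull sequence), \code{flim}
#' (segmentation and per-punctum lifetime/efficiency analysis),
#' \code{recoil} (pull-sequence tracking), and \code{stats} (grouped
#' difference on the simulated tables). Each stage writes CSV artifacts into
#' \code{cfg$out_dir} and appends a structured log entry (parameters, filter
#' accounting). Stages depend on earlier stages' artifacts; a missing
#' dependency aborts before any computation. Runs are idempotent for a fixed
#' seed.
#'
#' @param cfg a \code{run_config}.
#' @param stages character vector, subset of
#'   \code{c("simulate", "flim", "recoil", "stats")}, executed in canonical
#'   order.
#' @return list with per-stage artifact paths and the log (also written as
#'   \code{run_log.json}).
#' @export
run_pipeline <- function(cfg, stages = c("simulate", "flim", "recoil",
                                         "stats")) {
  stopifnot(inherits(cfg, "run_config"))
  canon <- c("simulate", "flim", "recoil", "stats")
  stages <- canon[canon %in% stages]
  if (!length(stages)) stop("no known stages requested")
  deps <- list(simulate = character(0), flim = "flim_scene.txt",
               recoil = "pull_pre.csv", stats = "grouped_table.csv")
  od <- cfg$out_dir
  if (!dir.exists(od)) dir.create(od, recursive = TRUE)
  for (s in stages) {
    for (dp in deps[[s]]) {
      if (!file.exists(file.path(od, dp)) && !"simulate" %in% stages)
        stop(sprintf("stage '%s' requires artifact '%s'; run 'simulate' first",
                     s, dp))
    }
  }
  log <- list(config = unclass(cfg), stages = list())
  artifacts <- list()
  if ("simulate" %in% stages) {
    set.seed(cfg$seed)
    sc <- simulate_flim_scene(
      shape = c(48L, 48L),
      puncta = data.frame(row = c(12, 24, 36), col = c(12, 30, 40),
                          sigma_px = 1.6, peak = c(60, 80, 50),
                          lifetime = c(2.0, 2.4, 2.8)),
      background_level = 0.2, seed = cfg$seed)
    write_flim_stack(sc$image, file.path(od, "flim_scene.txt"))
    utils::write.csv(sc$truth, file.path(od, "flim_truth.csv"),
                     row.names = FALSE)
    tab <- simulate_grouped_fret_table(10, 20, true_delta = 3,
                                       image_sd = 1.5, punctum_sd = 4,
                                       seed = cfg$seed + 1L)
    utils::write.csv(tab, file.path(od, "grouped_table.csv"),
                     row.names = FALSE)
    th <- 0.12
    H <- matrix(c(1, th, 0, 0, 1, 0, 0, 0, 1), 3, 3, byrow = TRUE)
    ps <- simulate_pull_sequence(
      puncta = data.frame(x_um = stats::runif(25, 5, 45),
                          y_um = stats::runif(25, 5, 45),
                          base_index = 55),
      homography = H, recoil_fraction = 0.9, gain = 0.8,
      index_noise_sd = 0.5, seed = cfg$seed + 2L)
    for (ph in c("pre", "pull", "post"))
      utils::write.csv(ps[[ph]], file.path(od, paste0("pull_", ph, ".csv")),
                       row.names = FALSE)
    utils::write.csv(ps$control_points, file.path(od, "control_points.csv"),
                     row.names = FALSE)
    utils::write.csv(ps$truth, file.path(od, "pull_truth.csv"),
                     row.names = FALSE)
    log$stages$simulate <- list(seed = cfg$seed, n_flim_puncta = 3,
                                n_pull_puncta = 25)
    artifacts$simulate <- file.path(od, c("flim_scene.txt",
                                          "grouped_table.csv",
                                          "pull_pre.csv"))
  }
  if ("flim" %in% stages) {
    img <- read_flim_stack(file.path(od, "flim_scene.txt"))
    seg <- segment_puncta_auto(img$intensity,
                               threshold_sd = cfg$threshold_sd,
                               min_area = cfg$min_area)
    ptab <- analyze_flim_image(img, seg, tau_d = cfg$tau_d,
                               mode = "per_punctum",
                               min_photons = cfg$min_photons,
                               offset_ns = cfg$offset_ns)
    ptab <- cbind(image_id = "sim_flim_1", ptab)
    utils::write.csv(ptab, file.path(od, "flim_puncta.csv"),
                     row.names = FALSE)
    flag_counts <- table(unlist(strsplit(ptab$flags[ptab$flags != ""], ";")))
    log$stages$flim <- list(n_puncta = nrow(ptab),
                            n_included = sum(ptab$included),
                            flag_counts = as.list(flag_counts))
    stopifnot(nrow(ptab) == sum(ptab$included) +
                sum(!ptab$included))         # filter accounting
    artifacts$flim <- file.path(od, "flim_puncta.csv")
  }
  if ("recoil" %in% stages) {
    rd <- function(f) utils::read.csv(file.path(od, f))
    tracks <- track_pull_sequence(rd("pull_pre.csv"), rd("pull_pull.csv"),
                                  rd("pull_post.csv"),
                                  rd("control_points.csv"),
                                  slope_radius_um = cfg$slope_radius_um,
                                  max_slope_se_deg = cfg$max_slope_se_deg,
                                  min_recoil_um = cfg$min_recoil_um,
                                  max_dr_um = cfg$max_dr_um)
    utils::write.csv(tracks, file.path(od, "tracks.csv"), row.names = FALSE)
    log$stages$recoil <- list(n_tracks = nrow(tracks),
                              n_included = sum(tracks$included))
    artifacts$recoil <- file.path(od, "tracks.csv")
  }
  if ("stats" %in% stages) {
    tab <- utils::read.csv(file.path(od, "grouped_table.csv"))
    gd <- fit_grouped_difference(tab, ci_level = cfg$ci_level)
    res <- data.frame(contrast = "ctrl_minus_TS", estimate = gd$delta,
                      ci_low = gd$ci_low, ci_high = gd$ci_high,
                      p = gd$p_value, n_puncta = gd$n_puncta,
                      n_images = gd$n_images,
                      flags = paste(gd$flags, collapse = ";"))
    utils::write.csv(res, file.path(od, "stats_delta.csv"),
                     row.names = FALSE)
    log$stages$stats <- list(delta = gd$delta, p = gd$p_value)
    artifacts$stats <- file.path(od, "stats_delta.csv")
  }
  jsonlite::write_json(log, file.path(od, "run_log.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  list(artifacts = artifacts, log = log, out_dir = od)
}
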