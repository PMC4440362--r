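#' Pipeline configuration
#'
#' Bundles the stage toggles and all stage parameters of the end-to-end
#' phantom pipeline: simulate -> prep (align, normalize, blur) -> segment
#' -> measure -> classify -> connect -> stats.  The configuration is
#' serialized verbatim into the output directory and hashed, so a rerun
#' with the same configuration reproduces the bundle exactly.
#'
#' @param spec a [phantom_spec] describing the simulated acquisition.
#' @param stages named logical vector toggling
#'   `simulate, prep, segment, measure, classify, connect, stats`.
#' @param align_max_shift_px alignment search half-window (pixels); the
#'   default covers twice the simulated per-slice jitter, since the
#'   relative shift between consecutive slices spans that range.
#' @param blur_radius_px Gaussian companion-blur radius (pixels).
#' @param threshold absolute intensity threshold for seed growing (between
#'   the DAB-dark objects and the neuropil background).
#' @param bin_width spine-volume bin width (nm^3) for the two-regime
#'   analysis.
#' @param thresholds classification cut-offs, see [spine_thresholds()].
#' @param method surface estimator for morphometry.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(spec,
                            stages = c(simulate = TRUE, prep = TRUE,
                                       segment = TRUE, measure = TRUE,
                                       classify = TRUE, connect = TRUE,
                                       stats = TRUE),
                            align_max_shift_px = NULL,
                            blur_radius_px = 10,
                            threshold = 0.35,
                            bin_width = 5.0e6,
                            thresholds = spine_thresholds(),
                            method = "voxel_face") {
  stopifnot(inherits(spec, "phantom_spec"))
  all_st <- c("simulate", "prep", "segment", "measure", "classify",
              "connect", "stats")
  st <- setNames(rep(TRUE, length(all_st)), all_st)
  if (!is.null(names(stages))) st[names(stages)] <- stages
  if (is.null(align_max_shift_px))
    align_max_shift_px <- 2L * spec$slice_jitter_px + 2L
  structure(list(spec = spec, stages = st,
                 align_max_shift_px = as.integer(align_max_shift_px),
                 blur_radius_px = blur_radius_px, threshold = threshold,
                 bin_width = bin_width, thresholds = thresholds,
                 method = method),
            class = "pipeline_config")
}

require_artifact <- function(env, what, stage, produced_by) {
  if (is.null(env[[what]]))
    stop(sprintf(
      "%s stage requires artifact '%s' produced by the %s stage", stage,
      what, produced_by), call. = FALSE)
}

#' Run the end-to-end phantom pipeline
#'
#' Executes the enabled stages on a simulated acquisition and writes a
#' report bundle: ground truth, alignment table (applied vs recovered
#' shifts), per-object morphometry, spine features and types, type
#' composition, connectivity tables with the SSB/MSB summary, and the
#' correlation / binned two-regime report where enough spines are present.
#' Every artifact is stamped with the configuration hash and seed; rerun
#' with an identical configuration gives byte-identical CSV output.
#'
#' @param config a [pipeline_config].
#' @param out_dir output directory for the report bundle.
#' @return A list of class `pipeline_report` with the in-memory tables and
#'   the paths written.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  cfg_path <- file.path(out_dir, "config.yaml")
  yaml::write_yaml(serialize_config(config), cfg_path)
  cfg_hash <- unname(tools::md5sum(cfg_path))
  st <- config$stages
  env <- new.env()
  spec <- config$spec
  spacing <- spec$spacing

  if (st[["simulate"]]) {
    env$phantom <- build_phantom(spec)
    art <- apply_acquisition_artifacts(env$phantom$stack, spec)
    env$raw <- art$stack
    env$jitter <- art$jitter
    write.csv(env$phantom$truth, file.path(out_dir, "ground_truth.csv"),
              row.names = FALSE)
  }

  if (st[["prep"]]) {
    require_artifact(env, "raw", "prep", "simulate")
    al <- align_translation(env$raw, config$align_max_shift_px)
    env$alignment <- al$alignment
    env$prepped <- normalize_slices(al$stack)
    env$blurred <- blur_stack(env$prepped, config$blur_radius_px)
    env$labels_aligned <- apply_alignment(env$phantom$segmentation$labels,
                                          al$alignment, crop_only = TRUE)
    sh <- al$alignment$shifts
    sh$applied_dy <- env$jitter[, "dy"]
    sh$applied_dx <- env$jitter[, "dx"]
    write.csv(sh, file.path(out_dir, "alignment.csv"), row.names = FALSE)
  }

  if (st[["segment"]]) {
    require_artifact(env, "blurred", "segment", "prep")
    truth <- env$phantom$truth
    shaft_id <- truth$id[truth$category == "dendrite_shaft"][1L]
    if (is.na(shaft_id)) stop("phantom contains no dendrite to segment")
    co <- vox_coords(which(env$labels_aligned == shaft_id),
                     dim(env$labels_aligned))
    seed <- round(colMeans(co))[c(2L, 1L, 3L)] # (x, y, z)
    grown <- seed_grow(env$blurred, seed, config$threshold)
    # junctions are traced independently; carve them out of the grown mask
    syn_ids <- truth$id[truth$category == "synaptic_junction"]
    keep <- grown$idx[!(env$labels_aligned[grown$idx] %in% syn_ids)]
    env$dendrite_mask <- voxel_mask(keep, grown$dim, spacing)
    split <- split_dendrite(env$dendrite_mask)
    env$shaft <- split$shaft
    env$spine_masks <- split$spines
    present <- sort(unique(env$labels_aligned[env$labels_aligned > 0L]))
    obj <- env$phantom$segmentation$objects
    obj <- obj[obj$id %in% present, , drop = FALSE]
    obj$labeled <- truth$labeled[match(obj$id, truth$id)]
    env$seg_aligned <- voxel_segmentation(env$labels_aligned, obj, spacing)
  }

  if (st[["measure"]] || st[["classify"]]) {
    require_artifact(env, "spine_masks", "measure", "segment")
    rows <- list(); feats <- list()
    for (i in seq_along(env$spine_masks)) {
      m <- env$spine_masks[[i]]
      # match the measured spine to the dominant ground-truth label
      lab <- env$labels_aligned[m$idx]
      lab <- lab[lab > 0L]
      gt_id <- if (length(lab)) as.integer(names(which.max(table(lab))))
               else NA_integer_
      f <- extract_features(m)
      sb <- if (!f$too_small) split_branched(m) else
        list(masks = list(m), branched = FALSE)
      mo <- measure_object(m, id = i, method = config$method)
      rows[[i]] <- cbind(mo, gt_id = gt_id, n_heads = length(sb$masks))
      feats[[i]] <- cbind(spine = i, gt_id = gt_id, f)
      env$split_heads[[as.character(i)]] <- sb
    }
    env$measurements <- do.call(rbind, rows)
    env$features <- do.call(rbind, feats)
    if (st[["measure"]]) {
      syn <- measure_objects(env$seg_aligned, config$method)
      env$synapse_measurements <-
        syn[syn$category == "synaptic_junction", , drop = FALSE]
      write.csv(env$measurements, file.path(out_dir, "measurements.csv"),
                row.names = FALSE)
      write.csv(env$synapse_measurements,
                file.path(out_dir, "synapse_measurements.csv"),
                row.names = FALSE)
    }
  }

  if (st[["classify"]]) {
    require_artifact(env, "features", "classify", "measure")
    ok <- !env$features$too_small
    env$features$type <- NA_character_
    env$features$type[ok] <- vapply(
      which(ok), function(i) classify_spine(env$features[i, ],
                                            config$thresholds),
      character(1))
    env$composition <- type_composition(env$features$type[ok])
    write.csv(env$features, file.path(out_dir, "features.csv"),
              row.names = FALSE)
    write.csv(env$composition, file.path(out_dir, "composition.csv"),
              row.names = FALSE)
  }

  if (st[["connect"]]) {
    require_artifact(env, "seg_aligned", "connect", "segment")
    env$graph <- build_graph(env$seg_aligned)
    env$ssb_msb <- ssb_msb_summary(env$graph$boutons)
    write.csv(env$graph$synapses, file.path(out_dir, "synapses.csv"),
              row.names = FALSE)
    write.csv(env$graph$boutons, file.path(out_dir, "boutons.csv"),
              row.names = FALSE)
    write.csv(env$graph$spines, file.path(out_dir, "spines.csv"),
              row.names = FALSE)
  }

  if (st[["stats"]]) {
    require_artifact(env, "measurements", "stats", "measure")
    require_artifact(env, "graph", "stats", "connect")
    # pair each measured spine with its head synapse size
    syn <- env$graph$synapses
    pair <- merge(env$measurements, syn, by.x = "gt_id", by.y = "post_id")
    pair <- merge(pair, env$synapse_measurements[, c("id", "volume_nm3")],
                  by.x = "synapse_id", by.y = "id",
                  suffixes = c("_spine", "_synapse"))
    env$pairs <- pair
    env$correlation <- if (nrow(pair) >= 3L &&
                           sd(pair$volume_nm3_spine) > 0 &&
                           sd(pair$volume_nm3_synapse) > 0)
      spearman_cor(pair$volume_nm3_spine, pair$volume_nm3_synapse)
    else NULL
    env$two_regime <- tryCatch({
      bs <- bin_average(pair$volume_nm3_spine, pair$volume_nm3_synapse,
                        config$bin_width)
      fit_two_regime(bs)
    }, error = function(e) NULL)
  }

  report <- structure(list(
    config_hash = cfg_hash, seed = spec$rng_seed,
    truth = env$phantom$truth %||% NULL,
    alignment = env$alignment %||% NULL,
    measurements = env$measurements %||% NULL,
    synapse_measurements = env$synapse_measurements %||% NULL,
    features = env$features %||% NULL,
    composition = env$composition %||% NULL,
    graph = env$graph %||% NULL,
    ssb_msb = env$ssb_msb %||% NULL,
    correlation = env$correlation %||% NULL,
    two_regime = env$two_regime %||% NULL,
    out_dir = out_dir), class = "pipeline_report")

  summary <- list(
    config_hash = cfg_hash, seed = spec$rng_seed,
    n_spines_measured = if (!is.null(env$measurements))
      nrow(env$measurements) else NULL,
    composition = env$composition %||% NULL,
    ssb_msb = if (!is.null(env$ssb_msb))
      env$ssb_msb[c("n", "pct_ssb", "pct_msb", "mean_msb_contacts")]
    else NULL,
    spearman = if (!is.null(env$correlation))
      list(r = env$correlation$r, p = env$correlation$p,
           n = env$correlation$n) else NULL,
    two_regime_threshold = if (!is.null(env$two_regime))
      env$two_regime$threshold else NULL)
  jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  report
}

serialize_config <- function(config) {
  sp <- unclass(config$spec)
  sp$n_spines_per_type <- as.list(sp$n_spines_per_type)
  list(spec = sp, stages = as.list(config$stages),
       align_max_shift_px = config$align_max_shift_px,
       blur_radius_px = config$blur_radius_px,
       threshold = config$threshold, bin_width = config$bin_width,
       thresholds = config$thresholds, method = config$method)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("<pipeline_report>", x$out_dir, "\n")
  cat("  config", substr(x$config_hash, 1, 8), "seed", x$seed, "\n")
  if (!is.null(x$composition)) {
    cat("  spine types (%):",
        paste(sprintf("%s %d", x$composition$type, x$composition$pct),
              collapse = ", "), "\n")
  }
  if (!is.null(x$ssb_msb))
    cat(sprintf("  SSB %d%% / MSB %d%% of %d boutons\n", x$ssb_msb$pct_ssb,
                x$ssb_msb$pct_msb, x$ssb_msb$n))
  invisible(x)
}

#' Field of view of an acquisition frame
#'
#' Physical extent of a frame in micrometres:
#' `pixels * nm_per_pixel / 1000`, rounded to one decimal for display (raw
#' values kept in the `raw_um` attribute).  The routine acquisition setting
#' of 2048 x 1536 px at 3.7 nm/px gives a 7.6 x 5.7 um field of view.
#'
#' @param pixels_x,pixels_y frame size in pixels.
#' @param nm_per_pixel lateral resolution, nm per pixel.
#' @return Named vector `c(x_um, y_um)` rounded to one decimal.
#' @export
fov_of_frame <- function(pixels_x, pixels_y, nm_per_pixel) {
  if (pixels_x <= 0 || pixels_y <= 0 || nm_per_pixel <= 0)
    stop("frame size and resolution must be positive")
  raw <- c(x_um = pixels_x * nm_per_pixel / 1000,
           y_um = pixels_y * nm_per_pixel / 1000)
  out <- round(raw, 1)
  attr(out, "raw_um") <- raw
  out
}
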