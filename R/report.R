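# End products: layer x cell-type summary matrices, depth profiles,
# grand-average time courses, and the end-to-end pipeline driver.

#' Layer x cell-type summary table
#'
#' Builds the summary matrix for one pathway and feature: rows L2..L6,
#' columns EXC/PV/SST/VIP, each cell holding mean, SD, median and n of the
#' pooled normalized (or absolute) feature. Cells with no recorded neurons
#' are blank; single-cell groups print only their median and n.
#'
#' @param pooled Output of [pool_groups()].
#' @param pathway `"VPM"` or `"POm"`.
#' @param feature `"amplitude"` or `"slope"`.
#' @param scale `"normalized"` (default) or `"absolute"`.
#' @return List with `numeric` (long data.frame of the group statistics)
#'   and `pretty` (character matrix of `"mean +/- SD *median* n = n"`
#'   cells, layers x cell types).
#' @export
build_summary_table <- function(pooled, pathway,
                                feature = c("amplitude", "slope"),
                                scale = c("normalized", "absolute")) {
  feature <- match.arg(feature)
  scale <- match.arg(scale)
  stub <- if (feature == "amplitude") "amp" else "slope"
  if (scale == "normalized") stub <- paste0("norm_", stub)
  df <- pooled[pooled$pathway == pathway, , drop = FALSE]
  num <- data.frame(pathway = pathway, cell_type = df$cell_type,
                    layer = df$layer,
                    n = df[[paste0("n_", stub)]],
                    mean = df[[paste0("mean_", stub)]],
                    sd = df[[paste0("sd_", stub)]],
                    median = df[[paste0("median_", stub)]])
  pretty <- matrix("", nrow = length(LAYERS), ncol = length(CELL_TYPES),
                   dimnames = list(LAYERS, CELL_TYPES))
  for (i in seq_len(nrow(num))) {
    if (is.na(num$n[i]) || num$n[i] == 0L) next
    cell <- if (num$n[i] == 1L || is.na(num$sd[i])) {
      sprintf("*%.3g* n = %d", num$median[i], num$n[i])
    } else {
      sprintf("%.2f ± %.2f *%.3g* n = %d",
              num$mean[i], num$sd[i], num$median[i], num$n[i])
    }
    pretty[num$layer[i], num$cell_type[i]] <- cell
  }
  list(numeric = num, pretty = pretty)
}

#' Depth profile of a feature
#'
#' Scatter records of a feature against subpial depth, sorted by depth,
#' with the layer band of each cell annotated. Cells without a recorded
#' depth are omitted; their count is attached as `attr(, "n_omitted")`.
#'
#' @param normalized Output of [normalize_dataset()] (or any table with
#'   `cell_id, depth_um` and the value column).
#' @param value Column to profile (default `"norm_amp"`).
#' @param boundaries A [layer_boundaries()] table for the band annotations.
#' @return data.frame `cell_id, depth_um, value, layer_band`, sorted by
#'   depth, with `attr(, "boundaries")` carrying the band table.
#' @export
build_depth_profile <- function(normalized, value = "norm_amp",
                                boundaries = layer_boundaries()) {
  stopifnot(value %in% names(normalized))
  keep <- !is.na(normalized$depth_um) & !is.na(normalized[[value]])
  n_omitted <- sum(!keep)
  if (n_omitted)
    message(n_omitted, " cell(s) without depth or value omitted from profile")
  df <- data.frame(cell_id = normalized$cell_id[keep],
                   depth_um = normalized$depth_um[keep],
                   value = normalized[[value]][keep])
  df <- df[order(df$depth_um), , drop = FALSE]
  df$layer_band <- assign_layer(df$depth_um, boundaries)
  rownames(df) <- NULL
  attr(df, "n_omitted") <- n_omitted
  attr(df, "boundaries") <- boundaries
  df
}

#' Grand-average EPSP time course per cell type
#'
#' Baseline-subtracted mean traces averaged across all cells of each cell
#' type (pooled across layers), on a common time grid around stimulus
#' onset. Optionally each cell's trace is first normalized to its own peak
#' amplitude, so the grand average reflects kinetics rather than strength.
#'
#' @param sweeps List of [sweep_set] objects.
#' @param meta Metadata data.frame.
#' @param normalize_per_cell Divide each cell's trace by its peak amplitude
#'   first? Default FALSE.
#' @param baseline_ms Baseline window in ms.
#' @return data.frame with `time_ms` and one column per cell type present.
#' @export
build_grand_average_timecourse <- function(sweeps, meta,
                                           normalize_per_cell = FALSE,
                                           baseline_ms = 100) {
  stopifnot(length(sweeps) >= 1L)
  meta <- cell_meta_table(meta)
  rates <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) != 1L)
    stop("grand average requires a common sampling rate")
  pre <- min(vapply(sweeps, function(s)
    sum(average_trace(s)$time_ms < 0), integer(1)))
  post <- min(vapply(sweeps, function(s)
    sum(average_trace(s)$time_ms >= 0), integer(1)))
  types <- intersect(CELL_TYPES, meta$cell_type)
  out <- NULL
  for (ct in types) {
    ids <- meta$cell_id[meta$cell_type == ct]
    traces <- lapply(sweeps[vapply(sweeps, function(s)
      s$cell_id %in% ids, logical(1))], function(s) {
        avg <- average_trace(s)
        bl <- compute_baseline(avg, baseline_ms)
        i0 <- which(avg$time_ms >= 0)[1L]
        v <- avg$vm_mV[(i0 - pre):(i0 + post - 1L)] - bl
        if (normalize_per_cell) {
          pk <- compute_peak(avg, bl)
          if (pk$peak_amp_mV > 0) v <- v / pk$peak_amp_mV
        }
        if (is.null(out))
          out <<- data.frame(time_ms = avg$time_ms[(i0 - pre):(i0 + post - 1L)])
        v
      })
    if (!length(traces)) next
    out[[ct]] <- rowMeans(do.call(cbind, traces))
  }
  out
}

#' Run the full analysis pipeline
#'
#' End-to-end driver: simulate a cohort (or read a dataset from disk),
#' extract features, normalize per slice, pool groups, build summary
#' tables and reference-layer comparisons, and write all artifacts plus a
#' manifest (input hashes, parameters, package version, exclusions) to an
#' output directory. Deterministic under a fixed configuration and seed.
#'
#' @param out_dir Output directory (created if needed).
#' @param config A [simulation_config()] to simulate from, or `NULL` when
#'   reading a recorded dataset.
#' @param dataset_path Dataset directory readable by [read_dataset()]
#'   (ignored when `config` is given).
#' @param boundaries A [layer_boundaries()] table.
#' @param quiet Suppress per-stage messages.
#' @return Invisibly, a list with the in-memory artifacts (`features`,
#'   `normalized`, `pooled`, `tables`, `pvalues`, `profile`, `timecourse`,
#'   `manifest`) and the paths written.
#' @export
run_pipeline <- function(out_dir, config = NULL, dataset_path = NULL,
                         boundaries = layer_boundaries(), quiet = FALSE) {
  say <- function(...) if (!quiet) message("[epspmap] ", ...)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(config)) {
    say("simulating cohort (", config$pathway, ", seed ", config$seed, ")")
    ds <- simulate_dataset(config, boundaries)
    input_desc <- list(source = "simulation",
                       config = unclass(config)[setdiff(names(config),
                                                        c("group_params",
                                                          "kinetics"))],
                       group_params = config$group_params,
                       kinetics = config$kinetics)
  } else {
    if (is.null(dataset_path)) stop("either config or dataset_path required")
    say("reading dataset from ", dataset_path)
    ds <- read_dataset(dataset_path)
    hashes <- tools::md5sum(list.files(dataset_path, recursive = TRUE,
                                       full.names = TRUE))
    input_desc <- list(source = "dataset", path = dataset_path,
                       md5 = as.list(hashes))
  }
  say("extracting features from ", length(ds$sweeps), " cells")
  features <- extract_features(ds$sweeps)
  say("normalizing per slice")
  normalized <- withCallingHandlers(
    normalize_dataset(features, ds$meta, boundaries),
    warning = function(w) { say("warning: ", conditionMessage(w))
      invokeRestart("muffleWarning") })
  excluded <- attr(normalized, "excluded_slices")
  pooled <- pool_groups(normalized)

  pathways <- unique(normalized$pathway)
  tables <- list(); pvalues <- NULL
  for (pw in pathways) {
    for (feat in c("amplitude", "slope"))
      for (sc in c("normalized", "absolute"))
        tables[[paste(pw, feat, sc, sep = "_")]] <-
          build_summary_table(pooled, pw, feat, sc)
    pvalues <- rbind(pvalues, compare_reference_layer(normalized, pw))
  }
  profile <- build_depth_profile(normalized)
  timecourse <- build_grand_average_timecourse(ds$sweeps, ds$meta)

  wcsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.csv(df, p, row.names = FALSE, na = "")
    p
  }
  paths <- c(wcsv(features, "features.csv"),
             wcsv(normalized, "normalized.csv"),
             wcsv(pvalues, "pvalues.csv"),
             wcsv(profile, "depth_profile.csv"),
             wcsv(timecourse, "timecourse.csv"))
  for (nm in names(tables)) {
    paths <- c(paths, wcsv(tables[[nm]]$numeric,
                           paste0("table_", nm, ".csv")))
    txt <- file.path(out_dir, paste0("table_", nm, ".txt"))
    utils::write.table(tables[[nm]]$pretty, txt, sep = "\t",
                       quote = FALSE, col.names = NA)
    paths <- c(paths, txt)
  }
  manifest <- list(
    package = "epspmap",
    version = as.character(utils::packageVersion("epspmap")),
    input = input_desc,
    n_cells = length(ds$sweeps),
    excluded_slices = as.list(excluded),
    n_cells_analyzed = nrow(normalized),
    artifact_md5 = as.list(tools::md5sum(paths)))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  say("wrote ", length(paths) + 1L, " artifacts to ", out_dir)
  invisible(list(features = features, normalized = normalized,
                 pooled = pooled, tables = tables, pvalues = pvalues,
                 profile = profile, timecourse = timecourse,
                 manifest = manifest, paths = paths))
}
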