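# Layer assignment from subpial depth and per-slice normalization to
# reference-layer excitatory neurons.

#' Assign a cortical layer from subpial depth
#'
#' Returns the layer whose half-open interval `[depth_lo_um, depth_hi_um)`
#' contains the depth. Depths outside the covered range are an error.
#' Note that L1 can be returned here (its band exists) but carries no
#' recordings and is flagged by downstream steps.
#'
#' @param depth_um Subpial depth(s) in micrometres (0 = pia).
#' @param boundaries A [layer_boundaries()] table.
#' @return Character vector of layer names.
#' @export
assign_layer <- function(depth_um, boundaries = layer_boundaries()) {
  lo <- boundaries$depth_lo_um[1L]
  hi <- boundaries$depth_hi_um[nrow(boundaries)]
  bad <- is.na(depth_um) | depth_um < lo | depth_um >= hi
  if (any(bad))
    stop("depth ", depth_um[bad][1L], " um outside covered range [",
         lo, ", ", hi, ")")
  idx <- findInterval(depth_um, boundaries$depth_lo_um)
  boundaries$layer[idx]
}

#' Resolve the analysis layer of every cell
#'
#' An explicit `layer` in the metadata takes precedence; otherwise the
#' layer is derived from `depth_um` via [assign_layer()]. Cells landing in
#' L1 are kept but marked not analyzed (`analyzed = FALSE`): no recordings
#' are made from L1 interneurons.
#'
#' @param meta Metadata data.frame.
#' @param boundaries A [layer_boundaries()] table.
#' @return `meta` with `layer` filled in and a logical `analyzed` column.
#' @export
resolve_layers <- function(meta, boundaries = layer_boundaries()) {
  meta <- cell_meta_table(meta)
  fill <- is.na(meta$layer)
  if (any(fill))
    meta$layer[fill] <- assign_layer(meta$depth_um[fill], boundaries)
  meta$analyzed <- meta$layer %in% LAYERS
  meta
}

#' Normalize features to reference-layer excitatory cells, slice by slice
#'
#' Removes slice-to-slice variability in opsin expression by dividing each
#' cell's EPSP amplitude by the mean amplitude over the reference-layer
#' excitatory cells (L4 for VPM, L5A for POm) recorded in the same slice;
#' slopes are divided by the reference cells' mean slope (over reference
#' cells with a defined slope). Reference cells are included in their own
#' reference mean, so the per-slice (and hence pooled) reference-group
#' mean of the normalized feature is exactly 1. Only control-condition
#' reference cells enter the denominators. Slices without any usable
#' reference cell are excluded with a warning naming the slice.
#'
#' @param features Feature table from [extract_features()].
#' @param meta Metadata data.frame (layers resolved if needed).
#' @param boundaries A [layer_boundaries()] table, used when metadata rows
#'   carry only depths.
#' @return data.frame joining metadata and features with added columns
#'   `ref_layer, norm_amp, norm_slope`; excluded slice ids are attached as
#'   `attr(, "excluded_slices")`.
#' @export
normalize_dataset <- function(features, meta,
                              boundaries = layer_boundaries()) {
  meta <- resolve_layers(meta, boundaries)
  if (!all(features$cell_id %in% meta$cell_id))
    stop("features contain cell_id absent from metadata")
  df <- merge(meta, features, by = "cell_id", sort = TRUE)
  df$ref_layer <- vapply(df$pathway, reference_layer, character(1))
  df$norm_amp <- NA_real_
  df$norm_slope <- NA_real_

  excluded <- character(0)
  for (sl in unique(df$slice_id)) {
    rows <- df$slice_id == sl
    ref <- rows & df$cell_type == "EXC" & df$layer == df$ref_layer &
      df$condition == "control" & !is.na(df$peak_amp_mV)
    if (!any(ref)) {
      warning("slice '", sl, "' has no reference-layer EXC cell; excluded")
      excluded <- c(excluded, sl)
      next
    }
    amp_den <- mean(df$peak_amp_mV[ref])
    if (!is.finite(amp_den) || amp_den <= 0) {
      warning("slice '", sl, "' has non-positive reference amplitude mean; excluded")
      excluded <- c(excluded, sl)
      next
    }
    df$norm_amp[rows] <- df$peak_amp_mV[rows] / amp_den
    ref_sl <- ref & !is.na(df$slope_mV_per_ms)
    if (any(ref_sl)) {
      slope_den <- mean(df$slope_mV_per_ms[ref_sl])
      if (is.finite(slope_den) && slope_den > 0)
        df$norm_slope[rows] <- df$slope_mV_per_ms[rows] / slope_den
    }
  }
  df <- df[!(df$slice_id %in% excluded), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "excluded_slices") <- excluded
  df
}

#' Pool normalized features into (pathway, cell type, layer) groups
#'
#' Aggregates cells across slices. Counts are feature-specific: a cell with
#' a defined amplitude but missing slope contributes to the amplitude n
#' but not the slope n.
#'
#' @param normalized Output of [normalize_dataset()].
#' @param analyzed_only Drop cells flagged not analyzed (L1)? Default TRUE.
#' @return data.frame keyed by `pathway, cell_type, layer` with, for each
#'   of absolute amplitude (`amp`), normalized amplitude (`norm_amp`),
#'   absolute slope (`slope`) and normalized slope (`norm_slope`):
#'   `n_*`, `mean_*`, `sd_*`, `median_*` columns. Single-cell groups carry
#'   `NA` SDs.
#' @export
pool_groups <- function(normalized, analyzed_only = TRUE) {
  df <- normalized
  if (analyzed_only && "analyzed" %in% names(df)) df <- df[df$analyzed, ]
  key <- unique(df[c("pathway", "cell_type", "layer")])
  key <- key[order(key$pathway, key$cell_type,
                   match(key$layer, LAYERS)), , drop = FALSE]
  stat <- function(v) {
    v <- v[!is.na(v)]
    n <- length(v)
    c(n = n,
      mean = if (n) mean(v) else NA_real_,
      sd = if (n > 1L) stats::sd(v) else NA_real_,
      median = if (n) stats::median(v) else NA_real_)
  }
  cols <- c(amp = "peak_amp_mV", norm_amp = "norm_amp",
            slope = "slope_mV_per_ms", norm_slope = "norm_slope")
  out <- key
  for (nm in names(cols)) {
    m <- t(vapply(seq_len(nrow(key)), function(i) {
      rows <- df$pathway == key$pathway[i] &
        df$cell_type == key$cell_type[i] & df$layer == key$layer[i]
      stat(df[[cols[[nm]]]][rows])
    }, numeric(4)))
    colnames(m) <- paste0(c("n_", "mean_", "sd_", "median_"), nm)
    out <- cbind(out, as.data.frame(m))
  }
  for (nm in names(cols))
    out[[paste0("n_", nm)]] <- as.integer(out[[paste0("n_", nm)]])
  rownames(out) <- NULL
  out
}
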