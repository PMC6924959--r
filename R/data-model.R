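# Shared domain types: sweep sets (one cell's trials x samples V_m matrix with
# stimulus timing), the cell metadata table, and cortical layer boundaries.

#' Controlled vocabularies
#'
#' Enumerations used throughout the package: thalamocortical pathways,
#' recorded cell classes, cortical layers and pharmacology/recording
#' conditions.
#'
#' @format Character vectors.
#' @name vocab
NULL

#' @rdname vocab
#' @export
PATHWAYS <- c("VPM", "POm")

#' @rdname vocab
#' @export
CELL_TYPES <- c("EXC", "PV", "SST", "VIP")

#' Layers that can carry recordings in a metadata table. L1 exists in the
#' boundary table (so depths can be classified) but holds no recordings.
#' @rdname vocab
#' @export
LAYERS <- c("L2", "L3", "L4", "L5A", "L5B", "L6")

#' @rdname vocab
#' @export
ALL_LAYERS <- c("L1", LAYERS)

#' @rdname vocab
#' @export
CONDITIONS <- c("control", "CNQX_APV", "late_timepoint")

#' Construct a sweep set
#'
#' A sweep set holds one cell's multi-trial membrane-potential recording:
#' an `n_trials x n_samples` matrix of V_m in mV, the sampling rate, and the
#' time of the (1 ms) optogenetic stimulus relative to trace start. All
#' downstream feature extraction operates on sweep sets.
#'
#' @param cell_id Character scalar, unique cell identifier.
#' @param trials Numeric matrix, `n_trials x n_samples`, membrane potential
#'   in mV. All values must be finite.
#' @param sampling_rate Sampling rate in Hz (acquisition default 20000).
#' @param stim_onset Stimulus onset in seconds from trace start. Must leave
#'   at least `min_baseline_s` of pre-stimulus trace so a full baseline
#'   window exists.
#' @param stim_duration Stimulus duration in seconds (default 0.001, the
#'   1 ms light pulse).
#' @param min_baseline_s Required pre-stimulus duration in seconds
#'   (default 0.1, the 100 ms baseline window).
#' @return An object of class `sweep_set`.
#' @export
sweep_set <- function(cell_id, trials, sampling_rate, stim_onset,
                      stim_duration = 0.001, min_baseline_s = 0.1) {
  stopifnot(is.character(cell_id), length(cell_id) == 1L, nzchar(cell_id))
  trials <- as.matrix(trials)
  storage.mode(trials) <- "double"
  if (nrow(trials) < 1L)
    stop("sweep_set '", cell_id, "': needs at least one trial")
  if (!all(is.finite(trials)))
    stop("sweep_set '", cell_id, "': non-finite membrane potential values")
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      sampling_rate <= 0)
    stop("sweep_set '", cell_id, "': sampling_rate must be a positive scalar")
  if (!is.numeric(stim_onset) || length(stim_onset) != 1L)
    stop("sweep_set '", cell_id, "': stim_onset must be a numeric scalar")
  if (stim_onset < min_baseline_s)
    stop("sweep_set '", cell_id, "': stim_onset (", stim_onset,
         " s) leaves less than ", min_baseline_s, " s of pre-stimulus baseline")
  if (stim_onset >= ncol(trials) / sampling_rate)
    stop("sweep_set '", cell_id, "': stim_onset beyond end of trace")
  structure(
    list(cell_id = cell_id, trials = trials,
         sampling_rate = as.numeric(sampling_rate),
         stim_onset = as.numeric(stim_onset),
         stim_duration = as.numeric(stim_duration)),
    class = "sweep_set")
}

#' @export
print.sweep_set <- function(x, ...) {
  cat(sprintf(
    "<sweep_set '%s': %d trials x %d samples @ %g kHz, stimulus at %g ms>\n",
    x$cell_id, nrow(x$trials), ncol(x$trials), x$sampling_rate / 1000,
    1000 * x$stim_onset))
  invisible(x)
}

#' Assemble and validate a cell metadata table
#'
#' The metadata table carries one row per recorded cell: identity (cell,
#' slice, mouse), pathway stimulated (VPM or POm), cell class, laminar
#' location (explicit layer and/or subpial depth in micrometres) and the
#' recording condition. At least one of `layer` / `depth_um` must be set
#' for every cell.
#'
#' @param df A data.frame with columns `cell_id, slice_id, mouse_id,
#'   pathway, cell_type, layer, depth_um, condition`. `layer` may be `NA`
#'   (or `""`) when `depth_um` is given, and vice versa.
#' @return The validated data.frame (character columns normalized, empty
#'   strings converted to `NA`).
#' @export
cell_meta_table <- function(df) {
  required <- c("cell_id", "slice_id", "mouse_id", "pathway", "cell_type",
                "layer", "depth_um", "condition")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols))
    stop("metadata is missing column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[required]
  for (col in c("cell_id", "slice_id", "mouse_id", "pathway", "cell_type",
                "layer", "condition")) {
    v <- as.character(df[[col]])
    v[!is.na(v) & v == ""] <- NA_character_
    df[[col]] <- v
  }
  df$depth_um <- as.numeric(df$depth_um)

  if (anyNA(df$cell_id)) stop("metadata: missing cell_id")
  if (anyDuplicated(df$cell_id))
    stop("metadata: duplicate cell_id '",
         df$cell_id[duplicated(df$cell_id)][1L], "'")
  .check_enum(df, "pathway", PATHWAYS)
  .check_enum(df, "cell_type", CELL_TYPES)
  .check_enum(df, "layer", LAYERS, allow_na = TRUE)
  .check_enum(df, "condition", CONDITIONS)
  no_loc <- is.na(df$layer) & is.na(df$depth_um)
  if (any(no_loc))
    stop("metadata: neither layer nor depth_um set for cell '",
         df$cell_id[no_loc][1L], "'")
  # a slice belongs to exactly one mouse
  sm <- unique(df[c("slice_id", "mouse_id")])
  dup <- duplicated(sm$slice_id)
  if (any(dup))
    stop("metadata: slice '", sm$slice_id[dup][1L],
         "' is attributed to more than one mouse")
  rownames(df) <- NULL
  df
}

.check_enum <- function(df, col, allowed, allow_na = FALSE) {
  v <- df[[col]]
  bad <- !(v %in% allowed) & !(allow_na & is.na(v))
  if (anyNA(v) && !allow_na) bad[is.na(v)] <- TRUE
  if (any(bad))
    stop("metadata: unknown ", col, " '", v[bad][1L], "' for cell '",
         df$cell_id[bad][1L], "'")
  invisible(TRUE)
}

#' Cortical layer boundaries
#'
#' An ordered, contiguous table of half-open depth intervals
#' `[depth_lo_um, depth_hi_um)` covering L1..L6 from the pial surface
#' (depth 0). The defaults are the average laminar borders measured for the
#' mouse barrel column by Lefort et al. (2009, Neuron 61:301-316).
#'
#' @param df Optional data.frame with columns `layer, depth_lo_um,
#'   depth_hi_um` to validate and use instead of the defaults.
#' @return A validated `layer_boundaries` data.frame.
#' @export
layer_boundaries <- function(df = NULL) {
  if (is.null(df)) {
    df <- data.frame(
      layer = ALL_LAYERS,
      depth_lo_um = c(0, 128, 269, 418, 588, 708, 890),
      depth_hi_um = c(128, 269, 418, 588, 708, 890, 1154))
  }
  stopifnot(all(c("layer", "depth_lo_um", "depth_hi_um") %in% names(df)))
  df <- df[c("layer", "depth_lo_um", "depth_hi_um")]
  df$layer <- as.character(df$layer)
  if (df$depth_lo_um[1L] != 0)
    stop("layer boundaries must start at depth 0 (pia)")
  if (any(df$depth_hi_um <= df$depth_lo_um))
    stop("layer boundaries must be strictly increasing")
  if (nrow(df) > 1L &&
      any(df$depth_lo_um[-1L] != df$depth_hi_um[-nrow(df)]))
    stop("layer boundaries must be contiguous")
  class(df) <- c("layer_boundaries", "data.frame")
  df
}

# internal: ms <-> sample index helpers on a sweep_set time base
.time_axis_ms <- function(n_samples, sampling_rate, stim_onset) {
  ((seq_len(n_samples) - 1L) / sampling_rate - stim_onset) * 1000
}
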