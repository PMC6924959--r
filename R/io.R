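# Dataset container I/O.
#
# A dataset lives in a directory:
#   <path>/meta.csv            cell metadata (schema of cell_meta_table)
#   <path>/attrs.json          per-cell dims and acquisition attributes
#   <path>/traces/<cell_id>.f64  raw little-endian float64 trial matrix,
#                                column-major over (trial, sample)
# Trace payloads are stored as float64 mV, times in seconds, rates in Hz,
# so a write -> read round trip is bit-exact.

#' Write a dataset to disk
#'
#' Writes sweep sets and their metadata table as a dataset directory.
#' Cells are written sorted by `cell_id` so output is deterministic.
#'
#' @param sweeps List of [sweep_set] objects.
#' @param meta Metadata data.frame (validated via [cell_meta_table()]).
#' @param path Target directory (created if absent).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(sweeps, meta, path) {
  meta <- cell_meta_table(meta)
  ids <- vapply(sweeps, function(s) s$cell_id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate cell_id '", ids[duplicated(ids)][1L], "' among sweep sets")
  if (!setequal(ids, meta$cell_id)) {
    odd <- c(setdiff(ids, meta$cell_id), setdiff(meta$cell_id, ids))
    stop("sweep sets and metadata disagree on cells: '", odd[1L], "'")
  }
  for (s in sweeps) {
    if (!inherits(s, "sweep_set")) stop("sweeps must be sweep_set objects")
    if (!all(is.finite(s$trials)))
      stop("non-finite V_m in sweep set '", s$cell_id, "'; not writing")
  }
  ord <- order(ids)
  sweeps <- sweeps[ord]
  meta <- meta[order(meta$cell_id), , drop = FALSE]

  dir.create(file.path(path, "traces"), recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(meta, file.path(path, "meta.csv"), row.names = FALSE,
                   na = "")
  attrs <- lapply(sweeps, function(s) {
    list(n_trials = nrow(s$trials), n_samples = ncol(s$trials),
         sampling_rate_hz = s$sampling_rate, stim_onset_s = s$stim_onset,
         stim_duration_s = s$stim_duration)
  })
  names(attrs) <- vapply(sweeps, function(s) s$cell_id, character(1))
  jsonlite::write_json(attrs, file.path(path, "attrs.json"),
                       auto_unbox = TRUE, digits = NA)
  for (s in sweeps) {
    con <- file(file.path(path, "traces", paste0(s$cell_id, ".f64")), "wb")
    writeBin(as.vector(s$trials), con, size = 8, endian = "little")
    close(con)
  }
  invisible(path)
}

#' Read a dataset from disk
#'
#' Inverse of [write_dataset()]. Every metadata row must have a matching
#' trace payload and vice versa; all loaded sweep sets are re-validated
#' against the type invariants. Inconsistent sampling rates across cells
#' are flagged with a warning (not fatal).
#'
#' @param path Dataset directory written by [write_dataset()].
#' @return A list with elements `sweeps` (list of [sweep_set], sorted by
#'   cell id) and `meta` (metadata data.frame).
#' @export
read_dataset <- function(path) {
  meta_file <- file.path(path, "meta.csv")
  attr_file <- file.path(path, "attrs.json")
  if (!file.exists(meta_file) || !file.exists(attr_file))
    stop("'", path, "' is not a dataset directory (missing meta.csv/attrs.json)")
  meta <- utils::read.csv(meta_file, colClasses = c(depth_um = "numeric"),
                          na.strings = "")
  meta$layer <- as.character(meta$layer)
  meta <- cell_meta_table(meta)
  attrs <- jsonlite::read_json(attr_file)
  if (!setequal(names(attrs), meta$cell_id)) {
    odd <- c(setdiff(meta$cell_id, names(attrs)),
             setdiff(names(attrs), meta$cell_id))
    stop("metadata and trace attributes disagree on cell '", odd[1L], "'")
  }
  ids <- sort(meta$cell_id)
  sweeps <- vector("list", length(ids))
  for (i in seq_along(ids)) {
    a <- attrs[[ids[i]]]
    f <- file.path(path, "traces", paste0(ids[i], ".f64"))
    if (!file.exists(f))
      stop("missing trace payload for cell '", ids[i], "'")
    n <- a$n_trials * a$n_samples
    con <- file(f, "rb")
    v <- readBin(con, "double", n = n, size = 8, endian = "little")
    close(con)
    if (length(v) != n)
      stop("truncated trace payload for cell '", ids[i], "'")
    sweeps[[i]] <- sweep_set(ids[i],
                             matrix(v, nrow = a$n_trials, ncol = a$n_samples),
                             sampling_rate = a$sampling_rate_hz,
                             stim_onset = a$stim_onset_s,
                             stim_duration = a$stim_duration_s)
  }
  rates <- vapply(sweeps, function(s) s$sampling_rate, numeric(1))
  if (length(unique(rates)) > 1L)
    warning("inconsistent sampling rates across cells: ",
            paste(unique(rates), collapse = ", "), " Hz")
  list(sweeps = sweeps, meta = meta[order(meta$cell_id), , drop = FALSE])
}
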