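# EPSP feature extraction on trial-averaged traces: baseline (mean V_m over
# the 100 ms before the stimulus), peak amplitude (maximum of the average
# trace in a post-stimulus window minus baseline), 20%/50% rise crossings
# and the rise slope (OLS fit over the 20-50% rise period). All features
# are computed on the mean trace, not per trial.

#' Trial-averaged trace
#'
#' Pointwise arithmetic mean across trials, with the time axis re-expressed
#' in ms relative to stimulus onset.
#'
#' @param sweeps A [sweep_set].
#' @return data.frame with columns `time_ms` (0 = stimulus onset) and
#'   `vm_mV`.
#' @export
average_trace <- function(sweeps) {
  stopifnot(inherits(sweeps, "sweep_set"))
  data.frame(
    time_ms = .time_axis_ms(ncol(sweeps$trials), sweeps$sampling_rate,
                            sweeps$stim_onset),
    vm_mV = colMeans(sweeps$trials))
}

#' Pre-stimulus baseline
#'
#' Mean membrane potential over the `window_ms` immediately preceding
#' stimulus onset, i.e. samples with time in `[-window_ms, 0)`.
#'
#' @param avg Averaged trace from [average_trace()].
#' @param window_ms Baseline window length in ms (default 100).
#' @return Baseline in mV.
#' @export
compute_baseline <- function(avg, window_ms = 100) {
  if (window_ms <= 0) stop("baseline window must be positive")
  sel <- avg$time_ms >= -window_ms & avg$time_ms < 0
  if (!any(sel) || min(avg$time_ms) > -window_ms + 1e-6)
    stop("trace does not cover the ", window_ms, " ms pre-stimulus window")
  mean(avg$vm_mV[sel])
}

#' Peak amplitude and latency
#'
#' Maximum of the averaged trace in a post-stimulus search window, minus
#' baseline. Ties are broken by the earliest sample.
#'
#' @param avg Averaged trace from [average_trace()].
#' @param baseline Baseline in mV from [compute_baseline()].
#' @param search_window_ms Post-stimulus search window `(0, search_window_ms]`
#'   in ms (default 100).
#' @return List with `peak_amp_mV` and `peak_latency_ms`.
#' @export
compute_peak <- function(avg, baseline, search_window_ms = 100) {
  sel <- which(avg$time_ms > 0 & avg$time_ms <= search_window_ms)
  if (!length(sel)) stop("peak search window outside trace")
  i <- sel[which.max(avg$vm_mV[sel])]
  list(peak_amp_mV = avg$vm_mV[i] - baseline,
       peak_latency_ms = avg$time_ms[i])
}

#' 20% and 50% rise crossing times
#'
#' Times at which the averaged trace crosses `baseline + 0.2 * peak_amp`
#' and `baseline + 0.5 * peak_amp` on the rising phase contiguous with the
#' peak: starting at the peak sample, the search walks backward while the
#' trace stays at or above threshold, then interpolates linearly between
#' the last sub-threshold sample and the first supra-threshold one. This
#' backward-contiguous rule ignores pre-stimulus noise excursions above
#' threshold. Crossings are `NA` when the trace never dips below threshold
#' between stimulus onset and the peak, or when `peak_amp <= 0`.
#'
#' @inheritParams compute_peak
#' @param peak_amp_mV,peak_latency_ms Peak features from [compute_peak()].
#' @return List with `t20_ms` and `t50_ms` (ms after stimulus onset; `NA`
#'   when undefined).
#' @export
compute_rise_crossings <- function(avg, baseline, peak_amp_mV,
                                   peak_latency_ms) {
  if (is.na(peak_amp_mV) || peak_amp_mV <= 0)
    return(list(t20_ms = NA_real_, t50_ms = NA_real_))
  ipk <- which.min(abs(avg$time_ms - peak_latency_ms))
  i0 <- which(avg$time_ms > 0)[1L]            # first in-window sample
  cross <- function(frac) {
    thr <- baseline + frac * peak_amp_mV
    i <- ipk                                  # v[ipk] >= thr by construction
    while (i > i0 && avg$vm_mV[i - 1L] >= thr) i <- i - 1L
    if (i == i0) return(NA_real_)             # no sub-threshold sample in window
    lo <- i - 1L                              # v[lo] < thr <= v[i]
    f <- (thr - avg$vm_mV[lo]) / (avg$vm_mV[i] - avg$vm_mV[lo])
    avg$time_ms[lo] + f * (avg$time_ms[i] - avg$time_ms[lo])
  }
  t20 <- cross(0.2)
  t50 <- cross(0.5)
  if (is.na(t20) || is.na(t50) || !(t20 < t50))
    return(list(t20_ms = NA_real_, t50_ms = NA_real_))
  list(t20_ms = t20, t50_ms = t50)
}

#' Rise slope over the 20-50% period
#'
#' Ordinary least-squares slope of V_m against time over the 20-50% rise
#' window `[t20_ms, t50_ms]`. Because the window of a fast EPSP can contain
#' only a handful of raw samples, the fit is evaluated on a dense linear
#' interpolation of the averaged trace across the window (201 equally
#' spaced points including both crossing times), which converges to the
#' continuous-time least-squares fit and keeps the estimate
#' sampling-grid-independent.
#'
#' @param avg Averaged trace from [average_trace()].
#' @param t20_ms,t50_ms Crossing times from [compute_rise_crossings()].
#' @return Slope in mV/ms, or `NA` when the crossings are undefined.
#' @export
compute_slope <- function(avg, t20_ms, t50_ms) {
  if (is.na(t20_ms) || is.na(t50_ms)) return(NA_real_)
  stopifnot(t20_ms < t50_ms)
  tt <- seq(t20_ms, t50_ms, length.out = 201L)
  vv <- stats::approx(avg$time_ms, avg$vm_mV, xout = tt)$y
  sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
}

#' Extract all EPSP features for one cell or a dataset
#'
#' Chains trial averaging, baseline, peak, rise crossings and slope. Cells
#' whose rising phase cannot be resolved (no 20%/50% crossing before the
#' peak, or non-positive peak) keep their amplitude but carry a missing
#' slope; this is why slope group counts can be smaller than amplitude
#' counts downstream.
#'
#' @param x A [sweep_set] or a list of them.
#' @param baseline_ms Baseline window in ms (default 100).
#' @param peak_window_ms Peak search window in ms (default 100).
#' @return data.frame with one row per cell: `cell_id, baseline_mV,
#'   peak_amp_mV, peak_latency_ms, t20_ms, t50_ms, slope_mV_per_ms`.
#' @export
extract_features <- function(x, baseline_ms = 100, peak_window_ms = 100) {
  if (inherits(x, "sweep_set")) x <- list(x)
  rows <- lapply(x, function(s) {
    avg <- average_trace(s)
    bl <- compute_baseline(avg, baseline_ms)
    pk <- compute_peak(avg, bl, peak_window_ms)
    cr <- compute_rise_crossings(avg, bl, pk$peak_amp_mV, pk$peak_latency_ms)
    data.frame(cell_id = s$cell_id, baseline_mV = bl,
               peak_amp_mV = pk$peak_amp_mV,
               peak_latency_ms = pk$peak_latency_ms,
               t20_ms = cr$t20_ms, t50_ms = cr$t50_ms,
               slope_mV_per_ms = compute_slope(avg, cr$t20_ms, cr$t50_ms))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
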