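# Independent oracles and fixture builders shared across test files.

# --- analytic dual-exponential oracles (root finding + fine-grid OLS),
#     independent of the feature-extraction code path -------------------

oracle_peak_time <- function(tau_rise, tau_decay) {
  # brute-force argmax on a 1 us grid
  t <- seq(0, 10 * tau_decay, by = 1e-3)
  t[which.max(exp(-t / tau_decay) - exp(-t / tau_rise))]
}

oracle_crossings <- function(tau_rise, tau_decay) {
  tp <- oracle_peak_time(tau_rise, tau_decay)
  w <- function(t) epsp_waveform(t, 1, tau_rise, tau_decay)
  root <- function(frac)
    stats::uniroot(function(x) w(x) - frac, c(1e-9, tp), tol = 1e-12)$root
  c(t20 = root(0.2), t50 = root(0.5))
}

oracle_slope <- function(amplitude, tau_rise, tau_decay) {
  cr <- oracle_crossings(tau_rise, tau_decay)
  tt <- seq(cr[["t20"]], cr[["t50"]], by = 1e-3)   # 1 us resampling
  vv <- epsp_waveform(tt, amplitude, tau_rise, tau_decay)
  sum((tt - mean(tt)) * (vv - mean(vv))) / sum((tt - mean(tt))^2)
}

# --- brute-force exact rank-test oracles (full enumeration) ------------

oracle_rank_sum_p <- function(x, y) {
  nx <- length(x); N <- nx + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(nx)])
  ws <- apply(utils::combn(N, nx), 2, function(idx) sum(r[idx]))
  min(1, 2 * min(mean(ws <= w_obs), mean(ws >= w_obs)))
}

oracle_signed_rank_p <- function(before, after) {
  d <- after - before
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  v_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), n)))
  vs <- apply(signs, 1, function(s) sum(r[s]))
  min(1, 2 * min(mean(vs <= v_obs), mean(vs >= v_obs)))
}

# --- fixture builders --------------------------------------------------

# short-trace config for fast simulation in tests (study acquisition
# settings otherwise: 20 kHz, 20 trials, 1 ms stimulus)
quick_config <- function(pathway = "VPM", ...) {
  simulation_config(pathway, trace_len_s = 0.25, stim_onset_s = 0.1, ...)
}

noiseless_config <- function(pathway = "VPM", ...) {
  quick_config(pathway, noise = list(sigma_mV = 0, tau_ms = 10),
               trial_amp_jitter_cv = 0, ...)
}

# small cohort: every group capped at `cap` cells, few slices
small_cohort_config <- function(pathway = "VPM", n_slices = 4L, cap = 5L,
                                ...) {
  gp <- default_group_params(pathway)
  gp$n_cells <- pmin(gp$n_cells, cap)
  quick_config(pathway, n_slices = n_slices, group_params = gp, ...)
}

# hand-built sweep_set holding one explicit mean trace (single trial)
trace_sweep <- function(v, sampling_rate = 20000, stim_onset = 0.1,
                        cell_id = "cell") {
  sweep_set(cell_id, matrix(v, nrow = 1), sampling_rate, stim_onset)
}

# a flat baseline with an appended linear ramp to `peak` over `ramp_ms`,
# holding the peak afterwards; stimulus onset aligned to a sample
ramp_trace <- function(peak, ramp_ms = 1, baseline = -70,
                       sampling_rate = 20000, stim_onset = 0.1,
                       total_s = 0.2) {
  n <- round(total_s * sampling_rate)
  t_ms <- ((seq_len(n) - 1) / sampling_rate - stim_onset) * 1000
  v <- baseline + peak * pmin(pmax(t_ms / ramp_ms, 0), 1)
  trace_sweep(v, sampling_rate, stim_onset)
}
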