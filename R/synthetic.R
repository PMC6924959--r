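# Generative simulator of optogenetic slice-mapping cohorts.
#
# The generative model, per cohort (one pathway):
#   slice s:   A_ref(s) ~ log-normal          (opsin expression level, mV)
#   cell i:    g_i ~ max(0, N(mu_g, sd_g))    (normalized input strength of
#                                              its cell-type x layer group)
#              absolute amplitude a_i = A_ref(s(i)) * g_i
#   trial k:   amplitude a_ik = max(0, N(a_i, cv * a_i))
#              V_m(t) = v_rest + OU(t) + a_ik * w(t - t_stim)
# with w a dual-exponential waveform normalized to unit peak and OU a
# stationary Ornstein-Uhlenbeck membrane-noise process. Reference-layer
# excitatory cells (L4 for VPM, L5A for POm) have group mean 1 by
# construction, anchoring the per-slice normalization downstream.

#' Dual-exponential EPSP waveform
#'
#' `w(t) = A (exp(-t/tau_decay) - exp(-t/tau_rise)) / N`, with `N` chosen so
#' the maximum over t equals `A`; `w(0) = 0` and `w(t < 0) = 0`.
#'
#' @param t_ms Time grid in ms (relative to synaptic onset).
#' @param amplitude Peak amplitude A in mV.
#' @param tau_rise_ms,tau_decay_ms Rise/decay time constants in ms;
#'   `tau_rise_ms < tau_decay_ms` required.
#' @return Numeric vector of deflections in mV, same length as `t_ms`.
#' @seealso [waveform_peak_time_ms()] for the analytic peak time.
#' @export
epsp_waveform <- function(t_ms, amplitude, tau_rise_ms, tau_decay_ms) {
  if (tau_rise_ms >= tau_decay_ms)
    stop("tau_rise_ms must be smaller than tau_decay_ms")
  tp <- waveform_peak_time_ms(tau_rise_ms, tau_decay_ms)
  norm <- exp(-tp / tau_decay_ms) - exp(-tp / tau_rise_ms)
  w <- ifelse(t_ms > 0,
              (exp(-t_ms / tau_decay_ms) - exp(-t_ms / tau_rise_ms)) / norm,
              0)
  amplitude * w
}

#' Analytic peak time of the dual-exponential waveform
#'
#' `t* = tau_r tau_d / (tau_d - tau_r) * log(tau_d / tau_r)`, in ms.
#'
#' @inheritParams epsp_waveform
#' @export
waveform_peak_time_ms <- function(tau_rise_ms, tau_decay_ms) {
  if (tau_rise_ms >= tau_decay_ms)
    stop("tau_rise_ms must be smaller than tau_decay_ms")
  tau_rise_ms * tau_decay_ms / (tau_decay_ms - tau_rise_ms) *
    log(tau_decay_ms / tau_rise_ms)
}

#' Default per-group normalized-amplitude parameters
#'
#' Mean, SD and cell count of normalized EPSP peak amplitude for each
#' (cell type, layer) group of a cohort. These defaults encode the laminar
#' input maps the simulator emulates: VPM input peaking in L4 (reference
#' group, mean 1 by construction) with strong L3 input, POm input peaking
#' in L5A; excitatory and PV cells receiving the largest inputs, SST cells
#' almost none, VIP cells intermediate. Groups observed only once or twice
#' carry their observed value with SD 0.
#'
#' @param pathway `"VPM"` or `"POm"`.
#' @return data.frame with columns `cell_type, layer, mean_norm_amp,
#'   sd_norm_amp, n_cells`.
#' @export
default_group_params <- function(pathway = c("VPM", "POm")) {
  pathway <- match.arg(pathway)
  g <- function(cell_type, mean, sd, n)
    data.frame(cell_type = cell_type, layer = LAYERS,
               mean_norm_amp = mean, sd_norm_amp = sd, n_cells = n)
  if (pathway == "VPM") {
    rbind(
      g("EXC", c(0.20, 0.46, 1.00, 0.14, 0.17, 0.39),
             c(0.54, 0.50, 0.37, 0.21, 0.22, 0.79),
             c(29L, 45L, 65L, 39L, 44L, 40L)),
      g("PV",  c(0.04, 0.35, 1.15, 0.12, 0.04, 0.17),
             c(0.02, 0.34, 0.92, 0.22, 0.02, 0.20),
             c(3L, 9L, 14L, 5L, 11L, 5L)),
      g("SST", c(0.01, 0.09, 0.09, 0.03, 0.01, 0.01),
             c(0.00, 0.10, 0.08, 0.01, 0.01, 0.01),
             c(3L, 3L, 8L, 6L, 9L, 4L)),
      g("VIP", c(0.13, 0.32, 0.15, 0.03, 0.13, 0.011),
             c(0.26, 0.49, 0.16, 0.01, 0.23, 0.00),
             c(10L, 17L, 8L, 5L, 5L, 1L)))
  } else {
    rbind(
      g("EXC", c(0.11, 0.16, 0.13, 1.00, 0.11, 0.23),
             c(0.18, 0.39, 0.35, 0.52, 0.31, 0.38),
             c(38L, 31L, 38L, 75L, 52L, 47L)),
      g("PV",  c(0.17, 0.04, 0.03, 1.17, 0.09, 0.03),
             c(0.13, 0.04, 0.06, 0.96, 0.10, 0.05),
             c(3L, 7L, 8L, 8L, 10L, 10L)),
      g("SST", c(0.02, 0.07, 0.02, 0.15, 0.03, 0.01),
             c(0.02, 0.16, 0.01, 0.15, 0.04, 0.01),
             c(5L, 7L, 3L, 5L, 13L, 18L)),
      g("VIP", c(0.18, 0.17, 0.21, 0.33, 0.20, 0.090),
             c(0.37, 0.25, 0.35, 0.32, 0.18, 0.00),
             c(14L, 20L, 12L, 10L, 7L, 2L)))
  }
}

#' Default cell-type kinetics presets
#'
#' Rise/decay time constants of the synaptic waveform per cell type. PV
#' kinetics are fast relative to excitatory cells, so equal-amplitude inputs
#' produce 2-3x steeper rise slopes in PV cells, reproducing the fast
#' feedforward character of thalamic input to PV interneurons.
#'
#' @return data.frame with columns `cell_type, tau_rise_ms, tau_decay_ms`.
#' @export
default_kinetics <- function() {
  data.frame(cell_type = c("EXC", "PV", "SST", "VIP"),
             tau_rise_ms = c(2, 0.5, 2, 1),
             tau_decay_ms = c(40, 15, 40, 25))
}

#' Reference layer of a pathway
#'
#' Normalization reference: L4 excitatory cells for VPM cohorts, L5A
#' excitatory cells for POm cohorts.
#'
#' @inheritParams default_group_params
#' @export
reference_layer <- function(pathway) {
  pathway <- match.arg(pathway, PATHWAYS)
  if (pathway == "VPM") "L4" else "L5A"
}

#' Build a simulation configuration
#'
#' Collects the full generative parameterization of a synthetic cohort.
#' Defaults reproduce the study conditions the analysis assumes: 20 trials
#' per cell digitized at 20 kHz, a 1 ms stimulus, per-slice log-normal
#' scaling of absolute amplitudes (median 14.5 mV for the VPM L4 reference,
#' 11.7 mV for the POm L5A reference), cell-type-specific kinetics and
#' stationary Ornstein-Uhlenbeck membrane noise (sigma 0.3 mV, tau 10 ms)
#' around a -70 mV resting potential.
#'
#' @param pathway Cohort pathway, `"VPM"` or `"POm"`.
#' @param n_slices Number of slices (default 33 for VPM, 43 for POm; one
#'   mouse per slice).
#' @param group_params Per-group sampling rule: data.frame as returned by
#'   [default_group_params()]. Must include the reference-layer EXC group
#'   with `n_cells >= n_slices` so every slice gets a reference cell.
#' @param ref_abs_amp Per-slice absolute reference amplitude distribution:
#'   `list(median_mV =, sdlog =)` of a log-normal.
#' @param kinetics data.frame as [default_kinetics()].
#' @param noise Ornstein-Uhlenbeck membrane noise: `list(sigma_mV =, tau_ms =)`.
#'   Set `sigma_mV = 0` for noiseless traces.
#' @param v_rest_mV Resting potential in mV.
#' @param n_trials Trials per cell.
#' @param sampling_rate Sampling rate in Hz.
#' @param trace_len_s Trace duration in seconds.
#' @param stim_onset_s Stimulus onset in seconds (>= 0.1 so the 100 ms
#'   baseline window fits).
#' @param trial_amp_jitter_cv Coefficient of variation of per-trial
#'   amplitude around the cell mean.
#' @param drift_per_hour Fractional amplitude drift applied to
#'   `late_timepoint` cells (0 = stable preparation).
#' @param condition Recording condition applied to the whole cohort.
#' @param seed Integer seed; together with the configuration it fully
#'   determines the simulated dataset.
#' @return A `simulation_config` object (list).
#' @export
simulation_config <- function(pathway = "VPM",
                              n_slices = if (pathway == "VPM") 33L else 43L,
                              group_params = default_group_params(pathway),
                              ref_abs_amp = list(
                                median_mV = if (pathway == "VPM") 14.5 else 11.7,
                                sdlog = 0.4),
                              kinetics = default_kinetics(),
                              noise = list(sigma_mV = 0.3, tau_ms = 10),
                              v_rest_mV = -70,
                              n_trials = 20L,
                              sampling_rate = 20000,
                              trace_len_s = 0.3,
                              stim_onset_s = 0.12,
                              trial_amp_jitter_cv = 0.1,
                              drift_per_hour = 0,
                              condition = "control",
                              seed = 1L) {
  pathway <- match.arg(pathway, PATHWAYS)
  condition <- match.arg(condition, CONDITIONS)
  stopifnot(n_slices >= 1L, n_trials >= 1L, sampling_rate > 0,
            trace_len_s > stim_onset_s, stim_onset_s >= 0.1,
            trial_amp_jitter_cv >= 0, noise$sigma_mV >= 0, noise$tau_ms > 0,
            ref_abs_amp$median_mV > 0, ref_abs_amp$sdlog >= 0)
  stopifnot(all(c("cell_type", "layer", "mean_norm_amp", "sd_norm_amp",
                  "n_cells") %in% names(group_params)))
  if (any(group_params$sd_norm_amp < 0))
    stop("group SDs must be non-negative")
  if (any(group_params$mean_norm_amp < 0))
    stop("group means must be non-negative")
  if (any(kinetics$tau_rise_ms >= kinetics$tau_decay_ms))
    stop("tau_rise must be smaller than tau_decay for every cell type")
  ref <- reference_layer(pathway)
  iref <- which(group_params$cell_type == "EXC" & group_params$layer == ref)
  if (length(iref) != 1L)
    stop("group_params must contain exactly one ", ref, " EXC group")
  if (group_params$n_cells[iref] < n_slices)
    stop("sampling rule leaves some slice without a reference ", ref,
         " EXC cell (n_cells = ", group_params$n_cells[iref],
         " < n_slices = ", n_slices, ")")
  structure(
    list(pathway = pathway, n_slices = as.integer(n_slices),
         group_params = group_params, ref_abs_amp = ref_abs_amp,
         kinetics = kinetics, noise = noise, v_rest_mV = v_rest_mV,
         n_trials = as.integer(n_trials), sampling_rate = sampling_rate,
         trace_len_s = trace_len_s, stim_onset_s = stim_onset_s,
         stim_duration_s = 0.001,
         trial_amp_jitter_cv = trial_amp_jitter_cv,
         drift_per_hour = drift_per_hour, condition = condition,
         seed = as.integer(seed)),
    class = "simulation_config")
}

#' Read a simulation configuration from a JSON file
#'
#' The file mirrors the [simulation_config()] argument names; absent fields
#' take their defaults.
#'
#' @param path JSON file.
#' @return A `simulation_config` object.
#' @export
read_simulation_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (nm in c("noise", "ref_abs_amp"))      # keep scalar maps as lists
    if (!is.null(raw[[nm]])) raw[[nm]] <- as.list(raw[[nm]])
  for (nm in c("group_params", "kinetics"))  # column maps or record arrays
    if (!is.null(raw[[nm]]))
      raw[[nm]] <- as.data.frame(raw[[nm]], stringsAsFactors = FALSE)
  known <- names(formals(simulation_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown configuration field(s): ", paste(unknown, collapse = ", "))
  do.call(simulation_config, raw)
}

# Stationary OU noise, one column per trial. AR(1) exact discretization:
# x[t+1] = a x[t] + sqrt(1 - a^2) sigma eps, a = exp(-dt/tau), x[1] ~ N(0, sigma).
.ou_noise <- function(n_samples, n_trials, sigma_mV, tau_ms, sampling_rate) {
  if (sigma_mV == 0) return(matrix(0, n_samples, n_trials))
  a <- exp(-1000 / (sampling_rate * tau_ms))
  innov <- matrix(stats::rnorm(n_samples * n_trials), n_samples, n_trials)
  innov[1L, ] <- innov[1L, ] * sigma_mV
  if (n_samples > 1L)
    innov[-1L, ] <- innov[-1L, ] * (sigma_mV * sqrt(1 - a^2))
  x <- stats::filter(innov, filter = a, method = "recursive")
  attributes(x) <- list(dim = c(n_samples, n_trials))
  x
}

#' Simulate one cell's sweep set
#'
#' Generates `n_trials` membrane-potential traces: resting potential plus
#' stationary Ornstein-Uhlenbeck noise plus a dual-exponential EPSP whose
#' per-trial amplitude is `max(0, Normal(amp_mean, cv * amp_mean))`. A
#' `CNQX_APV` condition forces the synaptic amplitude to zero (receptor
#' block); a `late_timepoint` condition scales the mean amplitude by
#' `1 + drift_per_hour`.
#'
#' Uses the R random number generator; seed management is the caller's
#' responsibility ([simulate_dataset()] seeds once per dataset).
#'
#' @param cell_id Cell identifier for the returned sweep set.
#' @param amp_mean Mean absolute EPSP peak amplitude in mV (>= 0).
#' @param cell_type Cell class, selects the kinetics preset.
#' @param config A [simulation_config()].
#' @param condition Recording condition for this cell (defaults to the
#'   cohort condition in `config`).
#' @return A [sweep_set].
#' @export
simulate_cell <- function(cell_id, amp_mean, cell_type, config,
                          condition = config$condition) {
  stopifnot(amp_mean >= 0)
  condition <- match.arg(condition, CONDITIONS)
  kin <- config$kinetics[config$kinetics$cell_type == cell_type, ]
  if (nrow(kin) != 1L) stop("no kinetics preset for cell type '", cell_type, "'")
  n_samples <- round(config$trace_len_s * config$sampling_rate)
  n_trials <- config$n_trials

  amp <- switch(condition,
                CNQX_APV = 0,
                late_timepoint = amp_mean * (1 + config$drift_per_hour),
                amp_mean)
  cv <- config$trial_amp_jitter_cv
  trial_amp <- if (amp == 0) {
    rep(0, n_trials)
  } else {
    pmax(0, stats::rnorm(n_trials, mean = amp, sd = cv * amp))
  }
  t_ms <- .time_axis_ms(n_samples, config$sampling_rate, config$stim_onset_s)
  w <- epsp_waveform(t_ms, 1, kin$tau_rise_ms, kin$tau_decay_ms)
  noise <- .ou_noise(n_samples, n_trials, config$noise$sigma_mV,
                     config$noise$tau_ms, config$sampling_rate)
  trials <- t(noise + outer(w, trial_amp)) + config$v_rest_mV
  sweep_set(cell_id, trials, sampling_rate = config$sampling_rate,
            stim_onset = config$stim_onset_s,
            stim_duration = config$stim_duration_s)
}

#' Simulate a complete cohort
#'
#' Draws a full synthetic experiment from a [simulation_config()]: per-slice
#' reference amplitudes, per-cell group-structured normalized strengths,
#' subpial depths uniform within each layer band, and per-cell sweep sets.
#' Every slice is guaranteed at least one reference-layer excitatory cell
#' (validated at configuration time); remaining cells are assigned to
#' slices at random. The output is fully determined by the configuration,
#' including its seed.
#'
#' @param config A [simulation_config()].
#' @param boundaries Layer boundaries used to draw subpial depths.
#' @return List with `sweeps` (list of [sweep_set]), `meta` (metadata
#'   data.frame) and `truth` (per-cell generative values: slice reference
#'   amplitude `ref_abs_amp_mV`, drawn normalized strength `gen_norm_amp`,
#'   absolute mean amplitude `gen_amp_mV`).
#' @export
simulate_dataset <- function(config, boundaries = layer_boundaries()) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  gp <- config$group_params
  gp <- gp[gp$n_cells > 0L, , drop = FALSE]
  ref <- reference_layer(config$pathway)

  slice_ids <- sprintf("%s_s%02d", config$pathway, seq_len(config$n_slices))
  mouse_ids <- sprintf("%s_m%02d", config$pathway, seq_len(config$n_slices))
  ref_abs <- stats::rlnorm(config$n_slices,
                           meanlog = log(config$ref_abs_amp$median_mV),
                           sdlog = config$ref_abs_amp$sdlog)

  # cell table: groups expanded, slices assigned (reference cells cover
  # every slice first, everything else uniform)
  cells <- gp[rep(seq_len(nrow(gp)), gp$n_cells),
              c("cell_type", "layer", "mean_norm_amp", "sd_norm_amp")]
  rownames(cells) <- NULL
  is_ref <- cells$cell_type == "EXC" & cells$layer == ref
  slice_of <- integer(nrow(cells))
  ref_idx <- which(is_ref)
  n_ref <- length(ref_idx)
  cover <- sample(config$n_slices)            # each slice one reference cell
  slice_of[ref_idx[seq_len(config$n_slices)]] <- cover
  extra <- ref_idx[-seq_len(config$n_slices)]
  slice_of[extra] <- sample.int(config$n_slices, length(extra), replace = TRUE)
  slice_of[-ref_idx] <- sample.int(config$n_slices, nrow(cells) - n_ref,
                                   replace = TRUE)

  b <- boundaries[match(cells$layer, boundaries$layer), ]
  depth <- stats::runif(nrow(cells), b$depth_lo_um, b$depth_hi_um)
  gen_norm <- pmax(0, stats::rnorm(nrow(cells), cells$mean_norm_amp,
                                   cells$sd_norm_amp))
  gen_amp <- ref_abs[slice_of] * gen_norm

  ord <- order(slice_of, cells$cell_type, cells$layer)
  cells <- cells[ord, ]; slice_of <- slice_of[ord]; depth <- depth[ord]
  gen_norm <- gen_norm[ord]; gen_amp <- gen_amp[ord]
  cell_ids <- sprintf("%s_c%03d", slice_ids[slice_of], seq_len(nrow(cells)))

  meta <- cell_meta_table(data.frame(
    cell_id = cell_ids, slice_id = slice_ids[slice_of],
    mouse_id = mouse_ids[slice_of], pathway = config$pathway,
    cell_type = cells$cell_type, layer = cells$layer,
    depth_um = round(depth, 1), condition = config$condition))
  truth <- data.frame(cell_id = cell_ids,
                      ref_abs_amp_mV = ref_abs[slice_of],
                      gen_norm_amp = gen_norm, gen_amp_mV = gen_amp)

  sweeps <- vector("list", nrow(cells))
  for (i in seq_len(nrow(cells))) {
    sweeps[[i]] <- simulate_cell(cell_ids[i], gen_amp[i],
                                 cells$cell_type[i], config)
  }
  list(sweeps = sweeps, meta = meta, truth = truth)
}

#' Expected value of a group's generative amplitude distribution
#'
#' Normalized amplitudes are drawn as `max(0, Normal(mean, sd))`; the
#' expectation of that censored normal is
#' `mean * pnorm(mean/sd) + sd * dnorm(mean/sd)`. Used when checking that
#' simulated cohorts recover their generative group means.
#'
#' @param mean,sd Group parameters (sd >= 0).
#' @return The generative mean after censoring at zero.
#' @export
group_generative_mean <- function(mean, sd) {
  ifelse(sd <= 0, pmax(0, mean),
         mean * stats::pnorm(mean / sd) + sd * stats::dnorm(mean / sd))
}
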