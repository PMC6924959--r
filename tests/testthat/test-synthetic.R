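test_that("dual-exponential waveform: peak, linearity, degenerate cases", {
  t <- seq(0, 200, by = 0.05)
  expect_identical(epsp_waveform(t, 0, 2, 40), rep(0, length(t)))
  expect_error(epsp_waveform(t, 1, 40, 2), "tau_rise")

  # analytic peak time against brute-force argmax on a 1 us grid
  expect_equal(waveform_peak_time_ms(2, 40), oracle_peak_time(2, 40),
               tolerance = 1e-3)
  expect_equal(waveform_peak_time_ms(0.5, 15), oracle_peak_time(0.5, 15),
               tolerance = 1e-3)
  # unit-peak normalization: max equals the amplitude to 1e-9 relative
  tf <- seq(0, 100, by = 1e-3)
  expect_equal(max(epsp_waveform(tf, 14.5, 2, 40)), 14.5,
               tolerance = 1e-9)
  expect_identical(epsp_waveform(0, 5, 2, 40), 0)       # w(0) = 0
  # linearity: doubling the amplitude doubles every sample
  expect_equal(epsp_waveform(t, 8, 1, 25), 2 * epsp_waveform(t, 4, 1, 25))
})

test_that("simulated datasets are fully determined by config + seed", {
  cfg <- small_cohort_config(seed = 11L)
  d1 <- simulate_dataset(cfg)
  d2 <- simulate_dataset(cfg)
  expect_identical(d1$meta, d2$meta)
  expect_identical(d1$truth, d2$truth)
  expect_identical(d1$sweeps, d2$sweeps)

  d3 <- simulate_dataset(small_cohort_config(seed = 12L))
  expect_false(identical(d1$sweeps[[1]]$trials, d3$sweeps[[1]]$trials))
})

test_that("OU membrane noise is stationary with the configured variance", {
  sigma <- 0.3
  set.seed(5)
  x <- epspmap:::.ou_noise(200000, 1, sigma, 10, 20000)  # 10 s of noise
  # effective sample size for the variance of an OU process:
  # n_eff ~ duration / (2 tau); 3 SE band around sigma^2
  n_eff <- 10 / (2 * 0.010)
  se <- sigma^2 * sqrt(2 / n_eff)
  expect_lt(abs(var(as.numeric(x)) - sigma^2), 3 * se)
  expect_lt(abs(mean(x)), 3 * sigma / sqrt(n_eff))
})

test_that("noiseless cells are deterministic and recover their amplitude", {
  cfg <- noiseless_config()
  ss <- simulate_cell("c", 5, "EXC", cfg)
  expect_identical(nrow(unique(ss$trials)), 1L)      # every trial identical
  fe <- extract_features(ss)
  expect_lt(abs(fe$peak_amp_mV - 5) / 5, 1e-3)
  expect_gt(fe$slope_mV_per_ms, 0)
})

test_that("pharmacology and stability conditions act on the amplitude only", {
  cfg <- quick_config()
  set.seed(21)
  blocked <- simulate_cell("c", 14.5, "EXC", cfg, condition = "CNQX_APV")
  # receptor block: deviation from rest bounded by the noise envelope,
  # nothing like the 14.5 mV EPSP
  expect_lt(max(abs(colMeans(blocked$trials) - cfg$v_rest_mV)), 1)

  # zero drift: a late_timepoint cell is draw-for-draw identical to control
  set.seed(33); a <- simulate_cell("c", 10, "EXC", cfg)
  set.seed(33); b <- simulate_cell("c", 10, "EXC", cfg,
                                   condition = "late_timepoint")
  expect_identical(a$trials, b$trials)

  # non-zero drift scales the mean amplitude
  cfg_d <- quick_config(drift_per_hour = 0.5)
  set.seed(33); d <- simulate_cell("c", 10, "EXC", cfg_d,
                                   condition = "late_timepoint")
  expect_equal(extract_features(d)$peak_amp_mV,
               1.5 * extract_features(a)$peak_amp_mV, tolerance = 0.05)
})

test_that("degenerate reference cohort: measured amplitude = slice expression level", {
  gp <- data.frame(cell_type = "EXC", layer = "L4",
                   mean_norm_amp = 1, sd_norm_amp = 0, n_cells = 8L)
  cfg <- noiseless_config(n_slices = 4L, group_params = gp, seed = 3L)
  ds <- simulate_dataset(cfg)
  fe <- extract_features(ds$sweeps)
  m <- merge(fe, ds$truth, by = "cell_id")
  expect_lt(max(abs(m$peak_amp_mV - m$ref_abs_amp_mV) / m$ref_abs_amp_mV),
            1e-3)
})

test_that("sampling rules that cannot cover every slice with a reference cell error", {
  gp <- data.frame(cell_type = "EXC", layer = c("L4", "L3"),
                   mean_norm_amp = c(1, 0.5), sd_norm_amp = 0.1,
                   n_cells = c(3L, 10L))
  expect_error(simulation_config("VPM", n_slices = 4L, group_params = gp),
               "without a reference")
  expect_error(simulation_config("VPM", group_params = gp[2, ]),
               "reference|EXC group")
})

test_that("noiseless pipeline returns each cell's drawn generative strength", {
  # degenerate reference draws (SD 0) so slice denominators are exact
  gp <- default_group_params("VPM")
  gp <- gp[gp$cell_type == "EXC", ]
  gp$n_cells <- pmin(gp$n_cells, 4L)
  gp$sd_norm_amp[gp$layer == "L4"] <- 0
  cfg <- noiseless_config(n_slices = 3L, group_params = gp, seed = 8L)
  ds <- simulate_dataset(cfg)
  nz <- normalize_dataset(extract_features(ds$sweeps), ds$meta)
  m <- merge(nz, ds$truth, by = "cell_id")
  nzero <- m$gen_norm_amp > 0
  expect_lt(max(abs(m$norm_amp[nzero] - m$gen_norm_amp[nzero]) /
                  m$gen_norm_amp[nzero]), 1e-9)

  # across kinetics presets the same identity needs a finer grid than the
  # 20 kHz acquisition (grid-peak bias ~4e-5 for the fast PV preset)
  gp2 <- rbind(gp[gp$layer %in% c("L4", "L3"), ],
               data.frame(cell_type = c("PV", "VIP"), layer = "L4",
                          mean_norm_amp = c(1.15, 0.15),
                          sd_norm_amp = c(0.5, 0.1), n_cells = 3L))
  cfg2 <- simulation_config("VPM", n_slices = 2L, group_params = gp2,
                            noise = list(sigma_mV = 0, tau_ms = 10),
                            trial_amp_jitter_cv = 0, n_trials = 1L,
                            sampling_rate = 2e5, trace_len_s = 0.25,
                            stim_onset_s = 0.1, seed = 9L)
  ds2 <- simulate_dataset(cfg2)
  nz2 <- normalize_dataset(extract_features(ds2$sweeps), ds2$meta)
  m2 <- merge(nz2, ds2$truth, by = "cell_id")
  nzero2 <- m2$gen_norm_amp > 0
  expect_lt(max(abs(m2$norm_amp[nzero2] - m2$gen_norm_amp[nzero2]) /
                  m2$gen_norm_amp[nzero2]), 1e-6)
})

test_that("raising a group's generative mean raises its extracted group mean", {
  gp <- default_group_params("VPM")
  gp$n_cells <- pmin(gp$n_cells, 4L)
  lift <- gp$cell_type == "SST" & gp$layer == "L5B"
  gp2 <- gp; gp2$mean_norm_amp[lift] <- 0.6     # up from 0.01
  extracted_mean <- function(g) {
    cfg <- quick_config(n_slices = 4L, group_params = g, seed = 14L)
    ds <- simulate_dataset(cfg)
    nz <- normalize_dataset(extract_features(ds$sweeps), ds$meta)
    mean(nz$norm_amp[nz$cell_type == "SST" & nz$layer == "L5B"])
  }
  expect_gt(extracted_mean(gp2), extracted_mean(gp))
})

test_that("configs round-trip through their JSON file form", {
  f <- withr::local_tempfile(fileext = ".json")
  jsonlite::write_json(list(pathway = "POm", n_slices = 5, seed = 99,
                            noise = list(sigma_mV = 0.2, tau_ms = 8)),
                       f, auto_unbox = TRUE)
  cfg <- read_simulation_config(f)
  expect_identical(cfg$pathway, "POm")
  expect_identical(cfg$n_slices, 5L)
  expect_identical(cfg$noise$sigma_mV, 0.2)
  expect_identical(reference_layer(cfg$pathway), "L5A")
  jsonlite::write_json(list(pathway = "VPM", bogus_field = 1), f,
                       auto_unbox = TRUE)
  expect_error(read_simulation_config(f), "unknown configuration field")
})
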