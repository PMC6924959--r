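test_that("summary tables print reference cells at 1.00 and leave gaps blank", {
  cfg <- small_cohort_config(seed = 23L)
  ds <- simulate_dataset(cfg)
  nz <- suppressWarnings(normalize_dataset(extract_features(ds$sweeps),
                                           ds$meta))
  pooled <- pool_groups(nz)
  tab <- build_summary_table(pooled, "VPM", "amplitude", "normalized")

  ref <- tab$numeric[tab$numeric$cell_type == "EXC" &
                       tab$numeric$layer == "L4", ]
  expect_equal(ref$mean, 1)
  expect_equal(ref$median, 1)
  expect_match(tab$pretty["L4", "EXC"], "^1\\.00 ± ")
  expect_match(tab$pretty["L4", "EXC"], "\\*1\\*")

  # a group absent from the cohort renders as a blank cell, not zero
  pooled_cut <- pooled[!(pooled$cell_type == "VIP" & pooled$layer == "L6"), ]
  tab2 <- build_summary_table(pooled_cut, "VPM", "amplitude")
  expect_identical(tab2$pretty["L6", "VIP"], "")

  # single-cell groups print median and n only
  one <- pooled
  keep <- one$cell_type == "SST" & one$layer == "L2"
  one$n_norm_amp[keep] <- 1L
  one$sd_norm_amp[keep] <- NA_real_
  tab3 <- build_summary_table(one, "VPM", "amplitude")
  expect_match(tab3$pretty["L2", "SST"], "^\\*.*\\* n = 1$")
})

test_that("depth profiles peak inside the reference band and log omissions", {
  gp <- default_group_params("VPM")
  gp <- gp[gp$cell_type == "EXC", ]
  gp$n_cells <- pmin(gp$n_cells, 12L)
  peak_in_l4 <- 0
  for (seed in 1:5) {
    cfg <- quick_config(n_slices = 6L, group_params = gp, seed = 400L + seed)
    ds <- simulate_dataset(cfg)
    nz <- suppressWarnings(normalize_dataset(extract_features(ds$sweeps),
                                             ds$meta))
    prof <- build_depth_profile(nz)
    # running median over depth-sorted cells
    k <- 15
    rmed <- vapply(seq_len(nrow(prof) - k + 1), function(i)
      median(prof$value[i:(i + k - 1)]), numeric(1))
    peak_depth <- prof$depth_um[which.max(rmed) + (k - 1) %/% 2]
    b <- layer_boundaries()
    l4 <- b[b$layer == "L4", ]
    peak_in_l4 <- peak_in_l4 +
      (peak_depth >= l4$depth_lo_um && peak_depth < l4$depth_hi_um)
  }
  expect_gte(peak_in_l4, 4)   # strongest input localizes to the L4 band

  # cells without depth are omitted and counted
  nz$depth_um[1:3] <- NA
  expect_message(prof2 <- build_depth_profile(nz), "omitted")
  expect_identical(attr(prof2, "n_omitted"), 3L)
  expect_false(any(prof2$cell_id %in% nz$cell_id[1:3]))
  expect_true(!is.unsorted(prof2$depth_um))
})

test_that("grand-average time courses separate kinetics by cell type", {
  cfg <- noiseless_config()
  sweeps <- list(simulate_cell("e1", 10, "EXC", cfg),
                 simulate_cell("e2", 6, "EXC", cfg),
                 simulate_cell("p1", 8, "PV", cfg))
  meta <- data.frame(cell_id = c("e1", "e2", "p1"), slice_id = "s1",
                     mouse_id = "m1", pathway = "VPM",
                     cell_type = c("EXC", "EXC", "PV"), layer = "L4",
                     depth_um = 500, condition = "control")
  tc <- build_grand_average_timecourse(sweeps, meta)
  expect_identical(names(tc), c("time_ms", "EXC", "PV"))
  # baseline-subtracted: pre-stimulus portion is flat at 0
  expect_lt(max(abs(tc$EXC[tc$time_ms < 0])), 1e-9)
  # single-type average of two cells is the mean of their amplitudes
  expect_equal(max(tc$EXC), 8, tolerance = 1e-3)

  half_time <- function(v) tc$time_ms[which(v >= max(v) / 2)[1]]
  expect_lt(half_time(tc$PV), half_time(tc$EXC))   # PV rises earlier

  # per-cell normalization rescales each trace to unit peak
  tcn <- build_grand_average_timecourse(sweeps, meta,
                                        normalize_per_cell = TRUE)
  expect_equal(max(tcn$EXC), 1, tolerance = 1e-3)

  # a receptor-blocked cohort averages to a near-flat trace
  cfgn <- quick_config()
  set.seed(50)
  blocked <- lapply(1:4, function(i)
    simulate_cell(paste0("e", i), 14.5, "EXC", cfgn,
                  condition = "CNQX_APV"))
  metab <- data.frame(cell_id = paste0("e", 1:4), slice_id = "s1",
                      mouse_id = "m1", pathway = "VPM", cell_type = "EXC",
                      layer = "L4", depth_um = 500, condition = "CNQX_APV")
  tcb <- build_grand_average_timecourse(blocked, metab)
  expect_lt(max(abs(tcb$EXC)), 0.5)
})

test_that("the pipeline is deterministic and records exclusions", {
  cfg <- small_cohort_config(n_slices = 3L, cap = 3L, seed = 61L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  r1 <- run_pipeline(d1, config = cfg, quiet = TRUE)
  r2 <- run_pipeline(d2, config = cfg, quiet = TRUE)
  csvs <- basename(r1$paths)
  expect_identical(unname(tools::md5sum(file.path(d1, csvs))),
                   unname(tools::md5sum(file.path(d2, csvs))))
  expect_true(file.exists(file.path(d1, "manifest.json")))
  expect_length(r1$manifest$excluded_slices, 0)
  # every feature row traceable to a cell
  expect_setequal(r1$features$cell_id,
                  vapply(simulate_dataset(cfg)$sweeps, `[[`, "", "cell_id"))

  # a dataset with a reference-free slice completes, with the exclusion
  # recorded in the manifest
  cfg1 <- noiseless_config()
  sweeps <- list(simulate_cell("a1", 12, "EXC", cfg1),
                 simulate_cell("a2", 6, "PV", cfg1),
                 simulate_cell("b1", 5, "PV", cfg1))
  meta <- data.frame(cell_id = c("a1", "a2", "b1"),
                     slice_id = c("sA", "sA", "sB"),
                     mouse_id = c("mA", "mA", "mB"), pathway = "VPM",
                     cell_type = c("EXC", "PV", "PV"), layer = "L4",
                     depth_um = 500, condition = "control")
  dpath <- withr::local_tempdir(); opath <- withr::local_tempdir()
  write_dataset(sweeps, meta, dpath)
  res <- run_pipeline(opath, dataset_path = dpath, quiet = TRUE)
  expect_identical(res$manifest$excluded_slices, list("sB"))
  expect_false("b1" %in% res$normalized$cell_id)
})
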