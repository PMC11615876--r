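test_that("datasets round-trip through disk with schema validation", {
  tn <- tiny_noiseless()
  dir <- withr::local_tempdir()
  write_dataset(tn$ds, dir)
  raw <- load_dataset(dir)
  expect_equal(nrow(raw$cgm), nrow(tn$ds$cgm))
  expect_equal(nrow(raw$meals), nrow(tn$ds$meals))
  expect_equal(nrow(raw$profiles), nrow(tn$ds$profiles))

  # a file lacking the glucose column is a schema error naming it
  cgm <- data.table::fread(file.path(dir, "cgm.csv"))
  data.table::fwrite(cgm[, .(patient_id, timestamp)], file.path(dir, "cgm.csv"))
  expect_error(load_dataset(dir), regexp = "glucose_mgdl",
               class = "glycotwin_schema_error")

  # one unparseable timestamp: that row is reported, the rest load
  cgm[, timestamp := as.character(timestamp)]
  cgm[2, timestamp := "not-a-date"]
  data.table::fwrite(cgm, file.path(dir, "cgm.csv"))
  raw2 <- load_dataset(dir)
  expect_equal(nrow(raw2$cgm), nrow(cgm) - 1)
  errs <- attr(raw2, "row_errors")
  expect_equal(nrow(errs), 1)
  expect_equal(errs$value, "not-a-date")
})

test_that("outlier flagging is sharp, monotone and idempotent", {
  const <- make_trace(rep(100, 60))
  expect_equal(sum(flag_outliers(const)$quality_flag == "outlier"), 0)

  spike <- rep(100, 60); spike[30] <- 400
  fl <- flag_outliers(make_trace(spike), z_threshold = 5)
  expect_identical(which(fl$quality_flag == "outlier"), 30L)

  # lower threshold flags a superset
  noisy <- make_trace(100 + rnorm(500, 0, 10))
  f5 <- which(flag_outliers(noisy, z_threshold = 5)$quality_flag == "outlier")
  f3 <- which(flag_outliers(noisy, z_threshold = 3)$quality_flag == "outlier")
  expect_true(all(f5 %in% f3))

  # idempotence and value preservation
  once <- flag_outliers(noisy)
  twice <- flag_outliers(once)
  expect_identical(once, twice)
  expect_identical(once$glucose_mgdl, noisy$glucose_mgdl)

  expect_error(flag_outliers(noisy, window = 2),
               class = "glycotwin_invalid_config")
})

test_that("injected sensor artifacts are recovered at documented defaults", {
  cfg <- sim_config(n_patients = 4, days = 10, seed = 17, noise_sd = 12,
                    outlier_rate = 0.02, enrollment_span_days = 0)
  ds <- simulate_study(generate_cohort(cfg), cfg)
  cor <- corrupt_dataset(ds, cfg)
  cleaned <- clean_cgm(cor)
  flags <- cleaned$cgm$quality_flag == "outlier"
  truth <- cleaned$cgm$truth_outlier
  recall <- sum(flags & truth) / sum(truth)
  expect_gte(recall, 0.9)
})

test_that("gap interpolation fills short interior gaps only", {
  tr <- make_trace(c(100, 120), by_min = 10)
  out <- interpolate_gaps(tr, max_gap = 15, interval = 5)
  expect_equal(nrow(out), 3)
  expect_equal(out$glucose_mgdl[2], 110)
  expect_equal(out$quality_flag[2], "imputed")

  # a 120-min gap with max_gap 30 is untouched
  tr2 <- make_trace(c(100, 105, 130, 131))
  tr2$timestamp[3:4] <- tr2$timestamp[3:4] + 120 * 60
  out2 <- interpolate_gaps(tr2, max_gap = 30, interval = 5)
  expect_identical(out2$glucose_mgdl, tr2$glucose_mgdl)

  # no gaps: identity
  tr3 <- make_trace(100 + seq_len(20))
  expect_identical(interpolate_gaps(tr3, max_gap = 30, interval = 5)$glucose_mgdl,
                   tr3$glucose_mgdl)
})

test_that("cleaning never alters observed, unflagged values", {
  sn <- small_noisy()
  raw <- memo("small_noisy_raw", function() {
    cfg <- sim_config(n_patients = 10, days = 20, seed = 21, noise_sd = 12,
                      enrollment_span_days = 70)
    simulate_study(generate_cohort(cfg), cfg)
  })
  m <- merge(sn$ds$cgm[quality_flag %in% c("ok", "outlier")],
             raw$cgm[, .(patient_id, timestamp, orig = glucose_mgdl)],
             by = c("patient_id", "timestamp"))
  expect_equal(m$glucose_mgdl, m$orig)
})
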