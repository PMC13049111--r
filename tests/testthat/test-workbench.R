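test_that("synthetic measurements are exact at zero noise and reproducible", {
  b <- beam_al_cu(90)
  m0 <- generate_synthetic_measurement(b, 0, "narrow", 0, seed = 1)
  expect_equal(m0$transmission, 1)
  m <- generate_synthetic_measurement(b, 0.5, "narrow", 0.01, seed = 10)
  m2 <- generate_synthetic_measurement(b, 0.5, "narrow", 0.01, seed = 10)
  expect_identical(m$k_air_with, m2$k_air_with)
  # broad readings are raised by the shield's secondaries (T_B = T_N B)
  mb <- generate_synthetic_measurement(beam_al_cu(100, 0.2), 0.5, "broad",
                                       0, seed = 1)
  mn <- generate_synthetic_measurement(beam_al_cu(100, 0.2), 0.5, "narrow",
                                       0, seed = 1)
  expect_gt(mb$transmission, mn$transmission)
})

test_that("noisy fixtures recover thickness within propagated uncertainty", {
  b <- beam_al_cu(90, 0.2)
  true_t <- 0.5
  err <- vapply(1:30, function(i) {
    m <- generate_synthetic_measurement(b, true_t, "narrow", 0.01,
                                        seed = 100 + i)
    lead_equivalence_narrow(m)$t_mm - true_t
  }, 0)
  # 1% noise on each of two readings -> ~1.4% on T; |dT/dt| maps that to t
  expect_lt(median(abs(err)) / true_t, 0.02)
  expect_gt(stats::sd(err), 0)  # noise does propagate
})

test_that("measurement CSV round-trips and feeds the batch report", {
  beams <- list(beam_al_cu(90), beam_al_cu(121, 0.2))
  ms <- c(lapply(seq_along(beams), function(i)
    generate_synthetic_measurement(beams[[i]], 0.5, "narrow", 0,
                                   seed = i)),
    list(generate_synthetic_measurement(beam_al_cu(100, 0.2), 0.35, "broad",
                                        0, seed = 9)))
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(ms, path)
  d <- read_measurement_csv(path)
  expect_equal(nrow(d), 3)
  expect_equal(d$geometry, c("narrow", "narrow", "broad"))
  out_json <- withr::local_tempfile(fileext = ".json")
  rep <- run_report(path, run_config(u_rel = 0.02), out_json = out_json)
  expect_true(all(is.na(rep$error)))
  expect_equal(rep$t_mm, c(0.5, 0.5, 0.35), tolerance = 1e-3)
  expect_true(all(rep$compliance_pass))
  j <- jsonlite::read_json(out_json)
  expect_true(nzchar(j$config_hash))
  expect_equal(j$config$u_rel, 0.02)
})

test_that("malformed rows become error records and the run continues", {
  b <- beam_al_cu(90)
  good <- generate_synthetic_measurement(b, 0.3, "narrow", 0, seed = 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(list(good), path)
  d <- read_measurement_csv(path)
  bad <- d; bad$k_with <- bad$k_without * 2  # transmission > 1
  bad$label <- "overunity"
  d <- rbind(d, bad)
  ugly <- d[1, ]; ugly$filters <- "Al-3"; ugly$label <- "typo"
  d <- rbind(d, ugly)
  write.csv(d, path, row.names = FALSE)
  rep <- run_report(path)
  expect_equal(nrow(rep), 3)
  expect_true(is.na(rep$error[1]))
  expect_match(rep$error[2], "> 1")
  expect_match(rep$error[3], "malformed")
})

test_that("an empty measurement file yields an empty report with a warning", {
  path <- withr::local_tempfile(fileext = ".csv")
  write_measurement_csv(list(), path)
  expect_warning(rep <- run_report(path), "empty")
  expect_equal(nrow(rep), 0)
})

test_that("the run config is serializable with a stable content hash", {
  cfg <- run_config(seed = 7, u_rel = 0.03)
  h1 <- pbeq:::config_hash(cfg)
  expect_identical(h1, pbeq:::config_hash(run_config(seed = 7, u_rel = 0.03)))
  expect_false(identical(h1, pbeq:::config_hash(run_config(seed = 8))))
})
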