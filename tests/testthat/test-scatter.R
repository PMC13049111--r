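test_that("fixed seed and histories reproduce tallies bitwise", {
  b <- beam_al_cu(90)
  t1 <- simulate_scatter(b, n_histories = 5e4, seed = 42)
  t2 <- simulate_scatter(b, n_histories = 5e4, seed = 42)
  expect_identical(t1[[2]]$fluence, t2[[2]]$fluence)
  t3 <- simulate_scatter(b, n_histories = 5e4, seed = 43)
  expect_false(identical(t1[[2]]$fluence, t3[[2]]$fluence))
})

test_that("no tally fluence appears above the incident endpoint or cutoff", {
  tal <- simulate_scatter(beam_al_cu(90), n_histories = 1e5, seed = 2)
  for (t in tal) {
    expect_true(all(t$fluence[t$energy_kev > 90] == 0))
    expect_true(all(t$fluence[t$energy_kev < 10] == 0))
    expect_true(all(t$fluence >= 0))
  }
})

test_that("single-scatter kinematics concentrate at the Compton line", {
  # monoenergetic 60-keV pencil beam on a small phantom; the 90-degree
  # line is 60/(1 + (60/511)(1 - cos 90)) = 53.66 keV
  mono <- fluence_spectrum(c(59.75, 60.25), 1, kv_max = 60.25)
  g <- scatter_geometry(cylinder_diameter_cm = 2, cylinder_height_cm = 2,
                        field_cm = 0.2)
  tal <- simulate_scatter(mono, g, n_histories = 1e5, seed = 4,
                          single_scatter_only = TRUE)
  sp <- tal[[2]]
  peak <- sp$energy_kev[which.max(sp$fluence)]
  expect_lt(abs(peak - 53.66), 1.6)
  inwin <- sum(sp$fluence[abs(sp$energy_kev - 53.66) < 3]) / sum(sp$fluence)
  expect_gt(inwin, 0.9)
})

test_that("track-length and boundary-crossing estimators agree", {
  tal <- simulate_scatter(beam_al_cu(90), n_histories = 4e5, seed = 9)
  for (t in tal) {
    tl <- sum(t$fluence); bc <- sum(t$fluence_bc)
    expect_lt(abs(tl / bc - 1), 0.05)
  }
})

test_that("batch standard error shrinks like one over root histories", {
  b <- beam_al_cu(90)
  se_of <- function(nh, seed) {
    t <- simulate_scatter(b, n_histories = nh, seed = seed, n_batches = 10)[[2]]
    top <- t$fluence > 0.3 * max(t$fluence)
    mean(t$rel_unc[top], na.rm = TRUE)
  }
  r <- se_of(1e5, 21) / se_of(16e5, 21)
  expect_gt(r, 2.4); expect_lt(r, 6.4)  # expect ~ 4
})

test_that("scatter quality orders with angle as published", {
  # Cu-filtered beam: scatter softens with angle, all softer than incident
  tal <- simulate_scatter(beam_al_cu(90, 0.5), n_histories = 5e5, seed = 6)
  q <- lapply(tal, scatter_quality)
  inc <- beam_quality(beam_al_cu(90, 0.5))
  expect_lt(q[[3]]$tvl1_mm_pb, q[[2]]$tvl1_mm_pb)  # 135 softer than 90
  expect_lt(q[[2]]$tvl1_mm_pb, inc$tvl1_mm_pb)
  expect_error(scatter_quality(structure(list(energy_kev = 1:20 - 0.5,
                                              fluence = rep(0, 20)),
                                         class = "scatter_tally")),
               "degenerate|empty")
})

test_that("MC buildup: thin sheets give no buildup, sub-K-edge beams ~ 1", {
  thin <- simulate_buildup(beam_al_cu(100, 0.2), 0.01, n_histories = 4e4,
                           seed = 8)
  expect_lt(abs(thin$b - 1), 0.02)
  soft <- simulate_buildup(beam_al_cu(50), 0.5, n_histories = 4e4, seed = 8)
  expect_lt(abs(soft$b - 1), 0.05)
  hard <- simulate_buildup(beam_al_cu(120, 0.2), 0.5, n_histories = 4e4,
                           seed = 8)
  expect_gt(hard$b, 1.05)
  expect_error(simulate_buildup(beam_al_cu(100), 0.5,
                                broad_geometry = list(bogus = 1)),
               "broad_geometry")
})
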