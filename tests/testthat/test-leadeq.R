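test_that("narrow inversion recovers known thicknesses across beams", {
  cases <- list(list(beam_al_cu(90), 0.5), list(beam_al_cu(121, 0.2), 1.0),
                list(beam_al_cu(60, 0.5), 0.25))
  for (cs in cases) {
    m <- generate_synthetic_measurement(cs[[1]], cs[[2]], "narrow",
                                        noise_rel = 0, seed = 7)
    r <- lead_equivalence_narrow(m)
    expect_true(r$converged)
    expect_lt(abs(r$t_mm - cs[[2]]), 1e-3)
  }
  # measured T = 1 means nothing in the beam
  m0 <- transmission_measurement(beam_al_cu(90), "narrow", 10, 10)
  expect_equal(lead_equivalence_narrow(m0)$t_mm, 0)
})

test_that("broad inversion with B = 1 collapses to the narrow result", {
  flat <- buildup_model(data.frame(hvl = c(1.9, 6.9), b025 = 1, b035 = 1,
                                   b050 = 1, b100 = 1))
  beam <- beam_al_cu(90, 0.2)
  tn <- narrow_transmission(beam, "Pb", 0.4)
  mb <- transmission_measurement(beam, "broad", tn * 100, 100)
  mn <- transmission_measurement(beam, "narrow", tn * 100, 100)
  rb <- lead_equivalence_broad(mb, flat)
  rn <- lead_equivalence_narrow(mn)
  expect_equal(rb$t_mm, rn$t_mm, tolerance = 1e-9)
  expect_equal(rb$buildup, 1)
})

test_that("broad inversion undoes the forward buildup model", {
  model <- buildup_model()
  for (cs in list(list(beam_al_cu(90), 0.5), list(beam_al_cu(121, 0.2), 1.0),
                  list(beam_al_cu(100, 0.2), 0.35))) {
    # the hardest beam sits above the anchor qualities: B is clamped there
    suppressWarnings({
      m <- generate_synthetic_measurement(cs[[1]], cs[[2]], "broad",
                                          noise_rel = 0, seed = 3,
                                          model = model)
      r <- lead_equivalence_broad(m, model)
    })
    expect_true(r$converged)
    expect_lte(r$iterations, 50)
    expect_lt(abs(r$t_mm - cs[[2]]), 1e-3)
    expect_gte(r$buildup, 1)
  }
})

test_that("ignoring buildup understates the thickness when B > 1", {
  beam <- beam_al_cu(100, 0.2)  # hard beam, B(1 mm) ~ 1.4
  m <- generate_synthetic_measurement(beam, 1.0, "broad", noise_rel = 0,
                                      seed = 5)
  corrected <- lead_equivalence_broad(m)$t_mm
  naive <- thickness_for_transmission(beam, "Pb", m$transmission)
  expect_gt(corrected, naive)
  # direction and rough size of the published 5-28% underestimate
  expect_gt((corrected - naive) / corrected, 0.03)
  expect_lt((corrected - naive) / corrected, 0.35)
})

test_that("lower transmission means more lead, in both geometries", {
  beam <- beam_al_cu(90)
  tr <- c(0.6, 0.3, 0.1, 0.03)
  tn <- vapply(tr, function(f) lead_equivalence_narrow(
    transmission_measurement(beam, "narrow", f * 50, 50))$t_mm, 0)
  expect_true(all(diff(tn) > 0))
  tb <- vapply(tr, function(f) lead_equivalence_broad(
    transmission_measurement(beam, "broad", f * 50, 50))$t_mm, 0)
  expect_true(all(diff(tb) > 0))
})

test_that("detector corrections enter as plain multipliers and are validated", {
  beam <- beam_al_cu(90)
  m <- transmission_measurement(beam, "narrow", 40, 100,
                                correction_with = 0.98,
                                correction_without = 1.02)
  expect_equal(m$transmission, 40 * 0.98 / (100 * 1.02))
  expect_error(transmission_measurement(beam, "narrow", 110, 100),
               "> 1")
  expect_error(transmission_measurement(beam, "narrow", -1, 100), "> 0")
})

test_that("a stated transmission uncertainty propagates to a k=2 interval", {
  beam <- beam_al_cu(90, 0.2)
  m <- generate_synthetic_measurement(beam, 0.5, "narrow", 0, seed = 1)
  r <- lead_equivalence_narrow(m, u_rel = 0.02)
  expect_true(is.finite(r$u_t_mm) && r$u_t_mm > 0)
  # the interval half-width should scale roughly linearly with u_rel
  r2 <- lead_equivalence_narrow(m, u_rel = 0.04)
  expect_equal(r2$u_t_mm / r$u_t_mm, 2, tolerance = 0.2)
})

test_that("IEC compliance uses the inclusive 0.93 boundary", {
  r <- pbeq:::leadeq_result(0.5, "narrow", 0.1)
  expect_true(compliance_check(r, 0.5)$pass)
  expect_equal(compliance_check(r, 0.5)$margin, 1.0)
  expect_true(compliance_check(pbeq:::leadeq_result(0.465, "narrow", .1),
                               0.5)$pass)
  expect_false(compliance_check(pbeq:::leadeq_result(0.45, "narrow", .1),
                                0.5)$pass)
})
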