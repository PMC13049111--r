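test_that("air kerma is linear and reduces to one term for a single bin", {
  sp <- make_spectrum(beam_spec(70, filters = "Al:3.0"))
  expect_equal(air_kerma(fluence_spectrum(sp$bin_edges, 3.7 * sp$fluence,
                                          sp$kv_max)),
               3.7 * air_kerma(sp), tolerance = 1e-12)
  mono <- fluence_spectrum(c(59.5, 60.5), 2.0, kv_max = 60.5)
  expect_equal(air_kerma(mono), 60 * 2.0 * muen("air", 60) * 1.0,
               tolerance = 1e-12)
  expect_error(fluence_spectrum(c(1, 2), 0), "no fluence")
})

test_that("quadrature is stable under grid refinement", {
  spec <- beam_al_cu(90, 0.2)
  t_half <- thickness_for_transmission(make_spectrum(spec), "Al", 0.5)
  coarse <- narrow_transmission(make_spectrum(spec, bin_kev = 0.5), "Al", t_half)
  fine <- narrow_transmission(make_spectrum(spec, bin_kev = 0.25), "Al", t_half)
  expect_lt(abs(fine / coarse - 1), 0.002)
})

test_that("narrow transmission: identity at zero, closed form for mono beams", {
  spec <- beam_al_cu(80)
  expect_equal(narrow_transmission(spec, "Pb", 0), 1.0)
  mono <- fluence_spectrum(c(59.5, 60.5), 1, kv_max = 60.5)
  t_mm <- 0.3
  expect_equal(narrow_transmission(mono, "Pb", t_mm),
               exp(-mu("Pb", 60) * material_density("Pb") * t_mm / 10),
               tolerance = 1e-9)
})

test_that("polychromatic hardening makes successive layers less effective", {
  for (i in seq_len(nrow(reference_hvl_table()))) {
    r <- reference_hvl_table()[i, ]
    sp <- make_spectrum(beam_al_cu(r$kv, r$cu))
    t1 <- 0.15; t2 <- 0.25
    expect_gte(narrow_transmission(sp, "Pb", t1 + t2) + 1e-12,
               narrow_transmission(sp, "Pb", t1) *
                 narrow_transmission(sp, "Pb", t2))
  }
})

test_that("transmission-to-thickness inversion round-trips", {
  spec <- beam_al_cu(90, 0.2)
  sp <- make_spectrum(spec)
  expect_identical(thickness_for_transmission(sp, "Pb", 1), 0)
  for (f in c(0.5, 0.1, 0.01)) {
    t <- thickness_for_transmission(sp, "Pb", f)
    expect_lt(abs(narrow_transmission(sp, "Pb", t) - f), 1e-6)
  }
  expect_error(thickness_for_transmission(sp, "Pb", 0), "\\(0, 1\\]")
  expect_error(thickness_for_transmission(sp, "Pb", 1.2), "\\(0, 1\\]")
  # a weak attenuator cannot reach 50% transmission within the bracket
  expect_error(thickness_for_transmission(sp, "air", 0.5), "no bracket")
})

test_that("beam quality metrics: mono beams have h = 1, poly beams h <= 1", {
  mono <- fluence_spectrum(c(79.5, 80.5), 1, kv_max = 80.5)
  q <- beam_quality(mono)
  expect_equal(q$h, 1, tolerance = 1e-4)
  for (kv in c(60, 100)) {
    q <- beam_quality(beam_al_cu(kv))
    expect_lte(q$h, 1 + 1e-9)
    expect_gt(q$tvl12_mm_pb, q$tvl1_mm_pb)
    # second TVL at least as thick as the first (hardening)
    expect_gte(q$tvl12_mm_pb - q$tvl1_mm_pb, q$tvl1_mm_pb)
  }
})
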