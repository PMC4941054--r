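test_that("Monte-Carlo sampling respects ranges, ties and determinism", {
  sp <- sample_species(300, 1)
  expect_equal(nrow(sp), 300)
  expect_equal(nrow(unique(sp)), 300)  # all distinct
  r <- default_species_ranges()
  for (k in seq_len(nrow(r))) {
    v <- switch(r$param[k], vcmax_ref = sp$vcmax_ref, q10 = sp$q10,
                d_co2_sat = sp$d_co2_sat, theta_max = sp$theta_max,
                albedo = sp$albedo, t_opt = sp$t_opt, NULL)
    if (!is.null(v)) {
      expect_true(all(v >= r$min[k] & v <= r$max[k]))
    }
  }
  # universal constraints are shared; respiration is tied to capacity
  expect_equal(length(unique(sp$phi_rr)), 1L)
  expect_equal(length(unique(sp$eta_ccm)), 1L)
  expect_equal(sp$resp_ref, sp$vcmax_ref / sp$phi_rr)
  expect_identical(sp, sample_species(300, 1))
})

test_that("degenerate ranges collapse the population to one phenotype", {
  r <- default_species_ranges()
  r$min <- r$max
  sp <- sample_species(5, 1, ranges = r)
  expect_equal(nrow(unique(sp)), 1L)
})

test_that("extending the diffusivity range extends the sampled extremes", {
  base <- sample_species(10000, 3)
  wide <- sample_species(10000, 3,
                         ranges = scale_dco2_range(default_species_ranges(),
                                                   high = 2))
  expect_gt(max(wide$d_co2_sat), max(base$d_co2_sat))
  narrow_lo <- sample_species(10000, 3,
                              ranges = scale_dco2_range(
                                default_species_ranges(), low = 0.5))
  expect_lt(min(narrow_lo$d_co2_sat), min(base$d_co2_sat))
})

test_that("invalid sampling inputs are rejected", {
  r <- default_species_ranges()
  r$min[1] <- r$max[1] + 1
  expect_error(sample_species(10, 1, ranges = r), "invalid sampling ranges")
  expect_error(sample_species(0, 1), ">= 1")
})
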