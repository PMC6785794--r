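s_test <- s_factor_set(5e-9, 2e-8, "male", "test values")

test_that("organ-mass weighting of S factors is a weighted mean", {
  one <- data.frame(organ = "x", mass_g = 123,
                    s_bm_gy_per_mbq_h = 2e-8)
  expect_equal(weighted_s_factor(one), 2e-8)
  two <- data.frame(organ = c("a", "b"), mass_g = c(1000, 3000),
                    s_bm_gy_per_mbq_h = c(1.153e-8, 2.307e-8))
  expect_equal(weighted_s_factor(two), 0.25 * 1.153e-8 + 0.75 * 2.307e-8)
  # equal S: the masses cancel
  eq <- data.frame(organ = letters[1:3], mass_g = c(10, 500, 9000),
                   s_bm_gy_per_mbq_h = 7e-9)
  expect_equal(weighted_s_factor(eq), 7e-9)
  expect_error(weighted_s_factor(two[0, ]), "non-empty")
  two$mass_g[1] <- 0
  expect_error(weighted_s_factor(two), "positive")
})

test_that("shipped default S factors load and differ by sex", {
  sf <- default_s_factors("female")
  sm <- default_s_factors("male")
  expect_gt(sf$s_bm_from_low, 0)
  expect_gt(sf$s_bm_from_high, sf$s_bm_from_low)
  expect_false(sf$s_bm_from_high == sm$s_bm_from_high)
  expect_match(sf$provenance, "synthetic")
})

test_that("self-dose term matches the independent unit conversion", {
  # 3.6e9 decays/(MBq h) * 147 keV * 1.602177e-16 J/keV * 1000 g/kg
  expect_equal(self_dose_coefficient(147), 0.08478, tolerance = 2e-4)
  inp <- dose_inputs(1, 0, 0, s_test)
  d <- bone_marrow_dose_planar(inp)
  expect_equal(d$dose_gy, 0.1526, tolerance = 5e-4)  # after the 1.8 ratio
})

test_that("planar dose sums hand-computed self and cross terms", {
  inp <- dose_inputs(0.5, 20000, 15000, s_test, administered_gbq = 7.4)
  d <- bone_marrow_dose_planar(inp)
  expect_equal(d$dose_gy, 0.5 * 1.8 * 0.0847872 + 1e-4 + 3e-4,
               tolerance = 1e-4)
  expect_equal(d$dose_gy_per_7p4gbq, d$dose_gy)
  zero <- bone_marrow_dose_planar(dose_inputs(0, 0, 0, s_test))
  expect_equal(zero$dose_gy, 0)
})

test_that("the hybrid equation reduces to the planar one at k = 1.8", {
  set.seed(8)
  for (i in 1:20) {
    inp <- dose_inputs(runif(1, 0, 3), runif(1, 0, 1e5), runif(1, 0, 1e5),
                       s_test, administered_gbq = runif(1, 6.8, 8))
    expect_identical(bone_marrow_dose_hybrid(inp, 1.8, "V_SPECT")$dose_gy,
                     bone_marrow_dose_planar(inp)$dose_gy)
  }
  # k scales only the self term
  inp1 <- dose_inputs(1, 0, 0, s_test)
  expect_equal(bone_marrow_dose_hybrid(inp1, 2.5, "L4_SPECT")$dose_gy,
               0.2120, tolerance = 1e-3)
  inp2 <- dose_inputs(1, 20000, 15000, s_test)
  expect_equal(bone_marrow_dose_hybrid(inp2, 0, "L_SPECT")$dose_gy,
               20000 * 5e-9 + 15000 * 2e-8)
})

test_that("hybrid scale factor divides vertebral by fitted concentration", {
  curve <- tac_biexponential(1440, 0.01)          # activity MBq
  conc <- to_concentration(curve, 63000)           # MBq/g
  c24 <- predict(conc, 24) * 1000                  # kBq/mL
  expect_equal(hybrid_scale_factor(1.8 * c24, conc), 1.8)
  expect_equal(hybrid_scale_factor(45, conc), 45 / c24)
  expect_equal(hybrid_scale_factor(0, conc), 0)
})

test_that("dose is linear and monotone in its activity inputs", {
  set.seed(19)
  for (i in 1:10) {
    c0 <- runif(1, 0.1, 2); al <- runif(1, 1e3, 1e5)
    ah <- runif(1, 1e3, 1e5); k <- runif(1, 0.5, 5)
    scale <- runif(1, 0.2, 4)
    d1 <- bone_marrow_dose_hybrid(dose_inputs(c0, al, ah, s_test), k,
                                  "V_SPECT")$dose_gy
    d2 <- bone_marrow_dose_hybrid(
      dose_inputs(scale * c0, scale * al, scale * ah, s_test), k,
      "V_SPECT")$dose_gy
    expect_equal(d2, scale * d1, tolerance = 1e-12)
    # monotonicity in each argument
    expect_gt(bone_marrow_dose_hybrid(dose_inputs(c0 * 1.1, al, ah, s_test),
                                      k, "V_SPECT")$dose_gy, d1)
    expect_gt(bone_marrow_dose_hybrid(dose_inputs(c0, al * 1.1, ah, s_test),
                                      k, "V_SPECT")$dose_gy, d1)
    expect_gt(bone_marrow_dose_hybrid(dose_inputs(c0, al, ah * 1.1, s_test),
                                      k, "V_SPECT")$dose_gy, d1)
  }
})

test_that("per-7.4-GBq normalisation is invariant under joint scaling", {
  set.seed(2)
  for (i in 1:10) {
    a0 <- runif(1, 6.8, 8); scale <- runif(1, 0.5, 2)
    d1 <- bone_marrow_dose_planar(
      dose_inputs(1, 2e4, 1e4, s_test, administered_gbq = a0))
    d2 <- bone_marrow_dose_planar(
      dose_inputs(scale, scale * 2e4, scale * 1e4, s_test,
                  administered_gbq = scale * a0))
    expect_equal(d2$dose_gy_per_7p4gbq, d1$dose_gy_per_7p4gbq,
                 tolerance = 1e-12)
  }
})

test_that("fraction doses accumulate within one method only", {
  inp <- dose_inputs(1, 2e4, 1e4, s_test)
  d1 <- bone_marrow_dose_planar(inp, fraction = 1)
  d2 <- bone_marrow_dose_planar(inp, fraction = 2)
  acc <- accumulate_doses(list(d1, d2))
  expect_equal(acc$cumulative_gy, d1$dose_gy + d2$dose_gy)
  expect_equal(acc$fraction, 2L)
  expect_equal(accumulate_doses(list(d1))$cumulative_gy, d1$dose_gy)
  h <- bone_marrow_dose_hybrid(inp, 2, "L4_SPECT", fraction = 2)
  expect_error(accumulate_doses(list(d1, h)), "different methods")
  expect_error(accumulate_doses(list(d1, d1)), "duplicate fraction")
})
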