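make_study <- function(ant, post, time_h = 24) {
  planar_study(ant, post, time_h, pixel_area_cm2 = 0.25, duration_s = 30)
}

test_that("geometric mean combines mirrored conjugate views pixelwise", {
  ant <- matrix(c(4, 9, 5, 0), 2, 2)
  post_mirrored <- matrix(c(4, 1, 0, 7), 2, 2)
  # stored posterior is the left-right flip of its anterior-frame image
  post <- post_mirrored[2:1, ]
  gm <- geometric_mean_image(make_study(ant, post))
  expect_equal(gm, matrix(c(4, 3, 0, 0), 2, 2))

  # symmetry under swapping anterior and mirrored posterior
  study_swapped <- make_study(post_mirrored, ant[2:1, ])
  expect_equal(geometric_mean_image(study_swapped), gm)
})

test_that("planar study constructor enforces shape and positivity", {
  expect_error(make_study(matrix(1, 2, 2), matrix(1, 3, 2)),
               "identical shape")
  expect_error(make_study(matrix(-1, 2, 2), matrix(1, 2, 2)),
               "non-negative")
})

test_that("two-compartment segmentation matches direct enumeration", {
  img <- matrix(10, 5, 5)
  img[2, 2] <- 100; img[3, 4] <- 100
  masks <- segment_two_compartments(img, smoothing_sigma = 0,
                                    wb_threshold_frac = 0.01,
                                    split_threshold_frac = 0.5)
  expect_equal(sum(masks$high), 2)
  expect_equal(sum(masks$low), 23)
  expect_true(masks$high[2, 2] && masks$high[3, 4])
})

test_that("segmentation partitions the whole body exactly", {
  # uniform image: every body pixel is at the maximum, so high == body
  uni <- matrix(7, 6, 6)
  m <- segment_two_compartments(uni, 0, 0.1, 0.5)
  expect_equal(m$high, m$whole_body)
  expect_equal(sum(m$low), 0)

  set.seed(4)
  for (i in 1:10) {
    img <- matrix(runif(400, 0, 50), 20, 20)
    m <- segment_two_compartments(img, smoothing_sigma = 1)
    expect_false(any(m$high & m$low))
    expect_equal(m$high | m$low, m$whole_body)
  }
  expect_error(segment_two_compartments(matrix(0, 4, 4)), "empty image")
})

test_that("conjugate-view formula reproduces hand-evaluated cases", {
  # attenuation-free limit: f = 1
  cal0 <- make_calibration(10, 0)
  expect_equal(conjugate_view_activity(1000 * 60, 1000 * 60, 60, cal0, 20),
               100)
  # worked closed-form case: sqrt(8e5) * e^1.2 / 10 * 0.48/sinh(0.48)
  cal <- make_calibration(10, 0.12)
  a <- conjugate_view_activity(1000 * 60, 800 * 60, 60, cal, 20, 8)
  expect_equal(a, 285.9, tolerance = 3e-4)
  # zero counts on either view give zero activity
  expect_equal(conjugate_view_activity(0, 500, 10, cal, 20), 0)
  expect_error(conjugate_view_activity(10, 10, 10, cal, 5, 8),
               "body_thickness")
})

test_that("conjugate-view recovery on the slab phantom is exact", {
  spec <- phantom_spec()
  cal <- make_calibration(spec$sensitivity_cps_per_mbq, spec$mu_eff_per_cm)
  sim <- simulate_phantom_planar(spec, 2)
  masks <- segment_two_compartments(geometric_mean_image(sim$study))
  act <- compartment_activities(sim$study, masks, cal,
                                spec$abdominal_thickness_cm, 8)
  expect_lt(abs(act$activity_mbq[act$compartment == "high"] /
                  sim$truth$a_high_mbq - 1), 1e-6)
  expect_lt(abs(act$activity_mbq[act$compartment == "low"] /
                  sim$truth$a_low_mbq - 1), 1e-6)
  expect_equal(act$area_cm2[act$compartment == "high"],
               sim$truth$high_area_cm2)
})

test_that("summed compartment activity at 2 h matches injection without excretion", {
  # kinetics constructed so that high + low equals the injected activity
  # at the 2-h imaging time (no excreted fraction by then)
  spec <- phantom_spec(low_f1 = 0.4487, low_lambda1 = 0.05,
                       low_f2 = 0.3, low_lambda2 = 0.01,
                       high_peak_frac = 0.32, high_frac_at_t1 = 0.9375)
  sim <- simulate_phantom_planar(spec, 2)
  cal <- make_calibration(spec$sensitivity_cps_per_mbq, spec$mu_eff_per_cm)
  masks <- segment_two_compartments(geometric_mean_image(sim$study))
  act <- compartment_activities(sim$study, masks, cal,
                                spec$abdominal_thickness_cm, 8)
  expect_lt(abs(sum(act$activity_mbq) / spec$injected_mbq - 1), 0.05)
})

test_that("compartment masses follow the area-times-thickness rule", {
  m <- compartment_masses(70000, 300, 20)
  expect_equal(m$m_high, 6000)
  expect_equal(m$m_low, 64000)
  expect_equal(compartment_masses(70000, 0, 20)$m_low, 70000)
  expect_error(compartment_masses(10000, 600, 20), "exceeds body mass")
})

test_that("planar images and masks round-trip through NIfTI", {
  img <- matrix(rpois(200, 40), 10, 20) * 1.0
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_planar_image(img, p)
  expect_equal(read_planar_image(p), img, ignore_attr = TRUE)

  mask <- img > 40
  pm <- withr::local_tempfile(fileext = ".nii.gz")
  write_mask(mask, pm)
  expect_equal(read_mask(pm), mask, ignore_attr = TRUE)
})
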