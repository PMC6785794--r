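test_that("sphere VOI masks hold the nominal volume", {
  m <- sphere_voi_mask(c(20, 20, 20), 1, c(10, 10, 10), 0.7)
  expect_lt(abs(sum(m) - 700) / 700, 0.05)
  # refinement halves the voxel: volume error shrinks
  m2 <- sphere_voi_mask(c(40, 40, 40), 0.5, c(10, 10, 10), 0.7)
  err1 <- abs(sum(m) * 1e-3 - 0.7)
  err2 <- abs(sum(m2) * 0.5^3 * 1e-3 - 0.7)
  expect_lt(err2, err1)

  expect_error(sphere_voi_mask(c(20, 20, 20), 1, c(10, 10, 10), 0),
               "positive")
  expect_error(sphere_voi_mask(c(20, 20, 20), 1, c(2, 10, 10), 0.7),
               "out of bounds")
})

test_that("VOI concentration is the in-mask mean", {
  vol <- spect_volume(array(50, c(10, 10, 10)), 2)
  m <- sphere_voi_mask(c(10, 10, 10), 2, c(10, 10, 10), 0.7)
  expect_equal(voi_concentration(vol, m), 50)

  mixed <- array(50, c(10, 10, 10))
  idx <- which(m)
  half <- idx[seq_len(floor(length(idx) / 2))]
  mixed[half] <- 40
  mixed[setdiff(idx, half)] <- 60
  vol2 <- spect_volume(mixed, 2)
  expect_equal(voi_concentration(vol2, m),
               mean(c(rep(40, length(half)),
                      rep(60, length(idx) - length(half)))))
  expect_error(voi_concentration(vol, array(FALSE, c(10, 10, 10))),
               "empty mask")
})

test_that("a vertebra of known concentration is read back exactly", {
  sv <- simulate_spect_volume(c(T10 = 37.1), background = 10)
  meas <- measure_vertebrae(sv$volume, sv$vertebrae)
  expect_equal(meas$concentration_kbq_ml, 37.1, tolerance = 1e-9)
})

test_that("reference selection reproduces the 22-patient fixture medians", {
  prof <- vertebral_reference_profile()
  tab <- data.frame(label = prof$label,
                    concentration_kbq_ml = prof$concentration_kbq_ml,
                    metastasis = FALSE)
  expect_equal(select_reference_concentration(tab, "L_SPECT"), 28.2)
  expect_equal(select_reference_concentration(tab, "V_SPECT"), 28.1)
  expect_equal(select_reference_concentration(tab, "T_SPECT"),
               median(prof$concentration_kbq_ml[1:8]))
  expect_equal(select_reference_concentration(tab, "L4_SPECT"), 23.9)
})

test_that("the single-vertebra fallback chain is L4, L5, L3, L2", {
  tab <- data.frame(label = c("L2", "L3", "L4", "L5"),
                    concentration_kbq_ml = c(20, 30, 40, 50),
                    metastasis = c(FALSE, FALSE, TRUE, TRUE))
  expect_equal(select_reference_concentration(tab, "L4_SPECT"), 30)
  tab$metastasis <- c(FALSE, TRUE, TRUE, TRUE)
  expect_equal(select_reference_concentration(tab, "L4_SPECT"), 20)
  tab$metastasis <- TRUE
  expect_error(select_reference_concentration(tab, "L4_SPECT"),
               "no eligible lumbar vertebra")
  # invisible vertebrae are skipped too
  tab2 <- data.frame(label = c("L4", "L5"),
                     concentration_kbq_ml = c(40, 50),
                     metastasis = FALSE, visible = c(FALSE, TRUE))
  expect_equal(select_reference_concentration(tab2, "L4_SPECT"), 50)
})

test_that("median references are permutation invariant and bounded", {
  set.seed(3)
  labels <- vertebral_reference_profile()$label
  for (i in 1:10) {
    conc <- runif(length(labels), 5, 60)
    tab <- data.frame(label = labels, concentration_kbq_ml = conc,
                      metastasis = FALSE)
    perm <- tab[sample(nrow(tab)), ]
    for (m in c("V_SPECT", "L_SPECT", "T_SPECT")) {
      v <- select_reference_concentration(tab, m)
      expect_equal(select_reference_concentration(perm, m), v)
      expect_gte(v, min(conc)); expect_lte(v, max(conc))
    }
  }
  # all methods agree when every vertebra shares one concentration
  tab <- data.frame(label = labels, concentration_kbq_ml = 25,
                    metastasis = FALSE)
  for (m in c("L4_SPECT", "V_SPECT", "L_SPECT", "T_SPECT"))
    expect_equal(select_reference_concentration(tab, m), 25)
})

test_that("metastatic vertebrae stay in the medians but not the L4 chain", {
  tab <- data.frame(label = c("L1", "L2", "L3", "L4", "L5"),
                    concentration_kbq_ml = c(10, 20, 30, 40, 500),
                    metastasis = c(FALSE, FALSE, FALSE, FALSE, TRUE))
  expect_equal(select_reference_concentration(tab, "L_SPECT"), 30)
  expect_equal(select_reference_concentration(tab, "L4_SPECT"), 40)
})

test_that("simulated SPECT volumes honour metastasis flags and seeds", {
  conc <- c(T7 = 20, T10 = 37.1, L4 = 23.9)
  sv <- simulate_spect_volume(conc, metastases = "T7", hot_factor = 3,
                              noise_sd = 0.05, seed = 12)
  expect_true(sv$vertebrae$metastasis[sv$vertebrae$label == "T7"])
  expect_equal(
    sv$vertebrae$true_concentration_kbq_ml[sv$vertebrae$label == "T7"], 60)
  sv2 <- simulate_spect_volume(conc, metastases = "T7", hot_factor = 3,
                               noise_sd = 0.05, seed = 12)
  expect_identical(sv$volume$data, sv2$volume$data)
  meas <- measure_vertebrae(sv$volume, sv$vertebrae)
  expect_equal(meas$concentration_kbq_ml[meas$label == "T7"], 60,
               tolerance = 0.05)
  expect_error(
    simulate_spect_volume(conc, vertebra_radius_mm = 14,
                          center_spacing_mm = 26),
    "overlapping")
})

test_that("SPECT volumes round-trip through NIfTI with spacing", {
  sv <- simulate_spect_volume(c(L4 = 23.9), background = 5)
  p <- withr::local_tempfile(fileext = ".nii.gz")
  write_spect_volume(sv$volume, p)
  back <- read_spect_volume(p)
  expect_equal(back$data, sv$volume$data, ignore_attr = TRUE,
               tolerance = 1e-6)
  expect_equal(back$spacing_mm, sv$volume$spacing_mm)
})
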