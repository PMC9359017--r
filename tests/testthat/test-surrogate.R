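cfg <- small_phantom_config()
ph <- build_phantom(cfg)

test_that("phantom construction is deterministic and anatomically consistent", {
  ph2 <- build_phantom(cfg)
  expect_identical(ph$image$values, ph2$image$values)
  expect_identical(lapply(ph$structures$masks, `[[`, "inside"),
                   lapply(ph2$structures$masks, `[[`, "inside"))

  s <- ph$structures$masks
  expect_setequal(names(s), canonical_rois())
  body <- s$Body$inside
  for (nm in setdiff(names(s), "Body")) {
    expect_true(all(!s[[nm]]$inside | body), label = paste(nm, "inside body"))
  }
  expect_false(any(s$Prostate$inside & s$Bladder$inside))
  expect_false(any(s$Prostate$inside & s$Rectum$inside))
  expect_false(any(s$Bladder$inside & s$Rectum$inside))
  expect_identical(s$PTV_7000$inside,
                   expand_margin(s$Prostate, cfg$ptv_margin_mm)$inside)
  expect_identical(s$CTV_7000$inside,
                   s$Prostate$inside | s$SeminalVesicles$inside)
})

test_that("autoseg surrogate: noiseless limit, determinism, monotone degradation", {
  truth <- ph$structures$masks$Prostate
  m0 <- seg_perturbation_model(0, 8, "corrected", seed = 1)
  expect_identical(simulate_autoseg(truth, m0)$inside, truth$inside)

  m1 <- seg_perturbation_model(1.5, 8, "ai", seed = 9)
  expect_identical(simulate_autoseg(truth, m1)$inside,
                   simulate_autoseg(truth, m1)$inside)

  stats <- vapply(c(0.5, 1, 2), function(sdv) {
    per <- vapply(1:8, function(k) {
      sim <- simulate_autoseg(truth, seg_perturbation_model(sdv, 8, "ai", seed = k))
      c(dice(sim, truth), mean_symmetric_surface_distance(sim, truth))
    }, numeric(2))
    rowMeans(per)
  }, numeric(2))
  expect_true(all(diff(stats[1, ]) < 0))   # mean Dice degrades with sd
  expect_true(all(diff(stats[2, ]) > 0))   # mean mSSD grows with sd
})

test_that("same-organ repeat draws agree more than cross-organ comparisons", {
  s <- ph$structures$masks
  organs <- c("Prostate", "Bladder", "Rectum")
  draws <- lapply(organs, function(o) {
    lapply(1:2, function(k) {
      simulate_autoseg(s[[o]], seg_perturbation_model(1, 8, "ai",
                                                      seed = 100 + 10 * k))
    })
  })
  names(draws) <- organs
  within <- vapply(organs, function(o) dice(draws[[o]][[1]], draws[[o]][[2]]), 0)
  for (i in seq_along(organs)) {
    for (j in seq_along(organs)) {
      if (i == j) next
      expect_gt(min(within), dice(draws[[organs[i]]][[1]], draws[[organs[j]]][[2]]))
    }
  }
})

test_that("dose surrogate: prescription in PTV, monotone falloff, distant sparing", {
  dm <- dose_model(rx = 70, plan_style = "VMAT", seed = 4)
  dose <- simulate_dose(ph$structures, dm)
  ptv <- ph$structures$masks$PTV_7000

  ctr <- round((adaptqa:::mask_centroid(ptv) - dose$geometry$origin) /
               dose$geometry$spacing) + 1
  expect_lt(abs(dose$values[ctr[1], ctr[2], ctr[3]] - 70) / 70, 0.01)

  # noise-free dose is a non-increasing function of PTV distance everywhere
  quiet <- simulate_dose(ph$structures, dm, noise = FALSE)
  d <- distance_map(ptv)$values
  ord <- order(d)
  expect_true(all(diff(quiet$values[ord]) <= 1e-9))
  expect_true(all(quiet$values[ptv$inside] == 70))

  # > 50 mm from the PTV the dose is below 10% of Rx for both plan styles
  far <- d > 50
  expect_lt(max(dose$values[far]), 0.10 * 70)
  dose_imrt <- simulate_dose(ph$structures, dose_model(70, "IMRT", seed = 4))
  expect_lt(max(dose_imrt$values[far]), 0.10 * 70)

  expect_error(simulate_dose(structure_set(ph$structures$geometry, list()), dm),
               "PTV")
})

test_that("virtual study layout matches the fractionation design", {
  study <- run_virtual_study(study_config(phantom = cfg), seed = 5)
  expect_equal(nrow(study$design), 130)           # 26 fractions x 5 instances
  counts <- dplyr::count(study$design, .data$deformation_id, .data$plan_type,
                         .data$mode)
  expect_true(all(counts$n[counts$mode == "ai"] == 3))
  expect_true(all(counts$n[counts$mode == "corrected"] == 10))
  expect_equal(nrow(counts), 5 * 2 * 2)
  expect_identical(run_virtual_study(study_config(phantom = cfg), seed = 5)$design,
                   study$design)
  expect_length(study$deformations, 5)
  expect_equal(study$deformations[[1]], reference_deformation_spec(1))
})

test_that("fraction realization is deterministic and internally consistent", {
  study <- run_virtual_study(small_study_config(), seed = 11)
  rf1 <- realize_fraction(study, 1, 4, phantom = ph)
  rf2 <- realize_fraction(study, 1, 4, phantom = ph)
  expect_identical(lapply(rf1$masks, `[[`, "inside"),
                   lapply(rf2$masks, `[[`, "inside"))
  expect_identical(rf1$dose$values, rf2$dose$values)
  expect_setequal(names(rf1$masks), setdiff(canonical_rois(), "Body"))
  # derived targets rebuilt from the simulated organs
  expect_identical(rf1$masks$PTV_7000$inside,
                   expand_margin(rf1$masks$Prostate, cfg$ptv_margin_mm)$inside)
  expect_equal(rf1$record$plan_type, "IMRT")
  expect_equal(rf1$record$mode, "corrected")
})
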