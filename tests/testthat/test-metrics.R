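test_that("Dice identities, formula arithmetic, and symmetry", {
  g <- geometry(size = c(10, 10, 10))
  a <- sphere_mask(g, c(4, 4, 4), 3)
  expect_equal(dice(a, a), 1.0)

  b <- array(FALSE, g$size); b[9:10, 9:10, 9:10] <- TRUE
  expect_equal(dice(a, binary_mask(g, b)), 0.0)

  # |A| = 100, |B| = 100, |A n B| = 50 -> 0.5
  x <- array(FALSE, g$size); x[1:100] <- TRUE
  y <- array(FALSE, g$size); y[51:150] <- TRUE
  expect_equal(dice(binary_mask(g, x), binary_mask(g, y)), 0.5)
  expect_equal(dice(binary_mask(g, x), binary_mask(g, y)),
               dice(binary_mask(g, y), binary_mask(g, x)))

  empty <- binary_mask(g, array(FALSE, g$size))
  expect_warning(d <- dice(empty, empty), "empty")
  expect_equal(d, 1.0)
  expect_error(dice(a, binary_mask(geometry(size = c(5, 5, 5)),
                                   array(TRUE, c(5, 5, 5)))), "geometry")
})

test_that("mean symmetric surface distance matches the all-pairs oracle", {
  g <- geometry(size = c(10, 10, 10))
  a <- sphere_mask(g, c(5, 5, 5), 3)
  expect_equal(mean_symmetric_surface_distance(a, a), 0.0)

  m1 <- array(FALSE, g$size); m1[3, 5, 5] <- TRUE
  m2 <- array(FALSE, g$size); m2[6, 5, 5] <- TRUE
  expect_equal(mssd(binary_mask(g, m1), binary_mask(g, m2)), 3.0)

  # 5x5x1 slabs offset by 2 voxels in X, exact against brute force
  s1 <- array(FALSE, g$size); s1[2:6, 2:6, 5] <- TRUE
  s2 <- array(FALSE, g$size); s2[4:8, 2:6, 5] <- TRUE
  a1 <- binary_mask(g, s1); a2 <- binary_mask(g, s2)
  expect_equal(mssd(a1, a2), oracle_mssd(a1, a2), tolerance = 1e-12)

  # random small masks, anisotropic spacing, 1e-9 agreement and symmetry
  ga <- geometry(spacing = c(1, 2, 2.5), size = c(9, 9, 9))
  for (s in 1:8) {
    ma <- random_mask(ga, 0.15, seed = s)
    mb <- random_mask(ga, 0.15, seed = s + 100)
    if (!any(ma$inside) || !any(mb$inside)) next
    expect_equal(mssd(ma, mb), oracle_mssd(ma, mb), tolerance = 1e-9)
    expect_equal(mssd(ma, mb), mssd(mb, ma))
  }
  expect_error(mssd(a, binary_mask(g, array(FALSE, g$size))), "empty")
})

test_that("STAPLE: unanimous raters, tie rule, and consensus equals majority vote at one E-step", {
  g <- geometry(size = c(16, 16, 16))
  truth <- sphere_mask(g, c(8, 8, 8), 5)
  st <- staple(replicate(5, truth, simplify = FALSE))
  expect_identical(st$consensus$inside, truth$inside)
  expect_true(all(st$p > 1 - 1e-5) && all(st$q > 1 - 1e-5))
  expect_true(st$converged)

  # with shared (p, q) and prior 0.5 the first E-step is a majority vote;
  # weight exactly 0.5 (even split) counts as foreground
  for (J in c(4, 5)) {
    for (s in 1:5) {
      masks <- lapply(1:J, function(j) {
        withr::with_seed(s * 10 + j, {
          binary_mask(g, array(runif(prod(g$size)) < 0.3, g$size))
        })
      })
      st1 <- staple(masks, prior = 0.5, max_iter = 1, crop = FALSE)
      votes <- Reduce(`+`, lapply(masks, function(m) m$inside))
      expect_identical(st1$consensus$inside, votes >= J / 2)
      expect_false(st1$converged)   # one E-step cannot certify convergence
    }
  }
  expect_error(staple(list()), "at least one")
})

test_that("STAPLE recovers rater performance and resists a bad rater", {
  g <- geometry(spacing = c(2, 2, 2), size = c(36, 36, 36))
  truth <- sphere_mask(g, c(35, 35, 35), 20)
  raters <- withr::with_seed(7, lapply(1:5, function(j) {
    flip <- ifelse(truth$inside, runif(length(truth$inside)) < 0.10,
                   runif(length(truth$inside)) < 0.02)
    binary_mask(g, xor(truth$inside, array(flip, g$size)))
  }))
  st <- staple(raters)
  expect_true(all(abs(st$p - 0.90) < 0.05))
  expect_true(all(abs(st$q - 0.98) < 0.02))
  expect_gt(dice(st$consensus, truth), 0.95)
  td <- tidy(st)
  expect_equal(nrow(td), 5)
  expect_named(td, c("rater", "sensitivity", "specificity"))
  expect_equal(glance(st)$n_raters, 5)

  # two identical raters dominate one grossly wrong rater
  wrong <- sphere_mask(g, c(18, 18, 18), 9)
  expect_lt(dice(wrong, truth), 0.2)
  st3 <- staple(list(truth, truth, wrong))
  expect_gt(dice(st3$consensus, truth), 0.99)
})

test_that("repetition comparison emits one record per repetition vs the consensus", {
  g <- geometry(spacing = c(2, 2, 2), size = c(24, 24, 24))
  truth <- sphere_mask(g, c(24, 24, 24), 12)
  identical_records <- tibble::tibble(
    roi = "Prostate", deformation_id = 1L, plan_type = "IMRT",
    mode = "corrected", fraction = 1:5,
    mask = replicate(5, truth, simplify = FALSE))
  cmp <- compare_repetitions(identical_records)
  expect_equal(nrow(cmp), 5)
  expect_true(all(cmp$dsc == 1.0))
  expect_true(all(cmp$mssd_mm == 0.0))
  expect_false("mask" %in% names(cmp))

  # perturbed repetitions: all dsc < 1 and mssd > 0
  perturbed <- identical_records
  perturbed$mask <- lapply(1:5, function(k) {
    simulate_autoseg(truth, seg_perturbation_model(1, 8, "ai", seed = k))
  })
  cmp2 <- compare_repetitions(perturbed)
  expect_true(all(cmp2$dsc < 1))
  expect_true(all(cmp2$mssd_mm > 0))

  # singleton groups are skipped with a warning
  lone <- identical_records[1, ]
  lone$roi <- "Bladder"
  expect_warning(cmp3 <- compare_repetitions(dplyr::bind_rows(identical_records, lone)),
                 "single repetition")
  expect_equal(nrow(cmp3), 5)
})
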