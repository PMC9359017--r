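test_that("one-way ANOVA reproduces closed-form sums of squares", {
  # identical groups: no between-group variation
  r0 <- one_way_anova(list(c(1, 2, 3), c(1, 2, 3), c(1, 2, 3)))
  expect_equal(r0$statistic, 0)
  expect_equal(r0$p_value, 1)

  # hand-computed: SS_between = 4, SS_within = 0.5, F = 8, df (1, 2)
  r1 <- one_way_anova(list(c(1, 2), c(3, 4)))
  expect_equal(r1$statistic, 8)
  expect_equal(r1$df_between, 1L)
  expect_equal(r1$df_within, 2L)
  expect_equal(r1$p_value, pf(8, 1, 2, lower.tail = FALSE))

  # degenerate within-group variance is flagged, not thrown
  rd <- one_way_anova(list(c(1, 1), c(2, 2)))
  expect_true(rd$degenerate)
  expect_true(is.na(rd$p_value))

  # data-frame interface
  df <- data.frame(value = c(1, 2, 3, 4), group = c("a", "a", "b", "b"))
  expect_equal(one_way_anova(df, value, group)$statistic, 8)
})

test_that("two-group ANOVA equals the squared pooled-variance t statistic", {
  for (s in 1:10) {
    x <- withr::with_seed(s, list(rnorm(8, 0, 1), rnorm(12, 0.4, 1)))
    f <- one_way_anova(x)$statistic
    t2 <- t.test(x[[1]], x[[2]], var.equal = TRUE)$statistic^2
    expect_equal(f, unname(t2), tolerance = 1e-12)
  }
})

test_that("ANOVA agrees with the reference implementation to 1e-8", {
  for (s in 1:100) {
    dat <- withr::with_seed(s, {
      k <- sample(2:5, 1)
      lapply(seq_len(k), function(i) rnorm(sample(3:12, 1), mean = runif(1, 0, 2)))
    })
    mine <- one_way_anova(dat)
    g <- factor(rep(seq_along(dat), lengths(dat)))
    ref <- oneway.test(unlist(dat) ~ g, var.equal = TRUE)
    expect_equal(mine$statistic, unname(ref$statistic), tolerance = 1e-8)
    expect_equal(mine$p_value, unname(ref$p.value), tolerance = 1e-8)
  }
})

test_that("interval_95 percentile and normal methods match their oracles", {
  expect_equal(unlist(interval_95(rep(3.2, 10))[c("lower", "upper")]),
               c(lower = 3.2, upper = 3.2))
  ci <- interval_95(0:100)
  expect_equal(c(ci$lower, ci$upper), c(2.5, 97.5))

  x <- withr::with_seed(13, rnorm(1000, 0.95, 0.01))
  cn <- interval_95(x, method = "normal")
  expect_equal(c(cn$lower, cn$upper), c(0.9304, 0.9696), tolerance = 2e-3)

  # domain clipping for bounded metrics
  cc <- interval_95(c(0.97, 0.99, 1.0, 1.0), method = "normal", domain = c(0, 1))
  expect_lte(cc$upper, 1)
  expect_error(interval_95(1), "two samples")
})

# Synthetic comparison records: 8 ROIs x 2 modes x 5 deformations x n reps.
make_null_comparisons <- function(seed, n_per_group = 10, shift_roi = NULL,
                                  shift_def = 1L, shift = 0) {
  withr::with_seed(seed, {
    grid <- tidyr::expand_grid(roi = canonical_rois(compared = TRUE),
                               mode = c("ai", "corrected"),
                               deformation_id = 1:5,
                               rep = seq_len(n_per_group))
    grid$plan_type <- rep_len(c("IMRT", "VMAT"), nrow(grid))
    grid$fraction <- grid$rep
    offset <- if (is.null(shift_roi)) 0 else
      ifelse(grid$roi == shift_roi & grid$deformation_id == shift_def, shift, 0)
    grid$dsc <- pmin(rnorm(nrow(grid), 0.95, 0.015) + offset, 1)
    grid$mssd_mm <- pmax(rnorm(nrow(grid), 0.4, 0.1), 0)
    grid
  })
}

test_that("pooling rule: null data pools, a shifted deformation stratifies", {
  null_cmp <- make_null_comparisons(seed = 101)
  rep0 <- build_action_level_report(null_cmp)
  pooled_per_mode <- dplyr::count(
    dplyr::filter(rep0$contour, .data$decision == "pooled"), .data$mode)
  expect_true(all(pooled_per_mode$n >= 7))   # expected false-positive rate

  shifted <- make_null_comparisons(seed = 101, shift_roi = "Bowel",
                                   shift = -0.06)
  rep1 <- build_action_level_report(shifted)
  bowel <- dplyr::filter(rep1$contour, .data$roi == "Bowel")
  expect_true(all(bowel$decision == "stratified"))
  # flagged rows carry per-deformation intervals (other ROIs may appear at
  # the expected 5% false-positive rate)
  detail <- dplyr::filter(rep1$contour_detail, .data$roi == "Bowel",
                          .data$metric == "dsc")
  expect_equal(sort(unique(detail$deformation_id)), 1:5)
})

test_that("action-level report schema is complete and ordered", {
  cmp <- make_null_comparisons(seed = 7)
  constraints <- tidyr::expand_grid(planning_constraints(),
                                    plan_type = c("IMRT", "VMAT"),
                                    fraction = 1:6)
  constraints$achieved <- withr::with_seed(8, runif(nrow(constraints), 1, 40))
  rep <- build_action_level_report(cmp, constraints)

  expect_equal(nrow(rep$contour), 16)    # 8 ROIs x 2 modes
  expect_true(all(table(rep$contour$mode) == 8))
  expect_true(all(rep$contour$dsc_ci_lo <= rep$contour$dsc_ci_hi))
  expect_true(all(rep$contour$mssd_ci_lo_mm <= rep$contour$mssd_ci_hi_mm))
  expect_equal(nrow(rep$dose), 18)       # 9 constraints x 2 plan types
  expect_true(all(rep$dose$lower <= rep$dose$upper))
  expect_equal(glance(rep)$n_rois, 8)
  expect_true(tibble::is_tibble(tidy(rep)))
})

test_that("report plots build without evaluation errors", {
  cmp <- make_null_comparisons(seed = 3, n_per_group = 4)
  p1 <- plot_contour_variability(cmp, "dsc")
  p2 <- plot_contour_variability(cmp, "mssd_mm", by_deformation = TRUE)
  expect_s3_class(p1, "ggplot")
  expect_s3_class(ggplot2::ggplot_build(p1)$plot, "ggplot")
  expect_s3_class(ggplot2::ggplot_build(p2)$plot, "ggplot")
  cons <- tidyr::expand_grid(planning_constraints(),
                             plan_type = c("IMRT", "VMAT"), fraction = 1:4)
  cons$achieved <- withr::with_seed(4, runif(nrow(cons), 1, 40))
  p3 <- plot_dose_repeatability(cons)
  expect_s3_class(ggplot2::ggplot_build(p3)$plot, "ggplot")
  g <- geometry(size = c(8, 8, 8))
  dvh <- cumulative_dvh(image_volume(g, array(runif(512, 0, 70), g$size), "Gy"),
                        binary_mask(g, array(TRUE, g$size)))
  expect_s3_class(ggplot2::ggplot_build(autoplot(dvh))$plot, "ggplot")
})
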