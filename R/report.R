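#' One-way fixed-effects ANOVA
#'
#' Classical F test computed from explicit sums of squares:
#' `F = MS_between / MS_within` with `df = (k - 1, N - k)`, p value from the
#' F distribution.  Zero pooled within-group variance is flagged as a
#' degenerate result (F and p set to NA) rather than raising an error.
#'
#' @param data data frame with the response and grouping columns, or a list
#'   of numeric vectors (one per group).
#' @param value,group column names (strings or bare names) when `data` is a
#'   data frame.
#' @return One-row tibble: `statistic` (F), `p_value`, `df_between`,
#'   `df_within`, `n`, `n_groups`, `degenerate`.
#' @examples
#' one_way_anova(list(c(1, 2), c(3, 4)))  # F = 8 on df (1, 2)
#' @export
one_way_anova <- function(data, value = "value", group = "group") {
  if (is.list(data) && !is.data.frame(data)) {
    samples <- lapply(data, as.double)
  } else {
    value <- rlang::as_name(rlang::enquo(value))
    group <- rlang::as_name(rlang::enquo(group))
    samples <- split(as.double(data[[value]]), data[[group]])
  }
  if (length(samples) < 2) stop("need at least two groups", call. = FALSE)
  if (any(lengths(samples) < 2)) stop("each group needs >= 2 samples", call. = FALSE)
  x <- unlist(samples, use.names = FALSE)
  k <- length(samples); N <- length(x)
  gm <- mean(x)
  means <- vapply(samples, mean, 0)
  ns <- lengths(samples)
  ss_between <- sum(ns * (means - gm)^2)
  ss_within <- sum(vapply(seq_len(k), function(i) {
    sum((samples[[i]] - means[i])^2)
  }, 0))
  df_b <- k - 1L; df_w <- N - k
  if (ss_within <= 0) {
    return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                          df_between = df_b, df_within = df_w, n = N,
                          n_groups = k, degenerate = TRUE))
  }
  f <- (ss_between / df_b) / (ss_within / df_w)
  tibble::tibble(statistic = f, p_value = pf(f, df_b, df_w, lower.tail = FALSE),
                 df_between = df_b, df_within = df_w, n = N, n_groups = k,
                 degenerate = FALSE)
}

#' 95% interval of a metric distribution
#'
#' Estimated directly from the sample: either empirical percentiles
#' (2.5th/97.5th at the default level, linear interpolation between order
#' statistics) or normal theory (mean +/- z * sd).  The interval is clipped
#' to the metric's domain when one is given (Dice lives in `[0, 1]`,
#' surface distances in `[0, Inf)`).
#'
#' @param x numeric sample, length >= 2.
#' @param method "percentile" or "normal".
#' @param level confidence level (default 0.95).
#' @param domain optional length-2 clipping range.
#' @return One-row tibble: `lower`, `upper`, `level`, `method`, `n`.
#' @export
interval_95 <- function(x, method = c("percentile", "normal"), level = 0.95,
                        domain = NULL) {
  method <- match.arg(method)
  x <- x[is.finite(x)]
  if (length(x) < 2) stop("need at least two samples", call. = FALSE)
  a <- (1 - level) / 2
  if (method == "percentile") {
    ci <- quantile(x, c(a, 1 - a), type = 7, names = FALSE)
  } else {
    z <- qnorm(1 - a)
    ci <- mean(x) + c(-1, 1) * z * sd(x)
  }
  if (!is.null(domain)) ci <- pmin(pmax(ci, domain[1]), domain[2])
  tibble::tibble(lower = ci[1], upper = ci[2], level = level, method = method,
                 n = length(x))
}

metric_domain <- function(metric) {
  if (metric == "dsc") c(0, 1) else c(0, Inf)
}

#' Organ-specific action-level report
#'
#' The statistical core of the end-to-end test: for every (ROI, mode,
#' metric), a one-way ANOVA across deformation instances decides whether
#' the deformations can be pooled (p >= alpha) into one 95% interval of the
#' metric distribution or must be reported stratified per deformation
#' (flagged, with per-deformation intervals in `$contour_detail`).  Dose
#' constraint results are always stratified by plan type (plan styles
#' differ systematically) with deformations pooled within plan type.
#'
#' @param comparisons output of [compare_repetitions()] (columns `roi`,
#'   `deformation_id`, `plan_type`, `mode`, `dsc`, `mssd_mm`).
#' @param constraint_results per-fraction constraint evaluations with
#'   columns `roi`, `metric`, `plan_type`, `achieved`, `unit` (optional;
#'   the dose section is skipped when NULL).
#' @param alpha pooling significance level (default 0.05; raw p values, no
#'   multiplicity correction across ROIs).
#' @param ci_method "percentile" or "normal".
#' @return An object of class `qa_report`: tibbles `contour` (wide,
#'   per ROI x mode), `contour_anova` (long), `contour_detail`
#'   (per-deformation intervals for stratified rows), `dose` (per
#'   constraint x plan type), plus `alpha` and `ci_method`.
#' @export
build_action_level_report <- function(comparisons, constraint_results = NULL,
                                      alpha = 0.05,
                                      ci_method = c("percentile", "normal")) {
  ci_method <- match.arg(ci_method)
  long <- tidyr::pivot_longer(comparisons, c("dsc", "mssd_mm"),
                              names_to = "metric", values_to = "value") |>
    dplyr::mutate(metric = ifelse(.data$metric == "dsc", "dsc", "mssd"))

  anova_tbl <- long |>
    dplyr::group_by(.data$roi, .data$mode, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      if (length(unique(d$deformation_id)) < 2) {
        return(tibble::tibble(statistic = NA_real_, p_value = NA_real_,
                              df_between = NA_integer_, df_within = NA_integer_,
                              n = nrow(d), n_groups = 1L, degenerate = TRUE))
      }
      one_way_anova(split(d$value, d$deformation_id))
    }) |>
    dplyr::ungroup() |>
    dplyr::mutate(decision = ifelse(!is.na(.data$p_value) & .data$p_value < alpha,
                                    "stratified", "pooled"))

  pooled_ci <- long |>
    dplyr::group_by(.data$roi, .data$mode, .data$metric) |>
    dplyr::group_modify(function(d, key) {
      interval_95(d$value, method = ci_method,
                  domain = metric_domain(key$metric))
    }) |>
    dplyr::ungroup()

  contour_long <- dplyr::left_join(anova_tbl, pooled_ci,
                                   by = c("roi", "mode", "metric"))

  contour <- contour_long |>
    dplyr::select("roi", "mode", "metric", "p_value", "decision",
                  "lower", "upper") |>
    tidyr::pivot_wider(names_from = "metric",
                       values_from = c("p_value", "decision", "lower", "upper")) |>
    dplyr::transmute(roi = .data$roi, mode = .data$mode,
                     p_value = .data$p_value_dsc,
                     decision = .data$decision_dsc,
                     dsc_ci_lo = .data$lower_dsc, dsc_ci_hi = .data$upper_dsc,
                     mssd_p_value = .data$p_value_mssd,
                     mssd_ci_lo_mm = .data$lower_mssd,
                     mssd_ci_hi_mm = .data$upper_mssd) |>
    dplyr::arrange(.data$mode, .data$roi)

  flagged <- contour_long |> dplyr::filter(.data$decision == "stratified")
  contour_detail <- if (nrow(flagged) > 0) {
    long |>
      dplyr::semi_join(flagged, by = c("roi", "mode", "metric")) |>
      dplyr::group_by(.data$roi, .data$mode, .data$metric,
                      .data$deformation_id) |>
      dplyr::group_modify(function(d, key) {
        interval_95(d$value, method = ci_method,
                    domain = metric_domain(key$metric))
      }) |>
      dplyr::ungroup()
  } else {
    tibble::tibble(roi = character(), mode = character(), metric = character(),
                   deformation_id = integer(), lower = double(),
                   upper = double(), level = double(), method = character(),
                   n = integer())
  }

  dose <- NULL
  if (!is.null(constraint_results) && nrow(constraint_results) > 0) {
    dose <- constraint_results |>
      dplyr::filter(!is.na(.data$achieved)) |>
      dplyr::group_by(.data$roi, .data$metric, .data$unit, .data$limit,
                      .data$comparator, .data$plan_type) |>
      dplyr::group_modify(function(d, key) interval_95(d$achieved,
                                                       method = ci_method)) |>
      dplyr::ungroup() |>
      dplyr::mutate(constraint = paste0(.data$roi, " ", .data$metric, " ",
                                        .data$comparator, " ", .data$limit,
                                        .data$unit)) |>
      dplyr::select("constraint", "roi", "metric", "plan_type", "lower",
                    "upper", "unit", "limit", "comparator", "n")
  }

  structure(list(contour = contour, contour_anova = contour_long,
                 contour_detail = contour_detail, dose = dose,
                 alpha = alpha, ci_method = ci_method),
            class = "qa_report")
}

#' @export
print.qa_report <- function(x, ...) {
  cat("<qa_report> contour action levels (alpha = ", x$alpha, ", ",
      x$ci_method, " intervals)\n", sep = "")
  print(x$contour, n = Inf)
  if (!is.null(x$dose)) {
    cat("\ndose-volume action levels (by plan type)\n")
    print(x$dose, n = Inf)
  }
  invisible(x)
}

#' @rdname build_action_level_report
#' @param x,object a `qa_report`.
#' @param ... unused.
#' @export
tidy.qa_report <- function(x, ...) x$contour_anova

#' @rdname build_action_level_report
#' @export
glance.qa_report <- function(object, ...) {
  tibble::tibble(
    n_rois = length(unique(object$contour$roi)),
    n_modes = length(unique(object$contour$mode)),
    n_stratified = sum(object$contour_anova$decision == "stratified",
                       na.rm = TRUE),
    n_dose_rows = if (is.null(object$dose)) 0L else nrow(object$dose),
    alpha = object$alpha, ci_method = object$ci_method
  )
}

#' Plot dose-constraint repeatability by plan type
#'
#' Achieved constraint values across fractions and deformations, split by
#' plan type, with the constraint limit marked.
#'
#' @param constraint_results per-fraction constraint evaluation tibble.
#' @return A ggplot object.
#' @export
plot_dose_repeatability <- function(constraint_results) {
  d <- dplyr::filter(constraint_results, !is.na(.data$achieved)) |>
    dplyr::mutate(label = paste(.data$roi, .data$metric))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$plan_type, y = .data$achieved,
                                  fill = .data$plan_type)) +
    ggplot2::geom_boxplot(outlier.size = 0.5, show.legend = FALSE) +
    ggplot2::geom_hline(ggplot2::aes(yintercept = .data$limit),
                        linetype = "dashed") +
    ggplot2::facet_wrap(~label, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "Achieved value (limit unit)") +
    ggplot2::theme_minimal()
}
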