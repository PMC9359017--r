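#' Cumulative dose-volume histogram
#'
#' Evaluates, at regularly spaced dose bin edges from 0 Gy to just past the
#' maximum structure dose, the fraction of the structure's voxels receiving
#' at least that dose.  The curve is 1 at 0 Gy and non-increasing.
#'
#' @param dose `qa_volume` of dose in Gy.
#' @param mask non-empty `qa_mask` on the same geometry.
#' @param bin_width_gy bin width in Gy (default 0.05).
#' @return An object of class `qa_dvh`: `dose_gy` (edges), `fraction`,
#'   `total_cc`, `dose_min`, `dose_max`, `n_voxels`.
#' @export
cumulative_dvh <- function(dose, mask, bin_width_gy = 0.05) {
  stop_if_geometry_differs(dose, mask, "dose and mask")
  if (!any(mask$inside)) stop("DVH of an empty mask is undefined", call. = FALSE)
  d <- sort(dose$values[mask$inside])
  n <- length(d)
  edges <- seq(0, max(d) + bin_width_gy, by = bin_width_gy)
  # count of voxels with dose >= edge = n - #{dose < edge}
  frac <- (n - findInterval(edges, d, left.open = TRUE)) / n
  structure(list(dose_gy = edges, fraction = frac,
                 total_cc = mask_volume_cc(mask),
                 dose_min = d[1], dose_max = d[n], n_voxels = n),
            class = "qa_dvh")
}

#' @export
print.qa_dvh <- function(x, ...) {
  cat("<qa_dvh> ", x$n_voxels, " voxels (", format(x$total_cc, digits = 4),
      " cm^3), dose range [", format(x$dose_min, digits = 4), ", ",
      format(x$dose_max, digits = 4), "] Gy, ", length(x$dose_gy),
      " bin edges\n", sep = "")
  invisible(x)
}

#' @rdname cumulative_dvh
#' @param x a `qa_dvh` object.
#' @param ... unused.
#' @export
tidy.qa_dvh <- function(x, ...) {
  tibble::tibble(dose_gy = x$dose_gy, fraction = x$fraction,
                 volume_cc = x$fraction * x$total_cc)
}

#' @rdname cumulative_dvh
#' @param object a `qa_dvh` object.
#' @export
autoplot.qa_dvh <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$dose_gy, y = 100 * .data$fraction)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "Dose (Gy)", y = "Volume (%)") +
    ggplot2::theme_minimal()
}

#' Dose at volume (Dv%)
#'
#' The minimum dose received by at least `v` percent of the structure,
#' linearly interpolated between bin edges.  `v = 100` returns the minimum
#' structure dose.
#'
#' @param dvh a `qa_dvh`.
#' @param v volume percentage in (0, 100].
#' @return Dose in Gy.
#' @export
dose_at_volume <- function(dvh, v) {
  if (!is.finite(v) || v <= 0 || v > 100) {
    stop("volume percentage must be in (0, 100]", call. = FALSE)
  }
  if (v == 100) return(dvh$dose_min)
  vf <- v / 100
  i <- max(which(dvh$fraction >= vf))
  if (i == length(dvh$fraction)) return(dvh$dose_gy[i])
  f0 <- dvh$fraction[i]; f1 <- dvh$fraction[i + 1]
  dvh$dose_gy[i] + (f0 - vf) / (f0 - f1) * (dvh$dose_gy[i + 1] - dvh$dose_gy[i])
}

#' Volume at dose (Vd)
#'
#' Fraction of the structure receiving at least `d` Gy, linearly
#' interpolated between bin edges, as a percentage or absolute volume.
#'
#' @param dvh a `qa_dvh`.
#' @param d dose in Gy, >= 0.
#' @param unit "%" or "cc".
#' @return Volume in the requested unit.
#' @export
volume_at_dose <- function(dvh, d, unit = c("%", "cc")) {
  unit <- match.arg(unit)
  if (!is.finite(d) || d < 0) stop("dose must be >= 0", call. = FALSE)
  f <- if (d >= max(dvh$dose_gy)) 0
       else approx(dvh$dose_gy, dvh$fraction, xout = d)$y
  if (unit == "%") 100 * f else f * dvh$total_cc
}

#' Maximum structure dose
#'
#' Point maximum over mask voxels (not a near-max volume statistic such as
#' D0.03cc).
#'
#' @param dose `qa_volume` of dose in Gy.
#' @param mask non-empty `qa_mask` on the same geometry.
#' @return Dose in Gy.
#' @export
d_max <- function(dose, mask) {
  stop_if_geometry_differs(dose, mask, "dose and mask")
  if (!any(mask$inside)) stop("Dmax of an empty mask is undefined", call. = FALSE)
  max(dose$values[mask$inside])
}

#' Parse one dose-volume constraint
#'
#' Understands the planning-template notation: `"D98% >= 100% of Rx"`,
#' `"Dmax <= 110% of Rx"`, `"V35 Gy < 50%"`, `"V45 Gy < 150cm3"`.
#'
#' @param roi ROI name the constraint applies to.
#' @param text constraint text.
#' @param rx prescription dose in Gy (for "% of Rx" limits).
#' @return One-row tibble: `roi`, `metric`, `kind`, `query`, `limit`,
#'   `unit`, `comparator`, `rx`.
#' @export
parse_constraint <- function(roi, text, rx = 70) {
  t <- gsub("\\s+", "", text)
  t <- gsub("cm\\^?3|cc", "cm3", t)
  m <- regmatches(t, regexec(
    "^(Dmax|D([0-9.]+)%|V([0-9.]+)Gy)(<=|>=|<|>)([0-9.]+)(%ofRx|%|Gy|cm3)$", t))[[1]]
  if (length(m) == 0) stop("cannot parse constraint: ", text, call. = FALSE)
  metric <- m[2]; comparator <- m[5]; limit <- as.double(m[6]); unit <- m[7]
  unit <- c("%ofRx" = "% of Rx", "%" = "%", "Gy" = "Gy", "cm3" = "cm3")[[unit]]
  if (metric == "Dmax") {
    kind <- "D_max"; query <- NA_real_
  } else if (startsWith(metric, "D")) {
    kind <- "D_at_volume"; query <- as.double(m[3])
  } else {
    kind <- "V_at_dose"; query <- as.double(m[4])
  }
  tibble::tibble(roi = roi, metric = metric, kind = kind, query = query,
                 limit = limit, unit = unit, comparator = comparator, rx = rx)
}

#' The planning constraint template
#'
#' The nine dose-volume rules of the prostate adaptive planning template
#' (prescription 2.5 Gy/fraction to `rx` = 70 Gy): PTV D98% >= 100% of Rx
#' and Dmax <= 110% of Rx; bladder V35 Gy < 50% and V57 Gy < 25%; rectum
#' V35 Gy < 35% and V57 Gy < 17%; bowel V45 Gy < 150 cm3; each femur
#' V45 Gy < 10%.
#'
#' @param rx prescription dose in Gy.
#' @return Tibble of constraint specs (one row per rule).
#' @export
planning_constraints <- function(rx = 70) {
  dplyr::bind_rows(
    parse_constraint("PTV_7000", "D98% >= 100% of Rx", rx),
    parse_constraint("PTV_7000", "Dmax <= 110% of Rx", rx),
    parse_constraint("Bladder", "V35 Gy < 50%", rx),
    parse_constraint("Bladder", "V57 Gy < 25%", rx),
    parse_constraint("Rectum", "V35 Gy < 35%", rx),
    parse_constraint("Rectum", "V57 Gy < 17%", rx),
    parse_constraint("Bowel", "V45 Gy < 150cm3", rx),
    parse_constraint("Femur_L", "V45 Gy < 10%", rx),
    parse_constraint("Femur_R", "V45 Gy < 10%", rx)
  )
}

#' Read a constraint template from YAML
#'
#' Expects a list of entries with keys `roi` and `constraint` (text form),
#' plus an optional top-level `rx`.
#'
#' @param path YAML file.
#' @param rx default prescription dose if the file does not set one.
#' @return Tibble of constraint specs.
#' @export
read_constraints <- function(path, rx = 70) {
  x <- yaml::read_yaml(path)
  if (!is.null(x$rx)) rx <- x$rx
  entries <- if (!is.null(x$constraints)) x$constraints else x
  dplyr::bind_rows(lapply(entries, function(e) {
    parse_constraint(e$roi, e$constraint, rx)
  }))
}

comparator_holds <- function(achieved, comparator, limit) {
  switch(comparator,
         "<" = achieved < limit, "<=" = achieved <= limit,
         ">" = achieved > limit, ">=" = achieved >= limit,
         stop("unknown comparator: ", comparator, call. = FALSE))
}

#' Evaluate dose-volume constraints against a dose grid
#'
#' Computes each constraint's achieved value in the limit's unit
#' ("% of Rx" limits are reported relative to the prescription) and a pass
#' flag.  Constraints whose ROI is missing produce an error row (NA
#' achieved/pass plus a note) and evaluation continues.
#'
#' @param dose `qa_volume` of dose in Gy.
#' @param structures `qa_structure_set` (or named list of masks) on the dose
#'   geometry.
#' @param specs constraint tibble, e.g. [planning_constraints()].
#' @param bin_width_gy DVH bin width.
#' @param per_fraction evaluate "% of Rx" limits against the per-fraction
#'   prescription (`rx / n_fractions`) instead of the course total.
#' @param n_fractions course fraction count used when `per_fraction = TRUE`.
#' @return Tibble: spec columns plus `achieved`, `pass`, `note`.
#' @export
evaluate_constraints <- function(dose, structures, specs = planning_constraints(),
                                 bin_width_gy = 0.05, per_fraction = FALSE,
                                 n_fractions = 28) {
  masks <- if (inherits(structures, "qa_structure_set")) structures$masks
           else structures
  rows <- lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    out <- s
    out$achieved <- NA_real_; out$pass <- NA; out$note <- ""
    m <- masks[[s$roi]]
    if (is.null(m)) {
      out$note <- "ROI missing"
      return(out)
    }
    rx_eff <- if (per_fraction) s$rx / n_fractions else s$rx
    dsub <- if (geometry_equal(m$geometry, dose$geometry)) dose
            else crop_volume_like(dose, m$geometry)
    achieved <- switch(s$kind,
      D_max = {
        dm <- d_max(dsub, m)
        if (s$unit == "% of Rx") 100 * dm / rx_eff else dm
      },
      D_at_volume = {
        dv <- dose_at_volume(cumulative_dvh(dsub, m, bin_width_gy), s$query)
        if (s$unit == "% of Rx") 100 * dv / rx_eff else dv
      },
      V_at_dose = {
        q <- if (per_fraction) s$query / n_fractions else s$query
        volume_at_dose(cumulative_dvh(dsub, m, bin_width_gy), q,
                       unit = if (s$unit == "cm3") "cc" else "%")
      },
      stop("unknown constraint kind: ", s$kind, call. = FALSE))
    out$achieved <- achieved
    out$pass <- comparator_holds(achieved, s$comparator, s$limit)
    out
  })
  dplyr::bind_rows(rows)
}
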