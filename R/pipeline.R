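#' Run the full end-to-end QA pipeline
#'
#' Executes the virtual study (phantom build, per-fraction auto-segmentation
#' surrogate, adaptive dose surrogate), compares every repetition to its
#' STAPLE consensus, evaluates the planning constraint template on every
#' fraction dose, and derives the contouring and dosimetric action-level
#' report.  Fully reproducible from the config plus master seed; two runs
#' with the same inputs produce byte-identical output tables.
#'
#' @param config a [study_config()].
#' @param seed master seed.
#' @param out_dir output directory (created if needed).  Writes
#'   `comparisons.tsv`, `anova.tsv`, `action_levels.tsv`,
#'   `dose_action_levels.tsv`, `constraint_metrics.tsv`, `report.md` and
#'   `provenance.yaml`.
#' @param verbose print per-stage progress with timings.
#' @param figures also write PNG figures (contour variability per
#'   deformation and pooled, for each metric, and dose repeatability by
#'   plan type) into `out_dir/figures`; skipped with a message if no PNG
#'   device is available.
#' @return Invisibly, a list: `comparisons`, `constraints`, `report`,
#'   `study`, `paths`.
#' @export
run_pipeline <- function(config = study_config(), seed = 1, out_dir,
                         verbose = TRUE, figures = FALSE) {
  t0 <- Sys.time()
  say <- function(...) {
    if (verbose) message(sprintf("[%6.1fs] ", as.double(difftime(Sys.time(), t0,
                                                                 units = "secs"))),
                         ...)
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  study <- run_virtual_study(config, seed)
  say("study layout: ", nrow(study$design), " fraction records")
  phantom <- build_phantom(config$phantom)
  boxes <- study_crop_boxes(phantom$structures)
  say("phantom built (", paste(config$phantom$geometry$size, collapse = "x"),
      " voxels)")

  specs <- planning_constraints(config$rx)
  compared <- canonical_rois(compared = TRUE)
  comparisons <- list()
  constraints <- list()
  for (d in seq_len(config$n_deformations)) {
    frs <- study$design$fraction[study$design$deformation_id == d]
    recs <- list()
    for (f in frs) {
      rf <- realize_fraction(study, d, f, phantom = phantom, boxes = boxes)
      cr <- evaluate_constraints(rf$dose, rf$masks, specs,
                                 bin_width_gy = config$dvh_bin_gy)
      cr$deformation_id <- d
      cr$fraction <- f
      cr$plan_type <- rf$record$plan_type
      cr$mode <- rf$record$mode
      constraints[[length(constraints) + 1L]] <- cr
      recs[[length(recs) + 1L]] <- tibble::tibble(
        roi = compared, deformation_id = d, fraction = f,
        plan_type = rf$record$plan_type, mode = rf$record$mode,
        mask = rf$masks[compared])
    }
    comparisons[[d]] <- compare_repetitions(dplyr::bind_rows(recs))
    say("deformation ", d, ": ", nrow(comparisons[[d]]), " comparison records")
  }
  comparisons <- dplyr::bind_rows(comparisons) |>
    dplyr::arrange(.data$mode, .data$roi, .data$deformation_id,
                   .data$plan_type, .data$fraction)
  constraints <- dplyr::bind_rows(constraints)

  report <- build_action_level_report(comparisons, constraints,
                                      alpha = config$alpha,
                                      ci_method = config$ci_method)
  say("report built")

  paths <- list(
    comparisons = file.path(out_dir, "comparisons.tsv"),
    anova = file.path(out_dir, "anova.tsv"),
    action_levels = file.path(out_dir, "action_levels.tsv"),
    dose_action_levels = file.path(out_dir, "dose_action_levels.tsv"),
    constraint_metrics = file.path(out_dir, "constraint_metrics.tsv"),
    report_md = file.path(out_dir, "report.md"),
    provenance = file.path(out_dir, "provenance.yaml")
  )
  readr::write_tsv(comparisons, paths$comparisons)
  readr::write_tsv(report$contour_anova, paths$anova)
  readr::write_tsv(report$contour, paths$action_levels)
  readr::write_tsv(report$dose, paths$dose_action_levels)
  readr::write_tsv(dplyr::select(constraints, "roi", "metric", "plan_type",
                                 "mode", "deformation_id", "fraction",
                                 "achieved", "limit", "unit", "pass"),
                   paths$constraint_metrics)
  writeLines(render_report_md(report, study), paths$report_md)
  yaml::write_yaml(list(
    seed = seed,
    package_version = as.character(utils::packageVersion("adaptqa")),
    design = list(n_deformations = config$n_deformations,
                  n_fractions = config$n_fractions,
                  n_ai_per_plan = config$n_ai_per_plan),
    rx = config$rx, alpha = config$alpha, ci_method = config$ci_method
  ), paths$provenance)
  if (figures) {
    fig_dir <- file.path(out_dir, "figures")
    dir.create(fig_dir, showWarnings = FALSE)
    tryCatch({
      for (metric in c("dsc", "mssd_mm")) {
        ggplot2::ggsave(file.path(fig_dir, paste0(metric, "_by_deformation.png")),
                        plot_contour_variability(comparisons, metric,
                                                 by_deformation = TRUE),
                        width = 8, height = 4.5, dpi = 150)
        ggplot2::ggsave(file.path(fig_dir, paste0(metric, "_pooled.png")),
                        plot_contour_variability(comparisons, metric),
                        width = 7, height = 4.5, dpi = 150)
      }
      ggplot2::ggsave(file.path(fig_dir, "dose_by_plan_type.png"),
                      plot_dose_repeatability(constraints),
                      width = 9, height = 7, dpi = 150)
      say("figures written to ", fig_dir)
    }, error = function(e) {
      message("figure rendering skipped: ", conditionMessage(e))
    })
  }
  say("outputs written to ", out_dir)
  invisible(list(comparisons = comparisons, constraints = constraints,
                 report = report, study = study, paths = paths))
}

fmt_md_table <- function(df, digits = 4) {
  cols <- names(df)
  fmt <- function(v) {
    if (is.numeric(v)) formatC(v, digits = digits, format = "g") else as.character(v)
  }
  body <- apply(vapply(df, fmt, character(nrow(df))), 1, paste, collapse = " | ")
  c(paste(cols, collapse = " | "),
    paste(rep("---", length(cols)), collapse = " | "),
    body)
}

render_report_md <- function(report, study) {
  c("# End-to-end QA action-level report",
    "",
    sprintf("Design: %d deformation instances x %d adapted fractions (%d records); master seed %d.",
            study$config$n_deformations, study$config$n_fractions,
            nrow(study$design), study$seed),
    sprintf("Pooling rule: deformations pooled when one-way ANOVA p >= %.2f; %s 95%% intervals.",
            report$alpha, report$ci_method),
    "",
    "## Contouring action levels",
    "",
    fmt_md_table(report$contour),
    "",
    "## Dose-volume action levels (by plan type)",
    "",
    if (!is.null(report$dose)) fmt_md_table(report$dose) else "(no dose data)",
    "")
}

#' Read a study configuration from YAML
#'
#' Recognized keys (all optional, defaults from [study_config()]):
#' `n_deformations`, `n_fractions`, `n_ai_per_plan`, `rx`, `alpha`,
#' `ci_method`, `dvh_bin_gy`, `correlation_mm`, `dose_noise_frac`,
#' `use_reference_deformations`, `phantom: {origin, spacing, size}`, and
#' `seg_noise:` a list of `{roi, mode, sd_mm}` entries overriding the
#' defaults.
#'
#' @param path YAML file.
#' @return A `qa_study_config`.
#' @export
read_study_config <- function(path) {
  x <- yaml::read_yaml(path)
  args <- list()
  for (k in c("n_deformations", "n_fractions", "n_ai_per_plan", "rx", "alpha",
              "ci_method", "dvh_bin_gy", "correlation_mm", "dose_noise_frac",
              "use_reference_deformations")) {
    if (!is.null(x[[k]])) args[[k]] <- x[[k]]
  }
  if (!is.null(x$phantom)) {
    ph <- x$phantom
    defaults <- phantom_config()
    g <- geometry(
      origin = if (!is.null(ph$origin)) unlist(ph$origin) else defaults$geometry$origin,
      spacing = if (!is.null(ph$spacing)) unlist(ph$spacing) else defaults$geometry$spacing,
      size = if (!is.null(ph$size)) unlist(ph$size) else defaults$geometry$size)
    args$phantom <- phantom_config(geom = g)
  }
  if (!is.null(x$seg_noise)) {
    sn <- default_seg_noise()
    for (e in x$seg_noise) {
      sn$sd_mm[sn$roi == e$roi & sn$mode == e$mode] <- e$sd_mm
    }
    args$seg_noise <- sn
  }
  do.call(study_config, args)
}
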