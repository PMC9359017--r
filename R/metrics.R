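#' Dice similarity coefficient
#'
#' `2|A n B| / (|A| + |B|)`.  Two empty masks agree perfectly on absence and
#' return 1 (with a warning so the degenerate case is visible).
#'
#' @param a,b `qa_mask` objects on one geometry.
#' @return Dice coefficient in `[0, 1]`.
#' @export
dice <- function(a, b) {
  stop_if_geometry_differs(a, b, "masks")
  na <- sum(a$inside); nb <- sum(b$inside)
  if (na == 0 && nb == 0) {
    warning("both masks empty; Dice defined as 1", call. = FALSE)
    return(1)
  }
  2 * sum(a$inside & b$inside) / (na + nb)
}

# Surface voxels: inside voxels with at least one face-adjacent outside
# voxel; the region beyond the grid counts as outside.
surface_voxels <- function(inside) {
  d <- dim(inside)
  shift <- function(ax, by) {
    out <- array(FALSE, d)
    n <- d[ax]
    src <- if (by > 0) 1:(n - 1) else 2:n
    dst <- if (by > 0) 2:n else 1:(n - 1)
    a_src <- a_dst <- list(TRUE, TRUE, TRUE)
    a_src[[ax]] <- src; a_dst[[ax]] <- dst
    out[a_dst[[1]], a_dst[[2]], a_dst[[3]]] <- inside[a_src[[1]], a_src[[2]], a_src[[3]]]
    out
  }
  all_nb_in <- shift(1, 1) & shift(1, -1) & shift(2, 1) & shift(2, -1) &
               shift(3, 1) & shift(3, -1)
  inside & !all_nb_in
}

#' Mean symmetric surface distance
#'
#' Surface voxels are inside voxels with a face-adjacent outside voxel
#' (6-neighborhood; beyond-grid counts as outside).  The metric is the
#' pooled symmetric mean: over the union of both surface voxel sets, the
#' mean world-space Euclidean distance of each surface voxel center to the
#' nearest surface voxel center of the other mask.  Zero iff the surfaces
#' coincide.  An alternative variant, the average of the two directed
#' means, is available via `variant = "averaged"`.
#'
#' @param a,b non-empty `qa_mask` objects on one geometry.
#' @param variant "pooled" (default) or "averaged".
#' @return Distance in mm.
#' @export
mean_symmetric_surface_distance <- function(a, b,
                                            variant = c("pooled", "averaged")) {
  variant <- match.arg(variant)
  stop_if_geometry_differs(a, b, "masks")
  if (!any(a$inside) || !any(b$inside)) {
    stop("mean surface distance is undefined for empty masks", call. = FALSE)
  }
  g <- a$geometry
  sa <- surface_voxels(a$inside)
  sb <- surface_voxels(b$inside)
  d2_to_b <- edt_squared_cpp(sb, g$size, g$spacing)
  d2_to_a <- edt_squared_cpp(sa, g$size, g$spacing)
  da <- sqrt(d2_to_b[as.vector(sa)])   # directed A -> B
  db <- sqrt(d2_to_a[as.vector(sb)])   # directed B -> A
  if (variant == "pooled") mean(c(da, db)) else (mean(da) + mean(db)) / 2
}

#' @rdname mean_symmetric_surface_distance
#' @export
mssd <- mean_symmetric_surface_distance

#' STAPLE consensus of repeated segmentations
#'
#' Simultaneous truth and performance level estimation: an EM algorithm that
#' treats the unknown true segmentation as latent and estimates, jointly,
#' per-voxel foreground probabilities (weights) and each rater's sensitivity
#' `p_j` and specificity `q_j`.  The E-step computes weights from the
#' current `(p, q)` and the foreground prior; the M-step re-estimates
#' `(p, q)` from the weights.  Iteration stops when the mean absolute
#' weight change falls below `tol` or after `max_iter` E-steps.  The
#' consensus is weight >= 0.5 (ties count as foreground).
#'
#' For efficiency the EM runs on the padded bounding box of the union of
#' the input masks; voxels outside it are background for every rater and
#' are excluded from the performance estimates.
#'
#' @param masks list of >= 1 `qa_mask` objects on one geometry.
#' @param prior "auto" (mean foreground fraction of the inputs) or a
#'   foreground prior probability in (0, 1).
#' @param tol convergence tolerance on the mean absolute weight change.
#' @param max_iter maximum number of E-steps.
#' @param init initial sensitivity/specificity for every rater.
#' @param crop run on the padded union bounding box (default) or the full
#'   grid.
#' @return An object of class `qa_staple`: `consensus` (`qa_mask` on the
#'   input geometry), `p`, `q` (per-rater), `iterations`, `converged`,
#'   `prior`.  Non-convergence is flagged, not an error.
#' @export
staple <- function(masks, prior = "auto", tol = 1e-6, max_iter = 100,
                   init = 0.99, crop = TRUE) {
  if (length(masks) < 1) stop("need at least one mask", call. = FALSE)
  geom <- masks[[1]]$geometry
  for (m in masks) stop_if_geometry_differs(m, masks[[1]], "rater masks")
  J <- length(masks)

  union_inside <- Reduce(`|`, lapply(masks, `[[`, "inside"))
  if (crop && any(union_inside)) {
    bb <- pad_bbox(mask_bbox(union_inside), geom, 2 * max(geom$spacing))
    sub <- lapply(masks, crop_mask, lo = bb$lo, hi = bb$hi)
  } else {
    bb <- NULL
    sub <- masks
  }
  n <- prod(sub[[1]]$geometry$size)
  D <- vapply(sub, function(m) as.double(m$inside), numeric(n))
  g <- if (identical(prior, "auto")) mean(D) else as.double(prior)
  g <- min(max(g, 1e-6), 1 - 1e-6)

  clamp <- function(x) pmin(pmax(x, 1e-7), 1 - 1e-7)
  p <- rep(init, J); q <- rep(init, J)
  W_prev <- NULL
  converged <- FALSE
  iterations <- 0L
  for (it in seq_len(max_iter)) {
    p <- clamp(p); q <- clamp(q)
    loga <- log(g) + sum(log(1 - p)) + drop(D %*% (log(p) - log(1 - p)))
    logb <- log(1 - g) + sum(log(q)) + drop(D %*% (log(1 - q) - log(q)))
    W <- 1 / (1 + exp(logb - loga))
    iterations <- it
    if (!is.null(W_prev) && mean(abs(W - W_prev)) < tol) {
      converged <- TRUE
      break
    }
    W_prev <- W
    sw <- sum(W)
    if (sw > 0) p <- drop(crossprod(D, W)) / sw
    if (n - sw > 0) q <- drop(crossprod(1 - D, 1 - W)) / (n - sw)
  }
  cons_sub <- binary_mask(sub[[1]]$geometry,
                          array(W >= 0.5, sub[[1]]$geometry$size))
  consensus <- if (is.null(bb)) cons_sub else embed_mask(cons_sub, geom)
  structure(list(consensus = consensus, p = p, q = q,
                 iterations = iterations, converged = converged, prior = g),
            class = "qa_staple")
}

#' @export
print.qa_staple <- function(x, ...) {
  cat("<qa_staple> ", length(x$p), " raters, ", x$iterations, " iterations (",
      if (x$converged) "converged" else "NOT converged", "), prior ",
      format(x$prior, digits = 3), "\n", sep = "")
  cat("  sensitivity: ", paste(format(x$p, digits = 3), collapse = " "), "\n",
      "  specificity: ", paste(format(x$q, digits = 3), collapse = " "), "\n",
      sep = "")
  invisible(x)
}

#' @rdname staple
#' @param x a `qa_staple` object.
#' @param ... unused.
#' @export
tidy.qa_staple <- function(x, ...) {
  tibble::tibble(rater = seq_along(x$p), sensitivity = x$p, specificity = x$q)
}

#' @rdname staple
#' @export
glance.qa_staple <- function(x, ...) {
  tibble::tibble(n_raters = length(x$p), iterations = x$iterations,
                 converged = x$converged, prior = x$prior,
                 consensus_cc = mask_volume_cc(x$consensus))
}

#' Compare repeated segmentations to their STAPLE consensus
#'
#' Groups the records by the repetition-set key (ROI, deformation instance,
#' plan type and correction mode by default), builds one STAPLE consensus
#' per group, and emits one comparison row per repetition: Dice similarity
#' and mean symmetric surface distance of that repetition versus the group
#' consensus.  Groups with a single repetition are skipped with a warning.
#'
#' @param records data frame with a list-column of `qa_mask` objects plus
#'   the grouping columns.
#' @param mask_col name of the mask list-column.
#' @param group_vars character vector of grouping column names.
#' @param ... passed on to [staple()].
#' @return Tibble: grouping columns plus every other record column,
#'   `dsc` and `mssd_mm`.
#' @export
compare_repetitions <- function(records, mask_col = "mask",
                                group_vars = c("roi", "deformation_id",
                                               "plan_type", "mode"),
                                ...) {
  group_vars <- intersect(group_vars, names(records))
  groups <- dplyr::group_split(dplyr::group_by(records,
                                               dplyr::across(dplyr::all_of(group_vars))))
  out <- purrr::map(groups, function(gr) {
    if (nrow(gr) < 2) {
      warning("skipping group with a single repetition (",
              paste(unlist(gr[1, group_vars]), collapse = "/"), ")",
              call. = FALSE)
      return(NULL)
    }
    cons <- staple(gr[[mask_col]], ...)$consensus
    gr$dsc <- purrr::map_dbl(gr[[mask_col]], dice, b = cons)
    gr$mssd_mm <- purrr::map_dbl(gr[[mask_col]], mean_symmetric_surface_distance,
                                 b = cons)
    gr[[mask_col]] <- NULL
    gr
  })
  dplyr::bind_rows(out)
}

#' Boxplots of contour reproducibility by ROI
#'
#' Distribution of Dice or mean symmetric surface distance versus the
#' repetition-set consensus, per ROI, optionally split by deformation
#' instance.
#'
#' @param comparisons output of [compare_repetitions()].
#' @param metric "dsc" or "mssd_mm".
#' @param by_deformation facet by deformation instance (the per-instance
#'   view) or pool all instances.
#' @return A ggplot object.
#' @export
plot_contour_variability <- function(comparisons, metric = c("dsc", "mssd_mm"),
                                     by_deformation = FALSE) {
  metric <- match.arg(metric)
  lab <- if (metric == "dsc") "Dice similarity coefficient"
         else "Mean symmetric surface distance (mm)"
  p <- ggplot2::ggplot(comparisons,
                       ggplot2::aes(x = .data$roi, y = .data[[metric]]))
  if (by_deformation) {
    p <- p + ggplot2::geom_boxplot(
      ggplot2::aes(fill = factor(.data$deformation_id)), outlier.size = 0.5) +
      ggplot2::labs(fill = "Deformation")
  } else {
    p <- p + ggplot2::geom_boxplot(outlier.size = 0.5)
  }
  p + ggplot2::labs(x = NULL, y = lab) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
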