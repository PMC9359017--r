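#' Segmentation perturbation model
#'
#' Surrogate for repeated auto-segmentation of fixed anatomy: the truth
#' surface is displaced by a smooth random vector field (Gaussian white
#' noise filtered at `correlation_mm`, rescaled so each component has
#' standard deviation `sd_mm`) and the mask is re-sampled through it.
#' `mode = "corrected"` represents AI contours after manual correction and
#' uses a lower-noise regime for target structures and bladder in the study
#' defaults; `mode = "ai"` represents uncorrected AI contours.
#'
#' @param sd_mm boundary displacement standard deviation (mm), >= 0.
#' @param correlation_mm smoothness (correlation length) of the displacement
#'   field (mm), > 0 and at least the voxel spacing.
#' @param mode "ai" or "corrected" (metadata describing the regime).
#' @param seed integer seed.
#' @return An object of class `qa_seg_model`.
#' @export
seg_perturbation_model <- function(sd_mm, correlation_mm = 8,
                                   mode = c("ai", "corrected"), seed = 1) {
  mode <- match.arg(mode)
  if (!is.finite(sd_mm) || sd_mm < 0) stop("sd_mm must be finite and >= 0", call. = FALSE)
  if (!is.finite(correlation_mm) || correlation_mm <= 0) {
    stop("correlation_mm must be > 0", call. = FALSE)
  }
  structure(list(sd_mm = sd_mm, correlation_mm = correlation_mm, mode = mode,
                 seed = as.integer(seed)),
            class = "qa_seg_model")
}

#' Simulate one auto-segmentation of a known truth mask
#'
#' Deterministic given the model seed; `sd_mm = 0` returns the truth
#' unchanged.  Computation is restricted to a padded bounding box around
#' the truth for efficiency; the result is returned on the input geometry.
#'
#' @param truth non-empty `qa_mask`.
#' @param model a [seg_perturbation_model()].
#' @return Perturbed `qa_mask` on the truth geometry.
#' @export
simulate_autoseg <- function(truth, model) {
  if (!any(truth$inside)) stop("truth mask is empty", call. = FALSE)
  if (model$sd_mm == 0) return(truth)
  geom <- truth$geometry
  if (model$correlation_mm < max(geom$spacing)) {
    stop("correlation_mm must be at least the voxel spacing", call. = FALSE)
  }
  pad <- 4 * model$sd_mm + 2 * model$correlation_mm
  bb <- pad_bbox(mask_bbox(truth$inside), geom, pad)
  sub <- crop_mask(truth, bb$lo, bb$hi)
  g <- sub$geometry
  n <- prod(g$size)
  sig_vox <- model$correlation_mm / g$spacing
  noise <- withr::with_seed(model$seed, rnorm(3 * n))
  vectors <- array(0, c(g$size, 3L))
  for (a in 1:3) {
    comp <- gaussian_smooth3_cpp(noise[((a - 1) * n + 1):(a * n)], g$size, sig_vox)
    s <- sd(comp)
    if (s > 0) comp <- comp * (model$sd_mm / s)
    vectors[, , , a] <- comp
  }
  warped <- warp_mask(sub, displacement_field(g, vectors))
  if (all(bb$lo == 1L) && all(bb$hi == geom$size)) {
    binary_mask(geom, warped$inside)
  } else {
    embed_mask(warped, geom)
  }
}

#' Adaptive-plan dose surrogate model
#'
#' Conformal dose stand-in: prescription dose inside the PTV, Gaussian
#' falloff of the PTV distance map outside, plus seeded low-amplitude noise
#' (at most `noise_frac` of Rx).  Plan styles differ by penumbra width:
#' VMAT-like plans use a narrower default penumbra (6 mm) for tighter target
#' conformity, IMRT-like plans a wider one (8 mm).
#'
#' @param rx total prescription dose in Gy (default 70, delivered at
#'   2.5 Gy/fraction).
#' @param plan_style "IMRT" or "VMAT".
#' @param penumbra_sd_mm Gaussian penumbra sd (mm); default by style.
#' @param noise_frac additive noise amplitude as a fraction of Rx (<= 0.01).
#' @param seed integer seed.
#' @return An object of class `qa_dose_model`.
#' @export
dose_model <- function(rx = 70, plan_style = c("IMRT", "VMAT"),
                       penumbra_sd_mm = NULL, noise_frac = 0.01, seed = 1) {
  plan_style <- match.arg(plan_style)
  if (rx <= 0) stop("rx must be > 0", call. = FALSE)
  if (is.null(penumbra_sd_mm)) {
    penumbra_sd_mm <- if (plan_style == "VMAT") 6 else 8
  }
  if (penumbra_sd_mm <= 0) stop("penumbra sd must be > 0", call. = FALSE)
  structure(list(rx = rx, plan_style = plan_style,
                 penumbra_sd_mm = penumbra_sd_mm,
                 noise_frac = noise_frac, seed = as.integer(seed)),
            class = "qa_dose_model")
}

#' Simulate an adaptive-plan dose distribution
#'
#' @param structures `qa_structure_set` containing `PTV_7000`.
#' @param model a [dose_model()].
#' @param noise add the seeded noise component (disable to inspect the
#'   noise-free falloff).
#' @return `qa_volume` of dose in Gy on the structure-set geometry.
#' @export
simulate_dose <- function(structures, model, noise = TRUE) {
  ptv <- structures$masks[["PTV_7000"]]
  if (is.null(ptv)) stop("structure set has no PTV_7000", call. = FALSE)
  d <- distance_map(ptv)$values
  dose <- model$rx * exp(-d^2 / (2 * model$penumbra_sd_mm^2))
  if (noise && model$noise_frac > 0) {
    amp <- model$noise_frac * model$rx
    e <- withr::with_seed(model$seed,
                          rnorm(length(dose), 0, amp / 2.5))
    dose <- pmax(dose + array(pmin(pmax(e, -amp), amp), dim(dose)), 0)
  }
  image_volume(ptv$geometry, dose, unit = "Gy")
}

#' Per-ROI boundary-noise defaults of the virtual study
#'
#' Displacement sd (mm) by ROI and contouring mode.  The corrected regime
#' tightens targets and bladder (manual correction helps where the adaptive
#' system struggles); the AI regime is tighter for bowel, femurs and rectum,
#' mirroring the qualitative organ ranking seen in phantom studies of
#' AI-assisted adaptive contouring.
#'
#' @return Tibble with columns `roi`, `mode`, `sd_mm`.
#' @export
default_seg_noise <- function() {
  tibble::tribble(
    ~roi,              ~corrected, ~ai,
    "Prostate",              1.2,  3.0,
    "SeminalVesicles",       1.2,  2.8,
    "Bladder",               1.2,  2.5,
    "Rectum",                1.0,  0.9,
    "Bowel",                 0.8,  0.6,
    "Femur_L",               0.6,  0.5,
    "Femur_R",               0.6,  0.5
  ) |>
    tidyr::pivot_longer(c("corrected", "ai"), names_to = "mode",
                        values_to = "sd_mm")
}

#' Virtual study configuration
#'
#' Bundles every parameter of the surrogate end-to-end study: phantom,
#' fractionation design (five deformation instances, 26 adapted fractions
#' each, split 13 IMRT / 13 VMAT with the first three fractions of each plan
#' delivered with uncorrected AI contours), segmentation noise, dose model
#' and statistics settings.
#'
#' @param phantom a [phantom_config()].
#' @param n_deformations number of deformation instances (default 5).
#' @param n_fractions adapted fractions per deformation (default 26; half
#'   IMRT, half VMAT).
#' @param n_ai_per_plan fractions per plan type delivered without manual
#'   correction (default 3).
#' @param use_reference_deformations use the five bundled deformation
#'   parameter sets when possible, otherwise sample from `bounds`.
#' @param bounds [sampling_bounds()] for sampled deformations; default
#'   anchors the box on the phantom PTV centroid.
#' @param seg_noise tibble `roi`/`mode`/`sd_mm` (see [default_seg_noise()]).
#' @param correlation_mm segmentation noise correlation length (mm).
#' @param rx total prescription dose (Gy).
#' @param penumbra_sd_mm named numeric, penumbra by plan style.
#' @param dose_noise_frac dose noise amplitude as fraction of Rx.
#' @param alpha ANOVA pooling significance level.
#' @param ci_method "percentile" or "normal".
#' @param dvh_bin_gy DVH bin width (Gy).
#' @return An object of class `qa_study_config` (a named list).
#' @export
study_config <- function(phantom = phantom_config(),
                         n_deformations = 5, n_fractions = 26,
                         n_ai_per_plan = 3,
                         use_reference_deformations = TRUE,
                         bounds = NULL,
                         seg_noise = default_seg_noise(),
                         correlation_mm = 8,
                         rx = 70,
                         penumbra_sd_mm = c(IMRT = 8, VMAT = 6),
                         dose_noise_frac = 0.01,
                         alpha = 0.05,
                         ci_method = "percentile",
                         dvh_bin_gy = 0.05) {
  stopifnot(n_deformations >= 1, n_fractions >= 1, n_ai_per_plan >= 0)
  if (n_fractions %% 2 != 0) stop("n_fractions must split evenly by plan type",
                                  call. = FALSE)
  if (n_ai_per_plan > n_fractions / 2) {
    stop("n_ai_per_plan exceeds the per-plan fraction count", call. = FALSE)
  }
  structure(list(phantom = phantom, n_deformations = n_deformations,
                 n_fractions = n_fractions, n_ai_per_plan = n_ai_per_plan,
                 use_reference_deformations = use_reference_deformations,
                 bounds = bounds, seg_noise = seg_noise,
                 correlation_mm = correlation_mm, rx = rx,
                 penumbra_sd_mm = penumbra_sd_mm,
                 dose_noise_frac = dose_noise_frac, alpha = alpha,
                 ci_method = ci_method, dvh_bin_gy = dvh_bin_gy),
            class = "qa_study_config")
}

#' Lay out the virtual end-to-end study
#'
#' Enumerates one record per (deformation, fraction) with plan type,
#' contour-correction mode and derived per-record seeds, and attaches the
#' deformation specification of each instance.  The default design yields
#' 130 records: 26 fractions for each of 5 deformation instances, with
#' 3 IMRT + 3 VMAT fractions per deformation flagged `mode = "ai"` and
#' 10 + 10 flagged `mode = "corrected"`.  Masks and doses are realized
#' lazily via [realize_fraction()] so the layout itself stays light.
#'
#' @param config a [study_config()].
#' @param seed master seed; the whole study is reproducible from it.
#' @return An object of class `qa_study`: list with `config`, `seed`,
#'   `design` (tibble: deformation_id, fraction, plan_type, mode, seed) and
#'   `deformations` (list of `qa_deformation_spec`).
#' @export
run_virtual_study <- function(config = study_config(), seed = 1) {
  per_plan <- config$n_fractions / 2
  plan_of <- rep(c("IMRT", "VMAT"), each = per_plan)
  mode_of <- rep(c(rep("ai", config$n_ai_per_plan),
                   rep("corrected", per_plan - config$n_ai_per_plan)), 2)
  design <- tidyr::expand_grid(deformation_id = seq_len(config$n_deformations),
                               fraction = seq_len(config$n_fractions)) |>
    dplyr::mutate(plan_type = plan_of[.data$fraction],
                  mode = mode_of[.data$fraction],
                  seed = purrr::map2_int(.data$deformation_id, .data$fraction,
                                         ~derive_seed(seed, .x, .y)))
  deformations <- lapply(seq_len(config$n_deformations), function(i) {
    if (config$use_reference_deformations && i <= 5) {
      reference_deformation_spec(i)
    } else {
      b <- config$bounds
      if (is.null(b)) {
        ph <- build_phantom(config$phantom)
        ctr <- mask_centroid(ph$structures$masks$PTV_7000)
        b <- sampling_bounds(center = ctr)
      }
      sample_deformation_spec(b, derive_seed(seed, 999, i))
    }
  })
  structure(list(config = config, seed = as.integer(seed), design = design,
                 deformations = deformations),
            class = "qa_study")
}

#' @export
print.qa_study <- function(x, ...) {
  cat("<qa_study> ", nrow(x$design), " fraction records (",
      x$config$n_deformations, " deformations x ", x$config$n_fractions,
      " fractions), master seed ", x$seed, "\n", sep = "")
  invisible(x)
}

# World centroid of a mask (mm).
mask_centroid <- function(mask) {
  idx <- which(mask$inside, arr.ind = TRUE)
  mask$geometry$origin + (colMeans(idx) - 1) * mask$geometry$spacing
}

#' Per-ROI crop boxes for the virtual study
#'
#' Padded truth bounding boxes, reused across fractions so all repetitions
#' of an ROI share one cropped geometry.  Prostate and seminal-vesicle
#' boxes get extra padding to accommodate the PTV margin expansion.
#'
#' @param structures the phantom `qa_structure_set`.
#' @param pad_mm,prostate_pad_mm padding in mm.
#' @return Named list of `{lo, hi}` voxel index boxes.
#' @export
study_crop_boxes <- function(structures, pad_mm = 18, prostate_pad_mm = 26) {
  rois <- c("Prostate", "SeminalVesicles", "Bladder", "Rectum", "Bowel",
            "Femur_L", "Femur_R")
  boxes <- lapply(rois, function(r) {
    pad <- if (r %in% c("Prostate", "SeminalVesicles")) prostate_pad_mm else pad_mm
    pad_bbox(mask_bbox(structures$masks[[r]]$inside), structures$geometry, pad)
  })
  names(boxes) <- rois
  # CTV/PTV boxes must contain their parents
  uni <- list(lo = pmin(boxes$Prostate$lo, boxes$SeminalVesicles$lo),
              hi = pmax(boxes$Prostate$hi, boxes$SeminalVesicles$hi))
  boxes$CTV_7000 <- uni
  boxes$PTV_7000 <- boxes$Prostate
  boxes
}

seg_sd_for <- function(config, roi, mode) {
  row <- config$seg_noise[config$seg_noise$roi == roi &
                          config$seg_noise$mode == mode, ]
  if (nrow(row) != 1) stop("no segmentation noise entry for ", roi, "/", mode,
                           call. = FALSE)
  row$sd_mm
}

#' Realize the masks and dose of one fraction record
#'
#' Simulates the per-fraction auto-segmentations of every base organ,
#' derives `CTV_7000` (prostate union seminal vesicles) and `PTV_7000`
#' (prostate + margin) from the simulated organs, and simulates the
#' adaptive dose for the record's plan style.  Deterministic given the
#' study master seed.
#'
#' @param study a `qa_study`.
#' @param deformation_id,fraction record coordinates.
#' @param phantom optional pre-built [build_phantom()] result (built on
#'   demand otherwise; pass it when realizing many fractions).
#' @param boxes optional precomputed [study_crop_boxes()] result (computed
#'   from the phantom otherwise).
#' @param crop return masks cropped to fixed per-ROI boxes (memory-friendly;
#'   all fractions of an ROI share one cropped geometry).  With
#'   `crop = FALSE` masks are returned on the full grid.
#' @param dose simulate the dose volume (full grid).
#' @return List with `record` (one-row tibble), `masks` (named list of
#'   `qa_mask`) and `dose` (`qa_volume` in Gy, or NULL).
#' @export
realize_fraction <- function(study, deformation_id, fraction, phantom = NULL,
                             boxes = NULL, crop = TRUE, dose = TRUE) {
  rec <- study$design[study$design$deformation_id == deformation_id &
                      study$design$fraction == fraction, ]
  if (nrow(rec) != 1) stop("no such fraction record", call. = FALSE)
  if (is.null(phantom)) phantom <- build_phantom(study$config$phantom)
  if (is.null(boxes)) boxes <- study_crop_boxes(phantom$structures)
  cfg <- study$config
  base_rois <- c("Prostate", "SeminalVesicles", "Bladder", "Rectum", "Bowel",
                 "Femur_L", "Femur_R")
  masks <- list()
  for (ri in seq_along(base_rois)) {
    roi <- base_rois[ri]
    truth <- crop_mask(phantom$structures$masks[[roi]],
                       boxes[[roi]]$lo, boxes[[roi]]$hi)
    mdl <- seg_perturbation_model(seg_sd_for(cfg, roi, rec$mode),
                                  cfg$correlation_mm, mode = rec$mode,
                                  seed = derive_seed(rec$seed, ri))
    masks[[roi]] <- simulate_autoseg(truth, mdl)
  }
  # derived targets from the simulated organs
  ubox <- boxes$CTV_7000
  ug <- crop_geometry(phantom$structures$geometry, ubox$lo, ubox$hi)
  pr_u <- embed_mask(masks$Prostate, ug)
  sv_u <- embed_mask(masks$SeminalVesicles, ug)
  masks$CTV_7000 <- binary_mask(ug, pr_u$inside | sv_u$inside)
  masks$PTV_7000 <- expand_margin(masks$Prostate, cfg$phantom$ptv_margin_mm)

  full_geom <- phantom$structures$geometry
  dose_vol <- NULL
  if (dose) {
    ptv_full <- embed_mask(masks$PTV_7000, full_geom)
    dm <- dose_model(rx = cfg$rx, plan_style = rec$plan_type,
                     penumbra_sd_mm = cfg$penumbra_sd_mm[[rec$plan_type]],
                     noise_frac = cfg$dose_noise_frac,
                     seed = derive_seed(rec$seed, 99))
    dose_vol <- simulate_dose(structure_set(full_geom, list(PTV_7000 = ptv_full)), dm)
  }
  if (!crop) {
    masks <- lapply(masks, embed_mask, full_geom = full_geom)
  }
  list(record = rec, masks = masks, dose = dose_vol)
}
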