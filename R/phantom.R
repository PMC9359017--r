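#' Digital pelvis phantom configuration
#'
#' Parametric stand-in for an anthropomorphic pelvis phantom: ellipsoid
#' prostate, bladder and seminal vesicles, a tubular rectum, a bowel region,
#' two spherical femoral heads and an elliptic-cylinder body, on a shared
#' grid.  The default grid (128 x 128 x 96 voxels at 2 mm isotropic) is
#' positioned so the prostate sits near the mean of the five reference
#' deformation centers, keeping those centers inside the PTV.
#'
#' Organ shapes are synthetic primitives chosen for plausible pelvic
#' topology (bladder anterior-superior, rectum posterior, femurs lateral),
#' not anatomical fidelity; the analytics only require repeatable geometry.
#'
#' @param geom grid `qa_geometry`.
#' @param organs named list of shape parameter lists (centers/radii in mm);
#'   see the default for the schema.
#' @param hu named numeric of tissue HU values.
#' @param noise_sd_hu additive Gaussian HU noise (sd, HU units).
#' @param ptv_margin_mm CTV-to-PTV margin; the PTV is the prostate expanded
#'   by this margin (default 5 mm).
#' @param seed integer seed for the HU noise.
#' @return An object of class `qa_phantom_config`.
#' @export
phantom_config <- function(geom = geometry(origin = c(-139, -7, 609),
                                           spacing = c(2, 2, 2),
                                           size = c(128, 128, 96)),
                           organs = default_organs(),
                           hu = c(background = -1000, body = 20, prostate = 45,
                                  seminal_vesicles = 35, bladder = 10,
                                  rectum = -80, bowel = 25, femur = 700),
                           noise_sd_hu = 10, ptv_margin_mm = 5, seed = 20220707) {
  structure(list(geometry = geom, organs = organs, hu = hu,
                 noise_sd_hu = noise_sd_hu, ptv_margin_mm = ptv_margin_mm,
                 seed = as.integer(seed)),
            class = "qa_phantom_config")
}

#' @rdname phantom_config
#' @export
default_organs <- function() {
  list(
    Body     = list(type = "ecyl",      center = c(-12, 118), radii = c(115, 105)),
    Prostate = list(type = "ellipsoid", center = c(-12, 120, 704), radii = c(22, 20, 20)),
    SeminalVesicles = list(type = "ellipsoid", center = c(-12, 132, 724),
                           radii = c(18, 8, 10)),
    Bladder  = list(type = "ellipsoid", center = c(-12, 82, 720), radii = c(32, 26, 26)),
    Rectum   = list(type = "tube", center = c(-12, 155), radius = 14,
                    z_range = c(640, 760)),
    Bowel    = list(type = "ellipsoid", center = c(-12, 105, 772), radii = c(70, 45, 26)),
    Femur_L  = list(type = "sphere", center = c(63, 125, 700), radius = 22),
    Femur_R  = list(type = "sphere", center = c(-87, 125, 700), radius = 22)
  )
}

rasterize_organ <- function(par, co) {
  switch(par$type,
    ellipsoid = ((co$x - par$center[1]) / par$radii[1])^2 +
                ((co$y - par$center[2]) / par$radii[2])^2 +
                ((co$z - par$center[3]) / par$radii[3])^2 <= 1,
    sphere = (co$x - par$center[1])^2 + (co$y - par$center[2])^2 +
             (co$z - par$center[3])^2 <= par$radius^2,
    tube = ((co$x - par$center[1]) / par$radius)^2 +
           ((co$y - par$center[2]) / par$radius)^2 <= 1 &
           co$z >= par$z_range[1] & co$z <= par$z_range[2],
    ecyl = ((co$x - par$center[1]) / par$radii[1])^2 +
           ((co$y - par$center[2]) / par$radii[2])^2 <= 1,
    stop("unknown organ type: ", par$type, call. = FALSE))
}

#' Build the digital phantom
#'
#' Deterministic given the config seed.  Structures include the canonical
#' set: base organs plus `CTV_7000` (prostate union seminal vesicles),
#' `PTV_7000` (prostate expanded by the PTV margin) and `Body`.  Soft-tissue
#' organs are clipped to the body and the prostate / bladder / rectum are
#' made pairwise disjoint by precedence (prostate > bladder > rectum).
#'
#' @param config a [phantom_config()].
#' @return List with elements `image` (`qa_volume`, HU) and `structures`
#'   (`qa_structure_set`).
#' @export
build_phantom <- function(config = phantom_config()) {
  geom <- config$geometry
  co <- coord_arrays(geom)
  raw <- lapply(config$organs, rasterize_organ, co = co)
  body <- raw$Body
  for (nm in setdiff(names(raw), "Body")) {
    if (any(raw[[nm]] & !body)) {
      stop("organ '", nm, "' escapes the body outline", call. = FALSE)
    }
  }
  prostate <- raw$Prostate
  sv <- raw$SeminalVesicles & !prostate
  bladder <- raw$Bladder & !prostate
  rectum <- raw$Rectum & !prostate & !bladder
  bowel <- raw$Bowel & !(prostate | sv | bladder | rectum)
  femur_l <- raw$Femur_L
  femur_r <- raw$Femur_R

  masks <- list(
    Prostate = binary_mask(geom, prostate),
    SeminalVesicles = binary_mask(geom, sv),
    Bladder = binary_mask(geom, bladder),
    Rectum = binary_mask(geom, rectum),
    Bowel = binary_mask(geom, bowel),
    Femur_L = binary_mask(geom, femur_l),
    Femur_R = binary_mask(geom, femur_r)
  )
  masks$CTV_7000 <- binary_mask(geom, prostate | sv)
  masks$PTV_7000 <- expand_margin(masks$Prostate, config$ptv_margin_mm)
  masks$Body <- binary_mask(geom, body)

  hu <- config$hu
  img <- array(hu[["background"]], geom$size)
  img[body] <- hu[["body"]]
  img[bowel] <- hu[["bowel"]]
  img[bladder] <- hu[["bladder"]]
  img[rectum] <- hu[["rectum"]]
  img[sv] <- hu[["seminal_vesicles"]]
  img[prostate] <- hu[["prostate"]]
  img[femur_l | femur_r] <- hu[["femur"]]
  if (config$noise_sd_hu > 0) {
    img <- img + withr::with_seed(config$seed,
                                  array(rnorm(prod(geom$size), 0, config$noise_sd_hu),
                                        geom$size))
  }
  list(image = image_volume(geom, img, unit = "HU"),
       structures = structure_set(geom, masks))
}
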