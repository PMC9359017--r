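#' Gaussian deformation specification
#'
#' One synthetic deformation: a per-axis displacement magnitude `m` (mm) at
#' the Gaussian center `c` (world mm), falling off isotropically with
#' standard deviation `sigma` (mm):
#' `d_a(r) = m_a * exp(-||r - c||^2 / (2 sigma^2))`.
#'
#' @param magnitude numeric length-3, signed per-axis displacement at the
#'   center (mm).  The study design uses one shared absolute magnitude with
#'   independent signs per axis.
#' @param center numeric length-3, world coordinates of the center (mm).
#' @param sigma Gaussian falloff (mm), > 0.
#' @return An object of class `qa_deformation_spec`.
#' @export
deformation_spec <- function(magnitude, center, sigma) {
  magnitude <- as.double(magnitude); center <- as.double(center)
  stopifnot(length(magnitude) == 3, length(center) == 3, length(sigma) == 1)
  if (!all(is.finite(c(magnitude, center, sigma)))) {
    stop("deformation parameters must be finite", call. = FALSE)
  }
  if (sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  structure(list(magnitude = magnitude, center = center, sigma = as.double(sigma)),
            class = "qa_deformation_spec")
}

#' @export
print.qa_deformation_spec <- function(x, ...) {
  cat("<qa_deformation_spec> m = (", paste(format(x$magnitude), collapse = ", "),
      ") mm at c = (", paste(format(x$center), collapse = ", "),
      ") mm, sigma = ", format(x$sigma), " mm\n", sep = "")
  invisible(x)
}

#' Sampling bounds for randomized deformations
#'
#' The deformation center is drawn uniformly inside a rectangular
#' parallelepiped inscribed in the PTV (default size 22.3 mm left-right,
#' 10.6 mm anterior-posterior, 62 mm superior-inferior), the shared
#' displacement magnitude uniformly in 10-20 mm with an independent random
#' sign per axis, and sigma uniformly in 15-25 mm.
#'
#' @param center numeric length-3, box center in world mm.
#' @param extents numeric length-3, full box edge lengths in mm.
#' @param magnitude_range length-2, magnitude range in mm.
#' @param sigma_range length-2, sigma range in mm.
#' @return An object of class `qa_sampling_bounds`.
#' @export
sampling_bounds <- function(center = c(0, 0, 0),
                            extents = c(22.3, 10.6, 62.0),
                            magnitude_range = c(10, 20),
                            sigma_range = c(15, 25)) {
  stopifnot(length(center) == 3, length(extents) == 3,
            length(magnitude_range) == 2, length(sigma_range) == 2)
  if (any(extents <= 0)) stop("box extents must be > 0", call. = FALSE)
  if (diff(magnitude_range) < 0 || diff(sigma_range) < 0) {
    stop("ranges must be non-decreasing", call. = FALSE)
  }
  structure(list(center = as.double(center), extents = as.double(extents),
                 magnitude_range = as.double(magnitude_range),
                 sigma_range = as.double(sigma_range)),
            class = "qa_sampling_bounds")
}

#' Sample a randomized Gaussian deformation
#'
#' @param bounds a [sampling_bounds()].
#' @param seed integer seed; the same seed yields the identical spec.
#' @return A `qa_deformation_spec`.
#' @export
sample_deformation_spec <- function(bounds, seed) {
  withr::with_seed(seed, {
    center <- bounds$center + (runif(3) - 0.5) * bounds$extents
    mag <- runif(1, bounds$magnitude_range[1], bounds$magnitude_range[2])
    signs <- sample(c(-1, 1), 3, replace = TRUE)
    sigma <- runif(1, bounds$sigma_range[1], bounds$sigma_range[2])
    deformation_spec(mag * signs, center, sigma)
  })
}

#' The five reference deformation parameter sets
#'
#' The deformation instances of the virtual study design: per-axis
#' magnitudes (mm), center world coordinates (mm) and Gaussian standard
#' deviation (mm) for instances 1-5.
#'
#' @return A tibble with columns `instance`, `mx`, `my`, `mz`, `cx`, `cy`,
#'   `cz`, `sigma`.
#' @export
reference_deformations <- function() {
  tibble::tribble(
    ~instance,   ~mx,    ~my,    ~mz,    ~cx,    ~cy,    ~cz, ~sigma,
    1L,         10.9,   10.9,   10.9,  -13.4,  119.6,  707.7,   18.7,
    2L,        -14.2,   14.2,  -14.2,  -21.1,  118.6,  700.6,   29.4,
    3L,         18.8,  -18.8,  -18.8,   -6.2,  119.8,  708.1,   15.6,
    4L,        -17.8,  -17.8,   17.8,   -3.2,  116.4,  707.3,   29.3,
    5L,         10.9,  -10.9,   10.9,  -17.3,  124.7,  699.8,   15.8
  )
}

#' @rdname reference_deformations
#' @param instance instance number 1-5.
#' @export
reference_deformation_spec <- function(instance) {
  row <- reference_deformations()[reference_deformations()$instance == instance, ]
  if (nrow(row) != 1) stop("unknown deformation instance: ", instance, call. = FALSE)
  deformation_spec(c(row$mx, row$my, row$mz), c(row$cx, row$cy, row$cz), row$sigma)
}

#' Render a Gaussian displacement field on a grid
#'
#' Evaluates `d_a(r) = m_a * exp(-||r - c||^2 / (2 sigma^2))` at every
#' voxel-center world coordinate `r`.  The displacement at the voxel nearest
#' the center equals the magnitude up to the sub-voxel offset factor.
#'
#' @param spec a `qa_deformation_spec`.
#' @param geom a `qa_geometry`.
#' @return An object of class `qa_dvf`: geometry plus a 4-D array
#'   `[x, y, z, component]` of mm displacements.
#' @export
render_displacement_field <- function(spec, geom) {
  if (spec$sigma <= 0) stop("sigma must be > 0", call. = FALSE)
  dx2 <- (voxel_coords(geom, 1) - spec$center[1])^2
  dy2 <- (voxel_coords(geom, 2) - spec$center[2])^2
  dz2 <- (voxel_coords(geom, 3) - spec$center[3])^2
  r2 <- outer(outer(dx2, dy2, "+"), dz2, "+")
  w <- exp(-r2 / (2 * spec$sigma^2))
  vectors <- array(0, c(geom$size, 3L))
  for (a in 1:3) vectors[, , , a] <- spec$magnitude[a] * w
  displacement_field(geom, vectors)
}

#' Displacement vector field
#'
#' @param geom a `qa_geometry`.
#' @param vectors 4-D numeric array `[x, y, z, component]` of mm
#'   displacements; all finite.
#' @return An object of class `qa_dvf`.
#' @export
displacement_field <- function(geom, vectors) {
  vectors <- as.array(vectors)
  if (!all(dim(vectors) == c(geom$size, 3L))) {
    stop("vector array must have dim (size, 3)", call. = FALSE)
  }
  if (!all(is.finite(vectors))) stop("displacements must be finite", call. = FALSE)
  structure(list(geometry = geom, vectors = vectors), class = "qa_dvf")
}

#' @export
print.qa_dvf <- function(x, ...) {
  mags <- sqrt(x$vectors[, , , 1]^2 + x$vectors[, , , 2]^2 + x$vectors[, , , 3]^2)
  cat("<qa_dvf> ", paste(x$geometry$size, collapse = " x "),
      " voxels, |d| up to ", format(max(mags), digits = 4), " mm\n", sep = "")
  invisible(x)
}

# Continuous 0-based grid indices of pull-back sample points (centers + d).
sample_indices <- function(geom, dvf) {
  co <- coord_arrays(geom)
  list(
    tx = (as.vector(co$x) + as.vector(dvf$vectors[, , , 1]) - geom$origin[1]) / geom$spacing[1],
    ty = (as.vector(co$y) + as.vector(dvf$vectors[, , , 2]) - geom$origin[2]) / geom$spacing[2],
    tz = (as.vector(co$z) + as.vector(dvf$vectors[, , , 3]) - geom$origin[3]) / geom$spacing[3]
  )
}

#' Warp an image by a displacement field
#'
#' Pull-back resampling: `output(x) = input(x + d(x))`.  Sample points
#' falling outside the grid take `fill` (default: the image minimum).
#'
#' @param image a `qa_volume`.
#' @param dvf a `qa_dvf` on the same geometry.
#' @param interpolation "linear" (trilinear) or "nearest".
#' @param fill out-of-grid fill value.
#' @return Warped `qa_volume`.
#' @export
warp_image <- function(image, dvf, interpolation = c("linear", "nearest"),
                       fill = NULL) {
  interpolation <- match.arg(interpolation)
  stop_if_geometry_differs(image, dvf, "image and displacement field")
  geom <- image$geometry
  if (is.null(fill)) fill <- min(image$values)
  si <- sample_indices(geom, dvf)
  n <- geom$size
  eps <- 1e-9
  oob <- si$tx < -eps | si$tx > n[1] - 1 + eps |
         si$ty < -eps | si$ty > n[2] - 1 + eps |
         si$tz < -eps | si$tz > n[3] - 1 + eps
  v <- as.vector(image$values)
  if (interpolation == "nearest") {
    ix <- pmin(pmax(as.integer(round(si$tx)), 0L), n[1] - 1L)
    iy <- pmin(pmax(as.integer(round(si$ty)), 0L), n[2] - 1L)
    iz <- pmin(pmax(as.integer(round(si$tz)), 0L), n[3] - 1L)
    out <- v[1L + ix + iy * n[1] + iz * n[1] * n[2]]
  } else {
    i0 <- pmin(pmax(floor(si$tx), 0), n[1] - 2); fx <- pmin(pmax(si$tx - i0, 0), 1)
    j0 <- pmin(pmax(floor(si$ty), 0), n[2] - 2); fy <- pmin(pmax(si$ty - j0, 0), 1)
    k0 <- pmin(pmax(floor(si$tz), 0), n[3] - 2); fz <- pmin(pmax(si$tz - k0, 0), 1)
    base <- 1 + i0 + j0 * n[1] + k0 * n[1] * n[2]
    sy <- n[1]; sz <- n[1] * n[2]
    c000 <- v[base];            c100 <- v[base + 1]
    c010 <- v[base + sy];       c110 <- v[base + 1 + sy]
    c001 <- v[base + sz];       c101 <- v[base + 1 + sz]
    c011 <- v[base + sy + sz];  c111 <- v[base + 1 + sy + sz]
    c00 <- c000 * (1 - fx) + c100 * fx
    c10 <- c010 * (1 - fx) + c110 * fx
    c01 <- c001 * (1 - fx) + c101 * fx
    c11 <- c011 * (1 - fx) + c111 * fx
    out <- (c00 * (1 - fy) + c10 * fy) * (1 - fz) +
           (c01 * (1 - fy) + c11 * fy) * fz
  }
  out[oob] <- fill
  image_volume(geom, array(out, n), unit = image$unit)
}

#' Warp a binary mask by a displacement field
#'
#' Nearest-neighbor pull-back of the binary volume; out-of-grid samples are
#' background.
#'
#' @param mask a `qa_mask`.
#' @param dvf a `qa_dvf` on the same geometry.
#' @return Warped `qa_mask`.
#' @export
warp_mask <- function(mask, dvf) {
  stop_if_geometry_differs(mask, dvf, "mask and displacement field")
  vol <- image_volume(mask$geometry, array(as.double(mask$inside), mask$geometry$size))
  w <- warp_image(vol, dvf, interpolation = "nearest", fill = 0)
  binary_mask(mask$geometry, w$values > 0.5)
}

#' Write / read a displacement field (3-channel MetaImage)
#'
#' @param dvf a `qa_dvf`.
#' @param path `.mha` file path.
#' @return The path (write) or a `qa_dvf` (read).
#' @export
write_displacement_field <- function(dvf, path) {
  if (!is_mha_path(path)) stop("displacement fields are stored as .mha", call. = FALSE)
  interleaved <- aperm(dvf$vectors, c(4, 1, 2, 3))   # channel fastest
  write_mha(path, dvf$geometry, interleaved, storage = "double", channels = 3L)
}

#' @rdname write_displacement_field
#' @export
load_displacement_field <- function(path) {
  rec <- read_mha(path)
  if (rec$channels != 3L) stop("expected a 3-channel field: ", path, call. = FALSE)
  v <- aperm(array(rec$values, c(3L, rec$geometry$size)), c(2, 3, 4, 1))
  displacement_field(rec$geometry, v)
}

#' Read / write a deformation spec as YAML
#'
#' Keys: `magnitude` (mm 3-vector), `center` (mm 3-vector), `sigma` (mm).
#'
#' @param spec a `qa_deformation_spec`.
#' @param path YAML (or JSON) file path.
#' @return The path (write) or a `qa_deformation_spec` (read).
#' @export
write_deformation_spec <- function(spec, path) {
  yaml::write_yaml(list(magnitude = spec$magnitude, center = spec$center,
                        sigma = spec$sigma), path)
  invisible(path)
}

#' @rdname write_deformation_spec
#' @export
read_deformation_spec <- function(path) {
  x <- yaml::read_yaml(path)
  deformation_spec(unlist(x$magnitude), unlist(x$center), x$sigma)
}
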