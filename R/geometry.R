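#' Axis-aligned 3-D image grid
#'
#' A geometry describes the sampling grid shared by CT volumes, dose grids,
#' binary masks and displacement fields: a world-space origin (mm), per-axis
#' voxel spacing (mm) and grid size (voxels).  Axes are fixed as
#' X = left-right, Y = anterior-posterior, Z = superior-inferior.  Voxel
#' indices are 0-based and voxel-centered: the world coordinate of voxel
#' `i` is `origin + i * spacing`.
#'
#' @param origin numeric length-3, world coordinate (mm) of voxel (0,0,0).
#' @param spacing numeric length-3, voxel spacing in mm; all > 0.
#' @param size integer length-3, grid size in voxels; all >= 1.
#' @return An object of class `qa_geometry`.
#' @examples
#' g <- geometry(c(0, 0, 0), c(1, 1, 3), c(10, 10, 5))
#' voxel_coords(g, axis = 3)
#' @export
geometry <- function(origin = c(0, 0, 0), spacing = c(1, 1, 1), size) {
  origin <- as.double(origin)
  spacing <- as.double(spacing)
  size <- as.integer(round(size))
  stopifnot(length(origin) == 3, length(spacing) == 3, length(size) == 3)
  if (any(!is.finite(origin))) stop("geometry origin must be finite", call. = FALSE)
  if (any(!is.finite(spacing)) || any(spacing <= 0)) {
    stop("geometry spacing must be positive and finite", call. = FALSE)
  }
  if (any(size < 1L)) stop("geometry size must be >= 1 voxel per axis", call. = FALSE)
  structure(list(origin = origin, spacing = spacing, size = size),
            class = "qa_geometry")
}

#' @export
print.qa_geometry <- function(x, ...) {
  cat("<qa_geometry> ", paste(x$size, collapse = " x "), " voxels, spacing (",
      paste(format(x$spacing), collapse = ", "), ") mm, origin (",
      paste(format(x$origin), collapse = ", "), ") mm\n", sep = "")
  invisible(x)
}

#' Compare two geometries
#'
#' Geometries are equal iff origin, spacing and size agree within `tol` mm.
#'
#' @param a,b `qa_geometry` objects.
#' @param tol absolute tolerance in mm (default 1e-6).
#' @return Logical scalar.
#' @export
geometry_equal <- function(a, b, tol = 1e-6) {
  all(abs(a$origin - b$origin) <= tol) &&
    all(abs(a$spacing - b$spacing) <= tol) &&
    all(a$size == b$size)
}

stop_if_geometry_differs <- function(a, b, what = "inputs") {
  if (!geometry_equal(geometry_of(a), geometry_of(b))) {
    stop(what, " must share one geometry", call. = FALSE)
  }
  invisible(TRUE)
}

#' Voxel-center world coordinates along one axis
#'
#' @param geom a `qa_geometry`.
#' @param axis axis index 1 (X), 2 (Y) or 3 (Z).
#' @return Numeric vector of world coordinates (mm), length `size[axis]`.
#' @export
voxel_coords <- function(geom, axis) {
  geom$origin[axis] + (seq_len(geom$size[axis]) - 1) * geom$spacing[axis]
}

# World coordinate arrays of every voxel center, as three arrays of dim size.
coord_arrays <- function(geom) {
  nx <- geom$size[1]; ny <- geom$size[2]; nz <- geom$size[3]
  list(
    x = array(voxel_coords(geom, 1), dim = geom$size),
    y = array(rep(voxel_coords(geom, 2), each = nx), dim = geom$size),
    z = array(rep(voxel_coords(geom, 3), each = nx * ny), dim = geom$size)
  )
}

#' Scalar image volume
#'
#' A scalar field (HU for CT, Gy for dose) sampled on a [geometry()] grid.
#'
#' @param geom a `qa_geometry`.
#' @param values numeric array with `dim` equal to `geom$size`.
#' @param unit free-text value unit, e.g. "HU" or "Gy".
#' @return An object of class `qa_volume`.
#' @export
image_volume <- function(geom, values, unit = "") {
  values <- as.array(values)
  if (!identical(dim(values), NULL) && !all(dim(values) == geom$size)) {
    stop("value array shape must match geometry size", call. = FALSE)
  }
  dim(values) <- geom$size
  structure(list(geometry = geom, values = values, unit = unit),
            class = "qa_volume")
}

#' Binary organ mask
#'
#' @param geom a `qa_geometry`.
#' @param inside logical array with `dim` equal to `geom$size`.
#' @return An object of class `qa_mask`.
#' @export
binary_mask <- function(geom, inside) {
  inside <- as.logical(inside)
  dim(inside) <- geom$size
  if (anyNA(inside)) stop("mask may not contain NA", call. = FALSE)
  structure(list(geometry = geom, inside = inside), class = "qa_mask")
}

geometry_of <- function(x) {
  if (inherits(x, "qa_geometry")) x else x$geometry
}

#' @export
print.qa_volume <- function(x, ...) {
  cat("<qa_volume> ", paste(x$geometry$size, collapse = " x "),
      " voxels, range [", format(min(x$values)), ", ", format(max(x$values)),
      "] ", x$unit, "\n", sep = "")
  invisible(x)
}

#' @export
print.qa_mask <- function(x, ...) {
  cat("<qa_mask> ", sum(x$inside), " of ", length(x$inside), " voxels inside (",
      format(mask_volume_cc(x), digits = 4), " cm^3)\n", sep = "")
  invisible(x)
}

#' Named set of masks on one grid
#'
#' A structure set holds named binary masks sharing a single geometry -- the
#' study's regions of interest (prostate, seminal vesicles, bladder, rectum,
#' bowel, femoral heads, CTV/PTV, body).
#'
#' @param geom a `qa_geometry`.
#' @param masks named list of `qa_mask` objects on `geom`.
#' @return An object of class `qa_structure_set`.
#' @export
structure_set <- function(geom, masks = list()) {
  if (length(masks) && (is.null(names(masks)) || any(names(masks) == ""))) {
    stop("all masks must be named", call. = FALSE)
  }
  for (nm in names(masks)) {
    if (!geometry_equal(masks[[nm]]$geometry, geom)) {
      stop("mask '", nm, "' does not share the set geometry", call. = FALSE)
    }
  }
  structure(list(geometry = geom, masks = masks), class = "qa_structure_set")
}

#' @export
print.qa_structure_set <- function(x, ...) {
  cat("<qa_structure_set> ", length(x$masks), " masks on ",
      paste(x$geometry$size, collapse = " x "), " grid: ",
      paste(names(x$masks), collapse = ", "), "\n", sep = "")
  invisible(x)
}

#' Canonical region-of-interest names
#'
#' The ROI vocabulary of the pelvis QA study.  `compared = TRUE` returns the
#' eight structures whose contour reproducibility is analyzed (seminal
#' vesicles enter through CTV_7000; Body is bookkeeping only).
#'
#' @param compared logical; restrict to the eight analyzed ROIs.
#' @return Character vector of ROI names.
#' @export
canonical_rois <- function(compared = FALSE) {
  if (compared) {
    c("Bladder", "Bowel", "CTV_7000", "Femur_L", "Femur_R",
      "Prostate", "PTV_7000", "Rectum")
  } else {
    c("Prostate", "SeminalVesicles", "Bladder", "Rectum", "Bowel",
      "Femur_L", "Femur_R", "CTV_7000", "PTV_7000", "Body")
  }
}

#' Physical mask volume
#'
#' @param mask a `qa_mask`.
#' @return Volume in cm^3 (voxel count times voxel volume).
#' @examples
#' g <- geometry(size = c(10, 10, 10))
#' m <- binary_mask(g, array(TRUE, g$size))
#' mask_volume_cc(m)  # 1000 voxels at 1 mm^3 = 1 cm^3
#' @export
mask_volume_cc <- function(mask) {
  sum(mask$inside) * prod(mask$geometry$spacing) / 1000
}

#' Isotropic margin expansion of a mask
#'
#' Expands a mask by a Euclidean margin: an output voxel is inside iff its
#' world-space distance to the nearest inside voxel of the input is at most
#' `margin` mm.  Computed with an exact anisotropic distance transform, so
#' the expansion is spacing-aware.  This is the CTV-to-PTV margin rule
#' (PTV = prostate + 5 mm).
#'
#' @param mask a non-empty `qa_mask`.
#' @param margin margin in mm, >= 0.
#' @return Expanded `qa_mask` on the same geometry.
#' @export
expand_margin <- function(mask, margin) {
  if (!is.finite(margin) || margin < 0) {
    stop("margin must be finite and >= 0", call. = FALSE)
  }
  if (!any(mask$inside)) stop("cannot expand an empty mask", call. = FALSE)
  if (margin == 0) return(mask)
  d2 <- edt_squared_cpp(mask$inside, mask$geometry$size, mask$geometry$spacing)
  binary_mask(mask$geometry, sqrt(d2) <= margin + 1e-9)
}

#' Distance map to a mask
#'
#' Exact Euclidean distance (mm) from each voxel center to the nearest
#' inside voxel of `mask`; zero inside the mask.
#'
#' @param mask a non-empty `qa_mask`.
#' @return A `qa_volume` of distances in mm.
#' @export
distance_map <- function(mask) {
  if (!any(mask$inside)) stop("distance map of an empty mask is undefined", call. = FALSE)
  d2 <- edt_squared_cpp(mask$inside, mask$geometry$size, mask$geometry$spacing)
  image_volume(mask$geometry, sqrt(array(d2, mask$geometry$size)), unit = "mm")
}

# --- crop / embed helpers (internal) ---------------------------------------

# Bounding box of TRUE voxels, 1-based inclusive [lo, hi] per axis.
mask_bbox <- function(inside) {
  idx <- which(inside, arr.ind = TRUE)
  if (nrow(idx) == 0) stop("empty mask has no bounding box", call. = FALSE)
  list(lo = apply(idx, 2, min), hi = apply(idx, 2, max))
}

# Pad a bbox by pad_mm (converted per axis) and clip to the grid.
pad_bbox <- function(bbox, geom, pad_mm) {
  pad_vox <- ceiling(pad_mm / geom$spacing)
  list(lo = pmax(bbox$lo - pad_vox, 1L),
       hi = pmin(bbox$hi + pad_vox, geom$size))
}

crop_geometry <- function(geom, lo, hi) {
  geometry(origin = geom$origin + (lo - 1) * geom$spacing,
           spacing = geom$spacing, size = hi - lo + 1)
}

crop_array <- function(a, lo, hi) {
  a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3], drop = FALSE]
}

crop_mask <- function(mask, lo, hi) {
  binary_mask(crop_geometry(mask$geometry, lo, hi), crop_array(mask$inside, lo, hi))
}

crop_volume <- function(vol, lo, hi) {
  image_volume(crop_geometry(vol$geometry, lo, hi), crop_array(vol$values, lo, hi),
               unit = vol$unit)
}

# Crop a full-grid volume to the grid of a cropped object (world-aligned).
crop_volume_like <- function(vol, target_geom) {
  off <- round((target_geom$origin - vol$geometry$origin) / vol$geometry$spacing)
  lo <- as.integer(off) + 1L
  hi <- lo + target_geom$size - 1L
  if (any(lo < 1L) || any(hi > vol$geometry$size)) {
    stop("target geometry extends outside the volume", call. = FALSE)
  }
  crop_volume(vol, lo, hi)
}

# Embed a cropped mask back into a full-grid geometry (world-aligned).
embed_mask <- function(mask, full_geom) {
  off <- round((mask$geometry$origin - full_geom$origin) / full_geom$spacing)
  lo <- as.integer(off) + 1L
  hi <- lo + mask$geometry$size - 1L
  if (any(lo < 1L) || any(hi > full_geom$size)) {
    stop("cropped mask extends outside the target geometry", call. = FALSE)
  }
  inside <- array(FALSE, full_geom$size)
  inside[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- mask$inside
  binary_mask(full_geom, inside)
}
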