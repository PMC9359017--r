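#' @title Volume file I/O
#' @description Read and write scalar volumes, masks and labelmaps in
#'   MetaImage (`.mha`, uncompressed local-endian raw) and NIfTI-1
#'   (`.nii`/`.nii.gz`) formats.  Grids are axis-aligned without a direction
#'   matrix; the affine carries spacing and origin only.
#' @name volume_io
NULL

mha_type <- function(storage) {
  switch(storage,
         double = list(met = "MET_DOUBLE", size = 8L, what = "double"),
         float  = list(met = "MET_FLOAT",  size = 4L, what = "double"),
         uchar  = list(met = "MET_UCHAR",  size = 1L, what = "integer"),
         stop("unsupported storage type", call. = FALSE))
}

write_mha <- function(path, geom, data, storage = "double", channels = 1L) {
  tp <- mha_type(storage)
  hdr <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    "TransformMatrix = 1 0 0 0 1 0 0 0 1",
    paste("Offset =", paste(format(geom$origin, digits = 17), collapse = " ")),
    "CenterOfRotation = 0 0 0",
    paste("ElementSpacing =", paste(format(geom$spacing, digits = 17), collapse = " ")),
    paste("DimSize =", paste(geom$size, collapse = " ")),
    if (channels > 1L) paste("ElementNumberOfChannels =", channels),
    paste("ElementType =", tp$met),
    "ElementDataFile = LOCAL"
  )
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(hdr, con)
  vals <- as.vector(data)
  if (storage == "uchar") {
    writeBin(as.raw(as.integer(vals)), con)
  } else if (storage == "float") {
    writeBin(as.double(vals), con, size = 4L, endian = "little")
  } else {
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  }
  invisible(path)
}

read_mha <- function(path) {
  raw <- readBin(path, "raw", n = file.size(path))
  key_at <- grepRaw("ElementDataFile", raw)
  if (length(key_at) == 0) stop("unreadable MetaImage header: ", path, call. = FALSE)
  hdr_end <- grepRaw("\n", raw, offset = key_at[1], fixed = TRUE)[1]
  if (is.na(hdr_end)) stop("unreadable MetaImage header: ", path, call. = FALSE)
  hdr <- strsplit(rawToChar(raw[seq_len(hdr_end - 1L)]), "\n", fixed = TRUE)[[1]]
  kv <- list()
  for (line in hdr) {
    p <- regmatches(line, regexec("^\\s*([A-Za-z]+)\\s*=\\s*(.*)$", line))[[1]]
    if (length(p) == 3) kv[[p[2]]] <- trimws(p[3])
  }
  need <- c("DimSize", "ElementSpacing", "ElementType")
  if (!all(need %in% names(kv))) {
    stop("unreadable MetaImage header (missing ",
         paste(setdiff(need, names(kv)), collapse = ", "), "): ", path, call. = FALSE)
  }
  num <- function(key, default = NULL) {
    if (is.null(kv[[key]])) return(default)
    as.double(strsplit(kv[[key]], "\\s+")[[1]])
  }
  size <- as.integer(num("DimSize"))
  spacing <- num("ElementSpacing")
  origin <- num("Offset", c(0, 0, 0))
  channels <- as.integer(num("ElementNumberOfChannels", 1))
  if (any(size == 0L) || any(spacing <= 0)) {
    stop("invalid MetaImage geometry (zero size or non-positive spacing): ",
         path, call. = FALSE)
  }
  geom <- geometry(origin, spacing, size)
  n <- prod(size) * channels
  data_raw <- raw[(hdr_end + 1L):length(raw)]
  met <- kv[["ElementType"]]
  vals <- switch(met,
    MET_DOUBLE = readBin(data_raw, "double", n = n, size = 8L, endian = "little"),
    MET_FLOAT  = readBin(data_raw, "double", n = n, size = 4L, endian = "little"),
    MET_UCHAR  = as.integer(readBin(data_raw, "raw", n = n)),
    MET_SHORT  = readBin(data_raw, "integer", n = n, size = 2L, endian = "little"),
    MET_INT    = readBin(data_raw, "integer", n = n, size = 4L, endian = "little"),
    stop("unsupported MetaImage element type: ", met, call. = FALSE))
  if (length(vals) < n) stop("truncated MetaImage data: ", path, call. = FALSE)
  list(geometry = geom, values = vals[seq_len(n)], channels = channels)
}

is_nifti_path <- function(path) grepl("\\.nii(\\.gz)?$", path, ignore.case = TRUE)
is_mha_path <- function(path) grepl("\\.mh[ad]$", path, ignore.case = TRUE)

write_nifti_vol <- function(path, geom, data) {
  arr <- array(as.double(data), dim = geom$size)
  img <- RNifti::asNifti(arr)
  RNifti::pixdim(img) <- geom$spacing
  mat <- diag(4)
  diag(mat)[1:3] <- geom$spacing
  mat[1:3, 4] <- geom$origin
  img <- RNifti::`sform<-`(img, structure(mat, code = 2L))
  img <- RNifti::`qform<-`(img, structure(mat, code = 2L))
  RNifti::writeNifti(img, path)
  invisible(path)
}

read_nifti_vol <- function(path) {
  img <- RNifti::readNifti(path)
  d <- dim(img)
  if (length(d) != 3) stop("expected a 3-D NIfTI volume: ", path, call. = FALSE)
  mat <- RNifti::xform(img)
  spacing <- sqrt(colSums(mat[1:3, 1:3]^2))
  origin <- mat[1:3, 4]
  if (any(d == 0L) || any(spacing <= 0)) {
    stop("invalid NIfTI geometry: ", path, call. = FALSE)
  }
  list(geometry = geometry(origin, spacing, d), values = as.double(img),
       channels = 1L)
}

#' Write a volume, mask or labelmap to disk
#'
#' Scalar volumes are written as double precision, masks and labelmaps as
#' 8-bit unsigned integers.  Format follows the file extension (`.mha`,
#' `.nii`, `.nii.gz`).
#'
#' @param x a `qa_volume`, `qa_mask`, or integer labelmap `qa_volume`.
#' @param path output file path.
#' @param storage storage type for `.mha` scalar output: "double" or "float".
#' @return The path, invisibly.
#' @export
write_volume <- function(x, path, storage = "double") {
  if (inherits(x, "qa_mask")) {
    data <- as.integer(x$inside)
    geom <- x$geometry
    storage <- "uchar"
  } else if (inherits(x, "qa_volume")) {
    data <- x$values
    geom <- x$geometry
    if (x$unit == "label") storage <- "uchar"
  } else {
    stop("write_volume expects a qa_volume or qa_mask", call. = FALSE)
  }
  if (is_mha_path(path)) {
    write_mha(path, geom, data, storage = storage)
  } else if (is_nifti_path(path)) {
    write_nifti_vol(path, geom, data)
  } else {
    stop("unsupported file extension (use .mha or .nii/.nii.gz): ", path,
         call. = FALSE)
  }
}

#' Load a volume, mask or labelmap
#'
#' @param path path to a MetaImage or NIfTI file.
#' @param kind "scalar" (returns `qa_volume`), "mask" (nonzero voxels, returns
#'   `qa_mask`), or "labelmap" (returns `qa_structure_set`; needs a
#'   label-to-name table).
#' @param label_names for `kind = "labelmap"`: either a named vector/list
#'   mapping label integers to ROI names, or the path of a YAML sidecar
#'   (`{label: name}`).  Defaults to `<path>.yaml` next to the image.
#' @param unit unit string attached to scalar volumes.
#' @return `qa_volume`, `qa_mask`, or `qa_structure_set`.
#' @export
load_volume <- function(path, kind = c("scalar", "mask", "labelmap"),
                        label_names = NULL, unit = "") {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  rec <- if (is_mha_path(path)) read_mha(path)
         else if (is_nifti_path(path)) read_nifti_vol(path)
         else stop("unsupported file extension: ", path, call. = FALSE)
  if (rec$channels != 1L) {
    stop("multi-channel volume; use load_displacement_field()", call. = FALSE)
  }
  geom <- rec$geometry
  if (kind == "scalar") {
    return(image_volume(geom, array(rec$values, geom$size), unit = unit))
  }
  if (kind == "mask") {
    return(binary_mask(geom, array(rec$values != 0, geom$size)))
  }
  labels <- array(as.integer(round(rec$values)), geom$size)
  if (is.null(label_names)) {
    sidecar <- paste0(sub("\\.(mha|mhd|nii|nii\\.gz)$", "", path), ".yaml")
    if (!file.exists(sidecar)) {
      stop("labelmap needs a label-name table (yaml sidecar not found: ",
           sidecar, ")", call. = FALSE)
    }
    label_names <- yaml::read_yaml(sidecar)
  } else if (is.character(label_names) && length(label_names) == 1 &&
             file.exists(label_names)) {
    label_names <- yaml::read_yaml(label_names)
  }
  lv <- sort(unique(labels[labels != 0L]))
  masks <- list()
  for (l in lv) {
    nm <- label_names[[as.character(l)]]
    if (is.null(nm)) stop("label ", l, " has no name entry", call. = FALSE)
    masks[[nm]] <- binary_mask(geom, labels == l)
  }
  structure_set(geom, masks)
}

#' Write a structure set as one labelmap plus a name table
#'
#' Masks are rasterized into a single uint8 labelmap; where masks overlap,
#' the first-listed mask wins (priority by order).  Derived structures that
#' necessarily overlap their parents (CTV_7000, PTV_7000, Body) are best
#' excluded and recomputed after loading.
#'
#' @param ss a `qa_structure_set`.
#' @param path labelmap output path (`.mha` or `.nii`); the YAML name table
#'   goes to `<path>.yaml`.
#' @param include names of masks to write, in priority order; defaults to all.
#' @return The labelmap path, invisibly.
#' @export
write_structure_set <- function(ss, path, include = names(ss$masks)) {
  labels <- array(0L, ss$geometry$size)
  for (k in rev(seq_along(include))) {     # reverse so first-listed wins
    labels[ss$masks[[include[k]]]$inside] <- k
  }
  write_volume(image_volume(ss$geometry, labels, unit = "label"), path)
  tab <- as.list(setNames(include, seq_along(include)))
  yaml::write_yaml(tab, paste0(sub("\\.(mha|mhd|nii|nii\\.gz)$", "", path), ".yaml"))
  invisible(path)
}
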