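#' Read a 3-D volume from NIfTI or NRRD
#'
#' Format is chosen by extension: `.nii` / `.nii.gz` are read with RNifti,
#' `.nrrd` with the package's raw-encoding NRRD reader. Voxel spacing and
#' origin are always taken from the file header; a header with missing or
#' non-positive spacing is rejected.
#'
#' @param path path to an existing `.nii`, `.nii.gz` or `.nrrd` file.
#' @return A [voxel_image()].
#' @seealso [write_volume()], [read_mask()]
#' @export
read_volume <- function(path) {
  if (!file.exists(path)) stop("read_volume: file does not exist: ", path)
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    nim <- RNifti::readNifti(path)
    vals <- array(as.numeric(nim), dim = dim(nim))
    if (length(dim(vals)) != 3L)
      stop("read_volume: expected a 3-D volume, got ",
           length(dim(vals)), " dimensions")
    pd <- attr(nim, "pixdim")
    if (is.null(pd)) pd <- RNifti::pixdim(nim)
    spacing <- as.numeric(pd[1:3])
    if (any(!is.finite(spacing)) || any(spacing <= 0))
      stop("read_volume: header field 'spacing' (pixdim) is missing or non-positive")
    xf <- RNifti::xform(nim)
    origin <- as.numeric(xf[1:3, 4])
    voxel_image(vals, spacing = spacing, origin = origin)
  } else {
    read_nrrd(path)
  }
}

#' Write a 3-D volume to NIfTI or NRRD
#'
#' @param image a [voxel_image()] (or [roi_mask()], stored as unsigned 8-bit).
#' @param path output path ending in `.nii`, `.nii.gz` or `.nrrd`.
#' @return `path`, invisibly. Round-trips preserve values, spacing and origin.
#' @export
write_volume <- function(image, path) {
  stopifnot(inherits(image, "voxel_image") || inherits(image, "roi_mask"))
  is_mask <- inherits(image, "roi_mask")
  fmt <- volume_format(path)
  if (fmt == "nifti") {
    nim <- RNifti::asNifti(image$values)
    RNifti::pixdim(nim) <- image$spacing
    mat <- diag(4)
    mat[1, 1] <- image$spacing[1]
    mat[2, 2] <- image$spacing[2]
    mat[3, 3] <- image$spacing[3]
    mat[1:3, 4] <- image$origin
    RNifti::sform(nim) <- structure(mat, code = 2L)
    RNifti::qform(nim) <- structure(mat, code = 2L)
    RNifti::writeNifti(nim, path,
                       datatype = if (is_mask) "uint8" else "double")
  } else {
    write_nrrd(image, path, type = if (is_mask) "uchar" else "double")
  }
  invisible(path)
}

#' Read a binary segmentation mask
#'
#' Same formats as [read_volume()]; values must be 0/1.
#' @param path file path.
#' @return An [roi_mask()].
#' @export
read_mask <- function(path) {
  img <- read_volume(path)
  roi_mask(img$values, spacing = img$spacing, origin = img$origin)
}

#' @rdname read_mask
#' @param mask an [roi_mask()] to write (stored as unsigned 8-bit).
#' @export
write_mask <- function(mask, path) {
  stopifnot(inherits(mask, "roi_mask"))
  write_volume(mask, path)
}

volume_format <- function(path) {
  lower <- tolower(path)
  if (grepl("\\.nii(\\.gz)?$", lower)) return("nifti")
  if (grepl("\\.nrrd$", lower)) return("nrrd")
  stop("unsupported volume format (use .nii, .nii.gz or .nrrd): ", path)
}

# ---- minimal NRRD0004 raw-encoding support ---------------------------------
# Header: text key/value lines terminated by a blank line, then raw
# little-endian voxel data, fastest axis first (matches R column-major order).

nrrd_types <- list(
  uchar  = list(what = "integer", size = 1L, signed = FALSE),
  short  = list(what = "integer", size = 2L, signed = TRUE),
  ushort = list(what = "integer", size = 2L, signed = FALSE),
  int    = list(what = "integer", size = 4L, signed = TRUE),
  float  = list(what = "numeric", size = 4L, signed = TRUE),
  double = list(what = "numeric", size = 8L, signed = TRUE)
)

write_nrrd <- function(image, path, type = "double") {
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("write_nrrd: unsupported type: ", type)
  dims <- dim(image$values)
  sp <- image$spacing
  hdr <- c(
    "NRRD0004",
    "# generated by cbctradiomics",
    paste0("type: ", type),
    "dimension: 3",
    paste0("sizes: ", paste(dims, collapse = " ")),
    "space dimension: 3",
    sprintf("space directions: (%.17g,0,0) (0,%.17g,0) (0,0,%.17g)",
            sp[1], sp[2], sp[3]),
    sprintf("space origin: (%.17g,%.17g,%.17g)",
            image$origin[1], image$origin[2], image$origin[3]),
    "encoding: raw",
    "endian: little")
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(hdr, ""), con, sep = "\n")  # blank line ends the header
  vals <- as.vector(image$values)
  if (spec$what == "integer") {
    writeBin(as.integer(vals), con, size = spec$size, endian = "little")
  } else {
    writeBin(as.numeric(vals), con, size = spec$size, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  raw_all <- readBin(path, what = "raw", n = file.size(path))
  # header ends at the first blank line (\n\n); data follows as raw bytes
  nl <- which(raw_all == as.raw(10L))
  blank_at <- nl[c(diff(nl) == 1L, FALSE)]
  if (!length(blank_at))
    stop("read_nrrd: header not terminated by a blank line")
  hdr_end <- blank_at[1]
  lines <- strsplit(rawToChar(raw_all[seq_len(hdr_end)]), "\n",
                    fixed = TRUE)[[1]]
  if (!grepl("^NRRD000[1-9]$", lines[1]))
    stop("read_nrrd: not an NRRD file: ", path)
  fields <- list()
  for (line in lines[-1]) {
    if (line == "" || startsWith(line, "#")) next
    m <- regmatches(line, regexec("^([^:]+): *(.*)$", line))[[1]]
    if (length(m) == 3L) fields[[trimws(m[2])]] <- trimws(m[3])
  }
  data_raw <- raw_all[(hdr_end + 2L):length(raw_all)]
  need <- function(key) {
    if (is.null(fields[[key]]))
      stop("read_nrrd: header field '", key, "' is missing")
    fields[[key]]
  }
  type <- need("type")
  spec <- nrrd_types[[type]]
  if (is.null(spec)) stop("read_nrrd: unsupported type: ", type)
  if (need("encoding") != "raw")
    stop("read_nrrd: only raw encoding is supported")
  dims <- as.integer(strsplit(need("sizes"), "[[:space:]]+")[[1]])
  if (length(dims) != 3L) stop("read_nrrd: expected a 3-D volume")
  spacing <- nrrd_parse_directions(need("space directions"))
  if (any(!is.finite(spacing)) || any(spacing <= 0))
    stop("read_nrrd: header field 'space directions' (spacing) is non-positive")
  origin <- nrrd_parse_vector(fields[["space origin"]] %||% "(0,0,0)")
  endian <- fields[["endian"]] %||% "little"
  n <- prod(dims)
  vals <- readBin(data_raw, what = spec$what, n = n, size = spec$size,
                  signed = spec$signed, endian = endian)
  if (length(vals) != n)
    stop("read_nrrd: truncated data block (expected ", n, " voxels, got ",
         length(vals), ")")
  voxel_image(array(as.numeric(vals), dims), spacing = spacing,
              origin = origin)
}

nrrd_parse_vector <- function(text) {
  as.numeric(strsplit(gsub("[()]", "", text), ",")[[1]])
}

nrrd_parse_directions <- function(text) {
  vecs <- regmatches(text, gregexpr("\\(([^)]*)\\)", text))[[1]]
  if (length(vecs) != 3L)
    stop("read_nrrd: header field 'space directions' must have 3 vectors")
  mat <- vapply(vecs, nrrd_parse_vector, numeric(3))
  offdiag <- mat - diag(diag(mat))
  if (any(abs(offdiag) > 1e-9))
    stop("read_nrrd: only axis-aligned space directions are supported")
  diag(mat)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
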