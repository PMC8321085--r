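#' Read a 3D volume from disk
#'
#' Supports three generic formats so the rest of the pipeline never touches
#' file formats directly: MetaImage (`.mha` single file or `.mhd` + `.raw`
#' pair, uncompressed), NIfTI-1 (`.nii`/`.nii.gz`, via RNifti), and a raw
#' little-endian block with a JSON sidecar describing `shape`, `dtype`,
#' `spacing` and optionally `origin`. Axis order is always `(x, y, z)` with
#' `z` the between-slice axis; spacing is taken verbatim from the header.
#'
#' NIfTI stores spacing and origin as 32-bit floats in its header, so values
#' round-trip at float precision; MetaImage and raw+sidecar round-trip
#' doubles exactly.
#'
#' @param path Path to the volume file (for raw, the `.raw` file; the sidecar
#'   is `<path>.json`).
#' @param format One of `"metaimage"`, `"nifti"`, `"raw"`. Default guesses
#'   from the file extension.
#' @return A [tomo_volume].
#' @seealso [write_volume()]
#' @export
read_volume <- function(path, format = NULL) {
  if (!file.exists(path)) {
    stop(sprintf("dbtvr_format_error: file not found: %s", path), call. = FALSE)
  }
  format <- format %||% guess_format(path)
  switch(format,
         metaimage = read_metaimage(path),
         nifti = read_nifti_volume(path),
         raw = read_raw_volume(path),
         stop(sprintf("dbtvr_usage_error: unknown format '%s'", format), call. = FALSE))
}

#' Write a 3D volume to disk
#'
#' @param vol A [tomo_volume].
#' @param path Output path; extension selects the container unless `format`
#'   is given (`.mha`/`.mhd` MetaImage, `.nii`/`.nii.gz` NIfTI, `.raw` raw +
#'   JSON sidecar).
#' @param format One of `"metaimage"`, `"nifti"`, `"raw"` (default from
#'   extension).
#' @return `path`, invisibly.
#' @export
write_volume <- function(vol, path, format = NULL) {
  stopifnot_volume(vol)
  format <- format %||% guess_format(path)
  switch(format,
         metaimage = write_metaimage(vol, path),
         nifti = write_nifti_volume(vol, path),
         raw = write_raw_volume(vol, path),
         stop(sprintf("dbtvr_usage_error: unknown format '%s'", format), call. = FALSE))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_format <- function(path) {
  lp <- tolower(path)
  if (grepl("\\.(mha|mhd)$", lp)) return("metaimage")
  if (grepl("\\.(nii|nii\\.gz)$", lp)) return("nifti")
  if (grepl("\\.raw$", lp)) return("raw")
  stop(sprintf("dbtvr_usage_error: cannot guess volume format from '%s'", path),
       call. = FALSE)
}

## ---- MetaImage -------------------------------------------------------------
## Minimal MetaImage support: text header, uncompressed binary block, the
## fields this pipeline needs. Data in file is x-fastest, matching R's array
## layout for dimension (nx, ny, nz).

met_types <- list(
  MET_DOUBLE = list(what = "double", size = 8L),
  MET_FLOAT  = list(what = "double", size = 4L),   # read as double via size=4
  MET_SHORT  = list(what = "integer", size = 2L),
  MET_USHORT = list(what = "integer", size = 2L),
  MET_UCHAR  = list(what = "integer", size = 1L)
)

read_metaimage <- function(path) {
  is_mha <- grepl("\\.mha$", tolower(path))
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  header <- list()
  repeat {
    line <- readLines(con, n = 1L, warn = FALSE)
    if (length(line) == 0L) break
    kv <- strsplit(line, "=", fixed = TRUE)[[1]]
    if (length(kv) != 2L) next
    key <- trimws(kv[1]); val <- trimws(kv[2])
    header[[key]] <- val
    if (key == "ElementDataFile") break
  }
  req <- c("NDims", "DimSize", "ElementType", "ElementSpacing", "ElementDataFile")
  missing <- setdiff(req, names(header))
  if (length(missing) > 0L) {
    stop(sprintf("dbtvr_format_error: MetaImage header missing %s",
                 paste(missing, collapse = ", ")), call. = FALSE)
  }
  if (as.integer(header$NDims) != 3L) {
    stop("dbtvr_dimensionality_error: only 3D MetaImage volumes are supported",
         call. = FALSE)
  }
  if (isTRUE(toupper(header$CompressedData %||% "FALSE") == "TRUE")) {
    stop("dbtvr_format_error: compressed MetaImage data is not supported", call. = FALSE)
  }
  dims <- as.integer(strsplit(header$DimSize, "\\s+")[[1]])
  spacing <- as.double(strsplit(header$ElementSpacing, "\\s+")[[1]])
  origin_field <- header$Offset %||% header$Origin %||% header$Position %||% "0 0 0"
  origin <- as.double(strsplit(origin_field, "\\s+")[[1]])
  typ <- met_types[[header$ElementType]]
  if (is.null(typ)) {
    stop(sprintf("dbtvr_format_error: unsupported ElementType %s", header$ElementType),
         call. = FALSE)
  }
  msb <- toupper(header$BinaryDataByteOrderMSB %||% "FALSE") == "TRUE"
  endian <- if (msb) "big" else "little"
  n <- prod(dims)
  if (is_mha || header$ElementDataFile == "LOCAL") {
    vals <- readBin(con, what = typ$what, n = n, size = typ$size,
                    endian = endian,
                    signed = !header$ElementType %in% c("MET_UCHAR", "MET_USHORT"))
  } else {
    rawpath <- file.path(dirname(path), header$ElementDataFile)
    if (!file.exists(rawpath)) {
      stop(sprintf("dbtvr_format_error: ElementDataFile not found: %s", rawpath),
           call. = FALSE)
    }
    rcon <- file(rawpath, "rb")
    on.exit(close(rcon), add = TRUE)
    vals <- readBin(rcon, what = typ$what, n = n, size = typ$size,
                    endian = endian,
                    signed = !header$ElementType %in% c("MET_UCHAR", "MET_USHORT"))
  }
  if (length(vals) != n) {
    stop("dbtvr_format_error: MetaImage data block shorter than DimSize implies",
         call. = FALSE)
  }
  tomo_volume(array(as.double(vals), dims), spacing, origin)
}

write_metaimage <- function(vol, path) {
  is_mha <- grepl("\\.mha$", tolower(path))
  d <- dim(vol$data)
  fmt17 <- function(x) paste(sprintf("%.17g", x), collapse = " ")
  datafile <- if (is_mha) "LOCAL" else paste0(sub("\\.mhd$", "", basename(path),
                                                  ignore.case = TRUE), ".raw")
  header <- c(
    "ObjectType = Image",
    "NDims = 3",
    "BinaryData = True",
    "BinaryDataByteOrderMSB = False",
    "CompressedData = False",
    sprintf("DimSize = %d %d %d", d[1], d[2], d[3]),
    sprintf("ElementSpacing = %s", fmt17(vol$spacing)),
    sprintf("Offset = %s", fmt17(vol$origin)),
    "ElementType = MET_DOUBLE",
    sprintf("ElementDataFile = %s", datafile)
  )
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeLines(header, con)
  if (is_mha) {
    writeBin(as.vector(vol$data), con, size = 8L, endian = "little")
  } else {
    rcon <- file(file.path(dirname(path), datafile), "wb")
    on.exit(close(rcon), add = TRUE)
    writeBin(as.vector(vol$data), rcon, size = 8L, endian = "little")
  }
  invisible(path)
}

## ---- NIfTI -----------------------------------------------------------------

read_nifti_volume <- function(path) {
  im <- RNifti::readNifti(path)
  arr <- as.array(im)
  if (length(dim(arr)) != 3L) {
    stop("dbtvr_dimensionality_error: only 3D NIfTI volumes are supported",
         call. = FALSE)
  }
  x <- RNifti::xform(im)
  spacing <- RNifti::pixdim(im)[1:3]
  origin <- as.double(x[1:3, 4])
  tomo_volume(array(as.double(arr), dim(arr)), spacing, origin)
}

write_nifti_volume <- function(vol, path) {
  im <- RNifti::asNifti(vol$data)
  RNifti::pixdim(im) <- vol$spacing
  m <- diag(c(vol$spacing, 1))
  m[1:3, 4] <- vol$origin
  im <- RNifti::`qform<-`(im, value = structure(m, code = 2L))
  RNifti::writeNifti(im, path)
  invisible(path)
}

## ---- raw + JSON sidecar ----------------------------------------------------

read_raw_volume <- function(path) {
  sidecar <- paste0(path, ".json")
  if (!file.exists(sidecar)) {
    stop(sprintf("dbtvr_format_error: raw volume requires JSON sidecar %s", sidecar),
         call. = FALSE)
  }
  meta <- jsonlite::fromJSON(sidecar)
  for (field in c("shape", "dtype", "spacing")) {
    if (is.null(meta[[field]])) {
      stop(sprintf("dbtvr_format_error: sidecar missing '%s'", field), call. = FALSE)
    }
  }
  dims <- as.integer(meta$shape)
  if (length(dims) != 3L) {
    stop("dbtvr_dimensionality_error: sidecar shape must have 3 entries", call. = FALSE)
  }
  sizes <- c(float64 = 8L, double = 8L, float32 = 4L, int16 = 2L, uint16 = 2L, uint8 = 1L)
  whats <- c(float64 = "double", double = "double", float32 = "double",
             int16 = "integer", uint16 = "integer", uint8 = "integer")
  dt <- as.character(meta$dtype)
  if (!dt %in% names(sizes)) {
    stop(sprintf("dbtvr_format_error: unsupported dtype '%s'", dt), call. = FALSE)
  }
  endian <- meta$byte_order %||% "little"
  con <- file(path, "rb")
  on.exit(close(con), add = TRUE)
  vals <- readBin(con, what = whats[[dt]], n = prod(dims), size = sizes[[dt]],
                  endian = endian, signed = dt != "uint8")
  if (length(vals) != prod(dims)) {
    stop("dbtvr_format_error: raw file shorter than sidecar shape implies",
         call. = FALSE)
  }
  tomo_volume(array(as.double(vals), dims), as.double(meta$spacing),
              as.double(meta$origin %||% c(0, 0, 0)))
}

write_raw_volume <- function(vol, path) {
  con <- file(path, "wb")
  on.exit(close(con), add = TRUE)
  writeBin(as.vector(vol$data), con, size = 8L, endian = "little")
  meta <- list(shape = dim(vol$data), dtype = "float64",
               spacing = vol$spacing, origin = vol$origin, byte_order = "little")
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

## ---- rendered images -------------------------------------------------------

#' Write a rendered image as 16-bit PNG or TIFF
#'
#' Intensities are linearly mapped from `[lo, hi]` to the 16-bit range; the
#' scale is recorded in a JSON sidecar (`<path>.json`) so the quantization is
#' reversible to 16-bit precision. Quantitative metrics always operate on the
#' in-memory float image, never on the quantized file.
#'
#' @param img A [tomo_image].
#' @param path Output path ending in `.png` or `.tif`/`.tiff`.
#' @param range Intensity range mapped onto the file's dynamic range;
#'   default `c(0, 1)`.
#' @return `path`, invisibly.
#' @export
write_rendered_image <- function(img, path, range = c(0, 1)) {
  if (!inherits(img, "tomo_image")) {
    stop("dbtvr_usage_error: expected a `tomo_image`", call. = FALSE)
  }
  lo <- range[1]; hi <- range[2]
  if (hi <= lo) stop("dbtvr_usage_error: invalid intensity range", call. = FALSE)
  scaled <- pmin(pmax((img$pixels - lo) / (hi - lo), 0), 1)
  lp <- tolower(path)
  if (grepl("\\.png$", lp)) {
    if (!requireNamespace("png", quietly = TRUE)) {
      stop("dbtvr_usage_error: package 'png' is required to write PNG", call. = FALSE)
    }
    png::writePNG(scaled, path, dpi = NULL)
  } else if (grepl("\\.tiff?$", lp)) {
    if (!requireNamespace("tiff", quietly = TRUE)) {
      stop("dbtvr_usage_error: package 'tiff' is required to write TIFF", call. = FALSE)
    }
    tiff::writeTIFF(scaled, path, bits.per.sample = 16L)
  } else {
    stop("dbtvr_usage_error: rendered images must be .png or .tif/.tiff", call. = FALSE)
  }
  sidecar <- list(intensity_range = c(lo, hi), axes = img$axes,
                  pixel_spacing = img$pixel_spacing, axis_origin = img$axis_origin)
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = FALSE, digits = NA)
  invisible(path)
}

## ---- metric tables ---------------------------------------------------------

#' Write sweep metric records to CSV
#'
#' One header row plus one row per record; numeric fields are written with
#' enough digits that a re-parse reproduces them to at least 6 significant
#' digits.
#'
#' @param records A data frame of metric records (one row per
#'   kernel/sampling-distance cell), or a list of homogeneous named lists.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_results_csv <- function(records, path) {
  records <- as_records_df(records)
  utils::write.csv(format_df_sig(records), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a metric-record CSV written by [write_results_csv()]
#' @param path CSV path.
#' @return A data frame.
#' @export
read_results_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

as_records_df <- function(records) {
  if (is.data.frame(records)) {
    if (nrow(records) == 0L) {
      stop("dbtvr_usage_error: `records` must be non-empty", call. = FALSE)
    }
    return(records)
  }
  if (!is.list(records) || length(records) == 0L) {
    stop("dbtvr_usage_error: `records` must be a non-empty data frame or list",
         call. = FALSE)
  }
  fields <- lapply(records, function(r) sort(names(r)))
  if (!all(vapply(fields, identical, logical(1), fields[[1]]))) {
    stop("dbtvr_usage_error: records have mixed field sets", call. = FALSE)
  }
  do.call(rbind, lapply(records, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
}

format_df_sig <- function(df, digits = 15) {
  for (nm in names(df)) {
    if (is.numeric(df[[nm]])) df[[nm]] <- signif(df[[nm]], digits)
  }
  df
}
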