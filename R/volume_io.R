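#' Construct a voxel volume
#'
#' A `voxel_volume` is a 3D scalar field on an isotropic voxel grid together
#' with the physical edge length of a voxel. Axis order is `(x, y, z)` with
#' `z` the stack-slice index; voxel centers sit at integer coordinates
#' `1..dim`, and continuous positions are expressed in voxel units, converted
#' to physical units only at reporting time.
#'
#' @param data numeric 3D array indexed `(x, y, z)`.
#' @param voxel_length physical edge length of a voxel in micrometers
#'   (isotropic: the same length applies along x, y and z).
#' @param name free-text label.
#' @return an object of class `voxel_volume`.
#' @export
voxel_volume <- function(data, voxel_length = 1, name = "") {
  data <- as.array(data)
  if (length(dim(data)) != 3L)
    stop("'data' must be a 3D array")
  if (any(dim(data) < 1L))
    stop("all three grid dimensions must be >= 1")
  if (!is.numeric(voxel_length) || length(voxel_length) != 1L ||
      !is.finite(voxel_length) || voxel_length <= 0)
    stop("'voxel_length' must be a single positive number")
  structure(
    list(data = data, voxel_length = as.numeric(voxel_length),
         name = as.character(name)),
    class = "voxel_volume")
}

#' Construct a binary lumen mask
#'
#' A `lumen_mask` is a `voxel_volume` whose values are exactly 0 or 1
#' (foreground = lumen).
#'
#' @inheritParams voxel_volume
#' @return an object of class `c("lumen_mask", "voxel_volume")`.
#' @export
lumen_mask <- function(data, voxel_length = 1, name = "") {
  v <- voxel_volume(data, voxel_length, name)
  vals <- unique(as.vector(v$data))
  if (!all(vals %in% c(0, 1)))
    stop("a lumen mask must contain only 0/1 values")
  storage.mode(v$data) <- "integer"
  class(v) <- c("lumen_mask", "voxel_volume")
  v
}

#' @export
print.voxel_volume <- function(x, ...) {
  d <- dim(x$data)
  cat(sprintf("<%s> %s%d x %d x %d voxels, voxel length %g um\n",
              class(x)[1L],
              if (nzchar(x$name)) paste0("'", x$name, "' ") else "",
              d[1L], d[2L], d[3L], x$voxel_length))
  rng <- range(x$data)
  cat(sprintf("  intensity range [%g, %g]\n", rng[1L], rng[2L]))
  invisible(x)
}

#' @export
dim.voxel_volume <- function(x) dim(x$data)

#' @export
as.array.voxel_volume <- function(x, ...) x$data

#' Threshold a volume into a lumen mask
#'
#' Foreground wherever `data >= threshold`. Idempotent on its own output for
#' thresholds in (0, 1].
#'
#' @param v a [voxel_volume()].
#' @param threshold scalar intensity threshold.
#' @return a [lumen_mask()].
#' @export
binarize <- function(v, threshold) {
  stopifnot(inherits(v, "voxel_volume"))
  lumen_mask(array(as.integer(v$data >= threshold), dim(v$data)),
             v$voxel_length, v$name)
}

detect_format <- function(path) {
  if (dir.exists(path)) return("tiff-stack")
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         nrrd = "nrrd",
         mha = "mha",
         tif = ,
         tiff = "tiff-stack",
         stop("cannot infer volume format from path: ", path))
}

#' Read a 3D volume
#'
#' Supported formats: a TIFF stack (a directory of one 2D TIFF per z-slice in
#' numeric filename order), NRRD (raw or gzip encoding) and MetaImage MHA
#' (local raw data). TIFF carries no reliable spacing, so `voxel_length` must
#' be supplied for stacks; for NRRD/MHA it is taken from the header unless
#' overridden. Anisotropic header spacings are rejected unless an explicit
#' `voxel_length` override is given.
#'
#' @param path file (NRRD/MHA) or directory (TIFF stack) path.
#' @param fmt one of `"auto"`, `"tiff-stack"`, `"nrrd"`, `"mha"`.
#' @param voxel_length optional isotropic voxel length in micrometers,
#'   overriding (or supplying, for TIFF) the file metadata.
#' @return a [voxel_volume()].
#' @export
read_volume <- function(path, fmt = c("auto", "tiff-stack", "nrrd", "mha"),
                        voxel_length = NULL) {
  fmt <- match.arg(fmt)
  if (!file.exists(path))
    stop("input does not exist: ", path)
  if (fmt == "auto") fmt <- detect_format(path)
  aniso_ok <- !is.null(voxel_length)
  v <- switch(fmt,
              "tiff-stack" = read_tiff_stack(path),
              "nrrd" = read_nrrd(path, aniso_ok),
              "mha" = read_mha(path, aniso_ok))
  if (!is.null(voxel_length)) {
    v$voxel_length <- voxel_length
  } else if (is.na(v$voxel_length)) {
    stop("TIFF stacks carry no spacing metadata; supply 'voxel_length'")
  }
  voxel_volume(v$data, v$voxel_length, name = basename(path))
}

#' Write a 3D volume
#'
#' Round-trips through [read_volume()] with bit-identical data for integer
#' grids and 32-bit float precision for TIFF. Masks are written as 8-bit
#' \{0, 255\} TIFF for viewer compatibility and read back as \{0, 1\}.
#'
#' @param v a [voxel_volume()] or [lumen_mask()].
#' @param path output file (NRRD/MHA) or directory (TIFF stack).
#' @param fmt one of `"auto"`, `"tiff-stack"`, `"nrrd"`, `"mha"`.
#' @return `path`, invisibly.
#' @export
write_volume <- function(v, path, fmt = c("auto", "tiff-stack", "nrrd", "mha")) {
  stopifnot(inherits(v, "voxel_volume"))
  fmt <- match.arg(fmt)
  if (fmt == "auto") fmt <- detect_format(path)
  switch(fmt,
         "tiff-stack" = write_tiff_stack(v, path),
         "nrrd" = write_nrrd(v, path),
         "mha" = write_mha(v, path))
  invisible(path)
}

## ---- TIFF stacks ----------------------------------------------------------

read_tiff_stack <- function(path) {
  if (dir.exists(path)) {
    files <- list.files(path, pattern = "\\.tiff?$", ignore.case = TRUE,
                        full.names = TRUE)
    if (!length(files)) stop("no TIFF slices found in ", path)
    num <- suppressWarnings(as.numeric(gsub("\\D", "", basename(files))))
    files <- files[order(num, basename(files))]
    slices <- lapply(files, tiff::readTIFF)
  } else {
    slices <- tiff::readTIFF(path, all = TRUE)
    if (!is.list(slices)) slices <- list(slices)
  }
  d <- dim(slices[[1L]])
  arr <- array(0, c(d[1L], d[2L], length(slices)))
  for (k in seq_along(slices)) arr[, , k] <- slices[[k]]
  # 8-bit mask convention: {0, 255} stored, readTIFF scales to {0, 1}
  list(data = arr, voxel_length = NA_real_)
}

write_tiff_stack <- function(v, path) {
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  nz <- dim(v$data)[3L]
  is_mask <- inherits(v, "lumen_mask")
  if (!is_mask && (min(v$data) < 0 || max(v$data) > 1))
    stop("TIFF stacks store intensities in [0, 1]; ",
         "use NRRD or MHA for arbitrary-range volumes")
  for (k in seq_len(nz)) {
    sl <- v$data[, , k] * 1.0
    f <- file.path(path, sprintf("slice_%05d.tif", k))
    if (is_mask) {
      tiff::writeTIFF(sl, f, bits.per.sample = 8L)     # stored as {0,255}
    } else {
      tiff::writeTIFF(sl, f, bits.per.sample = 32L)
    }
  }
  invisible(path)
}

## ---- NRRD (minimal raw/gzip reader and writer) ----------------------------

nrrd_types <- c("unsigned char" = "uint8", "uint8" = "uint8",
                "uchar" = "uint8", "short" = "int16", "int16" = "int16",
                "unsigned short" = "uint16", "uint16" = "uint16",
                "int" = "int32", "int32" = "int32",
                "float" = "float32", "double" = "float64")

read_nrrd <- function(path, aniso_ok = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line) || !nzchar(line)) break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexpr(":=?", line), invert = TRUE)[[1L]]
    fields[[trimws(tolower(kv[1L]))]] <- trimws(kv[2L])
  }
  dims <- as.integer(strsplit(fields[["sizes"]], "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D NRRD volumes are supported")
  type <- nrrd_types[[tolower(fields[["type"]])]]
  enc <- tolower(fields[["encoding"]])
  spacing <- NA_real_
  if (!is.null(fields[["spacings"]])) {
    sp <- as.numeric(strsplit(fields[["spacings"]], "\\s+")[[1L]])
    if (max(sp) - min(sp) > 1e-9 * max(sp)) {
      if (!aniso_ok)
        stop("anisotropic NRRD spacing ", paste(sp, collapse = " x "),
             "; supply an explicit 'voxel_length' override")
      spacing <- NA_real_
    } else spacing <- sp[1L]
  } else if (!is.null(fields[["space directions"]])) {
    nums <- as.numeric(regmatches(fields[["space directions"]],
                                  gregexpr("-?[0-9.eE+]+",
                                           fields[["space directions"]]))[[1L]])
    m <- matrix(nums, nrow = 3L, byrow = TRUE)
    sp <- sqrt(rowSums(m^2))
    if (max(sp) - min(sp) > 1e-9 * max(sp)) {
      if (!aniso_ok)
        stop("anisotropic NRRD spacing; supply an explicit 'voxel_length'")
      spacing <- NA_real_
    } else spacing <- sp[1L]
  }
  n <- prod(dims)
  raw_data <- readBin(con, "raw", n = n * 8L + 1024L)
  if (enc %in% c("gzip", "gz")) raw_data <- memDecompress(raw_data, "gzip")
  else if (enc != "raw") stop("unsupported NRRD encoding: ", enc)
  vals <- decode_binary(raw_data, type, n,
                        endian = if (identical(fields[["endian"]], "big"))
                          "big" else "little")
  list(data = array(vals, dims), voxel_length = spacing)
}

#' @noRd
decode_binary <- function(raw_data, type, n, endian = "little") {
  switch(type,
         uint8 = as.numeric(readBin(raw_data, "integer", n, size = 1L,
                                    signed = FALSE)),
         int16 = as.numeric(readBin(raw_data, "integer", n, size = 2L,
                                    signed = TRUE, endian = endian)),
         uint16 = as.numeric(readBin(raw_data, "integer", n, size = 2L,
                                     signed = FALSE, endian = endian)),
         int32 = as.numeric(readBin(raw_data, "integer", n, size = 4L,
                                    endian = endian)),
         float32 = readBin(raw_data, "double", n, size = 4L, endian = endian),
         float64 = readBin(raw_data, "double", n, size = 8L, endian = endian),
         stop("unsupported element type: ", type))
}

nrrd_type_of <- function(data) {
  if (is.integer(data) || isTRUE(all(data == round(data)))) {
    rng <- range(data)
    if (rng[1L] >= 0 && rng[2L] <= 255) "uint8"
    else if (rng[1L] >= -32768 && rng[2L] <= 32767) "int16"
    else "int32"
  } else "float64"
}

write_nrrd <- function(v, path) {
  type <- nrrd_type_of(v$data)
  hdr_type <- c(uint8 = "unsigned char", int16 = "short", int32 = "int",
                float64 = "double")[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("NRRD0004",
               "# lumenline volume",
               paste0("type: ", hdr_type),
               "dimension: 3",
               paste0("sizes: ", paste(dim(v$data), collapse = " ")),
               paste0("spacings: ", paste(rep(format(v$voxel_length), 3L),
                                          collapse = " ")),
               "endian: little",
               "encoding: raw",
               ""), con)
  write_binary(con, v$data, type)
  invisible(path)
}

write_binary <- function(con, data, type) {
  vec <- as.vector(data)
  switch(type,
         uint8 = writeBin(as.integer(vec), con, size = 1L),
         int16 = writeBin(as.integer(vec), con, size = 2L, endian = "little"),
         int32 = writeBin(as.integer(vec), con, size = 4L, endian = "little"),
         float32 = writeBin(as.numeric(vec), con, size = 4L,
                            endian = "little"),
         float64 = writeBin(as.numeric(vec), con, size = 8L,
                            endian = "little"))
}

## ---- MetaImage (MHA, local raw) -------------------------------------------

mha_types <- c(MET_UCHAR = "uint8", MET_SHORT = "int16", MET_USHORT = "uint16",
               MET_INT = "int32", MET_FLOAT = "float32", MET_DOUBLE = "float64")

read_mha <- function(path, aniso_ok = FALSE) {
  con <- file(path, "rb")
  on.exit(close(con))
  fields <- list()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed MHA header (no ElementDataFile)")
    kv <- strsplit(line, "=", fixed = TRUE)[[1L]]
    key <- trimws(kv[1L])
    fields[[key]] <- trimws(paste(kv[-1L], collapse = "="))
    if (key == "ElementDataFile") break
  }
  if (!identical(fields[["ElementDataFile"]], "LOCAL"))
    stop("only MHA files with local data are supported")
  dims <- as.integer(strsplit(fields[["DimSize"]], "\\s+")[[1L]])
  if (length(dims) != 3L) stop("only 3D MHA volumes are supported")
  spacing <- NA_real_
  spc <- fields[["ElementSpacing"]] %||% fields[["ElementSize"]]
  if (!is.null(spc)) {
    sp <- as.numeric(strsplit(spc, "\\s+")[[1L]])
    if (max(sp) - min(sp) > 1e-9 * max(sp)) {
      if (!aniso_ok)
        stop("anisotropic MHA spacing ", paste(sp, collapse = " x "),
             "; supply an explicit 'voxel_length' override")
      spacing <- NA_real_
    } else spacing <- sp[1L]
  }
  type <- mha_types[[fields[["ElementType"]]]]
  endian <- if (isTRUE(fields[["BinaryDataByteOrderMSB"]] == "True"))
    "big" else "little"
  n <- prod(dims)
  raw_data <- readBin(con, "raw", n = n * 8L)
  vals <- decode_binary(raw_data, type, n, endian)
  list(data = array(vals, dims), voxel_length = spacing)
}

write_mha <- function(v, path) {
  type <- nrrd_type_of(v$data)
  hdr_type <- c(uint8 = "MET_UCHAR", int16 = "MET_SHORT", int32 = "MET_INT",
                float64 = "MET_DOUBLE")[[type]]
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("ObjectType = Image",
               "NDims = 3",
               "BinaryData = True",
               "BinaryDataByteOrderMSB = False",
               paste0("DimSize = ", paste(dim(v$data), collapse = " ")),
               paste0("ElementSpacing = ",
                      paste(rep(format(v$voxel_length), 3L), collapse = " ")),
               paste0("ElementType = ", hdr_type),
               "ElementDataFile = LOCAL"), con)
  write_binary(con, v$data, type)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
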