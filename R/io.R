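#' Read a volumetric image stack
#'
#' Reads either a directory of 2D grayscale slices (PNG or TIFF; slice order
#' is the natural numeric sort of the filenames, z increasing) or a single
#' volume file (NRRD `.nrrd` or MetaImage `.mhd`).
#'
#' @param source path to a slice directory or a volume file.
#' @param spacing default spacing used for slice directories (no metadata).
#' @param origin default origin for slice directories.
#' @return A [stack_volume()].
#' @export
read_stack <- function(source, spacing = c(1, 1, 1), origin = c(0, 0, 0)) {
  if (dir.exists(source)) {
    return(read_slice_dir(source, spacing, origin))
  }
  if (!file.exists(source)) stop("input not found: ", source)
  ext <- tolower(tools::file_ext(source))
  switch(ext,
         nrrd = read_nrrd(source),
         mhd = read_mhd(source),
         stop("unsupported volume format: .", ext))
}

#' Write a volumetric image stack
#'
#' Byte volumes round-trip losslessly through both formats. Real
#' (averaged) volumes can only be written as volume files, which store
#' doubles.
#'
#' @param v a [stack_volume()].
#' @param dest output directory (slice-dir format) or file path.
#' @param format `"volume-file"` (NRRD or MetaImage, by extension) or
#'   `"slice-dir"` (PNG slices).
#' @return `dest`, invisibly.
#' @export
write_stack <- function(v, dest, format = c("volume-file", "slice-dir")) {
  stopifnot(is_stack_volume(v))
  format <- match.arg(format)
  if (format == "slice-dir") {
    if (v$role != "byte")
      stop("real-valued volumes cannot be written as image slices; ",
           "use format = \"volume-file\"")
    write_slice_dir(v, dest)
  } else {
    ext <- tolower(tools::file_ext(dest))
    if (ext == "mhd") write_mhd(v, dest) else write_nrrd(v, dest)
  }
  invisible(dest)
}

natural_order <- function(files) {
  # order by the first integer run in the basename, ties lexicographic
  base <- basename(files)
  num <- suppressWarnings(as.numeric(sub("^\\D*(\\d+).*$", "\\1", base)))
  num[!grepl("\\d", base)] <- Inf
  order(num, base)
}

read_slice_dir <- function(path, spacing, origin) {
  files <- list.files(path, pattern = "\\.(png|tif|tiff)$", ignore.case = TRUE,
                      full.names = TRUE)
  if (length(files) == 0) stop("no PNG/TIFF slices found in ", path)
  files <- files[natural_order(files)]
  slices <- lapply(files, read_gray_slice)
  dims <- vapply(slices, dim, integer(2))
  if (any(dims[1, ] != dims[1, 1]) || any(dims[2, ] != dims[2, 1]))
    stop("slices in ", path, " have mixed dimensions")
  arr <- array(0, dim = c(length(slices), dims[1, 1], dims[2, 1]))
  for (k in seq_along(slices)) arr[k, , ] <- slices[[k]]
  stack_volume(arr, spacing, origin, role = "byte")
}

read_gray_slice <- function(file) {
  ext <- tolower(tools::file_ext(file))
  img <- if (ext == "png") png::readPNG(file) else tiff::readTIFF(file)
  if (length(dim(img)) == 3L) img <- img[, , 1] # first channel of RGB(A)
  round(img * 255)
}

write_slice_dir <- function(v, path) {
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nz <- dim(v$data)[1]
  width <- max(4L, nchar(as.character(nz)))
  for (k in seq_len(nz)) {
    f <- file.path(path, sprintf(paste0("slice_%0", width, "d.png"), k))
    png::writePNG(v$data[k, , ] / 255, f)
  }
  invisible(path)
}

# --- NRRD ------------------------------------------------------------------
# Minimal NRRD4 support: attached raw little-endian data, types uint8 and
# double, 3D scalar or 4D (3-vector) fields.

write_nrrd <- function(v, path) {
  is_field <- length(dim(v)) == 4L # plain array for vector fields
  if (is_field) {
    arr <- v
    spacing <- attr(v, "spacing"); origin <- attr(v, "origin")
    type <- "double"
  } else {
    arr <- v$data
    spacing <- v$spacing; origin <- v$origin
    type <- if (v$role == "byte") "uint8" else "double"
  }
  d <- dim(arr)
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- c("NRRD0004",
           "# stackcarve volume",
           paste0("type: ", type),
           paste0("dimension: ", length(d)))
  if (is_field) {
    # field array dim (nz, ny, nx, 3): NRRD axes fastest-first are
    # z, y, x, component (R is column-major so dim[1] varies fastest)
    hdr <- c(hdr,
             paste0("sizes: ", paste(d, collapse = " ")),
             "kinds: domain domain domain vector",
             paste0("spacings: ", paste(spacing[3:1], collapse = " "), " nan"),
             paste0("axis mins: ", paste(origin[3:1], collapse = " "), " nan"))
  } else {
    hdr <- c(hdr,
             paste0("sizes: ", paste(d, collapse = " ")),
             "kinds: domain domain domain",
             paste0("spacings: ", paste(spacing[3:1], collapse = " ")),
             paste0("axis mins: ", paste(origin[3:1], collapse = " ")))
  }
  hdr <- c(hdr, "endian: little", "encoding: raw", "")
  writeLines(hdr, con, sep = "\n")
  if (type == "uint8") {
    writeBin(as.raw(as.integer(arr)), con)
  } else {
    writeBin(as.numeric(arr), con, size = 8, endian = "little")
  }
  invisible(path)
}

read_nrrd <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- list()
  magic <- readLines(con, n = 1)
  if (!grepl("^NRRD", magic)) stop("not an NRRD file: ", path)
  repeat {
    line <- readLines(con, n = 1)
    if (length(line) == 0 || line == "") break
    if (grepl("^#", line)) next
    kv <- regmatches(line, regexec("^([^:]+):\\s*(.*)$", line))[[1]]
    if (length(kv) == 3) hdr[[tolower(kv[2])]] <- kv[3]
  }
  sizes <- as.integer(strsplit(trimws(hdr$sizes), "\\s+")[[1]])
  type <- hdr$type
  if (!identical(hdr$encoding, "raw")) stop("only raw NRRD encoding supported")
  n <- prod(sizes)
  data <- if (type %in% c("uint8", "uchar", "unsigned char")) {
    as.numeric(readBin(con, "raw", n = n))
  } else if (type %in% c("double", "float64")) {
    readBin(con, "double", n = n, size = 8, endian = "little")
  } else stop("unsupported NRRD type: ", type)
  parse_axis <- function(key, skip_first) {
    if (is.null(hdr[[key]])) return(NULL)
    vals <- suppressWarnings(as.numeric(strsplit(trimws(hdr[[key]]), "\\s+")[[1]]))
    if (skip_first) vals <- vals[-1]
    vals
  }
  nd <- length(sizes)
  if (nd == 4L) {
    arr <- array(data, dim = sizes)
    sp <- parse_axis("spacings", FALSE)
    og <- parse_axis("axis mins", FALSE)
    attr(arr, "spacing") <- rev(sp[1:3])
    attr(arr, "origin") <- rev(og[1:3])
    return(arr)
  }
  spacing <- parse_axis("spacings", FALSE)
  origin <- parse_axis("axis mins", FALSE)
  if (is.null(spacing) || any(is.na(spacing))) spacing <- c(1, 1, 1)
  if (is.null(origin) || any(is.na(origin))) origin <- c(0, 0, 0)
  arr <- array(data, dim = sizes)
  stack_volume(arr, rev(spacing), rev(origin),
               role = if (type %in% c("double", "float64")) "real" else "byte")
}

# --- MetaImage -------------------------------------------------------------

write_mhd <- function(v, path) {
  raw_path <- sub("\\.mhd$", ".raw", path)
  d <- dim(v$data)
  type <- if (v$role == "byte") "MET_UCHAR" else "MET_DOUBLE"
  hdr <- c("ObjectType = Image",
           "NDims = 3",
           "BinaryData = True",
           "BinaryDataByteOrderMSB = False",
           paste0("DimSize = ", paste(d[3:1], collapse = " ")),
           paste0("ElementSpacing = ", paste(v$spacing, collapse = " ")),
           paste0("Offset = ", paste(v$origin, collapse = " ")),
           paste0("ElementType = ", type),
           paste0("ElementDataFile = ", basename(raw_path)))
  writeLines(hdr, path)
  con <- file(raw_path, "wb")
  on.exit(close(con))
  # MetaImage stores x fastest; our array has z fastest -> permute
  arr <- aperm(v$data, c(3, 2, 1))
  if (v$role == "byte") writeBin(as.raw(as.integer(arr)), con)
  else writeBin(as.numeric(arr), con, size = 8, endian = "little")
  invisible(path)
}

read_mhd <- function(path) {
  lines <- readLines(path)
  kv <- list()
  for (line in lines) {
    parts <- regmatches(line, regexec("^([^=]+)=\\s*(.*)$", line))[[1]]
    if (length(parts) == 3) kv[[trimws(parts[2])]] <- trimws(parts[3])
  }
  d_xyz <- as.integer(strsplit(kv$DimSize, "\\s+")[[1]])
  spacing <- if (!is.null(kv$ElementSpacing))
    as.numeric(strsplit(kv$ElementSpacing, "\\s+")[[1]]) else c(1, 1, 1)
  origin <- if (!is.null(kv$Offset))
    as.numeric(strsplit(kv$Offset, "\\s+")[[1]]) else c(0, 0, 0)
  raw_path <- file.path(dirname(path), kv$ElementDataFile)
  con <- file(raw_path, "rb")
  on.exit(close(con))
  n <- prod(d_xyz)
  type <- kv$ElementType
  data <- if (type == "MET_UCHAR") as.numeric(readBin(con, "raw", n = n))
  else if (type == "MET_DOUBLE") readBin(con, "double", n = n, size = 8,
                                         endian = "little")
  else stop("unsupported MetaImage type: ", type)
  arr <- aperm(array(data, dim = d_xyz), c(3, 2, 1)) # to (z, y, x)
  stack_volume(arr, spacing, origin,
               role = if (type == "MET_DOUBLE") "real" else "byte")
}
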