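#' Construct a micrograph object
#'
#' A micrograph is a plain numeric matrix (rows = y, cols = x, 0-based pixel
#' coordinates when addressing boxes) carrying an `identifier` attribute and
#' optionally a `pixel_size` attribute in Angstrom per pixel.
#'
#' @param pixels Numeric matrix of intensities, at least 32 x 32, all finite.
#' @param identifier Source path or synthetic ID.
#' @param pixel_size Optional pixel size in Angstrom.
#' @return The matrix with class `micrograph`.
#' @export
micrograph <- function(pixels, identifier = "", pixel_size = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop_cfg("micrograph pixels must be a numeric matrix")
  if (any(dim(pixels) < 32)) stop_cfg("micrograph must be at least 32 x 32")
  if (!all(is.finite(pixels))) stop_cfg("micrograph contains non-finite values")
  attr(pixels, "identifier") <- identifier
  if (!is.null(pixel_size)) attr(pixels, "pixel_size") <- pixel_size
  class(pixels) <- c("micrograph", class(matrix()))
  pixels
}

# ---------------------------------------------------------------------------
# MRC2014 single-image files (modes 0 = int8, 1 = int16, 2 = float32).
# Data are stored x-fastest, so a file with header nx, ny maps to an R matrix
# of shape (ny, nx). Little-endian only, which covers files written by the
# standard cryo-EM packages on commodity hardware.
# ---------------------------------------------------------------------------

read_mrc <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "integer", n = 10, size = 4, endian = "little")
  if (length(hdr) < 10) stop("truncated MRC header in ", path)
  nx <- hdr[1]; ny <- hdr[2]; nz <- hdr[3]; mode <- hdr[4]
  if (!(mode %in% c(0L, 1L, 2L)))
    stop_cfg("unsupported MRC mode ", mode, " in ", path,
             " (modes 0, 1, 2 supported)")
  if (nx <= 0 || ny <= 0 || nz < 1)
    stop("invalid MRC dimensions in ", path)
  # word 24 (0-based byte offset 92) holds the extended header size
  seek(con, 76)
  rest <- readBin(con, "integer", n = 5, size = 4, endian = "little")
  nsymbt <- rest[5]
  # pixel size from cella / mx if present
  seek(con, 28)
  m_xyz <- readBin(con, "integer", n = 3, size = 4, endian = "little")
  cella <- readBin(con, "numeric", n = 3, size = 4, endian = "little")
  px <- if (m_xyz[1] > 0 && cella[1] > 0) cella[1] / m_xyz[1] else NULL
  seek(con, 1024 + nsymbt)
  n <- nx * ny  # single image: first section only
  v <- switch(as.character(mode),
    "0" = readBin(con, "integer", n = n, size = 1, signed = TRUE),
    "1" = readBin(con, "integer", n = n, size = 2, signed = TRUE,
                  endian = "little"),
    "2" = readBin(con, "numeric", n = n, size = 4, endian = "little"))
  if (length(v) < n) stop("truncated MRC data in ", path)
  micrograph(t(matrix(as.numeric(v), nrow = nx, ncol = ny)),
             identifier = path, pixel_size = px)
}

#' Write a micrograph as an MRC2014 file
#'
#' @param img Numeric matrix (rows = y, cols = x).
#' @param path Output file path.
#' @param mode MRC data mode: 0 (int8), 1 (int16) or 2 (float32, default).
#'   Integer modes round and clamp to the type range.
#' @param pixel_size Pixel size in Angstrom recorded in the cell dimensions.
#' @return `path`, invisibly.
#' @export
write_mrc <- function(img, path, mode = 2L, pixel_size = 1.0) {
  if (!(mode %in% c(0L, 1L, 2L))) stop_cfg("unsupported MRC mode ", mode)
  ny <- nrow(img); nx <- ncol(img)
  con <- file(path, "wb")
  on.exit(close(con))
  wi <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")
  wf <- function(x) writeBin(as.numeric(x), con, size = 4, endian = "little")
  wi(c(nx, ny, 1L, mode, 0L, 0L, 0L))          # nx ny nz mode nstart
  wi(c(nx, ny, 1L))                            # mx my mz
  wf(c(nx * pixel_size, ny * pixel_size, pixel_size))  # cella
  wf(c(90, 90, 90))                            # cellb
  wi(c(1L, 2L, 3L))                            # mapc mapr maps
  wf(c(min(img), max(img), mean(img)))         # dmin dmax dmean
  wi(c(0L, 0L))                                # ispg nsymbt
  wi(rep(0L, 25))                              # extra
  wf(c(0, 0, 0))                               # origin
  writeChar("MAP ", con, 4, eos = NULL)        # map stamp
  writeBin(as.raw(c(0x44, 0x44, 0x00, 0x00)), con)  # little-endian stamp
  wf(sd(img))                                  # rms
  wi(0L)                                       # nlabl
  writeBin(raw(800), con)                      # labels
  v <- as.vector(t(img))                       # x-fastest
  if (mode == 2L) {
    wf(v)
  } else {
    lim <- if (mode == 0L) c(-128, 127) else c(-32768, 32767)
    writeBin(as.integer(pmin(pmax(round(v), lim[1]), lim[2])), con,
             size = if (mode == 0L) 1 else 2, endian = "little")
  }
  invisible(path)
}

to_gray <- function(a) {
  if (length(dim(a)) == 3) a <- apply(a, c(1, 2), mean)  # average channels
  a * 1.0
}

#' Read a micrograph from MRC, TIFF, PNG or JPG
#'
#' MRC data (modes 0/1/2) are converted to real values; multi-channel TIFF,
#' PNG or JPG images are averaged to a single channel. Intensities are used
#' as stored, with no gamma handling, since the picker normalizes each patch
#' downstream.
#'
#' @param path Path to the image file; the format is chosen by extension.
#' @return A [micrograph()] (matrix, rows = y, cols = x).
#' @export
read_micrograph <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- switch(ext,
    mrc = , mrcs = , map = return(read_mrc(path)),
    tif = , tiff = to_gray(tiff::readTIFF(path)),
    png = to_gray(png::readPNG(path)),
    jpg = , jpeg = {
      if (!requireNamespace("jpeg", quietly = TRUE))
        stop_cfg("reading JPG requires the 'jpeg' package")
      to_gray(jpeg::readJPEG(path))
    },
    stop_cfg("unsupported micrograph format: .", ext))
  micrograph(img, identifier = path)
}

# ---------------------------------------------------------------------------
# Coordinate files. EMAN1 .box: ASCII "corner_x corner_y w h" per line, the
# corner being the low-coordinate corner of the box in the stored-array frame
# (an optional y flip for files written against a bottom-left origin is
# exposed as a reader/writer flag). RELION coordinate STAR: a loop_ with
# _rlnCoordinateX/_rlnCoordinateY particle centers; box size is not stored
# in STAR and must be supplied.
# ---------------------------------------------------------------------------

#' Read particle coordinates from EMAN1 .box or RELION .star files
#'
#' All boxes are returned center-based. EMAN1 corners are converted with
#' `center = corner + size/2`; STAR coordinates are already centers and get
#' `w = h = box_size`.
#'
#' @param path Coordinate file path.
#' @param format `"eman1_box"`, `"star"`, or `"auto"` (by extension).
#' @param box_size Box side length in pixels, required for STAR input.
#' @param flip_y If `TRUE`, interpret the stored y axis as bottom-up and flip
#'   it against `image_height`.
#' @param image_height Image height in pixels, required when `flip_y = TRUE`.
#' @return A [boxes_df()] data frame; the declared box size is attached as
#'   attribute `box_size`.
#' @export
read_boxes <- function(path, format = c("auto", "eman1_box", "star"),
                       box_size = NULL, flip_y = FALSE, image_height = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (tolower(tools::file_ext(path)) == "star") "star"
              else "eman1_box"
  if (flip_y && is.null(image_height))
    stop_cfg("flip_y requires image_height")
  if (format == "eman1_box") {
    lines <- readLines(path, warn = FALSE)
    keep <- which(nzchar(trimws(lines)))
    if (length(keep) == 0) return(boxes_df())
    fields <- lapply(keep, function(i) {
      f <- strsplit(trimws(lines[i]), "[[:space:]]+")[[1]]
      v <- suppressWarnings(as.numeric(f))
      if (length(v) < 4 || anyNA(v[1:4]))
        stop(sprintf("%s: malformed box line %d: '%s'", path, i, lines[i]),
             call. = FALSE)
      v[1:4]
    })
    m <- do.call(rbind, fields)
    cy <- m[, 2] + m[, 4] / 2
    if (flip_y) cy <- image_height - cy
    b <- boxes_df(cx = m[, 1] + m[, 3] / 2, cy = cy, w = m[, 3], h = m[, 4])
    attr(b, "box_size") <- if (nrow(b)) m[1, 3] else box_size
    return(b)
  }
  # STAR
  tab <- parse_star_loop(path)
  need <- c("_rlnCoordinateX", "_rlnCoordinateY")
  if (!all(need %in% names(tab)))
    stop_cfg(path, ": STAR file lacks ", paste(setdiff(need, names(tab)),
                                               collapse = ", "))
  if (is.null(box_size)) stop_cfg("box_size is required for STAR input")
  if (nrow(tab) == 0) return(boxes_df())
  conf <- if ("_rlnAutopickFigureOfMerit" %in% names(tab))
    pmin(pmax(tab[["_rlnAutopickFigureOfMerit"]], 0), 1) else 1
  cy <- tab[["_rlnCoordinateY"]]
  if (flip_y) cy <- image_height - cy
  b <- boxes_df(cx = tab[["_rlnCoordinateX"]], cy = cy,
                w = box_size, h = box_size, confidence = conf)
  attr(b, "box_size") <- box_size
  b
}

# Minimal STAR loop_ parser: returns a data frame of the first loop block.
parse_star_loop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  loop_at <- which(trimws(lines) == "loop_")
  if (length(loop_at) == 0) stop_cfg(path, ": no loop_ block found")
  i <- loop_at[1] + 1
  cols <- character()
  while (i <= length(lines) && grepl("^_", trimws(lines[i]))) {
    cols <- c(cols, sub("[[:space:]]+#.*$", "", trimws(lines[i])))
    i <- i + 1
  }
  rows <- list()
  while (i <= length(lines)) {
    ln <- trimws(lines[i])
    if (!nzchar(ln) || grepl("^data_", ln)) break
    f <- strsplit(ln, "[[:space:]]+")[[1]]
    if (length(f) < length(cols))
      stop(sprintf("%s: malformed STAR row at line %d", path, i),
           call. = FALSE)
    rows[[length(rows) + 1]] <- f[seq_along(cols)]
    i <- i + 1
  }
  if (length(rows) == 0) {
    out <- as.data.frame(setNames(rep(list(numeric()), length(cols)), cols))
    return(out)
  }
  m <- do.call(rbind, rows)
  out <- as.data.frame(m, stringsAsFactors = FALSE)
  names(out) <- cols
  for (j in seq_along(out)) {
    v <- suppressWarnings(as.numeric(out[[j]]))
    if (!anyNA(v)) out[[j]] <- v
  }
  out
}

#' Write particle coordinates to EMAN1 .box or RELION .star files
#'
#' EMAN1 output writes integer low-corner coordinates (`corner = center -
#' size/2`, rounded), so a round trip reproduces centers within 0.5 px. STAR
#' output writes particle centers with the confidence as a figure-of-merit
#' column.
#'
#' @param boxes A [boxes_df()] data frame.
#' @param path Output path.
#' @param format `"eman1_box"` or `"star"`.
#' @param flip_y,image_height Mirror of the [read_boxes()] flags.
#' @return `path`, invisibly.
#' @export
write_boxes <- function(boxes, path, format = c("eman1_box", "star"),
                        flip_y = FALSE, image_height = NULL) {
  format <- match.arg(format)
  if (flip_y && is.null(image_height))
    stop_cfg("flip_y requires image_height")
  cy <- boxes$cy
  if (flip_y) cy <- image_height - cy
  if (format == "eman1_box") {
    lines <- sprintf("%d\t%d\t%d\t%d",
                     as.integer(round(boxes$cx - boxes$w / 2)),
                     as.integer(round(cy - boxes$h / 2)),
                     as.integer(round(boxes$w)), as.integer(round(boxes$h)))
    writeLines(lines, path)
  } else {
    hdr <- c("", "data_", "", "loop_",
             "_rlnCoordinateX #1", "_rlnCoordinateY #2",
             "_rlnAutopickFigureOfMerit #3")
    rows <- sprintf("%12.6f %12.6f %12.6f", boxes$cx, cy, boxes$confidence)
    writeLines(c(hdr, rows), path)
  }
  invisible(path)
}
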