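#' Read a grayscale image from PNG, TIFF or PGM
#'
#' Color rasters are converted to luminance (BT.601); unit-interval floats
#' are rescaled to the 8-bit working range. The format is chosen by file
#' extension (`.png`, `.tif`/`.tiff`, `.pgm`).
#'
#' @param path Path to the image file.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read image '%s'", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    png  = png::readPNG(path),
    tif  = ,
    tiff = tiff::readTIFF(path),
    pgm  = read_pgm(path),
    stop(sprintf("unsupported image format '%s'", ext))
  )
  as_gray_image(raw)
}

#' Write a grayscale image to PNG or PGM
#'
#' @param img A [gray_image()] or numeric matrix.
#' @param path Output path; `.png` or `.pgm` (plain-text P2).
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  img <- as_gray_image(img)
  ext <- tolower(tools::file_ext(path))
  maxv <- 2^image_depth(img) - 1
  if (ext == "png") {
    png::writePNG(pixel_matrix(img) / maxv, target = path)
  } else if (ext == "pgm") {
    write_pgm(img, path)
  } else {
    stop(sprintf("unsupported output format '%s'", ext))
  }
  invisible(path)
}

# Minimal PGM (P2 ascii / P5 binary) reader; neither the png nor the tiff
# package handles the netpbm formats.
read_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L, useBytes = TRUE)
  if (!magic %in% c("P2", "P5")) stop("not a PGM file")
  tokens <- character(0)
  # header: width, height, maxval; '#' starts a comment
  while (length(tokens) < 3L) {
    ch <- readChar(con, 1L, useBytes = TRUE)
    if (length(ch) == 0L || ch == "") stop("truncated PGM header")
    if (ch == "#") {
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "" || ch == "\n") break
      }
    } else if (grepl("[0-9]", ch)) {
      tok <- ch
      repeat {
        ch <- readChar(con, 1L, useBytes = TRUE)
        if (length(ch) == 0L || ch == "" || !grepl("[0-9]", ch)) break
        tok <- paste0(tok, ch)
      }
      tokens <- c(tokens, tok)
    }
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  n <- w * h
  if (magic == "P5") {
    vals <- if (maxval < 256) {
      as.integer(readBin(con, "raw", n))
    } else {
      readBin(con, "integer", n, size = 2L, signed = FALSE, endian = "big")
    }
  } else {
    vals <- scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) < n) stop("truncated PGM data")
  m <- matrix(vals, nrow = h, ncol = w, byrow = TRUE)
  depth <- if (maxval < 256) 8L else 16L
  gray_image(m, depth = depth)
}

write_pgm <- function(img, path) {
  px <- pixel_matrix(img)
  maxv <- 2^image_depth(img) - 1
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(px), nrow(px)), as.character(maxv)), con)
  apply(px, 1L, function(row) writeLines(paste(row, collapse = " "), con))
  invisible(path)
}
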