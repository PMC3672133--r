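#' Read and write 8-bit single-channel B-scan images
#'
#' Supported formats by file extension: PNG (default, via the png package),
#' TIFF (via the tiff package, if installed) and plain PGM (P2/P5).
#' Images are written as single-channel 8-bit; reading an image whose
#' samples are not 8-bit single-channel grayscale is an error.
#'
#' @param image a [BScanImage-class].
#' @param path file path; the extension selects the format.
#' @return `writeBScan` returns `path` invisibly; `readBScan` returns a
#'   [BScanImage-class].
#' @export
writeBScan <- function(image, path) {
  stopifnot(is(image, "BScanImage"))
  ext <- tolower(tools::file_ext(path))
  p <- image@pixels
  if (ext == "png") {
    png::writePNG(p / 255, target = path)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to write TIFF")
    tiff::writeTIFF(p / 255, where = path, bits.per.sample = 8L)
  } else if (ext == "pgm") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(c("P2", sprintf("%d %d", ncol(p), nrow(p)), "255"), con)
    write(t(p), file = con, ncolumns = ncol(p))
  } else {
    stop("unsupported image format: ", ext)
  }
  invisible(path)
}

#' @rdname writeBScan
#' @param scaleX,scaleY physical pixel size (mm) to attach.
#' @param imageId identifier; default is the file base name.
#' @export
readBScan <- function(path, scaleX = 16 / 600, scaleY = 6 / 300,
                      imageId = tools::file_path_sans_ext(basename(path))) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "png") {
    a <- png::readPNG(path)
    if (length(dim(a)) == 3L) {
      if (dim(a)[3L] > 2L && (max(abs(a[, , 1L] - a[, , 2L])) > 0 ||
                              max(abs(a[, , 1L] - a[, , 3L])) > 0))
        stop("image is not 8-bit single-channel grayscale")
      a <- a[, , 1L]
    }
    p <- round(a * 255)
  } else if (ext %in% c("tif", "tiff")) {
    if (!requireNamespace("tiff", quietly = TRUE))
      stop("the 'tiff' package is required to read TIFF")
    a <- tiff::readTIFF(path)
    if (length(dim(a)) == 3L) a <- a[, , 1L]
    p <- round(a * 255)
  } else if (ext == "pgm") {
    p <- readPGM(path)
  } else {
    stop("unsupported image format: ", ext)
  }
  new("BScanImage", pixels = p, scaleX = scaleX, scaleY = scaleY,
      imageId = imageId)
}

## Minimal PGM reader (plain P2 and binary P5), 8-bit only.
readPGM <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readChar(con, 2L)
  readToken <- function() {
    tok <- ""
    repeat {
      ch <- readChar(con, 1L)
      if (!length(ch) || ch == "") stop("truncated PGM header")
      if (ch == "#") {
        repeat {
          ch <- readChar(con, 1L)
          if (!length(ch) || ch == "\n") break
        }
        next
      }
      if (grepl("[[:space:]]", ch)) {
        if (nzchar(tok)) return(tok) else next
      }
      tok <- paste0(tok, ch)
    }
  }
  w <- as.integer(readToken()); h <- as.integer(readToken())
  maxval <- as.integer(readToken())
  if (maxval > 255L) stop("image is not 8-bit single-channel grayscale")
  n <- w * h
  if (magic == "P5") {
    v <- as.integer(readBin(con, "raw", n))
  } else if (magic == "P2") {
    v <- integer(0L)
    while (length(v) < n) {
      line <- readLines(con, n = 1L)
      if (!length(line)) stop("truncated PGM data")
      v <- c(v, as.integer(strsplit(trimws(line), "[[:space:]]+")[[1L]]))
    }
  } else {
    stop("unsupported PGM magic: ", magic)
  }
  matrix(v[seq_len(n)], nrow = h, ncol = w, byrow = TRUE)
}
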