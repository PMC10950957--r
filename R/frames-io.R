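# Reading and writing frame streams as image-sequence directories
# (PNG or PGM frames in lexicographic order, plus a plain-text sidecar with
# the sampling rate).

.sidecar_name <- "frames_meta.txt"

#' Write a frame stream to an image-sequence directory
#'
#' Frames are written as `frame_0001.png`, `frame_0002.png`, ... (or `.pgm`)
#' so that lexicographic order is frame order, together with a plain-text
#' sidecar recording `fps` and `side_length`. The round trip through
#' [read_frames()] is lossless for 8-bit grayscale.
#'
#' @param stream A [frame_stream].
#' @param path Directory to create/fill.
#' @param format `"png"` (default) or `"pgm"` (plain-text P2).
#' @return `path`, invisibly.
#' @export
write_frames <- function(stream, path, format = c("png", "pgm")) {
  stopifnot(inherits(stream, "frame_stream"))
  format <- match.arg(format)
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  nf <- stream$n_frames
  for (f in seq_len(nf)) {
    file <- file.path(path, sprintf("frame_%04d.%s", f, format))
    m <- stream$frames[, , f]
    if (format == "png") {
      png::writePNG(m / 255, target = file)
    } else {
      .write_pgm(m, file)
    }
  }
  writeLines(c(sprintf("fps: %g", stream$fps),
               sprintf("side_length: %d", stream$side_length),
               sprintf("n_frames: %d", nf)),
             file.path(path, .sidecar_name))
  invisible(path)
}

#' Read a frame stream from an image-sequence directory
#'
#' Reads all `.png`/`.pgm` files in `path` in lexicographic order. Color
#' frames are converted to luminance with Rec.601 weights
#' (0.299 R + 0.587 G + 0.114 B). The sidecar written by [write_frames()]
#' supplies `fps` when present (default 30 otherwise).
#'
#' @param path Directory containing the frames.
#' @return A [frame_stream].
#' @export
read_frames <- function(path) {
  if (!dir.exists(path)) stop("no such directory: ", path)
  files <- sort(list.files(path, pattern = "\\.(png|pgm)$", full.names = TRUE))
  if (!length(files)) stop("no frames (*.png, *.pgm) found in ", path)
  frames <- lapply(files, function(f) {
    m <- if (grepl("\\.png$", f)) .read_png_gray(f) else .read_pgm(f)
    if (is.null(m)) stop("unreadable frame: ", f)
    m
  })
  dims <- unique(lapply(frames, dim))
  if (length(dims) != 1) {
    bad <- files[which(vapply(frames, function(m)
      !identical(dim(m), dim(frames[[1]])), logical(1)))[1]]
    stop("mixed frame sizes; first offending frame: ", bad)
  }
  fps <- 30
  sc <- file.path(path, .sidecar_name)
  if (file.exists(sc)) {
    kv <- readLines(sc)
    m <- grep("^fps:", kv, value = TRUE)
    if (length(m)) fps <- as.numeric(sub("^fps:\\s*", "", m[1]))
  }
  frame_stream(frames, fps = fps)
}

.read_png_gray <- function(file) {
  a <- png::readPNG(file)
  if (length(dim(a)) == 3) {
    if (dim(a)[3] >= 3) {
      a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
    } else {
      a <- a[, , 1]
    }
  }
  round(a * 255)
}

# Minimal PGM codec (P2 plain text and P5 binary, maxval <= 255). No
# installed package reads PGM; the format is the package's text-fixture
# format of choice.
.read_pgm <- function(file) {
  con <- file(file, "rb")
  on.exit(close(con))
  magic <- rawToChar(readBin(con, "raw", 2))
  if (!magic %in% c("P2", "P5")) stop("not a PGM (P2/P5) file: ", file)
  # read header tokens, skipping whitespace and '#' comments
  tokens <- character(0)
  buf <- character(0)
  while (length(tokens) < 3) {
    ch <- rawToChar(readBin(con, "raw", 1))
    if (!length(ch) || ch == "") stop("truncated PGM header: ", file)
    if (ch == "#") {
      repeat {
        ch <- rawToChar(readBin(con, "raw", 1))
        if (ch %in% c("\n", "\r")) break
      }
      ch <- " "
    }
    if (grepl("[[:space:]]", ch)) {
      if (length(buf)) { tokens <- c(tokens, paste(buf, collapse = "")); buf <- character(0) }
    } else buf <- c(buf, ch)
  }
  w <- as.integer(tokens[1]); h <- as.integer(tokens[2])
  maxval <- as.integer(tokens[3])
  if (is.na(w) || is.na(h) || maxval > 255)
    stop("unsupported PGM header in ", file)
  if (magic == "P5") {
    vals <- as.integer(readBin(con, "raw", w * h))
  } else {
    txt <- readChar(con, file.size(file), useBytes = TRUE)
    vals <- as.integer(strsplit(trimws(txt), "[[:space:]]+")[[1]])
  }
  if (length(vals) < w * h) stop("truncated PGM data in ", file)
  matrix(vals[seq_len(w * h)] * (255 / maxval), nrow = h, ncol = w,
         byrow = TRUE)
}

.write_pgm <- function(m, file) {
  con <- file(file, "wt")
  on.exit(close(con))
  writeLines(c("P2", paste(ncol(m), nrow(m)), "255"), con)
  apply(m, 1, function(r) writeLines(paste(as.integer(r), collapse = " "), con))
  invisible(file)
}
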