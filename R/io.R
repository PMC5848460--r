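#' Write an RGB image as portable pixmap (PPM)
#'
#' Lossless 8-bit RGB container used for all on-disk images. Binary P6 by
#' default; `ascii = TRUE` writes plain-text P3 (useful for tiny fixtures).
#' The pixel scale (px/um) is recorded in a header comment so a round trip
#' preserves physical units.
#'
#' @param img An [rgb_image()].
#' @param path Output file path (conventionally `.ppm`).
#' @param ascii Write ASCII P3 instead of binary P6.
#' @return `path`, invisibly.
#' @export
write_ppm <- function(img, path, ascii = FALSE) {
  stopifnot(inherits(img, "rgb_image"))
  d <- dim(img$pixels)
  # interleave channels row-major: R G B per pixel, rows top to bottom
  flat <- aperm(img$pixels, c(3, 2, 1))  # channel, col, row
  vals <- as.integer(flat)
  header <- sprintf("%s\n# pixel_scale %.17g px/um\n%d %d\n255\n",
                    if (ascii) "P3" else "P6", img$pixel_scale, d[2], d[1])
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  if (ascii) {
    writeChar(paste(vals, collapse = " "), con, eos = NULL)
    writeChar("\n", con, eos = NULL)
  } else {
    writeBin(as.raw(vals), con)
  }
  invisible(path)
}

#' Read a portable pixmap (PPM) image
#'
#' Reads P3 (ASCII) or P6 (binary) pixmaps written by [write_ppm()] or other
#' tools. A `# pixel_scale <s> px/um` header comment restores the physical
#' scale; otherwise `pixel_scale` must be supplied.
#'
#' @param path PPM file path.
#' @param pixel_scale Pixels per micrometer; overrides any header comment.
#' @return An [rgb_image()].
#' @export
read_ppm <- function(path, pixel_scale = NULL) {
  con <- file(path, "rb")
  on.exit(close(con))
  read_token <- function() {
    tok <- character(0)
    repeat {
      ch <- readChar(con, 1, useBytes = TRUE)
      if (length(ch) == 0) break
      if (ch == "#") {  # comment to end of line
        line <- ""
        repeat {
          c2 <- readChar(con, 1, useBytes = TRUE)
          if (length(c2) == 0 || c2 == "\n") break
          line <- paste0(line, c2)
        }
        m <- regmatches(line, regexec("pixel_scale\\s+([0-9.eE+-]+)", line))[[1]]
        if (length(m) == 2 && is.null(pixel_scale)) {
          pixel_scale <<- as.numeric(m[2])
        }
        next
      }
      if (grepl("\\s", ch)) {
        if (length(tok) > 0) break else next
      }
      tok <- c(tok, ch)
    }
    paste(tok, collapse = "")
  }
  magic <- read_token()
  if (!magic %in% c("P3", "P6")) stop("not a P3/P6 pixmap: ", path)
  w <- as.integer(read_token())
  h <- as.integer(read_token())
  maxval <- as.integer(read_token())
  if (is.na(w) || is.na(h) || maxval != 255L) stop("unsupported PPM header")
  n <- w * h * 3L
  vals <- if (magic == "P6") {
    as.integer(readBin(con, "raw", n = n))
  } else {
    scan(con, what = integer(), n = n, quiet = TRUE)
  }
  if (length(vals) != n) stop("truncated pixel data in ", path)
  if (is.null(pixel_scale)) stop("pixel_scale not in header; supply it")
  px <- aperm(array(vals, dim = c(3, w, h)), c(3, 2, 1))
  rgb_image(px, pixel_scale)
}
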