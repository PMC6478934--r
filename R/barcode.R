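#' Convert a data matrix to a pre-data-matrix barcode (PDMB)
#'
#' Maps each 1-bit to a dark module and each 0-bit to a white module,
#' producing the unframed module grid of the barcode.
#'
#' @param matrix A `data_matrix` (or paths accepted by [encrypt_sort()]).
#' @return A `pdmb`: logical matrix (`TRUE` = dark) with attributes `framed`
#'   (FALSE) and `quiet_zone` (0).
#' @examples
#' p <- matrix_to_pdmb(encrypt_sort(extract_paths(dendrimer("DN-011-G1"))))
#' dim(p)   # 6 x 9
#' @export
matrix_to_pdmb <- function(matrix) {
  if (!inherits(matrix, "data_matrix")) matrix <- encrypt_sort(matrix)
  grid <- as.matrix(matrix) == 1L
  new_pdmb(grid, framed = FALSE)
}

new_pdmb <- function(grid, framed) {
  structure(grid, framed = framed, quiet_zone = 0L,
            class = c("pdmb", class(grid)))
}

#' Frame a PDMB with finder and timing patterns
#'
#' Adds the one-module Data-Matrix-style frame: a solid dark "L" along the
#' left column and bottom row (the finder pattern), and an alternating
#' dark/white timing pattern along the top row and right column, each phase
#' starting dark at the corner adjacent to the solid L (top-left for the top
#' row, bottom-right for the right column).  Where the two timing edges meet
#' at the top-right corner, dark wins.  Output is monochrome.
#'
#' @param pdmb An unframed `pdmb`.
#' @return A framed `pdmb`, two modules larger in each dimension.
#' @examples
#' p <- add_finder_patterns(matrix_to_pdmb(encrypt_sort(c("10", "01"))))
#' dim(p)   # 4 x 4
#' @export
add_finder_patterns <- function(pdmb) {
  stopifnot(inherits(pdmb, "pdmb"))
  if (isTRUE(attr(pdmb, "framed")))
    stop("PDMB is already framed", call. = FALSE)
  r <- nrow(pdmb); c <- ncol(pdmb)
  g <- matrix(FALSE, r + 2L, c + 2L)
  g[2:(r + 1L), 2:(c + 1L)] <- unclass(pdmb)
  g[, 1L] <- TRUE                      # solid left column
  g[r + 2L, ] <- TRUE                  # solid bottom row
  g[1L, seq(1L, c + 2L, by = 2L)] <- TRUE          # top timing, dark at left
  dark_rows <- which((r + 2L - seq_len(r + 2L)) %% 2L == 0L)
  g[dark_rows, c + 2L] <- TRUE         # right timing, dark at bottom
  new_pdmb(g, framed = TRUE)
}

#' @export
print.pdmb <- function(x, ...) {
  cat(sprintf("<pdmb> %d x %d modules (%s, %d dark)\n",
              nrow(x), ncol(x),
              if (isTRUE(attr(x, "framed"))) "framed" else "unframed",
              sum(x)))
  for (i in seq_len(nrow(x)))
    cat(" ", paste(ifelse(x[i, ], "#", "."), collapse = ""), "\n", sep = "")
  invisible(x)
}

#' @export
plot.pdmb <- function(x, ...) {
  g <- unclass(x)
  graphics::image(t(g[rev(seq_len(nrow(g))), , drop = FALSE]),
                  col = c("white", "black"), axes = FALSE, asp = nrow(g) / ncol(g),
                  ...)
  invisible(x)
}

#' Render a PDMB as a portable bitmap (P1)
#'
#' Deterministic plain-text raster output: each module becomes a
#' `scale x scale` block of pixels, surrounded by a white quiet zone.  The
#' same input always yields byte-identical output.
#'
#' @param pdmb A `pdmb`.
#' @param scale Pixels per module, `>= 1`.
#' @param quiet_zone White border width in modules.
#' @param file Optional path; when given the bitmap is written there.
#' @return The P1 bitmap as a single character string (invisibly when `file`
#'   is given).
#' @examples
#' cat(render_pbm(matrix_to_pdmb(encrypt_sort(c("10", "01")))))
#' @seealso [read_pbm()] for the exact inverse, [render_svg()].
#' @export
render_pbm <- function(pdmb, scale = 1L, quiet_zone = 0L, file = NULL) {
  px <- pdmb_pixels(pdmb, scale, quiet_zone)
  body <- apply(px, 1L, function(row) paste(as.integer(row), collapse = " "))
  out <- paste0("P1\n", ncol(px), " ", nrow(px), "\n",
                paste(body, collapse = "\n"), "\n")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

#' Render a PDMB as a scalable vector graphic
#'
#' @inheritParams render_pbm
#' @return SVG text as a single character string (invisibly when `file` is
#'   given); one `rect` per dark module over a white background.
#' @export
render_svg <- function(pdmb, scale = 10L, quiet_zone = 1L, file = NULL) {
  stopifnot(inherits(pdmb, "pdmb"))
  if (scale < 1L) stop("scale must be >= 1", call. = FALSE)
  r <- nrow(pdmb); c <- ncol(pdmb)
  w <- (c + 2L * quiet_zone) * scale
  h <- (r + 2L * quiet_zone) * scale
  rects <- character(0)
  for (i in seq_len(r)) for (j in seq_len(c)) {
    if (pdmb[i, j])
      rects <- c(rects, sprintf(
        '<rect x="%d" y="%d" width="%d" height="%d"/>',
        (j - 1L + quiet_zone) * scale, (i - 1L + quiet_zone) * scale,
        scale, scale))
  }
  out <- paste0(
    sprintf('<svg xmlns="http://www.w3.org/2000/svg" width="%d" height="%d">',
            w, h),
    sprintf('<rect width="%d" height="%d" fill="white"/>', w, h),
    '<g fill="black">', paste(rects, collapse = ""), "</g></svg>\n")
  if (!is.null(file)) {
    writeLines(out, file, sep = "")
    return(invisible(out))
  }
  out
}

pdmb_pixels <- function(pdmb, scale, quiet_zone) {
  stopifnot(inherits(pdmb, "pdmb"))
  if (!is.numeric(scale) || scale < 1L)
    stop("scale must be >= 1", call. = FALSE)
  scale <- as.integer(scale); quiet_zone <- as.integer(quiet_zone)
  g <- unclass(pdmb)
  big <- g[rep(seq_len(nrow(g)), each = scale),
           rep(seq_len(ncol(g)), each = scale), drop = FALSE]
  if (quiet_zone > 0L) {
    q <- quiet_zone * scale
    framed <- matrix(FALSE, nrow(big) + 2L * q, ncol(big) + 2L * q)
    framed[q + seq_len(nrow(big)), q + seq_len(ncol(big))] <- big
    big <- framed
  }
  big
}

#' Read a portable bitmap (P1) back into a module grid
#'
#' Exact inverse of [render_pbm()] at `scale = 1, quiet_zone = 0`; for other
#' settings it recovers the pixel matrix.
#'
#' @param x P1 text (single string or lines), or a file path.
#' @return Logical pixel matrix, `TRUE` = dark.
#' @export
read_pbm <- function(x) {
  if (length(x) == 1L && file.exists(x)) x <- readLines(x)
  lines <- unlist(strsplit(x, "\n", fixed = TRUE))
  lines <- lines[!grepl("^#", lines)]
  lines <- lines[nzchar(trimws(lines))]
  if (toupper(trimws(lines[[1]])) != "P1")
    stop("not a P1 portable bitmap", call. = FALSE)
  tokens <- unlist(strsplit(paste(lines[-1L], collapse = " "), "[[:space:]]+"))
  tokens <- tokens[nzchar(tokens)]
  wd <- as.integer(tokens[[1]]); ht <- as.integer(tokens[[2]])
  bits <- as.integer(tokens[-(1:2)])
  if (length(bits) != wd * ht) stop("pixel count mismatch", call. = FALSE)
  matrix(bits == 1L, nrow = ht, ncol = wd, byrow = TRUE)
}
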