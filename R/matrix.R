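#' Canonicalise binary paths into the encrypted data matrix
#'
#' Treats each binary path as a row of a 0/1 matrix and applies the
#' encryption rule "1 > 0, right to left, upper": rows are compared bit by
#' bit starting from the rightmost column, and at the first differing column
#' the row holding the 1 is placed nearer the top.  Any of the `k!`
#' arrangements of `k` rows therefore collapses to one unique matrix; the
#' sort is idempotent and invariant to input order.  Equal rows (impossible
#' for a true path set, possible via direct calls) keep their input order.
#'
#' @param paths A `path_set` or character vector of equal-length bit strings.
#' @return A `data_matrix`: list with `rows` (ordered character vector),
#'   `n_rows`, `n_cols`.
#' @examples
#' encrypt_sort(c("10", "01"))$rows   # "01" then "10"
#' @export
encrypt_sort <- function(paths) {
  rows <- as.character(paths)
  if (length(rows) == 0L) stop("empty path set", call. = FALSE)
  widths <- nchar(rows)
  if (length(unique(widths)) != 1L)
    stop("ragged rows: all paths must have equal length", call. = FALSE)
  if (!all(grepl("^[01]+$", rows)))
    stop("rows must be bit strings over {0,1}", call. = FALSE)
  reversed <- vapply(strsplit(rows, ""),
                     function(ch) paste(rev(ch), collapse = ""),
                     character(1))
  # Radix order is stable and locale-independent; decreasing on the reversed
  # string puts a 1 in the rightmost differing position in the upper row.
  ord <- order(reversed, method = "radix", decreasing = TRUE)
  structure(list(rows = rows[ord], n_rows = length(rows),
                 n_cols = widths[[1]]),
            class = "data_matrix")
}

#' @export
print.data_matrix <- function(x, ...) {
  cat(sprintf("<data_matrix> %d x %d\n", x$n_rows, x$n_cols))
  cat(paste0("  ", utils::head(x$rows, 20L), collapse = "\n"), "\n")
  if (x$n_rows > 20L) cat(sprintf("  ... and %d more rows\n", x$n_rows - 20L))
  invisible(x)
}

#' @export
as.matrix.data_matrix <- function(x, ...) {
  do.call(rbind, lapply(strsplit(x$rows, ""), as.integer))
}

#' Number of possible row arrangements of a path set
#'
#' The `k` rows of a data matrix can be stacked in `k!` orders, each a
#' different pre-encryption matrix; the encryption sort collapses all of them
#' into one.  The count is exact: computed in arbitrary precision and
#' returned as a decimal digit string (path sets grow quickly — a
#' second-generation dendrimer already has 1572 rows).
#'
#' @param paths A `path_set`, character vector of paths, or `data_matrix`.
#' @return Exact factorial of the number of paths, as a decimal character
#'   string (`"720"` for 6 paths).
#' @examples
#' count_row_arrangements(extract_paths(dendrimer("DN-011-G1")))   # "720"
#' @export
count_row_arrangements <- function(paths) {
  k <- if (inherits(paths, "data_matrix")) paths$n_rows else length(paths)
  if (k < 1L) stop("empty path set", call. = FALSE)
  factorial_exact(k)
}

# Exact n! as a decimal string; digits held little-endian in base 1e4.
factorial_exact <- function(n) {
  limbs <- 1
  for (f in seq_len(n)) {
    limbs <- limbs * f
    carry <- 0
    for (i in seq_along(limbs)) {
      tot <- limbs[[i]] + carry
      limbs[[i]] <- tot %% 10000
      carry <- tot %/% 10000
    }
    while (carry > 0) {
      limbs <- c(limbs, carry %% 10000)
      carry <- carry %/% 10000
    }
  }
  head_limb <- as.character(limbs[[length(limbs)]])
  rest <- vapply(rev(limbs[-length(limbs)]),
                 function(l) sprintf("%04d", l), character(1))
  paste0(head_limb, paste(rest, collapse = ""))
}
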