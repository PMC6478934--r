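#' Storage capacity of a data matrix
#'
#' Converts the module count of a dendrimer's canonical data matrix into
#' usable storage under an error-correction reservation, following the plain
#' Data-Matrix-style accounting: `bits = floor(modules * (1 - correction))`
#' and `bytes = floor(bits / 8)`.  The default correction level of 11%
#' ("normal" level) gives 48 bits for the 6 x 9 matrix of DN-011-G1 and 3672
#' bytes for DN-011-G2.  No error-correction codewords are actually computed;
#' the level is a capacity reservation only.
#'
#' @param matrix A `data_matrix` (or a `path_set`/character vector, which is
#'   canonicalised first).  An empty matrix yields a zero-capacity report.
#' @param correction Fraction of modules reserved for error correction,
#'   `0 <= correction < 1`.  Default `0.11`.
#' @return A `capacity_report`: list with `modules`, `correction`, `bits`,
#'   `bytes`.
#' @examples
#' m <- encrypt_sort(extract_paths(dendrimer("DN-011-G1")))
#' storage_capacity(m)   # 54 modules -> 48 bits
#' @export
storage_capacity <- function(matrix, correction = 0.11) {
  if (!inherits(matrix, "data_matrix")) {
    if (length(matrix) == 0L)
      return(structure(list(modules = 0L, correction = correction,
                            bits = 0L, bytes = 0L),
                       class = "capacity_report"))
    matrix <- encrypt_sort(matrix)
  }
  if (!is.numeric(correction) || length(correction) != 1L ||
      correction < 0 || correction >= 1)
    stop("correction must be a single fraction in [0, 1)", call. = FALSE)
  modules <- matrix$n_rows * matrix$n_cols
  # small epsilon guards the floor against binary representation of the
  # correction fraction (e.g. 100 * 0.89 landing a hair under 89)
  bits <- floor(modules * (1 - correction) + 1e-9)
  structure(list(modules = modules, correction = correction,
                 bits = as.integer(bits), bytes = as.integer(bits %/% 8)),
            class = "capacity_report")
}

#' @export
print.capacity_report <- function(x, ...) {
  cat(sprintf(
    "<capacity_report> %d modules, %.0f%% correction -> %d bits (%d bytes)\n",
    x$modules, 100 * x$correction, x$bits, x$bytes))
  invisible(x)
}
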