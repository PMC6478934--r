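#' Build the bit-labelled rooted tree of a dendrimer
#'
#' Expands a [dendrimer_spec][parse_notation] into its unit tree by divergent
#' growth: generation 0 is the bare focal monomer (three units: the focal
#' sub-unit plus its two periphery sub-units); at each further generation a
#' fresh monomer is attached to every periphery unit, its focal unit becoming
#' that periphery unit's single child.  Child order within a monomer is the
#' code order, left child first, so two builds of the same spec are
#' structurally identical.
#'
#' For a two-branch monomer family the tree has `3 * (2^(n+1) - 1)` units and
#' `2^(n+1)` leaves at generation `n`.
#'
#' @param spec A `dendrimer_spec`, or a notation string.
#' @return A `dendrimer_tree`: a list with parallel per-unit vectors `bit`
#'   (0/1), `parent` (index, `NA` at the root), `depth` (root = 0), `role`
#'   (`"focal"`, `"growth-link"`, `"monomer-focal"`, `"leaf"`), a `children`
#'   list, and the originating `spec`.  Units are stored in preorder.
#' @examples
#' tr <- build_tree(parse_notation("DN-011-G1"))
#' tr$unit_count    # 9
#' tr$leaf_count    # 4
#' @export
build_tree <- function(spec) {
  if (is.character(spec)) spec <- parse_notation(spec)
  stopifnot(inherits(spec, "dendrimer_spec"))
  n <- spec$generation

  bit <- integer(0); parent <- integer(0); depth <- integer(0)
  role <- character(0)
  add_unit <- function(b, par, d, r) {
    bit[[length(bit) + 1L]] <<- b
    parent[[length(parent) + 1L]] <<- par
    depth[[length(depth) + 1L]] <<- d
    role[[length(role) + 1L]] <<- r
    length(bit)
  }
  # Attach the monomer of generation g below unit `par` (NA for the root).
  add_monomer <- function(par, g) {
    bits <- monomer_bits(schedule_code(spec, g))
    d <- if (is.na(par)) 0L else depth[[par]] + 1L
    focal <- add_unit(bits[1], par, d,
                      if (is.na(par)) "focal" else "monomer-focal")
    for (b in bits[2:3]) {
      child <- add_unit(b, focal, d + 1L,
                        if (g < n) "growth-link" else "leaf")
      if (g < n) add_monomer(child, g + 1L)
    }
    focal
  }
  add_monomer(NA_integer_, 0L)

  children <- rep(list(integer(0)), length(bit))
  for (v in seq_along(parent)) {
    p <- parent[[v]]
    if (!is.na(p)) children[[p]] <- c(children[[p]], v)
  }
  structure(
    list(spec = spec, bit = bit, parent = parent, depth = depth,
         role = role, children = children,
         unit_count = length(bit),
         leaf_count = sum(lengths(children) == 0L)),
    class = "dendrimer_tree")
}

#' Parse and build a dendrimer in one step
#'
#' Convenience wrapper: `dendrimer("DN-011-G1")` is
#' `build_tree(parse_notation("DN-011-G1"))`.  A `dendrimer_spec` or an
#' already-built `dendrimer_tree` passes through unchanged.
#'
#' @param x Notation string, `dendrimer_spec`, or `dendrimer_tree`.
#' @return A `dendrimer_tree`.
#' @examples
#' dendrimer("DN-011-G0")
#' @export
dendrimer <- function(x) {
  if (inherits(x, "dendrimer_tree")) return(x)
  build_tree(x)
}

#' Count the 0- and 1-bits of a dendrimer tree
#'
#' The bit multiset of the whole molecule; it drives the calibrated precursor
#' mass (each extra 1-bit adds one C2H4 relative to a 0-bit).
#'
#' @param tree A `dendrimer_tree` (or anything [dendrimer()] accepts).
#' @return Named integer vector `c(zeros = , ones = )`; the two counts sum to
#'   the unit count.
#' @examples
#' bit_multiset(dendrimer("DN-011-G1"))   # 3 zeros, 6 ones
#' @export
bit_multiset <- function(tree) {
  tree <- dendrimer(tree)
  c(zeros = sum(tree$bit == 0L), ones = sum(tree$bit == 1L))
}

#' @export
print.dendrimer_tree <- function(x, ...) {
  bm <- bit_multiset(x)
  cat(sprintf("<dendrimer_tree> %s\n", format(x$spec)))
  cat(sprintf("  %d units (%d x 0-bit, %d x 1-bit), %d leaves, depth %d\n",
              x$unit_count, bm[["zeros"]], bm[["ones"]],
              x$leaf_count, max(x$depth)))
  invisible(x)
}

#' @export
format.dendrimer_tree <- function(x, ...) format(x$spec)
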