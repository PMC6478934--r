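#' Enumerate the distinct binary paths of a dendrimer
#'
#' A binary path is the bit string read along one topological ordering of the
#' unit tree (root first, every parent before its children) — equivalently,
#' the reversal of one order of cleaving units one by one from the periphery
#' terminals to the focal core.  Distinct orderings that read the same string
#' collapse: the path set is a set of strings, and it is the molecule's
#' MS/MS-accessible information content.
#'
#' Implementation: recursive shuffle product.  The path set of a unit is its
#' bit prepended to the deduplicated shuffle product of its child subtrees'
#' path sets, memoised on canonical subtree shape so that symmetric branches
#' share work.  `DN-011-G1` yields 6 paths; `DN-011-G2` yields 1572.
#'
#' @param tree A `dendrimer_tree` (or anything [dendrimer()] accepts).
#' @return A `path_set`: sorted character vector of distinct equal-length bit
#'   strings, focal bit first, with attribute `unit_count`.
#' @examples
#' extract_paths(dendrimer("DN-011-G1"))
#' @seealso [brute_force_paths()] for the explicit-enumeration oracle,
#'   [encrypt_sort()] for the canonical matrix.
#' @export
extract_paths <- function(tree) {
  tree <- dendrimer(tree)
  memo <- new.env(parent = emptyenv())

  shape_key <- function(v) {
    kids <- tree$children[[v]]
    if (length(kids) == 0L) return(as.character(tree$bit[[v]]))
    sub <- sort(vapply(kids, shape_key, character(1)))
    paste0(tree$bit[[v]], "(", paste(sub, collapse = ","), ")")
  }
  node_paths <- function(v) {
    key <- shape_key(v)
    hit <- memo[[key]]
    if (!is.null(hit)) return(hit)
    kids <- tree$children[[v]]
    res <- if (length(kids) == 0L) {
      as.character(tree$bit[[v]])
    } else if (length(kids) == 1L) {
      paste0(tree$bit[[v]], node_paths(kids[[1]]))
    } else {
      paste0(tree$bit[[v]], shuffle_sets(node_paths(kids[[1]]),
                                         node_paths(kids[[2]])))
    }
    memo[[key]] <- res
    res
  }
  new_path_set(node_paths(1L), tree$unit_count)
}

new_path_set <- function(paths, unit_count) {
  structure(sort(unique(paths)), unit_count = unit_count,
            class = "path_set")
}

#' @export
print.path_set <- function(x, ...) {
  cat(sprintf("<path_set> %d distinct binary path%s of length %d\n",
              length(x), if (length(x) == 1L) "" else "s",
              nchar(x[[1]])))
  show <- utils::head(unclass(x), 10L)
  cat(paste0("  ", show, collapse = "\n"), "\n")
  if (length(x) > 10L) cat(sprintf("  ... and %d more\n", length(x) - 10L))
  invisible(x)
}

# Deduplicated shuffle product of two sets of words.
shuffle_sets <- function(A, B) {
  out <- character(0)
  # shuffle(a, b) == shuffle(b, a): visit unordered pairs once.
  pairs <- unique_word_pairs(A, B)
  for (p in pairs) out <- c(out, shuffle_words(p[[1]], p[[2]]))
  unique(out)
}

unique_word_pairs <- function(A, B) {
  seen <- new.env(parent = emptyenv())
  pairs <- list()
  for (a in A) for (b in B) {
    key <- if (a <= b) paste(a, b) else paste(b, a)
    if (is.null(seen[[key]])) {
      seen[[key]] <- TRUE
      pairs[[length(pairs) + 1L]] <- c(a, b)
    }
  }
  pairs
}

# All distinct interleavings of two words, by suffix-grid dynamic programme.
shuffle_words <- function(a, b) {
  ca <- strsplit(a, "")[[1]]; cb <- strsplit(b, "")[[1]]
  n <- length(ca); m <- length(cb)
  dp <- vector("list", (n + 1L) * (m + 1L))
  idx <- function(i, j) (i - 1L) * (m + 1L) + j
  for (i in (n + 1L):1L) {
    for (j in (m + 1L):1L) {
      res <- character(0)
      if (i <= n) res <- paste0(ca[[i]], dp[[idx(i + 1L, j)]])
      if (j <= m) res <- c(res, paste0(cb[[j]], dp[[idx(i, j + 1L)]]))
      if (i > n && j > m) res <- ""
      dp[[idx(i, j)]] <- unique(res)
    }
  }
  dp[[idx(1L, 1L)]]
}

#' Enumerate binary paths by explicit topological-order search (oracle)
#'
#' Walks every topological ordering of the unit tree explicitly (maintaining
#' the frontier of units whose parent has been emitted) and collects the
#' distinct bit strings.  Exponential in tree size; guarded to at most 12
#' units.  Exists as an independent check of [extract_paths()].
#'
#' @inheritParams extract_paths
#' @return A `path_set`, additionally carrying attribute `n_orderings`, the
#'   total number of topological orderings walked (before deduplication).
#' @examples
#' brute_force_paths(dendrimer("DN-011-G0"))
#' @export
brute_force_paths <- function(tree) {
  tree <- dendrimer(tree)
  if (tree$unit_count > 12L)
    stop(sprintf("brute_force_paths is limited to 12 units (tree has %d)",
                 tree$unit_count), call. = FALSE)
  seen <- new.env(parent = emptyenv())
  n_orderings <- 0L
  rec <- function(frontier, prefix) {
    if (length(frontier) == 0L) {
      n_orderings <<- n_orderings + 1L
      assign(prefix, TRUE, envir = seen)
      return(invisible())
    }
    for (k in seq_along(frontier)) {
      v <- frontier[[k]]
      rec(c(frontier[-k], tree$children[[v]]),
          paste0(prefix, tree$bit[[v]]))
    }
  }
  rec(1L, "")
  out <- new_path_set(ls(seen), tree$unit_count)
  attr(out, "n_orderings") <- n_orderings
  out
}
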