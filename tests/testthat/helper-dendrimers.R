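# Shared fixtures: everything is generated in code.

all_monomer_codes <- function() {
  apply(expand.grid(0:1, 0:1, 0:1), 1, paste, collapse = "")
}

# Every tree with <= 12 units reachable from the grammar: all G0 monomers
# and all G1 two-code schedules (9 units each).
small_trees <- function() {
  codes <- all_monomer_codes()
  g0 <- lapply(codes, function(c0) dendrimer(sprintf("DN-%s-G0", c0)))
  g1 <- list()
  for (c0 in codes) for (c1 in codes)
    g1[[length(g1) + 1L]] <- dendrimer(sprintf("DN-%s-%s-G1", c0, c1))
  c(g0, g1)
}

# Independent fragment oracle: cut every inter-unit linkage explicitly,
# partition units by ancestor-walking (no reuse of the package's subtree
# aggregation), and sum the composition directly.
oracle_fragment_masses <- function(tree, table) {
  prec <- precursor_mz(tree, table)$mz
  is_leaf <- lengths(tree$children) == 0L
  unit_mass <- ifelse(tree$bit == 1L, table$bit1, table$bit0) +
    ifelse(is_leaf, table$hydrogen, 0)
  has_ancestor <- function(u, v) {
    while (!is.na(u)) {
      if (u == v) return(TRUE)
      u <- tree$parent[[u]]
    }
    FALSE
  }
  out <- list()
  for (v in which(!is.na(tree$parent))) {
    inside <- vapply(seq_len(tree$unit_count), has_ancestor, logical(1), v = v)
    D <- sum(unit_mass[inside])
    out[[length(out) + 1L]] <- data.frame(
      side = c("t", "a"),
      mz = c(prec - D + table$hydrogen, D - table$hydrogen + table$sodium))
  }
  do.call(rbind, out)
}
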