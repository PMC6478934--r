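#' Composition and calibration table for the mass engine
#'
#' Holds the unit masses, adduct/end-group constants and calibration anchors
#' from which precursor and fragment m/z values are computed.  All masses are
#' monoisotopic, in Da, and refer to the furan-free species actually observed
#' ([M+Na-nFu]+ precursors): the furans protecting the periphery maleimides
#' are lost by retro-Diels-Alder before/at ionisation.
#'
#' Defaults: the 0-bit (butyl) unit residue is 184.0432 (C8H10NO2S) and the
#' 1-bit (hexyl) residue exceeds it by exactly one C2H4 (28.0313), i.e.
#' 212.0745 (C10H14NO2S); each free (leaf) maleimide carries one extra H
#' relative to a thioether-linked unit; the focal end group (thioacetyl cap
#' remainder) contributes 41.0022.  These constants jointly reproduce the
#' additive-consistent calculated precursor masses of the DN family to
#' 0.01 Da, with no per-dendrimer fitting.
#'
#' @param bit0 Monoisotopic residue mass of a linked 0-bit (butyl) unit.
#' @param bit_delta Hexyl-minus-butyl mass difference (C2H4).
#' @param bit1 Monoisotopic residue mass of a linked 1-bit (hexyl) unit.
#' @param hydrogen,sodium,furan Monoisotopic H, Na and furan masses.
#' @param end_group Named vector of focal end-group mass constants per
#'   family.  The DR core composition is not determined by the DN data and
#'   must be supplied by the user for composition-mode DR masses.
#' @param anchors Data frame of calibration anchors
#'   (`name`, `family`, `generation`, `mz`): printed `[M+Na-nFu]+` values for
#'   one dendrimer per topology class, used by the calibrated precursor mode.
#' @param tolerance Default peak-matching tolerance in Da (MALDI-TOF
#'   reflector scale).
#' @return A `composition_table` list.
#' @examples
#' composition_table()
#' @export
composition_table <- function(bit0 = 184.0432,
                              bit_delta = 28.0313,
                              bit1 = bit0 + bit_delta,
                              hydrogen = 1.00783,
                              sodium = 22.98977,
                              furan = 68.0262,
                              end_group = c(DN = 41.0022),
                              anchors = default_anchors(),
                              tolerance = 0.5) {
  stopifnot(bit0 > 0, bit1 > 0, hydrogen > 0, sodium > 0, furan > 0)
  structure(list(bit0 = bit0, bit1 = bit1, bit_delta = bit_delta,
                 bit0_nominal = 184, bit1_nominal = 212,
                 hydrogen = hydrogen, sodium = sodium, furan = furan,
                 end_group = end_group, anchors = anchors,
                 tolerance = tolerance),
            class = "composition_table")
}

#' @export
print.composition_table <- function(x, ...) {
  cat("<composition_table>\n")
  cat(sprintf("  0-bit %.4f, 1-bit %.4f (delta %.4f), Na %.5f, H %.5f\n",
              x$bit0, x$bit1, x$bit_delta, x$sodium, x$hydrogen))
  cat(sprintf("  anchors: %s\n",
              paste(sprintf("%s=%.2f", x$anchors$name, x$anchors$mz),
                    collapse = ", ")))
  invisible(x)
}

default_anchors <- function() {
  data.frame(
    name = c("DN-011-G1", "DN-011-G2", "DR-011-G1", "DR-011-G2"),
    family = c("DN", "DN", "DR", "DR"),
    generation = c(1L, 2L, 1L, 2L),
    mz = c(1892.60, 4329.40, 1599.49, 4036.29),
    stringsAsFactors = FALSE)
}

# Residue sum of a set of units plus the maleimide H of each leaf among them.
unit_mass_sum <- function(tree, units, table) {
  bits <- tree$bit[units]
  leaves <- sum(lengths(tree$children[units]) == 0L)
  sum(ifelse(bits == 1L, table$bit1, table$bit0)) + leaves * table$hydrogen
}

#' Theoretical precursor m/z of a dendrimer
#'
#' Computes the `[M+Na-nFu]+` precursor, where n is the leaf (periphery
#' maleimide) count.  Two modes:
#'
#' * `"calibrated"` (default): the m/z is the anchor value of a dendrimer of
#'   identical family and generation, shifted by `bit_delta` for each 1-bit
#'   of difference.  This needs no end-group knowledge and reproduces
#'   tabulated values exactly for the anchor itself.
#' * `"composition"`: fully additive — unit residues + leaf hydrogens +
#'   family end group + Na.  Requires an `end_group` entry for the family.
#'
#' Calibrated mode falls back to composition mode when no anchor covers the
#' family/generation; if neither applies, an unsupported-structure error is
#' raised.
#'
#' @param tree A `dendrimer_tree` (or anything [dendrimer()] accepts).
#' @param table A [composition_table()].
#' @param mode `"calibrated"` or `"composition"`.
#' @return A `precursor_ion`: list with `species` (e.g. `"[M+Na-4Fu]+"`),
#'   `mz` and `n_furans`.
#' @examples
#' precursor_mz(dendrimer("DN-011-G1"))$mz          # 1892.60
#' precursor_mz(dendrimer("DN-111-000-G1"))$mz      # 1808.51
#' @export
precursor_mz <- function(tree, table = composition_table(),
                         mode = c("calibrated", "composition")) {
  tree <- dendrimer(tree)
  mode <- match.arg(mode)
  fam <- tree$spec$family
  mz <- NA_real_
  if (mode == "calibrated") {
    hit <- which(table$anchors$family == fam &
                 table$anchors$generation == tree$spec$generation)
    if (length(hit) >= 1L) {
      anchor <- table$anchors[hit[[1]], ]
      anchor_tree <- dendrimer(anchor$name)
      d_ones <- sum(tree$bit == 1L) - sum(anchor_tree$bit == 1L)
      mz <- anchor$mz + d_ones * table$bit_delta
    }
  }
  if (is.na(mz)) {
    if (!fam %in% names(table$end_group))
      stop(sprintf(paste0(
        "unsupported structure: no calibration anchor for family %s at ",
        "generation %d and no end_group composition configured"),
        fam, tree$spec$generation), call. = FALSE)
    mz <- unit_mass_sum(tree, seq_len(tree$unit_count), table) +
      table$end_group[[fam]] + table$sodium
  }
  structure(list(species = sprintf("[M+Na-%dFu]+", tree$leaf_count),
                 mz = mz, n_furans = tree$leaf_count),
            class = "precursor_ion")
}

#' @export
print.precursor_ion <- function(x, ...) {
  cat(sprintf("<precursor_ion> %s  m/z %.2f\n", x$species, x$mz))
  invisible(x)
}

#' Enumerate theoretical MS/MS fragment ions
#'
#' The succinimide-thioether S-C bond linking every pair of adjacent units
#' breaks preferentially under MS/MS.  Cleaving one such inter-unit linkage
#' splits the molecule into a focal-retaining fragment (`t` side, keeps the
#' thioacetyl core, gains the transferred H) and a periphery-retaining
#' fragment (`a` side, keeps its free maleimide ends, loses the H); both are
#' observed as sodium adducts, so every primary pair satisfies
#' `mz(t) + mz(a) = precursor + Na` exactly.
#'
#' Fragments are labelled `t<k>`/`a<k>` where `k` is the layer index of the
#' cleaved bond (depth of the cleaved child unit + 1, the focal unit being
#' depth 0); mass-degenerate fragments from symmetric branches are merged
#' into one species carrying a `multiplicity`, and species of equal side and
#' layer are suffixed `a`, `b`, ... (for the Greek branch letters) in order
#' of decreasing m/z.
#'
#' With `secondary = TRUE`, focal-retaining fragments arising from two
#' simultaneous cleavages on disjoint branches are added (labelled
#' `t[k1,k2]`); their periphery-side complements coincide with primary
#' `a`-fragments and are not duplicated.
#'
#' @inheritParams precursor_mz
#' @param secondary Also emit double-cleavage focal fragments.
#' @param merge Merge mass-degenerate fragments (default TRUE).
#' @return A data frame with columns `label`, `species`, `side`, `layer`,
#'   `retained_units`, `mz`, `multiplicity`, `secondary`.
#' @examples
#' fr <- enumerate_fragments(dendrimer("DN-011-G1"))
#' fr[fr$label == "t3a", "mz"]   # ~1283.4
#' @export
enumerate_fragments <- function(tree, table = composition_table(),
                                secondary = FALSE, merge = TRUE,
                                mode = c("calibrated", "composition")) {
  tree <- dendrimer(tree)
  mode <- match.arg(mode)
  prec <- precursor_mz(tree, table, mode)$mz

  sub_units <- subtree_units(tree)
  # one row per inter-unit linkage, identified by its child unit v
  vs <- which(!is.na(tree$parent))
  rows <- lapply(vs, function(v) {
    D <- unit_mass_sum(tree, sub_units[[v]], table)
    k <- tree$depth[[v]] + 1L
    size <- length(sub_units[[v]])
    rbind(
      data.frame(side = "t", layer = k,
                 retained_units = tree$unit_count - size,
                 mz = prec - D + table$hydrogen,
                 secondary = FALSE, stringsAsFactors = FALSE),
      data.frame(side = "a", layer = k, retained_units = size,
                 mz = D - table$hydrogen + table$sodium,
                 secondary = FALSE, stringsAsFactors = FALSE))
  })
  frags <- do.call(rbind, rows)

  if (secondary) {
    disjoint <- function(v, w)
      !(v %in% sub_units[[w]]) && !(w %in% sub_units[[v]])
    if (length(vs) >= 2L) {
      for (i in seq_len(length(vs) - 1L)) for (j in (i + 1L):length(vs)) {
        v <- vs[[i]]; w <- vs[[j]]
        if (!disjoint(v, w)) next
        D2 <- unit_mass_sum(tree, sub_units[[v]], table) +
          unit_mass_sum(tree, sub_units[[w]], table)
        frags <- rbind(frags, data.frame(
          side = "t",
          layer = NA_integer_,
          retained_units = tree$unit_count -
            length(sub_units[[v]]) - length(sub_units[[w]]),
          mz = prec - D2 + 2 * table$hydrogen,
          secondary = TRUE, stringsAsFactors = FALSE))
      }
    }
  }

  if (merge) {
    key <- sprintf("%s|%s|%.6f", frags$side,
                   ifelse(frags$secondary, "2nd", frags$layer), frags$mz)
    mult <- as.vector(base::table(key)[key])
    frags <- frags[!duplicated(key), , drop = FALSE]
    frags$multiplicity <- as.integer(mult[!duplicated(key)])
  } else {
    frags$multiplicity <- 1L
  }

  frags$label <- fragment_labels(frags)
  frags$species <- sprintf("[%s+Na]+", frags$label)
  rownames(frags) <- NULL
  frags[order(frags$secondary, frags$side, frags$layer, -frags$mz),
        c("label", "species", "side", "layer", "retained_units",
          "mz", "multiplicity", "secondary")]
}

# Branch letters within (side, layer): decreasing m/z -> a, b, c ...
fragment_labels <- function(frags) {
  lab <- character(nrow(frags))
  prim <- !frags$secondary
  groups <- split(which(prim),
                  paste(frags$side[prim], frags$layer[prim]))
  for (idx in groups) {
    ord <- idx[order(-frags$mz[idx])]
    lab[ord] <- sprintf("%s%d%s", frags$side[ord], frags$layer[ord],
                        letters[seq_along(ord)])
  }
  if (any(!prim)) {
    sec <- which(!prim)
    lab[sec] <- sprintf("t2nd.%02d", seq_along(sec))
  }
  lab
}

# List of unit-index vectors: units of the subtree rooted at each node.
subtree_units <- function(tree) {
  out <- vector("list", tree$unit_count)
  # preorder storage => children have larger indices; fill in reverse
  for (v in rev(seq_len(tree$unit_count))) {
    out[[v]] <- c(v, unlist(out[tree$children[[v]]], use.names = FALSE))
  }
  out
}
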