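#' Assign experimental peaks to theoretical fragments
#'
#' Greedy nearest-mass assignment: each peak is matched to the theoretical
#' fragment closest in m/z, provided the gap is within `tolerance`; ties
#' break deterministically toward the lower theoretical m/z.  Each peak
#' receives at most one fragment; unmatched peaks are reported as
#' unassigned.
#'
#' @param peaks A peak list: data frame with columns `mz` and `intensity`
#'   (see [read_peaklist()]), or a numeric vector of m/z values (intensities
#'   default to 1).
#' @param fragments Fragment table from [enumerate_fragments()].
#' @param tolerance Maximum |observed - theoretical| in Da, default 0.5.
#' @return Data frame with one row per peak: `peak` (index), `mz`,
#'   `intensity`, `label`, `theo_mz`, `mass_error` (observed minus
#'   theoretical), `matched`.
#' @examples
#' tr <- dendrimer("DN-011-G1")
#' fr <- enumerate_fragments(tr)
#' match_peaks(fr$mz[1:3], fr)$mass_error   # all zero
#' @export
match_peaks <- function(peaks, fragments, tolerance = 0.5) {
  peaks <- as_peaklist(peaks)
  if (!is.numeric(tolerance) || tolerance <= 0)
    stop("tolerance must be positive", call. = FALSE)
  n <- nrow(peaks)
  label <- rep(NA_character_, n)
  theo <- rep(NA_real_, n)
  if (n > 0L && nrow(fragments) > 0L) {
    # stable candidate order: increasing theoretical m/z settles ties low
    frg <- fragments[order(fragments$mz), , drop = FALSE]
    for (i in seq_len(n)) {
      d <- abs(peaks$mz[[i]] - frg$mz)
      j <- which(d == min(d))[1]
      if (d[[j]] <= tolerance) {
        label[[i]] <- frg$label[[j]]
        theo[[i]] <- frg$mz[[j]]
      }
    }
  }
  data.frame(peak = seq_len(n), mz = peaks$mz, intensity = peaks$intensity,
             label = label, theo_mz = theo,
             mass_error = peaks$mz - theo,
             matched = !is.na(label),
             stringsAsFactors = FALSE)
}

as_peaklist <- function(peaks) {
  if (is.numeric(peaks))
    peaks <- data.frame(mz = peaks, intensity = rep(1, length(peaks)))
  stopifnot(is.data.frame(peaks), all(c("mz", "intensity") %in% names(peaks)))
  if (nrow(peaks) > 0L && any(peaks$mz <= 0))
    stop("peak m/z values must be strictly positive", call. = FALSE)
  peaks
}

#' Rank candidate dendrimers against an experimental spectrum
#'
#' Scores each candidate by how completely and how intensely the observed
#' peaks cover its theoretical fragment set:
#' `score = fraction of theoretical fragment species matched by some peak
#' + fraction of total peak intensity carried by matched peaks`.
#' Candidates are ranked by decreasing score, ties broken alphabetically by
#' notation, so the ordering is deterministic.  Intended for
#' identification/anticounterfeiting reads of an unknown spectrum against a
#' dendrimer library.
#'
#' @inheritParams match_peaks
#' @param candidates List of candidate trees, specs or notation strings.
#' @param table A [composition_table()].
#' @return An `identification` data frame ranked best-first: `notation`,
#'   `score`, `frac_matched`, `intensity_share`, `n_fragments`,
#'   `n_peaks_matched`.
#' @examples
#' tr <- dendrimer("DN-011-G1")
#' peaks <- enumerate_fragments(tr)$mz
#' identify_dendrimer(peaks, c("DN-011-G1", "DN-101-G1"))[1, "notation"]
#' @export
identify_dendrimer <- function(peaks, candidates,
                               table = composition_table(),
                               tolerance = 0.5) {
  if (length(candidates) < 1L)
    stop("at least one candidate is required", call. = FALSE)
  peaks <- as_peaklist(peaks)
  if (is.character(candidates)) candidates <- as.list(candidates)
  rows <- lapply(candidates, function(cand) {
    tree <- dendrimer(cand)
    frg <- enumerate_fragments(tree, table)
    asg <- match_peaks(peaks, frg, tolerance)
    matched_species <- unique(asg$label[asg$matched])
    frac <- length(matched_species) / nrow(frg)
    total_int <- sum(peaks$intensity)
    share <- if (total_int > 0) sum(asg$intensity[asg$matched]) / total_int
             else 0
    data.frame(notation = format(tree$spec),
               score = frac + share,
               frac_matched = frac,
               intensity_share = share,
               n_fragments = nrow(frg),
               n_peaks_matched = sum(asg$matched),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$score, out$notation), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("identification", "data.frame")
  out
}

#' @export
print.identification <- function(x, ...) {
  cat("<identification> candidates ranked best-first\n")
  print.data.frame(x, digits = 4)
  invisible(x)
}
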