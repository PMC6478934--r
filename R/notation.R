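#' Parse a dendrimer notation string
#'
#' Dendrimer notation names a binary-coded dendron (`DN`) or dendrimer variant
#' (`DR`) by its monomer schedule and generation, e.g. `"DN-011-G1"` or
#' `"DN-100-011-G1"`.  Each three-character code `b b1 b2` over `{0,1}`
#' describes one branched monomer `t-b(b1 b2)-f2`: a focal sub-unit carrying
#' bit `b` (thiol side) and two periphery sub-units carrying bits `b1` and
#' `b2` (furan-protected maleimide side).  A 0-bit is a butyl spacer, a 1-bit
#' a hexyl spacer.
#'
#' The schedule holds either a single code, replicated across every
#' generation, or exactly `generation + 1` codes listed innermost first (the
#' G0 focal monomer first).  `"DN-100-011-G1"` therefore grows a `1(00)`
#' focal monomer and attaches `0(11)` monomers at generation 1.
#'
#' @param text A single non-empty notation string,
#'   `(DN|DR)-<code>(-<code>)*-G<digits>`.
#' @return A `dendrimer_spec` object: a list with elements `family`
#'   (`"DN"` or `"DR"`), `schedule` (character vector of monomer codes) and
#'   `generation` (integer >= 0).  `parse_notation(format(spec))` recovers
#'   `spec`.
#' @examples
#' parse_notation("DN-011-G1")
#' parse_notation("DN-100-011-G1")$schedule
#' @seealso [build_tree()], [dendrimer()]
#' @export
parse_notation <- function(text) {
  if (!is.character(text) || length(text) != 1L || is.na(text) || !nzchar(text))
    stop("notation must be a single non-empty string", call. = FALSE)
  tokens <- strsplit(text, "-", fixed = TRUE)[[1]]
  if (length(tokens) < 3L)
    stop(sprintf("malformed notation '%s': expected FAMILY-CODE...-Gn", text),
         call. = FALSE)
  family <- tokens[1]
  if (!family %in% c("DN", "DR"))
    stop(sprintf("unknown family token '%s' (expected DN or DR)", family),
         call. = FALSE)
  gen_tok <- tokens[length(tokens)]
  if (!grepl("^G[0-9]+$", gen_tok))
    stop(sprintf("missing or malformed generation suffix '%s'", gen_tok),
         call. = FALSE)
  generation <- as.integer(sub("^G", "", gen_tok))
  codes <- tokens[-c(1L, length(tokens))]
  if (length(codes) == 0L)
    stop(sprintf("malformed notation '%s': no monomer code", text),
         call. = FALSE)
  for (code in codes) {
    if (!grepl("^[01]{3}$", code))
      stop(sprintf("invalid monomer code '%s': must be three bits over {0,1}",
                   code), call. = FALSE)
  }
  if (length(codes) != 1L && length(codes) != generation + 1L)
    stop(sprintf(
      "schedule length %d is neither 1 nor generation+1 (= %d) in '%s'",
      length(codes), generation + 1L, text), call. = FALSE)
  new_dendrimer_spec(family, codes, generation)
}

new_dendrimer_spec <- function(family, schedule, generation) {
  structure(
    list(family = family, schedule = schedule,
         generation = as.integer(generation)),
    class = "dendrimer_spec")
}

#' @export
format.dendrimer_spec <- function(x, ...) {
  paste(c(x$family, x$schedule, sprintf("G%d", x$generation)), collapse = "-")
}

#' @export
print.dendrimer_spec <- function(x, ...) {
  cat(sprintf("<dendrimer_spec> %s\n", format(x)))
  cat(sprintf("  family: %s, generation: %d, schedule: %s%s\n",
              x$family, x$generation,
              paste(monomer_code_pretty(x$schedule), collapse = ", "),
              if (length(x$schedule) == 1L && x$generation > 0L)
                " (replicated across generations)" else ""))
  invisible(x)
}

monomer_code_pretty <- function(code) {
  sprintf("%s(%s)", substr(code, 1, 1), substr(code, 2, 3))
}

# Bits of a monomer code "b b1 b2" as integers c(b, b1, b2).
monomer_bits <- function(code) {
  as.integer(strsplit(code, "")[[1]])
}

# Code used at growth generation g (0-based) of a schedule.
schedule_code <- function(spec, g) {
  if (length(spec$schedule) == 1L) spec$schedule[[1]]
  else spec$schedule[[g + 1L]]
}
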