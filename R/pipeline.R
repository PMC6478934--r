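#' Run the full decode pipeline for one dendrimer
#'
#' Executes paths -> encryption sort -> capacity -> PDMB for a notation,
#' optionally writing a JSON report plus bitmap/vector renderings.  Each
#' stage failure is re-signalled with a stage tag so callers (and the CLI)
#' can report where the pipeline stopped.
#'
#' @param notation Dendrimer notation string.
#' @param correction Error-correction level for [storage_capacity()].
#' @param framed Frame the PDMB with finder/timing patterns.
#' @param scale,quiet_zone Rendering parameters for the written images.
#' @param out_dir Optional directory; when given, `report.json`,
#'   `barcode.pbm` and `barcode.svg` are written there.
#' @param seed Optional integer recorded in the report (the pipeline itself
#'   is deterministic).
#' @return A `dendrimer_report` list: `notation`, `spec`, `paths`, `matrix`,
#'   `capacity`, `pdmb`, `seed`, and `files` when outputs were written.
#' @examples
#' rep <- run_pipeline("DN-011-G1")
#' rep$capacity$bits   # 48
#' @export
run_pipeline <- function(notation, correction = 0.11, framed = TRUE,
                         scale = 10L, quiet_zone = 1L, out_dir = NULL,
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE))
  }
  spec <- stage("parse", parse_notation(notation))
  tree <- stage("build", build_tree(spec))
  paths <- stage("paths", extract_paths(tree))
  dm <- stage("matrix", encrypt_sort(paths))
  cap <- stage("capacity", storage_capacity(dm, correction))
  pdmb <- stage("barcode", {
    p <- matrix_to_pdmb(dm)
    if (framed) add_finder_patterns(p) else p
  })
  report <- structure(
    list(notation = format(spec), spec = spec, tree = tree,
         paths = paths, matrix = dm, capacity = cap, pdmb = pdmb,
         seed = seed),
    class = "dendrimer_report")
  if (!is.null(out_dir)) {
    stage("write", {
      dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
      files <- c(
        report = file.path(out_dir, "report.json"),
        pbm = file.path(out_dir, "barcode.pbm"),
        svg = file.path(out_dir, "barcode.svg"))
      jsonlite::write_json(report_json(report), files[["report"]],
                           auto_unbox = TRUE, pretty = TRUE, digits = NA)
      render_pbm(pdmb, scale, quiet_zone, file = files[["pbm"]])
      render_svg(pdmb, scale, quiet_zone, file = files[["svg"]])
      report$files <- files
    })
  }
  report
}

report_json <- function(report) {
  list(notation = report$notation,
       generation = report$spec$generation,
       unit_count = report$tree$unit_count,
       paths = as.character(report$paths),
       matrix = report$matrix$rows,
       n_rows = report$matrix$n_rows,
       n_cols = report$matrix$n_cols,
       modules = report$capacity$modules,
       correction = report$capacity$correction,
       bits = report$capacity$bits,
       bytes = report$capacity$bytes,
       seed = report$seed)
}

#' @export
print.dendrimer_report <- function(x, ...) {
  cat(sprintf("<dendrimer_report> %s\n", x$notation))
  cat(sprintf("  %d paths -> %d x %d matrix -> %d bits (%d bytes) at %.0f%%\n",
              length(x$paths), x$matrix$n_rows, x$matrix$n_cols,
              x$capacity$bits, x$capacity$bytes,
              100 * x$capacity$correction))
  invisible(x)
}

#' Generate a reproducible synthetic decoding fixture
#'
#' Draws a random dendrimer (family DN, generation up to `max_generation`,
#' random monomer codes, schedule either replicated or per-generation) and
#' simulates the spectrum an MS/MS read of it would produce: every
#' theoretical fragment becomes a peak with Gaussian m/z jitter, with
#' intensity proportional to its multiplicity, and uniform-random noise
#' peaks are sprinkled across the mass range.  The same seed always
#' reproduces the same fixture.
#'
#' @param seed Integer seed for the fixture's private RNG stream.
#' @param max_generation Upper bound on the drawn generation (<= 3).
#' @param table A [composition_table()].
#' @param jitter_sd Gaussian m/z jitter, Da (default 0.05, reflector-scale
#'   accuracy).
#' @param n_noise Number of uniform noise peaks.
#' @return A `dendrimer_fixture`: list with `notation`, `spec`, `tree`,
#'   `peaks` (data frame), `fragments`, `seed` and `meta`.
#' @examples
#' fx <- generate_fixture(1)
#' identical(fx$peaks, generate_fixture(1)$peaks)
#' @export
generate_fixture <- function(seed, max_generation = 2L,
                             table = composition_table(),
                             jitter_sd = 0.05, n_noise = 15L) {
  if (max_generation > 3L)
    stop("max_generation must be <= 3", call. = FALSE)
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()))
  }
  set.seed(seed)

  gen <- sample(0:max_generation, 1L)
  n_codes <- if (gen > 0L && stats::runif(1) < 0.5) gen + 1L else 1L
  codes <- vapply(seq_len(n_codes), function(i)
    paste(sample(0:1, 3L, replace = TRUE), collapse = ""), character(1))
  spec <- new_dendrimer_spec("DN", codes, gen)
  tree <- build_tree(spec)
  frg <- enumerate_fragments(tree, table)

  signal <- data.frame(
    mz = stats::rnorm(nrow(frg), frg$mz, jitter_sd),
    intensity = frg$multiplicity * stats::runif(nrow(frg), 50, 100))
  lo <- min(frg$mz) * 0.8
  hi <- max(frg$mz) * 1.05
  noise <- data.frame(mz = stats::runif(n_noise, lo, hi),
                      intensity = stats::runif(n_noise, 2, 20))
  peaks <- rbind(signal, noise)
  peaks <- peaks[order(peaks$mz), , drop = FALSE]
  rownames(peaks) <- NULL

  structure(
    list(notation = format(spec), spec = spec, tree = tree,
         peaks = peaks, fragments = frg, seed = seed,
         meta = list(max_generation = max_generation,
                     jitter_sd = jitter_sd, n_noise = n_noise)),
    class = "dendrimer_fixture")
}

#' @export
print.dendrimer_fixture <- function(x, ...) {
  cat(sprintf("<dendrimer_fixture> %s (seed %d): %d peaks (%d signal, %d noise)\n",
              x$notation, x$seed, nrow(x$peaks),
              nrow(x$fragments), x$meta$n_noise))
  invisible(x)
}

#' Read a run configuration file
#'
#' YAML or JSON dictionary of defaults for the CLI and pipeline: any of
#' `notation`, `correction`, `tolerance`, `scale`, `quiet_zone`, `seed`,
#' plus mass-table overrides under `mass` (passed to [composition_table()])
#' and extra monomer definitions under `monomers` (currently informational:
#' the grammar fixes codes to three bits).
#'
#' @param file Path to a `.yaml`/`.yml`/`.json` config file.
#' @return Named list of settings.
#' @export
read_config <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::read_json(file, simplifyVector = TRUE)
  else yaml::read_yaml(file)
  if (!is.list(cfg)) stop("config must be a mapping", call. = FALSE)
  cfg
}

# Build a composition_table from a config `mass` block (list of overrides).
config_table <- function(cfg) {
  if (is.null(cfg$mass)) return(composition_table())
  args <- cfg$mass
  if (!is.null(args$end_group)) args$end_group <- unlist(args$end_group)
  do.call(composition_table, args)
}
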