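#' Read an experimental peak list
#'
#' Two plain-text formats are supported:
#' * CSV with header `mz,intensity` (extra columns are ignored);
#' * MGF (Mascot generic format): the first `BEGIN IONS`/`END IONS` block is
#'   read, its fragment lines as `mz intensity` pairs; `PEPMASS` and `TITLE`
#'   are kept as attributes.
#'
#' @param file Path to a `.csv` or `.mgf` file.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @return Data frame with columns `mz`, `intensity`, sorted by m/z;
#'   attributes `pepmass` and `title` when present in an MGF.
#' @seealso [write_peaklist()]
#' @export
read_peaklist <- function(file, format = c("auto", "csv", "mgf")) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", file, ignore.case = TRUE)) "mgf" else "csv"
  peaks <- if (format == "mgf") read_mgf(file) else {
    df <- utils::read.csv(file)
    if (!all(c("mz", "intensity") %in% names(df)))
      stop("CSV peak list needs 'mz' and 'intensity' columns", call. = FALSE)
    df[, c("mz", "intensity")]
  }
  peaks <- as_peaklist(peaks)
  peaks[order(peaks$mz), , drop = FALSE]
}

read_mgf <- function(file) {
  lines <- trimws(readLines(file, warn = FALSE))
  begin <- which(lines == "BEGIN IONS")
  end <- which(lines == "END IONS")
  if (length(begin) == 0L || length(end) == 0L)
    stop("no BEGIN IONS/END IONS block found in MGF", call. = FALSE)
  block <- lines[(begin[[1]] + 1L):(end[[1]] - 1L)]
  meta <- grepl("=", block, fixed = TRUE)
  kv <- strsplit(block[meta], "=", fixed = TRUE)
  keys <- toupper(vapply(kv, `[[`, character(1), 1L))
  vals <- vapply(kv, function(x) paste(x[-1], collapse = "="), character(1))
  rows <- strsplit(block[!meta & nzchar(block)], "[[:space:]]+")
  peaks <- data.frame(
    mz = vapply(rows, function(r) as.numeric(r[[1]]), numeric(1)),
    intensity = vapply(rows, function(r)
      if (length(r) > 1L) as.numeric(r[[2]]) else 1, numeric(1)))
  if ("PEPMASS" %in% keys)
    attr(peaks, "pepmass") <-
      as.numeric(strsplit(vals[[which(keys == "PEPMASS")[1]]],
                          "[[:space:]]+")[[1]][[1]])
  if ("TITLE" %in% keys)
    attr(peaks, "title") <- vals[[which(keys == "TITLE")[1]]]
  peaks
}

#' Write a peak list
#'
#' @param peaks Data frame with `mz` and `intensity` (or numeric m/z
#'   vector).
#' @param file Output path.
#' @param format `"auto"` (by extension), `"csv"` or `"mgf"`.
#' @param pepmass Precursor m/z recorded in the MGF `PEPMASS` line.
#' @param title MGF `TITLE` line.
#' @return `file`, invisibly.
#' @export
write_peaklist <- function(peaks, file, format = c("auto", "csv", "mgf"),
                           pepmass = NULL, title = NULL) {
  format <- match.arg(format)
  if (format == "auto")
    format <- if (grepl("\\.mgf$", file, ignore.case = TRUE)) "mgf" else "csv"
  peaks <- as_peaklist(peaks)
  if (format == "csv") {
    utils::write.csv(peaks[, c("mz", "intensity")], file, row.names = FALSE,
                     quote = FALSE)
  } else {
    con <- file(file, "w"); on.exit(close(con))
    writeLines("BEGIN IONS", con)
    if (!is.null(title)) writeLines(sprintf("TITLE=%s", title), con)
    if (!is.null(pepmass)) writeLines(sprintf("PEPMASS=%.5f", pepmass), con)
    writeLines(sprintf("%.5f %.5f", peaks$mz, peaks$intensity), con)
    writeLines("END IONS", con)
  }
  invisible(file)
}
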