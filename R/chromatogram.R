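#' Construct a chromatogram
#'
#' A chromatogram is one antibody's elution trace: a strictly increasing
#' time grid (minutes) with UV absorbance values (mAU), plus the metadata
#' needed to place it in the experiment (antibody, condition, treatment
#' timepoint, replicate, batch) and the instrument settings (detection
#' wavelength, flow rate, run length).
#'
#' @param time_min Numeric vector, strictly increasing, in minutes.
#' @param absorbance_mAU Numeric vector, same length as `time_min`.
#' @param antibody Antibody name.
#' @param condition `"control"` or `"treated"` (negative-control background
#'   traces use `"control"` with antibody `"negative control"` by
#'   convention).
#' @param timepoint_h Treatment duration in hours: 0, 8, 16 or 24.
#' @param replicate Positive integer replicate index.
#' @param batch Batch label; the negative-control trace is shared per batch.
#' @param meta List with `wavelength_nm`, `flow_mL_per_min`,
#'   `run_length_min`. Defaults: 280 nm, 0.4 mL/min, 30 min.
#' @return A `chromatogram` object.
#' @export
chromatogram <- function(time_min, absorbance_mAU, antibody = "unknown",
                         condition = c("control", "treated"),
                         timepoint_h = 0, replicate = 1L, batch = "b1",
                         meta = list()) {
  condition <- match.arg(condition)
  time_min <- as.numeric(time_min)
  absorbance_mAU <- as.numeric(absorbance_mAU)
  if (length(time_min) != length(absorbance_mAU)) {
    stop("time and absorbance vectors differ in length (",
         length(time_min), " vs ", length(absorbance_mAU), ")")
  }
  if (length(time_min) < 8L) {
    stop("trace too short: ", length(time_min), " samples (need >= 8)")
  }
  if (anyNA(time_min) || anyNA(absorbance_mAU)) {
    stop("chromatogram contains missing values")
  }
  if (any(diff(time_min) <= 0)) {
    stop("time grid is not strictly increasing")
  }
  if (!timepoint_h %in% c(0, TIMEPOINTS_H)) {
    stop("timepoint_h must be one of 0, 8, 16, 24 (got ", timepoint_h, ")")
  }
  if (replicate < 1L) stop("replicate must be a positive integer")
  m <- utils::modifyList(DEFAULT_META, meta)
  if (m$run_length_min <= 0) stop("run_length_min must be positive")
  structure(list(
    antibody = antibody, condition = condition,
    timepoint_h = as.numeric(timepoint_h),
    replicate = as.integer(replicate), batch = batch,
    time_min = time_min, absorbance_mAU = absorbance_mAU,
    meta = m
  ), class = "chromatogram")
}

#' @export
print.chromatogram <- function(x, ...) {
  cat(sprintf(
    "<chromatogram> %s | %s, %g h, rep %d, batch %s\n  %d samples over [%.3g, %.3g] min @ %g nm, max %.3g mAU\n",
    x$antibody, x$condition, x$timepoint_h, x$replicate, x$batch,
    length(x$time_min), min(x$time_min), max(x$time_min),
    x$meta$wavelength_nm, max(x$absorbance_mAU)))
  invisible(x)
}

#' Read a chromatogram from its text format
#'
#' The on-disk format is a UTF-8 text file: comment-prefixed header lines
#' (`# key: value`) carrying the trace metadata, then a CSV body with
#' columns `time_min,absorbance_mAU`. Values round-trip at full double
#' precision (written with 17 significant digits).
#'
#' @param path File path.
#' @return A `chromatogram`.
#' @seealso [write_chromatogram()]
#' @export
read_chromatogram <- function(path) {
  raw <- readLines(path, encoding = "UTF-8")
  is_hdr <- grepl("^#", raw)
  meta_chr <- list()
  for (h in raw[is_hdr]) {
    m <- regmatches(h, regexec("^#\\s*([A-Za-z_0-9]+):\\s*(.*)\\s*$", h))[[1]]
    if (length(m) == 3L) meta_chr[[m[2]]] <- m[3]
  }
  body <- raw[!is_hdr]
  body <- body[!grepl("^\\s*$", body)]
  if (length(body) < 2L) stop("trace too short: no data rows in ", path)
  if (body[1] != "time_min,absorbance_mAU") {
    stop("unexpected column header in ", path, ": '", body[1], "'")
  }
  cells <- strsplit(body[-1], ",", fixed = TRUE)
  bad_ncol <- which(lengths(cells) != 2L)
  if (length(bad_ncol)) {
    stop("parse error at line ", sum(is_hdr) + 1L + bad_ncol[1],
         " of ", path, ": expected 2 comma-separated values")
  }
  mat <- matrix(suppressWarnings(as.numeric(unlist(cells))),
                ncol = 2L, byrow = TRUE)
  if (anyNA(mat)) {
    bad <- which(apply(is.na(mat), 1L, any))[1]
    stop("parse error at line ", sum(is_hdr) + 1L + bad, " of ", path,
         ": non-numeric cell")
  }
  num_or <- function(key, default) {
    v <- meta_chr[[key]]
    if (is.null(v)) default else as.numeric(v)
  }
  chromatogram(
    time_min = mat[, 1], absorbance_mAU = mat[, 2],
    antibody = meta_chr$antibody %||% "unknown",
    condition = meta_chr$condition %||% "control",
    timepoint_h = num_or("timepoint_h", 0),
    replicate = as.integer(num_or("replicate", 1)),
    batch = meta_chr$batch %||% "b1",
    meta = list(wavelength_nm = num_or("wavelength_nm", 280),
                flow_mL_per_min = num_or("flow_mL_per_min", 0.4),
                run_length_min = num_or("run_length_min", 30))
  )
}

#' @rdname read_chromatogram
#' @param chrom A `chromatogram`.
#' @return `write_chromatogram()` returns `path` invisibly.
#' @export
write_chromatogram <- function(chrom, path) {
  stopifnot(inherits(chrom, "chromatogram"))
  num <- function(x) formatC(x, digits = 17, format = "g")
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(c(
    sprintf("# antibody: %s", chrom$antibody),
    sprintf("# condition: %s", chrom$condition),
    sprintf("# timepoint_h: %s", num(chrom$timepoint_h)),
    sprintf("# replicate: %d", chrom$replicate),
    sprintf("# batch: %s", chrom$batch),
    sprintf("# wavelength_nm: %s", num(chrom$meta$wavelength_nm)),
    sprintf("# flow_mL_per_min: %s", num(chrom$meta$flow_mL_per_min)),
    sprintf("# run_length_min: %s", num(chrom$meta$run_length_min)),
    "time_min,absorbance_mAU",
    paste(num(chrom$time_min), num(chrom$absorbance_mAU), sep = ",")
  ), con)
  invisible(path)
}

RESULTS_COLS <- c("protein", "timepoint_h", "ratio_percent", "sd", "se",
                  "n_replicates", "converged", "change_bin", "qc_pass")

validate_results <- function(table) {
  stopifnot(is.data.frame(table))
  missing_cols <- setdiff(RESULTS_COLS, names(table))
  if (length(missing_cols)) {
    stop("results table is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  ok <- is.finite(table$ratio_percent) & table$ratio_percent > 0
  if (!all(ok)) {
    stop("ratio_percent must be finite and > 0 (rows ",
         paste(which(!ok), collapse = ", "), ")")
  }
  if (any(table$n_replicates < 2L | table$n_replicates > 6L)) {
    stop("n_replicates must be between 2 and 6")
  }
  recls <- vapply(table$ratio_percent,
                  function(r) classify_change(r)$bin, character(1))
  if (!all(recls == table$change_bin)) {
    stop("change_bin inconsistent with ratio_percent (rows ",
         paste(which(recls != table$change_bin), collapse = ", "), ")")
  }
  invisible(table)
}

#' Write / read a results table
#'
#' The results table holds one row per (protein, timepoint): the aggregated
#' percent expression ratio relative to untreated control, its replicate SD
#' and SE (percentage points), replicate count, convergence flag, change
#' bin and QC flag. Written as a TSV with deterministic row order (protein,
#' then timepoint) and fixed formatting: percent-scale values with one
#' decimal, SE with three decimals.
#'
#' Note the 1-decimal formatting is the reporting precision of the written
#' file; the in-memory table keeps full precision.
#'
#' @param table Results data.frame (see [profile_experiment()]).
#' @param path Output TSV path.
#' @return `write_results()`: `path`, invisibly. `read_results()`: the
#'   table as written (reported precision).
#' @export
write_results <- function(table, path) {
  validate_results(table)
  tab <- table[order(table$protein, table$timepoint_h), RESULTS_COLS]
  fmt <- tab
  fmt$ratio_percent <- formatC(tab$ratio_percent, format = "f", digits = 1)
  fmt$sd <- formatC(tab$sd, format = "f", digits = 1)
  fmt$se <- formatC(tab$se, format = "f", digits = 3)
  fmt$converged <- as.integer(tab$converged)
  fmt$qc_pass <- as.integer(tab$qc_pass)
  con <- file(path, open = "w", encoding = "UTF-8")
  on.exit(close(con))
  write.table(fmt, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_results
#' @export
read_results <- function(path) {
  tab <- read.delim(path, sep = "\t", stringsAsFactors = FALSE, quote = "")
  tab$converged <- as.logical(tab$converged)
  tab$qc_pass <- as.logical(tab$qc_pass)
  validate_results(tab)
  tab
}
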