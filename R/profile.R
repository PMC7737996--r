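#' Percent expression ratio of treated vs control levels
#'
#' The untreated control defines 100%. A control level of zero (a clamped,
#' below-background peak) leaves the ratio undefined and is an error; the
#' orchestration in [profile_experiment()] converts such runs into QC
#' failures instead of propagating them.
#'
#' @param level_treated Treated expression level, >= 0.
#' @param level_control Control expression level, > 0.
#' @return Ratio in percent.
#' @export
expression_ratio <- function(level_treated, level_control) {
  if (any(level_control <= 0)) {
    stop("undefined ratio: control level is zero (clamped peak); ",
         "run fails QC")
  }
  if (any(level_treated < 0)) stop("treated level must be >= 0")
  100 * level_treated / level_control
}

#' Aggregate replicate ratios under the SD-convergence stopping rule
#'
#' Replicate percent ratios are consumed in arrival order: the first
#' `min_runs` always, then one more at a time while the sample SD exceeds
#' `sd_threshold` percentage points and fewer than `max_runs` have been
#' used. The aggregate is converged when the final SD is at or below the
#' threshold; hitting the run cap without reaching it leaves the aggregate
#' unconverged but still reported. The SE is `sd / sqrt(n)`.
#'
#' @param ratios Numeric vector of replicate percent ratios in arrival
#'   order; up to `max_runs` are consumed.
#' @param sd_threshold Convergence threshold, percentage points.
#' @param min_runs,max_runs Replication bounds (2 and 6 by default).
#' @return List: `ratios` (consumed values), `mean`, `sd`, `se`, `n`,
#'   `converged`.
#' @examples
#' aggregate_replicates(c(100, 110, 105))  # stops at n = 3, sd = 5
#' @export
aggregate_replicates <- function(ratios, sd_threshold = 5, min_runs = 2,
                                 max_runs = 6) {
  stopifnot(min_runs >= 2, max_runs >= min_runs, sd_threshold >= 0)
  ratios <- as.numeric(ratios)
  if (length(ratios) < min_runs) {
    stop("replicate stream exhausted: ", length(ratios),
         " run(s) available, need at least ", min_runs)
  }
  n <- min_runs
  while (sd(ratios[seq_len(n)]) > sd_threshold &&
         n < max_runs && n < length(ratios)) {
    n <- n + 1L
  }
  used <- ratios[seq_len(n)]
  s <- sd(used)
  list(ratios = used, mean = mean(used), sd = s, se = s / sqrt(n),
       n = as.integer(n), converged = s <= sd_threshold)
}

CHANGE_BINS <- c("minimal", "slight", "significant", "marked")

#' Classify an expression change into the effect-size bins
#'
#' Deviations of the percent ratio from the 100% control line are binned:
#' below 5 percentage points in magnitude is minimal, 5 up to 10 slight,
#' 10 up to 20 significant, and 20 or more marked. Boundaries belong to the
#' larger-magnitude bin (a 5.0-point change is slight). Direction is the
#' sign of the deviation; `none` only for an exactly unchanged ratio.
#'
#' @param ratio_percent Percent ratio, > 0.
#' @return List: `delta_percent` (signed), `bin`, `direction`.
#' @examples
#' classify_change(129.3)  # marked, up
#' classify_change(84.8)   # significant, down
#' @export
classify_change <- function(ratio_percent) {
  stopifnot(length(ratio_percent) == 1L, is.finite(ratio_percent),
            ratio_percent > 0)
  delta <- ratio_percent - 100
  mag <- abs(delta)
  bin <- if (mag < 5) "minimal" else if (mag < 10) "slight"
         else if (mag < 20) "significant" else "marked"
  direction <- if (delta > 0) "up" else if (delta < 0) "down" else "none"
  list(delta_percent = delta, bin = bin, direction = direction)
}

#' Housekeeping-protein quality control
#'
#' The housekeeping controls are assumed non-responsive to treatment; a
#' timepoint passes QC only if every housekeeping ratio lies within
#' `tolerance` percentage points of 100%. All housekeeping proteins must be
#' present at each assessed timepoint, otherwise QC cannot be evaluated.
#'
#' @param profile Data.frame with columns `protein`, `timepoint_h`,
#'   `ratio_percent` (extra columns ignored).
#' @param housekeeping Character vector of housekeeping protein names.
#' @param tolerance Allowed deviation from 100%, percentage points.
#' @return Data.frame `(timepoint_h, pass, offenders)`; `offenders` is a
#'   semicolon-joined list of failing proteins, empty when passing.
#' @export
housekeeping_qc <- function(profile, housekeeping, tolerance = 5) {
  stopifnot(all(c("protein", "timepoint_h", "ratio_percent") %in%
                  names(profile)),
            length(housekeeping) >= 1)
  hk <- profile[profile$protein %in% housekeeping, , drop = FALSE]
  tps <- sort(unique(profile$timepoint_h))
  out <- do.call(rbind, lapply(tps, function(tp) {
    rows <- hk[hk$timepoint_h == tp, , drop = FALSE]
    present <- unique(rows$protein)
    absent <- setdiff(housekeeping, present)
    if (length(absent)) {
      stop("housekeeping QC cannot be evaluated at ", tp,
           " h: missing ", paste(absent, collapse = ", "))
    }
    dev <- abs(rows$ratio_percent - 100)
    offenders <- unique(rows$protein[dev > tolerance])
    data.frame(timepoint_h = tp, pass = length(offenders) == 0L,
               offenders = paste(offenders, collapse = ";"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Largest-magnitude expression change of one protein across timepoints
#'
#' Returns the signed deviation from 100% with the largest absolute value
#' over the supplied timepoints, ties broken by the earliest timepoint —
#' the per-protein quantity summarized on the full-panel star plot.
#'
#' @param ratios Percent ratios, one per timepoint.
#' @param timepoints_h Matching timepoints (hours).
#' @return List: `delta_percent`, `timepoint_h`.
#' @export
extremum_change <- function(ratios, timepoints_h) {
  if (length(ratios) == 0L) stop("no timepoints supplied")
  stopifnot(length(ratios) == length(timepoints_h))
  ord <- order(timepoints_h)
  ratios <- ratios[ord]; timepoints_h <- timepoints_h[ord]
  delta <- ratios - 100
  i <- which.max(abs(delta))   # first (earliest) index at the maximum
  list(delta_percent = delta[i], timepoint_h = timepoints_h[i])
}

#' Proliferation index from per-image cell counts
#'
#' Per-timepoint mean and SD of the image counts, indexed to the 0 h
#' (untreated) mean as 100%.
#'
#' @param count_table Data.frame `(timepoint_h, count)`; one row per image
#'   (see [simulate_cell_counts()]).
#' @return Data.frame `(timepoint_h, mean_count, sd, n_images,
#'   index_percent)`.
#' @examples
#' tab <- data.frame(timepoint_h = rep(c(0, 8, 16, 24), each = 2),
#'                   count = rep(c(65.9, 63.2, 56.4, 51.7), each = 2))
#' proliferation_index(tab)$index_percent  # 100.0 95.9 85.6 78.5
#' @export
proliferation_index <- function(count_table) {
  stopifnot(all(c("timepoint_h", "count") %in% names(count_table)))
  tps <- sort(unique(count_table$timepoint_h))
  if (!0 %in% tps) stop("0 h (control) counts are required")
  out <- do.call(rbind, lapply(tps, function(tp) {
    x <- count_table$count[count_table$timepoint_h == tp]
    data.frame(timepoint_h = tp, mean_count = mean(x),
               sd = if (length(x) > 1L) sd(x) else 0,
               n_images = length(x))
  }))
  out$index_percent <- 100 * out$mean_count /
    out$mean_count[out$timepoint_h == 0]
  rownames(out) <- NULL
  out
}

#' Profile a whole experiment: quantification to results table
#'
#' Full pipeline orchestration. Every trace is quantified against its
#' batch's negative control; per antibody, timepoint and replicate the
#' treated/control level ratio is formed from the paired runs; replicate
#' ratios are aggregated under the SD-convergence rule; the aggregate is
#' classified; and housekeeping QC is evaluated per timepoint. Runs whose
#' control peak clamps to zero are skipped (logged in the `skipped`
#' attribute) rather than aborting the profile.
#'
#' A row's `qc_pass` is true when its own ratio is defined and its
#' timepoint passes housekeeping QC.
#'
#' @param experiment An `iphplc_experiment` or compatible list.
#' @param registry A `panel_registry` (for housekeeping membership).
#' @param sd_threshold,min_runs,max_runs Aggregation rule parameters.
#' @param window Optional fixed integration window.
#' @return Results data.frame (see [write_results()]) with attributes
#'   `qc` (per-timepoint housekeeping QC table) and `skipped`
#'   (data.frame of runs excluded for undefined ratios).
#' @export
profile_experiment <- function(experiment, registry, sd_threshold = 5,
                               min_runs = 2, max_runs = 6, window = NULL) {
  stopifnot(inherits(registry, "panel_registry"))
  quant <- quantify_experiment(experiment, window = window)
  ctl <- quant[quant$condition == "control", ]
  trt <- quant[quant$condition == "treated", ]
  key <- function(d) paste(d$antibody, d$timepoint_h, d$replicate)
  trt$ctl_level <- ctl$level[match(key(trt), key(ctl))]
  trt$ctl_clamped <- ctl$clamped[match(key(trt), key(ctl))]
  if (anyNA(trt$ctl_level)) {
    stop("unpaired treated run(s): ",
         paste(unique(trt$antibody[is.na(trt$ctl_level)]), collapse = ", "))
  }

  usable <- !trt$ctl_clamped & trt$ctl_level > 0
  skipped <- trt[!usable, c("antibody", "timepoint_h", "replicate"),
                 drop = FALSE]
  trt <- trt[usable, , drop = FALSE]
  trt$ratio <- expression_ratio(trt$level, trt$ctl_level)

  cells <- unique(trt[, c("antibody", "timepoint_h")])
  cells <- cells[order(match(cells$antibody, registry$records$name),
                       cells$timepoint_h), ]
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sel <- trt$antibody == cells$antibody[i] &
      trt$timepoint_h == cells$timepoint_h[i]
    runs <- trt[sel, ]
    runs <- runs[order(runs$replicate), ]
    agg <- aggregate_replicates(runs$ratio, sd_threshold = sd_threshold,
                                min_runs = min_runs, max_runs = max_runs)
    cls <- classify_change(agg$mean)
    data.frame(protein = cells$antibody[i],
               timepoint_h = cells$timepoint_h[i],
               ratio_percent = agg$mean, sd = agg$sd, se = agg$se,
               n_replicates = agg$n, converged = agg$converged,
               change_bin = cls$bin, qc_pass = NA,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)

  qc <- housekeeping_qc(
    data.frame(protein = res$protein, timepoint_h = res$timepoint_h,
               ratio_percent = res$ratio_percent),
    housekeeping = housekeeping_proteins(registry),
    tolerance = sd_threshold)
  res$qc_pass <- qc$pass[match(res$timepoint_h, qc$timepoint_h)]
  rownames(res) <- NULL
  attr(res, "qc") <- qc
  attr(res, "skipped") <- skipped
  res
}

#' Per-protein extremum table for a results table
#'
#' Applies [extremum_change()] to every profiled protein, in registry
#' order when a registry is given.
#'
#' @param results Results data.frame.
#' @param registry Optional `panel_registry` fixing the protein order.
#' @return Data.frame `(protein, delta_percent, timepoint_h)`.
#' @export
extremum_table <- function(results, registry = NULL) {
  proteins <- unique(results$protein)
  if (!is.null(registry)) {
    proteins <- proteins[order(match(proteins, registry$records$name))]
  }
  out <- do.call(rbind, lapply(proteins, function(p) {
    rows <- results[results$protein == p, ]
    ex <- extremum_change(rows$ratio_percent, rows$timepoint_h)
    data.frame(protein = p, delta_percent = ex$delta_percent,
               timepoint_h = ex$timepoint_h, stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
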