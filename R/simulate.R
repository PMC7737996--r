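#' Specify a chromatographic peak by its area
#'
#' Peaks are exponentially modified Gaussians (EMG) parameterized by their
#' analytic area, not height, so the simulator's ground truth is exact
#' under tailing: convolving a Gaussian with an exponential decay
#' redistributes but preserves area. `tau_min = 0` gives a pure Gaussian.
#'
#' @param center_min Gaussian center (minutes).
#' @param sigma_min Gaussian width (minutes), > 0.
#' @param area_mAU_s Analytic peak area in mAU·s, > 0.
#' @param tau_min Exponential tail constant (minutes), >= 0.
#' @return A `peak_spec` object.
#' @export
peak_spec <- function(center_min, sigma_min, area_mAU_s, tau_min = 0) {
  stopifnot(sigma_min > 0, area_mAU_s > 0, tau_min >= 0)
  structure(list(center_min = center_min, sigma_min = sigma_min,
                 area_mAU_s = area_mAU_s, tau_min = tau_min),
            class = "peak_spec")
}

# EMG density over minutes (integrates to 1). Stable evaluation via
# log-space: log f = -log(tau) + sigma^2/(2 tau^2) - (t-mu)/tau
#                    + log Phi((t-mu)/sigma - sigma/tau),
# with pnorm(log.p = TRUE) absorbing the far-tail cancellation. Falls back
# to the Gaussian density when tau is negligible relative to sigma.
emg_density <- function(t, mu, sigma, tau) {
  if (tau < 1e-6 * sigma) {
    return(stats::dnorm(t, mean = mu, sd = sigma))
  }
  logf <- -log(tau) + sigma^2 / (2 * tau^2) - (t - mu) / tau +
    stats::pnorm((t - mu) / sigma - sigma / tau, log.p = TRUE)
  exp(logf)
}

#' Simulate a UV-detector chromatogram
#'
#' Renders a trace on a uniform time grid as the sum of the given peaks, a
#' linear baseline and i.i.d. Gaussian detector noise. Time is in minutes
#' and absorbance in mAU; because areas are carried in mAU·s, a peak of
#' area `A` contributes `A / 60 * emg(t)` mAU at time `t`.
#'
#' @param peaks List of [peak_spec()] objects (may be empty).
#' @param baseline_slope Baseline slope in mAU/min.
#' @param baseline_offset Baseline offset in mAU.
#' @param noise_sd Detector noise SD in mAU, >= 0.
#' @param run_length_min Run length (minutes).
#' @param step_min Sampling step (minutes), > 0.
#' @param seed Integer seed; identical seeds give identical traces.
#' @param ... Metadata passed on to [chromatogram()] (antibody, condition,
#'   timepoint_h, replicate, batch).
#' @return A `chromatogram`.
#' @examples
#' pk <- peak_spec(center_min = 12, sigma_min = 0.1, area_mAU_s = 150.4)
#' ch <- simulate_chromatogram(list(pk), noise_sd = 0, seed = 1)
#' @export
simulate_chromatogram <- function(peaks = list(), baseline_slope = 0,
                                  baseline_offset = 0, noise_sd = 0,
                                  run_length_min = 30, step_min = 0.01,
                                  seed = 1L, ...) {
  if (inherits(peaks, "peak_spec")) peaks <- list(peaks)
  stopifnot(step_min > 0, run_length_min > 0)
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  for (p in peaks) {
    stopifnot(inherits(p, "peak_spec"))
    if (p$center_min < 0 || p$center_min > run_length_min) {
      stop("peak center ", p$center_min, " min lies outside the run [0, ",
           run_length_min, "]")
    }
  }
  t <- seq(0, run_length_min, by = step_min)
  y <- baseline_offset + baseline_slope * t
  for (p in peaks) {
    y <- y + p$area_mAU_s / 60 *
      emg_density(t, p$center_min, p$sigma_min, p$tau_min)
  }
  if (noise_sd > 0) {
    old <- .Random.seed_save()
    on.exit(.Random.seed_restore(old))
    set.seed(seed)
    y <- y + rnorm(length(t), sd = noise_sd)
  }
  chromatogram(time_min = t, absorbance_mAU = y,
               meta = list(run_length_min = run_length_min), ...)
}

# save/restore the global RNG state so simulators are pure in (params, seed)
.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv())
}
.Random.seed_restore <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}

#' Build a ground-truth table for an experiment simulation
#'
#' One row per (antibody, timepoint): the control-condition net peak area,
#' the level fold change (treated level / control level; treated area is
#' `level_fold^2` times the control area since levels are square roots of
#' areas), the shared negative-control background area, and the
#' multiplicative replicate coefficient of variation. Housekeeping
#' antibodies must keep `level_fold = 1` at all timepoints.
#'
#' @param registry A `panel_registry`.
#' @param antibodies Antibody names to simulate; default the whole panel.
#' @param fold_table Optional data.frame `(antibody, timepoint_h,
#'   level_fold)` overriding the default fold of 1 for selected cells.
#' @param control_net_area Control-condition net area, mAU·s.
#' @param negative_control_area Background (negative-control antibody)
#'   area, mAU·s.
#' @param replicate_cv Multiplicative replicate CV on net areas (e.g. 0.02).
#' @param noise_sd_mAU Additive detector noise SD, mAU.
#' @param baseline_slope,baseline_offset Linear baseline (mAU/min, mAU).
#' @return Data.frame with class `simulation_truth`.
#' @export
simulation_truth <- function(registry, antibodies = NULL, fold_table = NULL,
                             control_net_area = 10000,
                             negative_control_area = 150,
                             replicate_cv = 0.02, noise_sd_mAU = 0.2,
                             baseline_slope = 0.02, baseline_offset = 1) {
  stopifnot(inherits(registry, "panel_registry"),
            replicate_cv >= 0, control_net_area > 0,
            negative_control_area >= 0)
  antibodies <- antibodies %||% registry$records$name
  unknown <- setdiff(antibodies, registry$records$name)
  if (length(unknown)) {
    stop("antibod(ies) absent from the registry: ",
         paste(unknown, collapse = ", "))
  }
  truth <- expand.grid(antibody = antibodies, timepoint_h = TIMEPOINTS_H,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  truth$control_net_area <- control_net_area
  truth$level_fold <- 1
  if (!is.null(fold_table)) {
    stopifnot(all(c("antibody", "timepoint_h", "level_fold") %in%
                    names(fold_table)))
    idx <- match(paste(fold_table$antibody, fold_table$timepoint_h),
                 paste(truth$antibody, truth$timepoint_h))
    if (anyNA(idx)) {
      stop("fold_table rows outside the simulated design: ",
           paste(fold_table$antibody[is.na(idx)], collapse = ", "))
    }
    truth$level_fold[idx] <- fold_table$level_fold
  }
  if (any(truth$level_fold <= 0)) stop("level_fold must be > 0")
  hk <- housekeeping_proteins(registry)
  bad_hk <- unique(truth$antibody[truth$antibody %in% hk &
                                    truth$level_fold != 1])
  if (length(bad_hk)) {
    stop("housekeeping antibod(ies) must have level_fold = 1: ",
         paste(bad_hk, collapse = ", "))
  }
  truth$negative_control_area <- negative_control_area
  truth$replicate_cv <- replicate_cv
  truth$noise_sd_mAU <- noise_sd_mAU
  truth$baseline_slope <- baseline_slope
  truth$baseline_offset <- baseline_offset
  class(truth) <- c("simulation_truth", "data.frame")
  truth
}

#' Simulate a whole IP-HPLC experiment with known ground truth
#'
#' Emits, for every antibody and timepoint in the truth table, paired
#' control and treated chromatograms for `n_replicates` replicates, plus
#' one negative-control background trace per batch (a batch is one
#' timepoint × replicate run pair). Replicate net areas are drawn
#' multiplicatively as `truth area × Lognormal(cv)` (mean 1), so a level
#' fold `f` with `cv = 0` yields a measured ratio of exactly `100 f` %.
#'
#' The default peak layout places each antibody's pooled target peak at
#' 12 min (sigma 0.1 min, tail 0.05 min) and the negative-control peak at
#' the same position; the gross target area is the net area plus the
#' background area, matching the area-domain background subtraction done
#' during quantification.
#'
#' @param registry A `panel_registry`.
#' @param truth A [simulation_truth()] table.
#' @param n_replicates Replicates per condition, >= 2.
#' @param seed Integer seed; the full output is a pure function of
#'   (arguments, seed).
#' @param step_min Trace sampling step, minutes.
#' @param peak_center_min,peak_sigma_min,peak_tau_min Target peak shape.
#' @return List with class `iphplc_experiment`: `chromatograms` (list),
#'   `negative_controls` (named by batch), `truth`, `n_replicates`, `seed`.
#' @export
simulate_experiment <- function(registry, truth, n_replicates = 6, seed = 1L,
                                step_min = 0.01, peak_center_min = 12,
                                peak_sigma_min = 0.1, peak_tau_min = 0.05) {
  stopifnot(inherits(registry, "panel_registry"),
            inherits(truth, "simulation_truth"))
  if (n_replicates < 2) stop("n_replicates must be >= 2")
  unknown <- setdiff(truth$antibody, registry$records$name)
  if (length(unknown)) {
    stop("antibod(ies) absent from the registry: ",
         paste(unknown, collapse = ", "))
  }
  antibodies <- unique(truth$antibody)
  # full design coverage check
  want <- paste(rep(antibodies, each = length(TIMEPOINTS_H)), TIMEPOINTS_H)
  have <- paste(truth$antibody, truth$timepoint_h)
  if (!all(want %in% have)) {
    miss <- want[!want %in% have][1]
    stop("truth table does not cover antibody/timepoint: ", miss)
  }

  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)

  # mean-1 lognormal multiplicative factors: sdlog from cv
  draw_factor <- function(cv, n) {
    if (cv == 0) return(rep(1, n))
    sdlog <- sqrt(log(1 + cv^2))
    rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
  }

  chroms <- vector("list", nrow(truth) * 2L * n_replicates)
  negs <- list()
  k <- 0L
  trace_seed <- function() sample.int(.Machine$integer.max, 1L)

  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    ctl_areas <- row$control_net_area * draw_factor(row$replicate_cv, n_replicates)
    trt_areas <- row$level_fold^2 * row$control_net_area *
      draw_factor(row$replicate_cv, n_replicates)
    for (r in seq_len(n_replicates)) {
      batch <- sprintf("t%02d_r%d", row$timepoint_h, r)
      if (is.null(negs[[batch]])) {
        negs[[batch]] <- simulate_chromatogram(
          peak_spec(peak_center_min, peak_sigma_min,
                    row$negative_control_area, peak_tau_min),
          baseline_slope = row$baseline_slope,
          baseline_offset = row$baseline_offset,
          noise_sd = row$noise_sd_mAU, step_min = step_min,
          seed = trace_seed(), antibody = "negative control",
          condition = "control", timepoint_h = row$timepoint_h,
          replicate = r, batch = batch)
      }
      for (cond in c("control", "treated")) {
        net <- if (cond == "control") ctl_areas[r] else trt_areas[r]
        k <- k + 1L
        chroms[[k]] <- simulate_chromatogram(
          peak_spec(peak_center_min, peak_sigma_min,
                    net + row$negative_control_area, peak_tau_min),
          baseline_slope = row$baseline_slope,
          baseline_offset = row$baseline_offset,
          noise_sd = row$noise_sd_mAU, step_min = step_min,
          seed = trace_seed(), antibody = row$antibody, condition = cond,
          timepoint_h = row$timepoint_h, replicate = r, batch = batch)
      }
    }
  }
  structure(list(chromatograms = chroms, negative_controls = negs,
                 truth = truth, n_replicates = as.integer(n_replicates),
                 seed = as.integer(seed)),
            class = "iphplc_experiment")
}

#' @export
print.iphplc_experiment <- function(x, ...) {
  cat(sprintf(
    "<iphplc_experiment> %d antibodies x %d timepoints x %d replicates\n  %d traces + %d negative-control traces (seed %d)\n",
    length(unique(x$truth$antibody)), length(unique(x$truth$timepoint_h)),
    x$n_replicates, length(x$chromatograms), length(x$negative_controls),
    x$seed))
  invisible(x)
}

#' Simulate per-image cell counts for the proliferation assay
#'
#' Draws `n_images` microscope-field cell counts per timepoint from
#' Gaussian distributions with the given means and common SD, rounded to
#' non-negative integers — emulating direct cell counting over repeated
#' representative images.
#'
#' @param mean_counts Named or ordered numeric vector of mean counts, one
#'   per timepoint (default order 0, 8, 16, 24 h).
#' @param sd Common SD of counts, >= 0.
#' @param n_images Images per timepoint, >= 1.
#' @param seed Integer seed.
#' @param timepoints_h Timepoints matching `mean_counts`.
#' @return Data.frame `(timepoint_h, image, count)`.
#' @export
simulate_cell_counts <- function(mean_counts, sd = 6, n_images = 30,
                                 seed = 1L, timepoints_h = c(0, TIMEPOINTS_H)) {
  stopifnot(length(mean_counts) == length(timepoints_h))
  if (any(mean_counts < 0)) stop("mean counts must be non-negative")
  if (sd < 0) stop("sd must be >= 0")
  if (n_images < 1) stop("n_images must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  out <- do.call(rbind, lapply(seq_along(timepoints_h), function(i) {
    counts <- pmax(0, round(rnorm(n_images, mean_counts[i], sd)))
    data.frame(timepoint_h = timepoints_h[i], image = seq_len(n_images),
               count = as.integer(counts))
  }))
  rownames(out) <- NULL
  out
}
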