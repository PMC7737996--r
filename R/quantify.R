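# trapezoidal integral of y over t (units: y-unit x t-unit)
trapz <- function(t, y) {
  n <- length(t)
  sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# Robust detector-noise estimate: 1.4826 x MAD of the first-differenced
# signal / sqrt(2). Differencing removes baseline and (mostly) peak trends;
# the median absorbs the few large peak-flank differences.
robust_noise <- function(y) {
  d <- diff(y)
  1.4826 * median(abs(d - median(d))) / sqrt(2)
}

# centered moving average with edge truncation; k odd
moving_average <- function(y, k) {
  if (length(y) <= k) return(y)
  sm <- stats::filter(y, rep(1 / k, k), sides = 2)
  half <- (k - 1L) %/% 2L
  n <- length(y)
  edge <- c(seq_len(half), seq(n - half + 1L, n))
  sm[edge] <- y[edge]
  as.numeric(sm)
}

# coarse whole-trace baseline through the medians of the leading and
# trailing 15% of samples; used only to seed peak detection
coarse_baseline <- function(t, y) {
  k <- max(3L, round(0.15 * length(t)))
  t1 <- median(t[seq_len(k)]); y1 <- median(y[seq_len(k)])
  t2 <- median(tail(t, k));    y2 <- median(tail(y, k))
  slope <- (y2 - y1) / (t2 - t1)
  list(slope = slope, offset = y1 - slope * t1)
}

#' Estimate a linear baseline under a peak window
#'
#' Anchors a straight line on the medians of two short flanking segments
#' (default 0.2 min each) immediately outside the window. The median makes
#' the anchors robust to residual noise; a peak fully inside the window
#' does not bias them.
#'
#' @param chrom A `chromatogram`.
#' @param window Numeric `c(start_min, end_min)`.
#' @param flank_min Flank segment length, minutes.
#' @return List with `slope` (mAU/min) and `offset` (mAU).
#' @export
estimate_baseline <- function(chrom, window, flank_min = 0.2) {
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2L,
            window[1] < window[2])
  t <- chrom$time_min; y <- chrom$absorbance_mAU
  if (window[1] < min(t) || window[2] > max(t)) {
    stop("window [", window[1], ", ", window[2], "] outside trace extent")
  }
  left  <- t >= window[1] - flank_min & t < window[1]
  right <- t > window[2] & t <= window[2] + flank_min
  if (sum(left) < 3L || sum(right) < 3L) {
    stop("window touches the trace edge: need >= 3 samples on each ",
         "flank (have ", sum(left), " left, ", sum(right), " right)")
  }
  t1 <- median(t[left]);  y1 <- median(y[left])
  t2 <- median(t[right]); y2 <- median(y[right])
  slope <- (y2 - y1) / (t2 - t1)
  list(slope = slope, offset = y1 - slope * t1)
}

#' Locate the integration window of the dominant peak
#'
#' Subtracts a coarse whole-trace baseline and lightly smooths the
#' corrected signal (5-sample moving average, the usual pre-detection
#' filter: it leaves chromatographic peaks intact but keeps single noise
#' excursions from masquerading as an apex). The smoothed apex must exceed
#' `snr_min` times a robust noise estimate; the window is then walked
#' outward from the apex to where the signal first falls below
#' `height_frac` of the apex height on each side, and finally widened by
#' `margin` of each half-width so that the slow tails (and, for tailed
#' peaks, the exponential decay) fall inside the window.
#'
#' @param chrom A `chromatogram`.
#' @param height_frac Boundary threshold as a fraction of apex height.
#' @param snr_min Minimum apex signal-to-noise ratio.
#' @param margin Half-width widening factor applied per side.
#' @return Numeric `c(start_min, end_min)`.
#' @export
detect_peak_window <- function(chrom, height_frac = 0.01, snr_min = 3,
                               margin = 0.5) {
  stopifnot(inherits(chrom, "chromatogram"), height_frac > 0,
            height_frac < 1)
  t <- chrom$time_min; y <- chrom$absorbance_mAU
  bl <- coarse_baseline(t, y)
  yc <- y - (bl$offset + bl$slope * t)
  yc <- moving_average(yc, 5L)
  noise <- robust_noise(y)
  apex <- which.max(yc)
  if (!(yc[apex] > snr_min * noise) || yc[apex] <= 0) {
    stop("no peak detected: apex ", signif(yc[apex], 3),
         " mAU above baseline does not exceed ", snr_min,
         " x noise (", signif(noise, 3), " mAU)")
  }
  thr <- height_frac * yc[apex]
  lo <- apex
  while (lo > 1L && yc[lo] >= thr) lo <- lo - 1L
  hi <- apex
  n <- length(t)
  while (hi < n && yc[hi] >= thr) hi <- hi + 1L
  half_l <- t[apex] - t[lo]
  half_r <- t[hi] - t[apex]
  c(max(min(t), t[lo] - margin * half_l),
    min(max(t), t[hi] + margin * half_r))
}

#' Integrate a baseline-corrected peak
#'
#' Trapezoidal integral of (signal − baseline) over the window, converted
#' from mAU·min to mAU·s (× 60). Negative sub-areas are retained so that
#' zero-mean noise cancels in expectation; the trapezoidal rule is exact
#' for the piecewise-linear data the detector actually delivers.
#'
#' @param chrom A `chromatogram`.
#' @param window Numeric `c(start_min, end_min)`.
#' @param baseline List with `slope`, `offset` (see [estimate_baseline()]).
#' @return Gross area, mAU·s.
#' @export
integrate_peak <- function(chrom, window, baseline) {
  stopifnot(inherits(chrom, "chromatogram"), length(window) == 2L,
            window[1] < window[2])
  sel <- chrom$time_min >= window[1] & chrom$time_min <= window[2]
  if (sum(sel) < 3L) {
    stop("window spans fewer than 3 samples")
  }
  t <- chrom$time_min[sel]
  y <- chrom$absorbance_mAU[sel] - (baseline$offset + baseline$slope * t)
  60 * trapz(t, y)
}

#' Subtract the negative-control antibody background area
#'
#' The negative-control antiserum estimates non-specific binding; its peak
#' area is subtracted from the target's gross area in the area domain. A
#' net area below zero means the target signal is indistinguishable from
#' background: it is clamped to zero and flagged, and downstream ratio
#' computation treats the protein as a QC failure.
#'
#' @param gross Gross target area, mAU·s, >= 0.
#' @param negctrl Negative-control area, mAU·s, >= 0.
#' @return List with `net_area` (mAU·s) and `clamped` (logical).
#' @export
subtract_negative_control <- function(gross, negctrl) {
  if (gross < 0 || negctrl < 0) {
    stop("areas must be non-negative (gross = ", gross,
         ", negctrl = ", negctrl, ")")
  }
  net <- gross - negctrl
  list(net_area = max(net, 0), clamped = net < 0)
}

#' Convert a net peak area to an expression level
#'
#' The concentration-like expression level is the square root of the net
#' peak area; treated/control level ratios are therefore invariant to a
#' common detector gain (sqrt(g a)/sqrt(g b) = sqrt(a/b)).
#'
#' @param net_area Net area, mAU·s, >= 0 (clamp upstream).
#' @return Level, sqrt(mAU·s).
#' @export
to_level <- function(net_area) {
  if (any(net_area < 0)) {
    stop("net_area must be >= 0; clamp with subtract_negative_control()")
  }
  sqrt(net_area)
}

#' Quantify one chromatogram against its negative control
#'
#' Runs the full single-trace pipeline: peak-window detection (or a fixed
#' window override), flank-anchored baseline estimation, trapezoidal
#' integration, background subtraction and square-root normalization.
#'
#' @param chrom Target `chromatogram`.
#' @param negctrl Either the negative-control `chromatogram` (quantified
#'   with the same procedure) or a pre-computed background area (mAU·s).
#' @param window Optional fixed `c(start_min, end_min)` override applied to
#'   both traces.
#' @param flank_min Baseline flank length, minutes.
#' @return One-row data.frame: antibody, condition, timepoint_h, replicate,
#'   batch, gross_area_mAU_s, negctrl_area_mAU_s, net_area_mAU_s, level,
#'   window_start_min, window_end_min, baseline_slope, baseline_offset,
#'   clamped.
#' @export
quantify_chromatogram <- function(chrom, negctrl, window = NULL,
                                  flank_min = 0.2) {
  stopifnot(inherits(chrom, "chromatogram"))
  if (inherits(negctrl, "chromatogram")) {
    nw <- window %||% detect_peak_window(negctrl)
    nb <- estimate_baseline(negctrl, nw, flank_min)
    negctrl_area <- max(0, integrate_peak(negctrl, nw, nb))
  } else {
    negctrl_area <- as.numeric(negctrl)
    if (negctrl_area < 0) stop("negative-control area must be >= 0")
  }
  w <- window %||% detect_peak_window(chrom)
  bl <- estimate_baseline(chrom, w, flank_min)
  gross <- max(0, integrate_peak(chrom, w, bl))
  sub <- subtract_negative_control(gross, negctrl_area)
  data.frame(
    antibody = chrom$antibody, condition = chrom$condition,
    timepoint_h = chrom$timepoint_h, replicate = chrom$replicate,
    batch = chrom$batch,
    gross_area_mAU_s = gross, negctrl_area_mAU_s = negctrl_area,
    net_area_mAU_s = sub$net_area, level = to_level(sub$net_area),
    window_start_min = w[1], window_end_min = w[2],
    baseline_slope = bl$slope, baseline_offset = bl$offset,
    clamped = sub$clamped,
    stringsAsFactors = FALSE
  )
}

#' Quantify every trace of a simulated or assembled experiment
#'
#' Quantifies each batch's negative-control trace once, then every target
#' trace against its batch's background area.
#'
#' @param experiment An `iphplc_experiment` (see [simulate_experiment()]),
#'   or a list with elements `chromatograms` and `negative_controls`
#'   (named by batch).
#' @param window Optional fixed window override.
#' @return Data.frame of [quantify_chromatogram()] rows.
#' @export
quantify_experiment <- function(experiment, window = NULL) {
  stopifnot(!is.null(experiment$chromatograms),
            !is.null(experiment$negative_controls))
  neg_area <- vapply(experiment$negative_controls, function(nc) {
    nw <- window %||% detect_peak_window(nc)
    nb <- estimate_baseline(nc, nw)
    max(0, integrate_peak(nc, nw, nb))
  }, numeric(1))
  rows <- lapply(experiment$chromatograms, function(ch) {
    if (is.null(neg_area[[ch$batch]]) || is.na(neg_area[[ch$batch]])) {
      stop("no negative-control trace for batch '", ch$batch, "'")
    }
    quantify_chromatogram(ch, neg_area[[ch$batch]], window = window)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
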