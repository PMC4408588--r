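# A254 polysome-gradient profile analysis: baseline correction, peak
# segmentation (40S / 60S / 80S monosome / polysome region) and the
# polysome:monosome (P:M) area ratio, the cell-level measure of
# translational activity.

new_profile_trace <- function(position, absorbance) {
  if (length(position) != length(absorbance)) {
    stop("position and absorbance lengths differ", call. = FALSE)
  }
  if (length(position) < 50) {
    stop("a profile trace needs at least 50 points", call. = FALSE)
  }
  if (any(!is.finite(position)) || any(!is.finite(absorbance))) {
    stop("non-finite values in trace", call. = FALSE)
  }
  if (any(diff(position) <= 0)) {
    stop("positions must be strictly increasing", call. = FALSE)
  }
  structure(list(position = as.numeric(position),
                 absorbance = as.numeric(absorbance)),
            class = "profile_trace")
}

#' Read an A254 gradient trace from a two-column delimited file
#'
#' Expects two numeric columns (position, absorbance), tab- or
#' whitespace-delimited, with an optional header line.
#'
#' @param path File path.
#' @return A `profile_trace`.
#' @export
read_trace <- function(path) {
  first <- readLines(path, n = 1)
  has_header <- suppressWarnings(
    anyNA(as.numeric(strsplit(trimws(first), "[\t ,;]+")[[1]]))
  )
  df <- read.delim(path, header = has_header, sep = "",
                   stringsAsFactors = FALSE)
  if (ncol(df) < 2) stop("trace file needs two columns", call. = FALSE)
  pos <- suppressWarnings(as.numeric(df[[1]]))
  ab <- suppressWarnings(as.numeric(df[[2]]))
  if (anyNA(pos) || anyNA(ab)) {
    stop("malformed (non-numeric) rows in trace file", call. = FALSE)
  }
  new_profile_trace(pos, ab)
}

# Savitzky-Golay smoothing in position units (preserves peak areas far
# better than a boxcar of the same width).
sg_smooth <- function(trace, width = 2.5, order = 3) {
  dx <- median(diff(trace$position))
  n <- max(order + 2, round(width / dx))
  if (n %% 2 == 0) n <- n + 1
  n <- min(n, length(trace$absorbance) - (1 - length(trace$absorbance) %% 2))
  as.numeric(signal::sgolayfilt(trace$absorbance, p = order, n = n))
}

roll_stat <- function(y, k, fun) {
  as.numeric(zoo::rollapply(zoo::zoo(y), width = k, FUN = fun,
                            align = "center", partial = TRUE))
}

# Asymmetric-least-squares polynomial baseline (Eilers-style weights on
# a polynomial basis): points above the fit — the peaks — get weight p
# << 1, points at or below it full weight, iterated to convergence, so
# the fit settles onto the signal-free stretches between peak regions
# without riding up on the valleys inside the polysome cluster.
lower_envelope_baseline <- function(x, y, degree = 1, p = 1e-3,
                                    max_iter = 30) {
  w <- rep(1, length(y))
  f <- fitted(lm(y ~ poly(x, degree)))
  for (i in seq_len(max_iter)) {
    f <- fitted(lm(y ~ poly(x, degree), weights = w))
    w_new <- ifelse(y > f, p, 1)
    if (all(w_new == w)) break
    w <- w_new
  }
  f
}

#' Baseline-correct a gradient trace
#'
#' Estimates the slowly varying drift under the peaks and subtracts
#' it, clipping at zero. The default `"lower_envelope"` method fits a
#' low-order polynomial iteratively clipped onto the smoothed trace's
#' signal-free stretches (gradient start, the gap between the 80S peak
#' and the first polysome peak, and the gradient end), which recovers
#' linear or gently curved drift without riding up on the valleys
#' between polysome peaks. The `"rolling_min"` method instead takes
#' the rolling minimum of the smoothed trace over `window` position
#' units and interpolates linearly between the positions where the
#' trace attains it.
#'
#' @param trace A `profile_trace`.
#' @param window Rolling-minimum window in position units; must be
#'   smaller than the trace span. Default: half the span.
#' @param smooth_width Pre-smoothing width in position units.
#' @param method `"lower_envelope"` (default) or `"rolling_min"`.
#' @param degree Polynomial degree for the lower-envelope method
#'   (default 1: linear drift; raise for curved baselines).
#' @return List of class `corrected_trace`: `trace` (corrected),
#'   `baseline`, and the `raw` input.
#' @export
correct_baseline <- function(trace, window = NULL, smooth_width = 2.5,
                             method = c("lower_envelope",
                                        "rolling_min"),
                             degree = 1) {
  method <- match.arg(method)
  span <- diff(range(trace$position))
  if (is.null(window)) window <- span / 2
  if (window >= span) {
    stop("'window' must be smaller than the trace span", call. = FALSE)
  }
  y_s <- sg_smooth(trace, smooth_width)
  x <- trace$position
  if (method == "lower_envelope") {
    base <- lower_envelope_baseline(x, y_s, degree = degree)
  } else {
    dx <- median(diff(x))
    k <- max(3, round(window / dx))
    rmin <- roll_stat(y_s, k, min)
    anchor <- which(y_s <= rmin + 1e-12)
    base <- approx(x[anchor], y_s[anchor], xout = x, rule = 2)$y
  }
  residual <- trace$absorbance - base
  structure(
    list(trace = new_profile_trace(trace$position, pmax(residual, 0)),
         residual = residual, baseline = base, raw = trace),
    class = "corrected_trace"
  )
}

# Local maxima with topographic prominence on a smoothed trace.
find_prominent_peaks <- function(x, y, min_prominence) {
  n <- length(y)
  is_max <- c(FALSE, y[2:(n - 1)] > y[1:(n - 2)] &
                y[2:(n - 1)] >= y[3:n], FALSE)
  idx <- which(is_max)
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(i) {
    left <- y[1:i]; right <- y[i:n]
    higher_l <- which(left > y[i])
    higher_r <- which(right > y[i]) + i - 1L
    lo_l <- if (length(higher_l)) min(y[max(higher_l):i]) else min(left)
    lo_r <- if (length(higher_r)) min(y[i:min(higher_r)]) else min(right)
    y[i] - max(lo_l, lo_r)
  }, numeric(1))
  keep <- idx[prom >= min_prominence]
  # ties in prominence are broken by position: order is positional anyway
  sort(keep)
}

#' Segment a baseline-corrected trace into labeled peak regions
#'
#' The first three prominent peaks in position order are labeled 40S,
#' 60S and monosome (80S); the polysome region runs from the local
#' minimum after the 80S peak to the end of the trace. Boundaries
#' between labeled peaks sit at the local minima of the smoothed trace.
#'
#' @param corrected A [correct_baseline()] result (or a `profile_trace`
#'   already baseline-free).
#' @param prominence Minimum peak prominence as a fraction of the
#'   maximum corrected absorbance.
#' @param smooth_width Smoothing width (position units) for peak
#'   detection.
#' @return List of class `peak_segmentation`: `intervals` (named list
#'   of half-open [from, to) position pairs), `peaks` (positions),
#'   `trace` (the corrected trace), `baseline`.
#' @export
segment_peaks <- function(corrected, prominence = 0.05,
                          smooth_width = 2.5) {
  if (inherits(corrected, "profile_trace")) {
    corrected <- list(trace = corrected,
                      residual = corrected$absorbance,
                      baseline = rep(0, length(corrected$position)))
  }
  tr <- corrected$trace
  y_s <- sg_smooth(tr, smooth_width)
  x <- tr$position
  pk <- find_prominent_peaks(x, y_s, prominence * max(y_s))
  if (length(pk) < 4) {
    stop(sprintf(
      "unsegmentable trace: %d prominent peak(s) found, need >= 4 (40S, 60S, 80S and at least one polysome peak)",
      length(pk)), call. = FALSE)
  }
  valley <- function(i1, i2) {
    seg <- i1:i2
    seg[which.min(y_s[seg])]
  }
  b1 <- valley(pk[1], pk[2])   # 40S | 60S
  b2 <- valley(pk[2], pk[3])   # 60S | 80S
  b3 <- valley(pk[3], pk[4])   # 80S | polysomes
  n <- length(x)
  intervals <- list(
    `40S` = c(x[1], x[b1]),
    `60S` = c(x[b1], x[b2]),
    monosome = c(x[b2], x[b3]),
    polysome = c(x[b3], x[n])
  )
  structure(
    list(intervals = intervals,
         peaks = setNames(x[pk[1:4]],
                          c("40S", "60S", "monosome", "first_polysome")),
         n_peaks = length(pk),
         trace = tr, residual = corrected$residual,
         baseline = corrected$baseline),
    class = "peak_segmentation"
  )
}

#' Compute peak areas and the P:M ratio from a segmentation
#'
#' Trapezoidal areas of the baseline-subtracted trace over each labeled
#' interval; the P:M ratio is the polysome-region area divided by the
#' 80S monosome peak area. Invariant under affine rescaling of the
#' (baseline-corrected) absorbance.
#'
#' @param seg A [segment_peaks()] result.
#' @return List of class `pm_result`: `pm_ratio` and the named `areas`.
#' @export
compute_pm_ratio <- function(seg) {
  x <- seg$trace$position
  # integrate the unclipped baseline-subtracted residual: clipping at
  # zero first would rectify noise into a positive area bias over the
  # signal-free stretches of the wide polysome region
  y <- if (!is.null(seg$residual)) seg$residual else
    seg$trace$absorbance
  areas <- vapply(seg$intervals, function(iv) {
    inside <- x >= iv[1] & x <= iv[2]
    max(trapezoid(x[inside], y[inside]), 0)
  }, numeric(1))
  if (areas[["monosome"]] <= 0) {
    stop("zero monosome area: cannot form P:M ratio", call. = FALSE)
  }
  structure(list(pm_ratio = unname(areas[["polysome"]] /
                                     areas[["monosome"]]),
                 areas = areas),
            class = "pm_result")
}

# Segmentation-informed baseline refinement: once peak positions are
# known, the drift polynomial is refit using only the signal-free
# anchor windows — the gradient lead-in before the 40S peak and the
# trailing end of the scored range — where the smoothed trace IS the
# baseline. With a linear or gently curved drift this removes the
# residual bias of the envelope fit under the polysome cluster.
refine_baseline <- function(trace, seg, degree = 1,
                            smooth_width = 2.5, trail_frac = 0.08) {
  x <- trace$position
  y_s <- sg_smooth(trace, smooth_width)
  x0 <- x[1]; x1 <- x[length(x)]
  lead_hi <- x0 + 0.5 * (seg$peaks[["40S"]] - x0)
  trail_lo <- x1 - trail_frac * (x1 - x0)
  anchor <- (x <= lead_hi) | (x >= trail_lo)
  if (sum(anchor) <= degree + 2) return(NULL)
  fit <- lm(y_s[anchor] ~ poly(x[anchor], degree, raw = TRUE))
  base <- drop(cbind(1, poly(x, degree, raw = TRUE)) %*% coef(fit))
  base
}

#' One-call trace analysis
#'
#' Baseline correction, segmentation, baseline refinement on the
#' signal-free anchor windows, and P:M computation in one step.
#'
#' @param trace A `profile_trace` or [simulate_profile_trace()] result.
#' @param window Baseline window, see [correct_baseline()].
#' @param baseline_subtract Set `FALSE` to skip baseline correction
#'   (areas measured from the raw curve).
#' @param refine Refit the drift on the signal-free lead-in and
#'   trailing windows once the peaks are located (recommended; set
#'   `FALSE` for traces whose ends are not signal-free).
#' @param refine_degree Polynomial degree of the refined drift.
#' @param ... Passed to [segment_peaks()].
#' @return A `pm_result` with the segmentation attached as `$segmentation`.
#' @export
#' @examples
#' sim <- simulate_profile_trace(2.5, seed = 7)
#' analyze_trace(sim)$pm_ratio
analyze_trace <- function(trace, window = NULL, baseline_subtract = TRUE,
                          refine = TRUE, refine_degree = 1, ...) {
  if (inherits(trace, "simulated_trace")) trace <- trace$trace
  corr <- if (baseline_subtract) {
    correct_baseline(trace, window)
  } else {
    list(trace = trace, baseline = rep(0, length(trace$position)))
  }
  seg <- segment_peaks(corr, ...)
  if (baseline_subtract && refine) {
    base <- refine_baseline(trace, seg, degree = refine_degree)
    if (!is.null(base)) {
      seg$residual <- trace$absorbance - base
      seg$trace <- new_profile_trace(trace$position,
                                     pmax(seg$residual, 0))
      seg$baseline <- base
    }
  }
  res <- compute_pm_ratio(seg)
  res$segmentation <- seg
  res
}

#' @export
print.pm_result <- function(x, ...) {
  cat("P:M ratio:", format(x$pm_ratio, digits = 4), "\n")
  cat("areas:", paste(sprintf("%s=%.4g", names(x$areas), x$areas),
                      collapse = ", "), "\n")
  invisible(x)
}

#' @export
plot.peak_segmentation <- function(x, ...) {
  graphics::plot(x$trace$position, x$trace$absorbance, type = "l",
                 xlab = "gradient position", ylab = "A254 (corrected)",
                 ...)
  for (iv in x$intervals) graphics::abline(v = iv[1], lty = 3)
  graphics::abline(v = x$intervals$polysome[2], lty = 3)
  invisible(x)
}
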