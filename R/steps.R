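## Automated photobleaching step detection: penalized binary segmentation
## of a trace into piecewise-constant levels, then a monotone-decreasing
## level filter and a terminal-baseline check. Traces that fail the filters
## are discarded with a reason, never raised as errors.

# best single split of x[lo:hi]: returns the split index (last frame of the
# left segment, absolute) and the RSS gain, using cumulative sums
best_split <- function(cs, cs2, lo, hi) {
  n <- hi - lo + 1
  if (n < 2) return(NULL)
  seg_sum <- cs[hi + 1] - cs[lo]
  seg_sum2 <- cs2[hi + 1] - cs2[lo]
  sse_all <- seg_sum2 - seg_sum^2 / n
  k <- lo:(hi - 1)
  nl <- k - lo + 1
  nr <- hi - k
  sl <- cs[k + 1] - cs[lo]
  sr <- seg_sum - sl
  sse_split <- (cs2[k + 1] - cs2[lo] - sl^2 / nl) +
    (seg_sum2 - (cs2[k + 1] - cs2[lo]) - sr^2 / nr)
  i <- which.min(sse_split)
  list(at = k[i], gain = sse_all - sse_split[i])
}

# recursive binary segmentation; returns sorted changepoints (last frame of
# each upper segment, 1-based positions within x)
binseg <- function(x, threshold) {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x^2))
  cps <- integer(0)
  queue <- list(c(1L, length(x)))
  while (length(queue) > 0) {
    seg <- queue[[1]]; queue <- queue[-1]
    sp <- best_split(cs, cs2, seg[1], seg[2])
    if (is.null(sp) || sp$gain <= threshold) next
    cps <- c(cps, sp$at)
    queue <- c(queue, list(c(seg[1], sp$at)), list(c(sp$at + 1L, seg[2])))
  }
  sort(cps)
}

#' Detect photobleaching steps in a trace
#'
#' Changepoints by binary segmentation of the residual sum of squares; a
#' split is accepted only if it reduces the RSS by more than
#' `penalty * sigma^2 * log(T)`, with `sigma` estimated robustly as the
#' median absolute first difference / (sqrt(2) * 0.6745). Post-filters mark
#' a call `discarded` (with a reason) unless all fitted levels are strictly
#' decreasing with drops of at least `min_step`, and the final level is
#' within `3 sigma` of the terminal `baseline`.
#'
#' @param trace a `trace`.
#' @param min_step minimum accepted level drop (counts).
#' @param penalty penalty multiplier on `sigma^2 log(T)` (default 6).
#' @param baseline expected terminal baseline (counts, default 0).
#' @return a `step_call`: list with `id`, `k` (NA when discarded),
#'   `changepoints` (frame indices of the first frame at the new level),
#'   `levels` (k + 1 fitted means), `quality` ("clean"/"discarded"),
#'   `reason`, `sigma`.
#' @export
detect_steps <- function(trace, min_step = 50, penalty = 6, baseline = 0) {
  stopifnot(inherits(trace, "trace"))
  x <- trace$intensity
  T_ <- length(x)
  if (T_ < 10) {
    return(step_call(trace$id, NA_integer_, integer(0), numeric(0),
                     "discarded", "trace shorter than 10 frames", NA_real_))
  }
  d <- diff(x)
  sigma <- stats::median(abs(d)) / (sqrt(2) * 0.6745)
  thr <- penalty * max(sigma, 1e-12)^2 * log(T_)
  cps <- binseg(x, thr)
  bounds <- c(0L, cps, T_)
  levels <- vapply(seq_len(length(bounds) - 1L), function(i)
    mean(x[(bounds[i] + 1L):bounds[i + 1L]]), numeric(1))
  k <- length(cps)
  call_frames <- trace$frame[cps + 1L]   # first frame at the new level
  fail <- function(reason)
    step_call(trace$id, NA_integer_, call_frames, levels, "discarded",
              reason, sigma)
  if (k == 0) return(fail("no steps"))
  drops <- -diff(levels)
  if (any(drops < min_step))
    return(fail(sprintf("level change %.1f below min_step %.1f",
                        min(drops), min_step)))
  if (abs(levels[k + 1] - baseline) > max(3 * sigma, 1e-9))
    return(fail(sprintf("final level %.1f not within 3 sigma of baseline %.1f",
                        levels[k + 1], baseline)))
  step_call(trace$id, k, call_frames, levels, "clean", NA_character_, sigma)
}

step_call <- function(id, k, changepoints, levels, quality, reason, sigma) {
  structure(list(id = id, k = k, changepoints = changepoints,
                 levels = levels, quality = quality, reason = reason,
                 sigma = sigma),
            class = "step_call")
}

#' @export
print.step_call <- function(x, ...) {
  if (x$quality == "clean")
    cat(sprintf("<step_call> %s: %d step(s) at {%s}\n", x$id, x$k,
                paste(x$changepoints, collapse = ", ")))
  else
    cat(sprintf("<step_call> %s: discarded (%s)\n", x$id, x$reason))
  invisible(x)
}

#' Aggregate step calls into a step-count distribution
#'
#' @param calls list of `step_call`.
#' @param k_max largest step count tracked (default: max observed).
#' @return a `step_distribution`: list with `counts` (named vector over
#'   k = 1..k_max), `discarded`, `total`.
#' @export
step_distribution <- function(calls, k_max = NULL) {
  stopifnot(length(calls) >= 1)
  ks <- vapply(calls, function(c_) c_$k %||% NA_integer_, 1L)
  clean <- !is.na(ks)
  if (!any(clean)) stop("all traces were discarded")
  if (is.null(k_max)) k_max <- max(ks[clean])
  counts <- tabulate(ks[clean], nbins = k_max)
  names(counts) <- seq_len(k_max)
  structure(list(counts = counts, discarded = sum(!clean),
                 total = length(calls)),
            class = "step_distribution")
}

#' @export
print.step_distribution <- function(x, ...) {
  pct <- 100 * x$counts / sum(x$counts)
  cat(sprintf("<step_distribution> %d clean, %d discarded\n",
              sum(x$counts), x$discarded))
  for (k in seq_along(x$counts))
    cat(sprintf("  %d step(s): %5d  (%.1f%%)\n", k, x$counts[k], pct[k]))
  invisible(x)
}

#' Two-step to one-step initial-brightness ratio
#'
#' (mean initial fitted level of clean two-step traces - baseline) /
#' (mean initial fitted level of clean one-step traces - baseline). For a
#' faithful staircase this is 2: two fluorophores are twice as bright as
#' one.
#'
#' @param calls list of `step_call`.
#' @param baseline baseline offset subtracted from levels.
#' @return the ratio (numeric).
#' @export
intensity_ratio <- function(calls, baseline = 0) {
  ks <- vapply(calls, function(c_) c_$k %||% NA_integer_, 1L)
  lvl0 <- vapply(calls, function(c_)
    if (length(c_$levels)) c_$levels[1] else NA_real_, 1)
  one <- !is.na(ks) & ks == 1L
  two <- !is.na(ks) & ks == 2L
  if (!any(one) || !any(two))
    stop("need at least one clean one-step and one clean two-step trace")
  (mean(lvl0[two]) - baseline) / (mean(lvl0[one]) - baseline)
}
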