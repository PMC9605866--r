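## Synthetic photobleaching traces drawn from a binomial subunit-labeling
## model: per complex, k ~ Binomial(n, p) fluorophores mature; each bleaches
## at a time drawn from a truncated exponential; intensity is
## baseline + (active count) * unit + Gaussian noise.

#' Photobleaching trace specification
#'
#' Defaults emulate the single-molecule pulldown experiment this package
#' models: a dimer (`n = 2`) with fluorophore maturation probability
#' `p = 0.8`, recorded for 200 frames at signal-to-noise 10
#' (`unit / noise_sd`).
#'
#' @param n_traces number of traces to generate.
#' @param n subunit (fluorophore site) count, >= 1.
#' @param p maturation probability in `[0, 1]`.
#' @param unit intensity per active fluorophore (camera counts).
#' @param noise_sd additive Gaussian noise sd (counts).
#' @param mean_bleach mean bleach time (frames) of the exponential.
#' @param n_frames trace length (frames), > 0.
#' @param baseline constant offset (counts).
#' @param reblink_prob optional probability that a bleached fluorophore
#'   re-brightens once (stress case for detectors); default 0.
#' @param seed RNG seed.
#' @return a `trace_spec` object.
#' @export
trace_spec <- function(n_traces = 100, n = 2, p = 0.8, unit = 100,
                       noise_sd = 10, mean_bleach = 50, n_frames = 200,
                       baseline = 0, reblink_prob = 0, seed = 1) {
  stopifnot(n_traces >= 1, n >= 1, p >= 0, p <= 1, n_frames > 0,
            unit > 0, noise_sd >= 0, mean_bleach > 0,
            reblink_prob >= 0, reblink_prob < 1)
  structure(list(n_traces = as.integer(n_traces), n = as.integer(n), p = p,
                 unit = unit, noise_sd = noise_sd,
                 mean_bleach = mean_bleach, n_frames = as.integer(n_frames),
                 baseline = baseline, reblink_prob = reblink_prob,
                 seed = as.integer(seed)),
            class = "trace_spec")
}

# inverse-CDF draw from Exp(rate = 1/mean) truncated to (0, upper)
rexp_truncated <- function(n, mean, upper) {
  u <- stats::runif(n)
  -mean * log(1 - u * (1 - exp(-upper / mean)))
}

#' Generate photobleaching traces with ground truth
#'
#' Per trace, `k ~ Binomial(n, p)` active fluorophores; `k` bleach times
#' i.i.d. from an exponential with the given mean, truncated to the trace
#' length so every mature fluorophore bleaches on camera; intensity at
#' frame `t` is `baseline + (# unbleached at t) * unit + noise`.
#' Deterministic given the spec.
#'
#' @param spec a `trace_spec`.
#' @return list with `traces` (list of `trace`) and `truth` (data.frame:
#'   trace id, true step count `k`, comma-joined step frames).
#' @export
make_traces <- function(spec) {
  stopifnot(inherits(spec, "trace_spec"))
  with_seed_(spec$seed, {
    traces <- vector("list", spec$n_traces)
    truth <- data.frame(id = character(spec$n_traces),
                        k = integer(spec$n_traces),
                        steps = character(spec$n_traces),
                        stringsAsFactors = FALSE)
    tgrid <- seq_len(spec$n_frames) - 1L
    for (i in seq_len(spec$n_traces)) {
      k <- stats::rbinom(1, spec$n, spec$p)
      times <- sort(rexp_truncated(k, spec$mean_bleach, spec$n_frames - 1))
      step_frames <- ceiling(times)        # first frame at the lower level
      active <- outer(tgrid, step_frames, `<`)
      n_active <- if (k > 0) rowSums(active) else rep(0L, spec$n_frames)
      if (spec$reblink_prob > 0 && k > 0) {
        for (s in seq_len(k)) {
          if (stats::runif(1) < spec$reblink_prob &&
              step_frames[s] < spec$n_frames - 2) {
            on_at <- step_frames[s] +
              sample.int(spec$n_frames - 1 - step_frames[s], 1)
            off_at <- min(spec$n_frames - 1,
                          on_at + sample.int(5, 1))
            idx <- tgrid >= on_at & tgrid < off_at
            n_active[idx] <- n_active[idx] + 1
          }
        }
      }
      intensity <- spec$baseline + n_active * spec$unit +
        stats::rnorm(spec$n_frames, 0, spec$noise_sd)
      id <- sprintf("trace%05d", i)
      traces[[i]] <- trace(id, intensity, tgrid)
      truth$id[i] <- id
      truth$k[i] <- k
      truth$steps[i] <- paste(step_frames, collapse = ",")
    }
    list(traces = traces, truth = truth)
  })
}
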