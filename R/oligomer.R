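## Binomial subunit-stoichiometry inference from a step-count distribution.
## Observed molecules are conditioned on detection (k >= 1, dark complexes
## are invisible) and mixed with a uniform outlier kernel so that observed
## k > n (e.g. coincidental colocalization) has nonzero likelihood.

#' Conditional binomial step-count model
#'
#' Base pmf `B(k; n, p)`; conditional on detection `B(k)/(1 - B(0))` for
#' `1 <= k <= n`, zero above; mixed with uniform outliers:
#' `P(k) = (1 - eps) cond(k) + eps / k_max`.
#'
#' @param n subunit count, >= 1.
#' @param p maturation probability (must be > 0: detection is impossible
#'   otherwise).
#' @param eps outlier rate in `[0, 1)`.
#' @param k_max support upper bound (default `n`).
#' @return list with `unconditional` (k = 0..n), `conditional`
#'   (k = 1..k_max, sums to 1), `n`, `p`, `eps`, `k_max`.
#' @export
conditional_binomial <- function(n, p, eps = 0, k_max = n) {
  stopifnot(n >= 1, p >= 0, p <= 1, eps >= 0, eps < 1, k_max >= 1)
  if (p == 0) stop("p = 0: detection impossible, conditional undefined")
  uncond <- stats::dbinom(0:n, n, p)
  cond <- numeric(k_max)
  kk <- seq_len(min(n, k_max))
  cond[kk] <- uncond[kk + 1] / (1 - uncond[1])
  cond <- cond / sum(cond)              # renormalise if k_max < n
  pk <- (1 - eps) * cond + eps / k_max
  list(unconditional = stats::setNames(uncond, 0:n),
       conditional = stats::setNames(pk, seq_len(k_max)),
       n = n, p = p, eps = eps, k_max = k_max)
}

# multinomial log-likelihood of counts (k = 1..k_max) under the model
oligomer_loglik <- function(counts, n, p, eps, k_max) {
  pk <- conditional_binomial(n, p, eps, k_max)$conditional
  if (any(counts > 0 & pk <= 0)) return(-Inf)
  sum(counts[counts > 0] * log(pk[counts > 0]))
}

# golden-section maximisation of the log-likelihood over p in (lo, hi)
golden_p <- function(counts, n, eps, k_max, lo = 1e-4, hi = 1 - 1e-9,
                     tol = 1e-7) {
  gr <- (sqrt(5) - 1) / 2
  a <- lo; b <- hi
  f <- function(p) oligomer_loglik(counts, n, p, eps, k_max)
  x1 <- b - gr * (b - a); x2 <- a + gr * (b - a)
  f1 <- f(x1); f2 <- f(x2)
  while (b - a > tol) {
    if (f1 < f2) {
      a <- x1; x1 <- x2; f1 <- f2
      x2 <- a + gr * (b - a); f2 <- f(x2)
    } else {
      b <- x2; x2 <- x1; f2 <- f1
      x1 <- b - gr * (b - a); f1 <- f(x1)
    }
  }
  p <- (a + b) / 2
  list(p = p, loglik = f(p))
}

#' Fit subunit stoichiometry to a step-count distribution
#'
#' Maximum-likelihood model selection over candidate subunit counts
#' `n_range` under the conditional binomial with outlier rate `eps`. The
#' maturation probability is either fixed (default 0.8) or profiled by
#' golden-section maximisation per candidate. Ties (log-likelihoods within
#' 1e-9) break toward the smaller n (parsimony).
#'
#' @param dist a `step_distribution` (or a named counts vector over
#'   k = 1, 2, ...).
#' @param p fixed maturation probability, or `"free"` to fit it.
#' @param eps outlier rate (default 0.02).
#' @param n_range candidate subunit counts (default 1:6).
#' @return an `oligomer_fit`: list with `best_n`, `p` (per candidate),
#'   `loglik` (per candidate), `predicted` (conditional distribution of the
#'   best model), `counts`, `eps`, `k_max`.
#' @export
fit_oligomer <- function(dist, p = 0.8, eps = 0.02, n_range = 1:6) {
  counts <- if (inherits(dist, "step_distribution")) dist$counts
            else dist
  stopifnot(length(counts) >= 1, all(counts >= 0), sum(counts) > 0)
  k_obs <- max(which(counts > 0))
  k_max <- max(k_obs, max(n_range))
  counts <- c(counts, numeric(k_max - length(counts)))
  if (eps == 0 && all(n_range < k_obs))
    stop("observed k = ", k_obs, " exceeds every candidate n and eps = 0: ",
         "all likelihoods are zero; set eps > 0")
  free_p <- identical(p, "free")
  lls <- numeric(length(n_range))
  ps <- numeric(length(n_range))
  for (i in seq_along(n_range)) {
    if (free_p) {
      g <- golden_p(counts, n_range[i], eps, k_max)
      ps[i] <- g$p; lls[i] <- g$loglik
    } else {
      ps[i] <- p
      lls[i] <- oligomer_loglik(counts, n_range[i], p, eps, k_max)
    }
  }
  # ties toward smaller n: first index within 1e-9 of the max
  best_i <- which(lls >= max(lls) - 1e-9)[1]
  best_n <- n_range[best_i]
  structure(list(best_n = best_n,
                 p = stats::setNames(ps, n_range),
                 loglik = stats::setNames(lls, n_range),
                 predicted = conditional_binomial(best_n, ps[best_i], eps,
                                                  k_max)$conditional,
                 counts = stats::setNames(counts, seq_len(k_max)),
                 eps = eps, k_max = k_max),
            class = "oligomer_fit")
}

#' @export
print.oligomer_fit <- function(x, ...) {
  cat(sprintf("<oligomer_fit> best n = %d (eps = %g)\n", x$best_n, x$eps))
  df <- data.frame(n = as.integer(names(x$loglik)), p = round(x$p, 4),
                   loglik = round(x$loglik, 2))
  print(df, row.names = FALSE)
  invisible(x)
}
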