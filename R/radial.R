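## Radial thickness profiles around the protein footprint and the distance
## over which a deformation propagates before the map returns to bulk.

#' Radial thickness profile around a protein footprint
#'
#' Occupied map bins are grouped into annuli by distance from the protein
#' surface, `d = |r_xy - center| - radius` (minimum image, `d >= 0`); each
#' annulus carries a count-weighted mean thickness. The bulk reference is
#' the count-weighted mean over annuli whose inner edge lies at or beyond
#' `bulk_min`.
#'
#' @param map a `thickness_map`.
#' @param center protein footprint center `(x, y)`, Angstrom.
#' @param radius footprint radius, Angstrom (>= 0).
#' @param r_bin annulus width, Angstrom.
#' @param bulk_min distance beyond which annuli define the bulk reference,
#'   Angstrom. Default: 60% of the largest retained distance.
#' @param r_max largest surface distance retained. Default
#'   `min(box)/2 - radius`: annuli beyond the inscribed circle are
#'   incomplete (corner bins only) and statistically unstable.
#' @return a `radial_profile`: data.frame with `r_lo`, `r_hi`, `r_mid`,
#'   `mean`, `n`, plus attributes `bulk` and `r_bin`.
#' @export
radial_thickness_profile <- function(map, center, radius = 0, r_bin = 2,
                                     bulk_min = NULL, r_max = NULL) {
  stopifnot(inherits(map, "thickness_map"), r_bin > 0, radius >= 0)
  nx <- nrow(map$mean); ny <- ncol(map$mean)
  box <- map$box %||% (c(nx, ny) * map$bin)
  bx <- map$origin[1] + (seq_len(nx) - 0.5) * map$bin
  by <- map$origin[2] + (seq_len(ny) - 0.5) * map$bin
  dx <- minimum_image(rep(bx, times = ny) - center[1], box[1])
  dy <- minimum_image(rep(by, each = nx) - center[2], box[2])
  d <- sqrt(dx^2 + dy^2) - radius
  if (is.null(r_max)) r_max <- min(box) / 2 - radius
  occ <- map$counts > 0 & d >= 0 & d <= r_max
  if (!any(occ)) stop("all occupied bins lie inside the protein footprint")
  di <- d[occ]
  w <- map$counts[occ]
  v <- map$mean[occ]
  ann <- floor(di / r_bin)
  wsum <- rowsum(w, ann, reorder = TRUE)
  vsum <- rowsum(w * v, ann, reorder = TRUE)
  lo <- as.integer(rownames(wsum)) * r_bin
  prof <- data.frame(r_lo = lo, r_hi = lo + r_bin, r_mid = lo + r_bin / 2,
                     mean = vsum[, 1] / wsum[, 1], n = wsum[, 1])
  rownames(prof) <- NULL
  if (is.null(bulk_min)) bulk_min <- 0.6 * max(prof$r_hi)
  bulk_idx <- prof$r_lo >= bulk_min
  if (!any(bulk_idx))
    stop("no annuli beyond bulk_min = ", bulk_min, " A to define the bulk")
  bulk <- sum(prof$mean[bulk_idx] * prof$n[bulk_idx]) / sum(prof$n[bulk_idx])
  structure(prof, bulk = bulk, r_bin = r_bin, bulk_min = bulk_min,
            class = c("radial_profile", "data.frame"))
}

#' @export
print.radial_profile <- function(x, ...) {
  cat(sprintf("<radial_profile> %d annuli of %g A, bulk %.3f A (r >= %g A)\n",
              nrow(x), attr(x, "r_bin"), attr(x, "bulk"),
              attr(x, "bulk_min")))
  invisible(x)
}

#' Deformation propagation distance
#'
#' The smallest distance `d*` from the protein surface beyond which every
#' annulus mean stays within `tolerance` of the bulk reference. If the
#' profile never settles, the outermost annulus edge is returned with
#' attribute `converged = FALSE`.
#'
#' @param profile a `radial_profile`.
#' @param tolerance Angstrom, > 0.
#' @return distance in Angstrom with attribute `converged`.
#' @export
propagation_distance <- function(profile, tolerance = 0.5) {
  stopifnot(inherits(profile, "radial_profile"))
  if (tolerance <= 0) stop("tolerance must be > 0")
  bulk <- attr(profile, "bulk")
  dev <- abs(profile$mean - bulk)
  off <- which(dev >= tolerance)
  if (length(off) == 0)
    return(structure(0, converged = TRUE))
  last_off <- max(off)
  if (last_off == nrow(profile))
    return(structure(profile$r_hi[nrow(profile)], converged = FALSE))
  structure(profile$r_hi[last_off], converged = TRUE)
}

#' Recover a Gaussian deformation from a radial profile
#'
#' Weighted least-squares fit of `thickness(d) = bulk + a * exp(-(d + radius
#' - r0)^2 / (2 sigma^2))` to the annulus means, used to score how well a
#' mapped deformation matches an imposed field. The Gaussian is centred at
#' the footprint surface (`r0 = radius`, i.e. distance 0) as the generator
#' places it.
#'
#' @param profile a `radial_profile`.
#' @param amplitude0,sigma0 starting values.
#' @return list with `amplitude` (signed, Angstrom; negative = thinner than
#'   bulk), `sigma` (Angstrom), `bulk`, and the `nls` fit.
#' @export
fit_gaussian_profile <- function(profile, amplitude0 = NULL, sigma0 = 10) {
  stopifnot(inherits(profile, "radial_profile"))
  bulk <- attr(profile, "bulk")
  df <- data.frame(d = profile$r_mid, y = profile$mean - bulk,
                   w = profile$n)
  if (is.null(amplitude0))
    amplitude0 <- df$y[which.max(abs(df$y))]
  fit <- stats::nls(y ~ a * exp(-d^2 / (2 * s^2)), data = df,
                    start = list(a = amplitude0, s = sigma0),
                    weights = df$w,
                    control = stats::nls.control(maxiter = 200,
                                                 warnOnly = TRUE))
  co <- stats::coef(fit)
  list(amplitude = unname(co["a"]), sigma = abs(unname(co["s"])),
       bulk = bulk, fit = fit)
}
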