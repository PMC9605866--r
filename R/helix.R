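## Helix bend geometry: each half's axis is estimated from its CA trace and
## the bend is the angle between the two half-axes. The axis estimator uses
## the fact that second differences of consecutive CA positions of an ideal
## helix are exactly perpendicular to its axis: the axis is the null-space
## (smallest right singular) vector of the second-difference matrix. Unlike
## the raw principal direction of the CA cloud, this is unbiased for
## fractional numbers of turns, which dominate at 3-4-turn helix lengths.

# helix axis of an ordered CA segment, oriented from the first toward the
# last point
helix_axis <- function(xyz) {
  n <- nrow(xyz)
  d2 <- diff(diff(xyz))           # (n-2) x 3 second differences
  v <- svd(d2, nu = 0)$v[, 3]     # direction least explained by wobble
  span <- xyz[n, ] - xyz[1, ]
  if (sum(v * span) < 0) v <- -v
  v
}

#' Helix axis and bend geometry from a CA trace
#'
#' @param coords ordered CA coordinates (n x 3 matrix, data.frame with
#'   x/y/z, or `atom_model` of CA atoms), N- to C-terminal; n >= 8 with at
#'   least 4 CA per half.
#' @param split index of the last residue of the N-terminal half; default
#'   the midpoint.
#' @return a `helix_geometry`: list with `axis_n`, `axis_c` (unit vectors,
#'   N->C oriented), `bend` (degrees in [0, 180]), `centroid`,
#'   `axial_length` (projection of the end-to-end vector on the full-helix
#'   axis, Angstrom).
#' @export
helix_geometry <- function(coords, split = NULL) {
  xyz <- as_coord_matrix(coords)
  n <- nrow(xyz)
  if (n < 8) stop("need >= 8 CA atoms for helix geometry")
  if (is.null(split)) split <- floor(n / 2)
  if (split < 4 || n - split < 4)
    stop("each half needs >= 4 CA atoms (split = ", split, ", n = ", n, ")")
  ax_n <- helix_axis(xyz[1:split, , drop = FALSE])
  ax_c <- helix_axis(xyz[(split + 1):n, , drop = FALSE])
  ct <- max(-1, min(1, sum(ax_n * ax_c)))
  full_axis <- helix_axis(xyz)
  structure(list(axis_n = ax_n, axis_c = ax_c,
                 bend = acos(ct) * 180 / pi,
                 centroid = colMeans(xyz),
                 axial_length = abs(sum((xyz[n, ] - xyz[1, ]) * full_axis))),
            class = "helix_geometry")
}

#' @export
print.helix_geometry <- function(x, ...) {
  cat(sprintf("<helix_geometry> bend %.2f deg, axial length %.1f A\n",
              x$bend, x$axial_length))
  invisible(x)
}
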