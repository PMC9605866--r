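#' @keywords internal
"_PACKAGE"

## Internal geometry and validation helpers shared across modules.

#' Wrap coordinates into the primary periodic box
#'
#' Maps each coordinate into `[0, L)` along its axis. Wrapping is
#' idempotent: applying it twice gives the same result as once.
#'
#' @param x numeric vector of coordinates (Angstrom).
#' @param box_length box edge along this axis (Angstrom), > 0.
#' @return numeric vector, each element in `[0, box_length)`.
#' @export
wrap_coords <- function(x, box_length) {
  stopifnot(is.numeric(x), is.numeric(box_length), box_length > 0)
  w <- x - floor(x / box_length) * box_length
  # floating point can land exactly on L after the modulo; fold it back
  w[w >= box_length] <- 0
  w
}

#' Minimum-image displacement along one periodic axis
#'
#' @param dx numeric vector of raw coordinate differences.
#' @param box_length box edge (Angstrom).
#' @return displacement in `(-L/2, L/2]`.
#' @export
minimum_image <- function(dx, box_length) {
  dx - box_length * round(dx / box_length)
}

#' Rotation matrix from axis and angle
#'
#' Rodrigues' formula for a proper rotation about `axis` by `angle_deg`
#' degrees (right-handed).
#'
#' @param axis length-3 numeric vector, need not be unit norm, not zero.
#' @param angle_deg rotation angle in degrees.
#' @return 3x3 proper orthogonal matrix.
#' @export
axis_angle_matrix <- function(axis, angle_deg) {
  stopifnot(length(axis) == 3, all(is.finite(axis)))
  nrm <- sqrt(sum(axis^2))
  if (nrm < .Machine$double.eps) stop("rotation axis must be non-zero")
  u <- axis / nrm
  th <- angle_deg * pi / 180
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
}

#' Rotation angle of a rotation matrix
#'
#' `theta = acos((trace(R) - 1) / 2)`, clamped against round-off, in
#' degrees within `[0, 180]`.
#'
#' @param R 3x3 rotation matrix.
#' @return angle in degrees.
#' @export
rotation_angle <- function(R) {
  stopifnot(is.matrix(R), all(dim(R) == c(3L, 3L)))
  ct <- (sum(diag(R)) - 1) / 2
  acos(max(-1, min(1, ct))) * 180 / pi
}

## coordinate-matrix coercion: accepts an atom_model, a data.frame with
## x/y/z columns, or an n x 3 matrix.
as_coord_matrix <- function(x) {
  if (is.matrix(x)) {
    stopifnot(ncol(x) == 3)
    m <- x
  } else if (is.data.frame(x)) {
    stopifnot(all(c("x", "y", "z") %in% names(x)))
    m <- cbind(x$x, x$y, x$z)
  } else {
    stop("cannot interpret object of class '", class(x)[1],
         "' as coordinates")
  }
  storage.mode(m) <- "double"
  if (!all(is.finite(m))) stop("coordinates contain non-finite values")
  colnames(m) <- c("x", "y", "z")
  m
}

## run `expr` under a private RNG stream seeded with `seed`, restoring the
## caller's RNG state afterwards
with_seed_ <- function(seed, expr) {
  withr::with_seed(as.integer(seed), expr)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
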