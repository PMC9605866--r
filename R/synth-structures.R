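## Structure fixtures with exact rigid-transform and helix-geometry ground
## truth, used to validate the superposition and helix metrics.

#' Rigidly transformed copy of a model
#'
#' Rotates the model about its centroid by `angle_deg` around `axis`, then
#' translates; the true rotation matrix and translation are returned as
#' ground truth.
#'
#' @param model an `atom_model`.
#' @param axis length-3 rotation axis (non-zero).
#' @param angle_deg rotation angle, degrees.
#' @param translation length-3 translation, Angstrom.
#' @return list with `model` (transformed `atom_model`) and `truth`
#'   (rotation matrix `R`, `translation`, `angle_deg`, `axis`).
#' @export
make_rotated_copy <- function(model, axis = c(0, 0, 1), angle_deg = 0,
                              translation = c(0, 0, 0)) {
  stopifnot(inherits(model, "atom_model"), nrow(model) > 0,
            length(translation) == 3)
  R <- axis_angle_matrix(axis, angle_deg)
  xyz <- as_coord_matrix(model)
  ctr <- colMeans(xyz)
  new_xyz <- sweep(sweep(xyz, 2, ctr) %*% t(R), 2, ctr + translation, `+`)
  out <- model
  out$x <- new_xyz[, 1]; out$y <- new_xyz[, 2]; out$z <- new_xyz[, 3]
  list(model = out,
       truth = list(R = R, translation = translation,
                    angle_deg = angle_deg, axis = axis / sqrt(sum(axis^2))))
}

#' Ideal (optionally kinked) alpha-helix CA trace
#'
#' CA atoms on a regular helix (defaults: rise 1.5 A per residue, twist
#' 100 degrees, radius 2.3 A) along z. With `kink != 0` the C-terminal half
#' is tilted by that angle about an axis perpendicular to the helix axis at
#' the midpoint CA.
#'
#' @param n_res number of residues, >= 8 (axis fitting is undefined below).
#' @param rise rise per residue, Angstrom.
#' @param twist twist per residue, degrees.
#' @param radius helix radius, Angstrom.
#' @param kink kink angle at the midpoint, degrees.
#' @param chain chain id for the returned model.
#' @return an `atom_model` of CA atoms (residues 1..n_res).
#' @export
make_helix <- function(n_res, rise = 1.5, twist = 100, radius = 2.3,
                       kink = 0, chain = "A") {
  if (n_res < 8) stop("need >= 8 residues for a well-defined helix axis")
  i <- seq_len(n_res) - 1
  th <- i * twist * pi / 180
  xyz <- cbind(radius * cos(th), radius * sin(th), i * rise)
  if (kink != 0) {
    half <- ceiling(n_res / 2)
    pivot <- xyz[half, ]
    R <- axis_angle_matrix(c(1, 0, 0), kink)
    tail_idx <- (half + 1):n_res
    xyz[tail_idx, ] <- sweep(sweep(xyz[tail_idx, , drop = FALSE], 2, pivot)
                             %*% t(R), 2, pivot, `+`)
  }
  atom_model(data.frame(
    chain = chain, resid = seq_len(n_res), inscode = "",
    resname = "ALA", atom = "CA", element = "C",
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, bfac = 0, stringsAsFactors = FALSE))
}
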