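## Shrake-Rupley solvent-accessible surface area with a deterministic
## Fibonacci-sphere point set (no RNG: results are bit-reproducible), and
## buried interface area between two disjoint parts of a model.

# default van der Waals radii (Angstrom); replaceable because the radii
# behind published SASA figures are rarely stated
.default_vdw <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80, P = 1.80,
                  H = 1.20, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85,
                  FE = 1.80, ZN = 1.39, MG = 1.73, MN = 1.61)

#' Default van der Waals radii table
#'
#' @return named numeric vector of radii (Angstrom) by element symbol.
#' @export
vdw_radii <- function() .default_vdw

#' Deterministic quasi-uniform sphere point set
#'
#' Fibonacci (golden-angle) spiral on the unit sphere.
#'
#' @param n number of points.
#' @return n x 3 matrix of unit vectors.
#' @export
fibonacci_sphere <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- pi * (3 - sqrt(5)) * (seq_len(n) - 1)
  z <- 1 - 2 * i / n
  r <- sqrt(pmax(0, 1 - z^2))
  cbind(r * cos(phi), r * sin(phi), z)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Per atom, `area = 4 pi (r + probe)^2 * (accessible points / points)`,
#' where a sample point on the expanded sphere is accessible iff it lies
#' outside every neighbour's expanded sphere. Neighbours are atoms within
#' `r_i + r_j + 2 probe`. The point set is a deterministic Fibonacci
#' sphere.
#'
#' @param model an `atom_model` (elements must be known) or a data.frame
#'   with x/y/z and `element` columns.
#' @param probe probe radius, Angstrom (default 1.4, water).
#' @param points sample points per atom (default 960).
#' @param radii named radii table by element (default [vdw_radii()]).
#' @return list with `total` (Angstrom^2) and `per_atom` (numeric vector).
#' @export
sasa <- function(model, probe = 1.4, points = 960, radii = vdw_radii()) {
  stopifnot(probe >= 0, points >= 12)
  xyz <- as_coord_matrix(model)
  elem <- toupper(model$element)
  unknown <- setdiff(unique(elem), names(radii))
  if (length(unknown) > 0)
    stop("no van der Waals radius configured for element(s): ",
         paste(unknown, collapse = ", "),
         " (atoms ", paste(which(elem %in% unknown)[1:min(5, sum(elem %in% unknown))],
                           collapse = ", "), " ...)")
  r <- unname(radii[elem]) + probe
  n <- nrow(xyz)
  sphere <- fibonacci_sphere(points)
  per_atom <- numeric(n)
  # neighbour candidates via squared-distance threshold per pair
  max_r <- max(r)
  for (i in seq_len(n)) {
    d2 <- rowSums(sweep(xyz, 2, xyz[i, ])^2)
    cut2 <- (r[i] + r)^2
    nb <- which(d2 < cut2 & seq_len(n) != i)
    if (length(nb) == 0) {
      per_atom[i] <- 4 * pi * r[i]^2
      next
    }
    pts <- sphere * r[i]
    pts <- sweep(pts, 2, xyz[i, ], `+`)
    accessible <- rep(TRUE, points)
    for (j in nb) {
      if (!any(accessible)) break
      dd <- sweep(pts[accessible, , drop = FALSE], 2, xyz[j, ])
      accessible[accessible] <- rowSums(dd^2) > r[j]^2
    }
    per_atom[i] <- 4 * pi * r[i]^2 * sum(accessible) / points
  }
  list(total = sum(per_atom), per_atom = per_atom)
}

#' Buried interface area between two parts of a model
#'
#' `buried = sasa(A) + sasa(B) - sasa(A U B)`; both that sum and its half
#' ("interface area", the per-side convention) are reported, since
#' published figures use either convention.
#'
#' @param model an `atom_model` containing both parts.
#' @param part_a,part_b `selection_spec`s; must select disjoint atom sets.
#' @param probe probe radius, Angstrom.
#' @param points sample points per atom.
#' @param radii radii table.
#' @return an `interface_area`: list with `sasa_a`, `sasa_b`, `sasa_ab`,
#'   `buried`, `interface` (= buried / 2), `probe`, `points`.
#' @export
buried_interface_area <- function(model, part_a, part_b, probe = 1.4,
                                  points = 960, radii = vdw_radii()) {
  a <- apply_selection(model, part_a)
  b <- apply_selection(model, part_b)
  ka <- paste(a$chain, a$resid, a$inscode, a$atom)
  kb <- paste(b$chain, b$resid, b$inscode, b$atom)
  if (length(intersect(ka, kb)) > 0)
    stop("part_a and part_b overlap (", length(intersect(ka, kb)),
         " shared atoms)")
  ab <- rbind(as.data.frame(a), as.data.frame(b))
  sa <- sasa(a, probe, points, radii)$total
  sb <- sasa(b, probe, points, radii)$total
  sab <- sasa(ab, probe, points, radii)$total
  buried <- sa + sb - sab
  structure(list(sasa_a = sa, sasa_b = sb, sasa_ab = sab, buried = buried,
                 interface = buried / 2, probe = probe, points = points),
            class = "interface_area")
}

#' @export
print.interface_area <- function(x, ...) {
  cat(sprintf(
    "<interface_area> buried %.1f A^2 (per-side %.1f A^2); A %.1f, B %.1f, AB %.1f\n",
    x$buried, x$interface, x$sasa_a, x$sasa_b, x$sasa_ab))
  invisible(x)
}
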