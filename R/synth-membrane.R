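## Synthetic two-leaflet bead membranes with exact ground truth. Reference
## beads sit on jittered hexagonal lattices at z = +/- z0 + dz(x, y) + noise;
## the deformation field is a sum of Gaussians per leaflet, species are
## multinomial draws from the declared composition (re-weighted inside the
## protein shell), and a cylindrical protein footprint is emitted as a ring
## of "PROT" beads. Frames are i.i.d. redraws of jitter and noise around the
## same field, so time-averaging code paths are exercised without dynamics.

#' Membrane species composition
#'
#' Defaults to the PE:PC:SM:cholesterol 54:32:8:6 molar ratio.
#'
#' @param fractions named numeric vector of molar fractions; must be
#'   positive and sum to 1 within 1e-9.
#' @return named numeric vector (class `membrane_composition`).
#' @export
membrane_composition <- function(fractions = c(PE = 0.54, PC = 0.32,
                                               SM = 0.08, CHOL = 0.06)) {
  stopifnot(is.numeric(fractions), !is.null(names(fractions)),
            all(nzchar(names(fractions))))
  if (any(fractions <= 0)) stop("species fractions must be positive")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("species fractions must sum to 1 (got ", sum(fractions), ")")
  structure(fractions, class = "membrane_composition")
}

#' Gaussian deformation field
#'
#' `dz(x, y) = sum_i amplitude_i * exp(-r_i^2 / (2 sigma_i^2))`, evaluated
#' per leaflet. Amplitude is a signed z displacement in Angstrom applied to
#' that leaflet's reference-bead plane: on the lower leaflet a positive
#' amplitude moves beads toward the midplane (local thinning), a negative
#' one away from it.
#'
#' @param leaflet "upper" or "lower", one per component.
#' @param amplitude signed amplitude(s), Angstrom.
#' @param cx,cy component center(s), Angstrom.
#' @param sigma Gaussian width(s), Angstrom, > 0.
#' @return a `deformation_field` object (data.frame of components).
#' @export
deformation_field <- function(leaflet = character(), amplitude = numeric(),
                              cx = numeric(), cy = numeric(),
                              sigma = numeric()) {
  stopifnot(all(leaflet %in% c("upper", "lower")), all(sigma > 0),
            length(amplitude) == length(leaflet),
            length(cx) == length(leaflet), length(cy) == length(leaflet),
            length(sigma) == length(leaflet))
  structure(data.frame(leaflet = as.character(leaflet),
                       amplitude = amplitude, cx = cx, cy = cy,
                       sigma = sigma, stringsAsFactors = FALSE),
            class = c("deformation_field", "data.frame"))
}

#' Evaluate a deformation field
#'
#' @param field a `deformation_field`.
#' @param x,y coordinates (Angstrom).
#' @param leaflet which leaflet's components to evaluate.
#' @param box optional `(Lx, Ly)` for minimum-image radial distances.
#' @return signed z displacement at each (x, y), Angstrom.
#' @export
eval_deformation <- function(field, x, y, leaflet, box = NULL) {
  dz <- numeric(length(x))
  comp <- field[field$leaflet == leaflet, , drop = FALSE]
  for (i in seq_len(nrow(comp))) {
    dx <- x - comp$cx[i]
    dy <- y - comp$cy[i]
    if (!is.null(box)) {
      dx <- minimum_image(dx, box[1])
      dy <- minimum_image(dy, box[2])
    }
    r2 <- dx^2 + dy^2
    dz <- dz + comp$amplitude[i] * exp(-r2 / (2 * comp$sigma[i]^2))
  }
  dz
}

#' Synthetic membrane specification
#'
#' Defaults emulate the simulated patches of the source system: a
#' 400 x 400 A^2 box, ~64 A^2 area per lipid (coarse-grained fluid bilayer),
#' phosphate planes at +/-19 A, and a single embedded protein footprint at
#' the box center.
#'
#' @param box `(Lx, Ly)` Angstrom.
#' @param area_per_lipid Angstrom^2 per lipid per leaflet.
#' @param z0 leaflet reference offset (phosphate plane at +/- z0), Angstrom.
#' @param box_lz box height, Angstrom.
#' @param jitter_sd in-plane positional jitter sd, Angstrom.
#' @param noise_sd z noise sd, Angstrom.
#' @param composition a `membrane_composition`.
#' @param field a `deformation_field` (default: flat).
#' @param protein_center `(x, y)` footprint center; default box center.
#' @param protein_radius footprint radius, Angstrom (0 disables footprint).
#' @param shell_width width of the enrichment shell beyond the footprint
#'   surface, Angstrom.
#' @param shell_multipliers named multipliers applied to species fractions
#'   inside the shell (renormalised there); names must be in the
#'   composition.
#' @param chol_depth depth of the cholesterol hydroxyl bead below its
#'   leaflet's phosphate plane (toward the midplane), Angstrom.
#' @param n_frames number of frames (i.i.d. redraws), >= 1.
#' @param seed RNG seed (mandatory: generators are pure functions of the
#'   spec).
#' @return a `synthetic_membrane_spec` object.
#' @export
synthetic_membrane_spec <- function(box = c(400, 400),
                                    area_per_lipid = 64,
                                    z0 = 19,
                                    box_lz = 100,
                                    jitter_sd = 1,
                                    noise_sd = 0.8,
                                    composition = membrane_composition(),
                                    field = deformation_field(),
                                    protein_center = box / 2,
                                    protein_radius = 0,
                                    shell_width = 7,
                                    shell_multipliers = NULL,
                                    chol_depth = 5,
                                    n_frames = 1,
                                    seed = 1) {
  stopifnot(length(box) == 2, all(box > 0), area_per_lipid > 0, z0 > 0,
            n_frames >= 1, jitter_sd >= 0, noise_sd >= 0, box_lz > 2 * z0)
  if (protein_radius >= min(box) / 2)
    stop("protein footprint radius must be < min(Lx, Ly) / 2")
  if (!is.null(shell_multipliers)) {
    if (!all(names(shell_multipliers) %in% names(composition)))
      stop("shell multipliers name unknown species: ",
           paste(setdiff(names(shell_multipliers), names(composition)),
                 collapse = ", "))
    if (any(shell_multipliers < 0))
      stop("shell multipliers must be non-negative")
  }
  structure(list(box = box, area_per_lipid = area_per_lipid, z0 = z0,
                 box_lz = box_lz, jitter_sd = jitter_sd, noise_sd = noise_sd,
                 composition = composition, field = field,
                 protein_center = protein_center,
                 protein_radius = protein_radius,
                 shell_width = shell_width,
                 shell_multipliers = shell_multipliers,
                 chol_depth = chol_depth,
                 n_frames = as.integer(n_frames), seed = as.integer(seed)),
            class = "synthetic_membrane_spec")
}

# hexagonal lattice covering [0,Lx) x [0,Ly) at the given area per site
hex_lattice <- function(box, area) {
  a <- sqrt(2 * area / sqrt(3))      # lattice constant: area = sqrt(3)/2 a^2
  dy <- a * sqrt(3) / 2
  ny <- max(1L, round(box[2] / dy))
  dy <- box[2] / ny                  # stretch slightly so rows tile the box
  nx <- max(1L, round(box[1] / a))
  dx <- box[1] / nx
  pts <- do.call(rbind, lapply(seq_len(ny) - 1L, function(j) {
    xs <- (seq_len(nx) - 1L) * dx + (j %% 2) * dx / 2
    cbind(xs, j * dy)
  }))
  colnames(pts) <- c("x", "y")
  pts
}

# shell fractions: composition re-weighted by multipliers, renormalised
shell_fractions <- function(composition, multipliers) {
  f <- as.numeric(composition)
  names(f) <- names(composition)
  if (!is.null(multipliers)) f[names(multipliers)] <-
      f[names(multipliers)] * multipliers
  if (sum(f) <= 0) stop("shell multipliers leave no positive species mass")
  f / sum(f)
}

#' Generate a synthetic membrane frame set with ground truth
#'
#' Two leaflets of lipid reference beads (phosphate `PO4` for
#' phospholipids, hydroxyl `ROH` for cholesterol, placed `chol_depth`
#' Angstrom below the phosphate plane toward the midplane) on jittered
#' hexagonal lattices, plus a ring of protein beads (`species = "PROT"`,
#' bead `BB`) tracing the cylindrical footprint. Deterministic given the
#' spec (which includes the seed).
#'
#' @param spec a `synthetic_membrane_spec`.
#' @return list with `frames` (a `frame_set`) and `truth` (list: the spec,
#'   field, per-leaflet expected z function inputs, species fractions in
#'   shell and bulk, lattice sites, and seed).
#' @export
build_membrane <- function(spec) {
  stopifnot(inherits(spec, "synthetic_membrane_spec"))
  with_seed_(spec$seed, {
    sites <- hex_lattice(spec$box, spec$area_per_lipid)
    # exclude lattice sites inside the protein footprint
    if (spec$protein_radius > 0) {
      dx <- minimum_image(sites[, 1] - spec$protein_center[1], spec$box[1])
      dy <- minimum_image(sites[, 2] - spec$protein_center[2], spec$box[2])
      d <- sqrt(dx^2 + dy^2)
      in_shell <- d > spec$protein_radius &
        d <= spec$protein_radius + spec$shell_width
      sites <- sites[d > spec$protein_radius, , drop = FALSE]
      in_shell <- in_shell[d > spec$protein_radius]
    } else {
      in_shell <- rep(FALSE, nrow(sites))
    }
    n_per_leaflet <- nrow(sites)
    species_names <- names(spec$composition)
    bulk_f <- as.numeric(spec$composition)
    shell_f <- shell_fractions(spec$composition, spec$shell_multipliers)
    # fixed species identity per lattice site (lipids do not mutate between
    # frames); independent draws per leaflet
    draw_species <- function() {
      sp <- character(n_per_leaflet)
      n_sh <- sum(in_shell)
      if (n_sh > 0)
        sp[in_shell] <- sample(species_names, n_sh, TRUE, prob = shell_f)
      sp[!in_shell] <- sample(species_names, n_per_leaflet - n_sh, TRUE,
                              prob = bulk_f)
      sp
    }
    sp_up <- draw_species()
    sp_lo <- draw_species()

    # protein beads: rings at the footprint radius spanning the bilayer
    prot <- NULL
    if (spec$protein_radius > 0) {
      n_ring <- max(12L, round(2 * pi * spec$protein_radius / 3))
      th <- 2 * pi * (seq_len(n_ring) - 1) / n_ring
      zs <- seq(-spec$z0, spec$z0, length.out = 7)
      prot <- data.frame(
        species = "PROT", molid = 0L, bead = "BB",
        x = rep(spec$protein_center[1] + spec$protein_radius * cos(th),
                times = length(zs)),
        y = rep(spec$protein_center[2] + spec$protein_radius * sin(th),
                times = length(zs)),
        z = rep(zs, each = n_ring),
        stringsAsFactors = FALSE)
    }

    zmid <- spec$box_lz / 2   # membrane is centred in the box
    one_leaflet <- function(sign_, sp) {
      x <- wrap_coords(sites[, 1] + stats::rnorm(n_per_leaflet, 0,
                                                 spec$jitter_sd), spec$box[1])
      y <- wrap_coords(sites[, 2] + stats::rnorm(n_per_leaflet, 0,
                                                 spec$jitter_sd), spec$box[2])
      leaf <- if (sign_ > 0) "upper" else "lower"
      dz <- eval_deformation(spec$field, x, y, leaf, spec$box)
      z <- sign_ * spec$z0 + dz + stats::rnorm(n_per_leaflet, 0,
                                               spec$noise_sd)
      bead <- ifelse(sp == "CHOL", "ROH", "PO4")
      # cholesterol hydroxyl rides chol_depth below the phosphate plane,
      # toward the midplane
      z <- z - sign_ * ifelse(sp == "CHOL", spec$chol_depth, 0)
      data.frame(species = sp, molid = NA_integer_, bead = bead,
                 x = x, y = y, z = z, stringsAsFactors = FALSE)
    }

    frames <- lapply(seq_len(spec$n_frames), function(fi) {
      up <- one_leaflet(+1, sp_up)
      lo <- one_leaflet(-1, sp_lo)
      df <- rbind(up, lo)
      df$molid <- seq_len(nrow(df))
      if (!is.null(prot)) {
        pr <- prot
        pr$molid <- nrow(df) + seq_len(nrow(pr))
        df <- rbind(df, pr)
      }
      df$z <- df$z + zmid
      membrane_frame(df, box = c(spec$box, spec$box_lz), time = fi - 1)
    })

    truth <- list(
      spec = spec,
      z0 = spec$z0,
      midplane = zmid,
      field = spec$field,
      shell_fractions = shell_f,
      bulk_fractions = stats::setNames(bulk_f, species_names),
      n_lipids_per_leaflet = n_per_leaflet,
      species_upper = sp_up,
      species_lower = sp_lo,
      sites = sites,
      in_shell = in_shell,
      seed = spec$seed)
    list(frames = frame_set(frames,
                            composition = spec$composition),
         truth = truth)
  })
}
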