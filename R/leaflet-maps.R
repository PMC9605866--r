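## Per-leaflet membrane thickness and lipid density maps. "Thickness" is
## the per-leaflet |z_phosphate - z_midplane| binned on a 2 A xy grid and
## averaged over the frame window (default: second half of the frame set);
## the midplane is recomputed per frame as the global mean phosphate z.

# resolve a frame window: "second_half", "full", or explicit c(first, last)
resolve_window <- function(n_frames, window) {
  if (is.character(window)) {
    window <- match.arg(window, c("second_half", "full"))
    if (window == "second_half") c(floor(n_frames / 2) + 1L, n_frames)
    else c(1L, n_frames)
  } else {
    stopifnot(length(window) == 2, window[1] >= 1, window[2] <= n_frames,
              window[1] <= window[2])
    as.integer(window)
  }
}

#' Global bilayer midplane of a frame
#'
#' Mean z over all phospholipid phosphate reference beads. Cholesterol
#' hydroxyls are excluded: only phosphates define the midplane.
#'
#' @param frame a `membrane_frame`.
#' @param beads reference-bead name sets ([bead_config()]).
#' @return midplane z, Angstrom.
#' @export
compute_midplane <- function(frame, beads = bead_config()) {
  ph <- is_phosphate_bead(frame, beads)
  if (!any(ph)) stop("frame contains no phosphate beads")
  mean(frame$z[ph])
}

#' Assign reference beads to leaflets
#'
#' Phospholipids by the sign of `z_phosphate - z0`, cholesterol by the sign
#' of `z_hydroxyl - z0`. A bead exactly at the midplane goes to the upper
#' leaflet with a warning.
#'
#' @param frame a `membrane_frame`.
#' @param z0 midplane z (from [compute_midplane()]).
#' @param beads reference-bead name sets.
#' @return character vector over frame rows: "upper", "lower", or NA for
#'   non-reference beads (protein, tails).
#' @export
assign_leaflets <- function(frame, z0 = compute_midplane(frame, beads),
                            beads = bead_config()) {
  ref <- is_reference_bead(frame, beads)
  out <- rep(NA_character_, nrow(frame))
  dz <- frame$z[ref] - z0
  if (any(dz == 0))
    warning(sum(dz == 0), " reference bead(s) exactly at the midplane; ",
            "assigned to the upper leaflet")
  out[ref] <- ifelse(dz >= 0, "upper", "lower")
  out
}

# shared binned accumulation: returns sum and count matrices over the grid
accumulate_grid <- function(x, y, values, box, bin) {
  nx <- max(1L, ceiling(box[1] / bin - 1e-9))
  ny <- max(1L, ceiling(box[2] / bin - 1e-9))
  ix <- pmin(nx - 1L, floor(wrap_coords(x, box[1]) / bin))
  iy <- pmin(ny - 1L, floor(wrap_coords(y, box[2]) / bin))
  idx <- ix + nx * iy + 1L
  counts <- tabulate(idx, nbins = nx * ny)
  sums <- numeric(nx * ny)
  if (length(values) > 0) {
    by_bin <- rowsum(values, idx, reorder = FALSE)
    sums[as.integer(rownames(by_bin))] <- by_bin[, 1]
  }
  list(sums = matrix(sums, nx, ny), counts = matrix(counts, nx, ny))
}

#' Per-leaflet thickness map
#'
#' For each 2 A (default) xy bin, the arithmetic mean over all in-window
#' (frame, phosphate) samples of `|z - z0(frame)|` for phosphates of the
#' requested leaflet. The midplane is recomputed per frame. Bins with zero
#' samples are `NA`, never zero.
#'
#' @param frames a `frame_set`.
#' @param leaflet "upper" or "lower".
#' @param bin bin edge, Angstrom (default 2).
#' @param window "second_half" (default), "full", or `c(first, last)`
#'   (1-based, inclusive).
#' @param beads reference-bead name sets.
#' @return a `thickness_map`: list with `mean` and `counts` matrices
#'   (nx x ny, row index along x), `bin`, `origin`, `leaflet`, `window`.
#' @export
thickness_map <- function(frames, leaflet = c("upper", "lower"), bin = 2,
                          window = "second_half", beads = bead_config()) {
  stopifnot(inherits(frames, "frame_set"), bin > 0)
  leaflet <- match.arg(leaflet)
  win <- resolve_window(length(frames), window)
  box <- attr(frames[[win[1]]], "box")
  sums <- NULL; counts <- NULL
  for (i in win[1]:win[2]) {
    f <- frames[[i]]
    z0 <- compute_midplane(f, beads)
    side <- assign_leaflets(f, z0, beads)
    sel <- is_phosphate_bead(f, beads) & !is.na(side) & side == leaflet
    if (!any(sel)) next
    acc <- accumulate_grid(f$x[sel], f$y[sel], abs(f$z[sel] - z0), box, bin)
    if (is.null(sums)) { sums <- acc$sums; counts <- acc$counts }
    else { sums <- sums + acc$sums; counts <- counts + acc$counts }
  }
  if (is.null(sums)) stop("no phosphate samples of the ", leaflet,
                          " leaflet in the window")
  m <- sums / counts
  m[counts == 0] <- NA_real_
  structure(list(leaflet = leaflet, mean = m, counts = counts, bin = bin,
                 origin = c(0, 0), window = win, box = box[1:2]),
            class = "thickness_map")
}

#' @export
print.thickness_map <- function(x, ...) {
  cat(sprintf(
    "<thickness_map> %s leaflet: %d x %d bins of %g A, frames %d-%d, %d samples\n",
    x$leaflet, nrow(x$mean), ncol(x$mean), x$bin, x$window[1], x$window[2],
    sum(x$counts)))
  cat(sprintf("  occupied-bin mean thickness %.2f A\n",
              mean(x$mean, na.rm = TRUE)))
  invisible(x)
}

#' Lipid density map for one species
#'
#' Raw counts of the species' reference bead per xy bin, summed over the
#' frame window.
#'
#' @param frames a `frame_set`.
#' @param species species label (must be present in the frames).
#' @param bin bin edge, Angstrom.
#' @param window frame window (see [thickness_map()]).
#' @param beads reference-bead name sets.
#' @return a `density_map`: list with `counts`, `bin`, `origin`, `species`,
#'   `window`.
#' @export
density_map <- function(frames, species, bin = 2, window = "second_half",
                        beads = bead_config()) {
  stopifnot(inherits(frames, "frame_set"), bin > 0)
  if (!species %in% frames[[1]]$species)
    stop("unknown species '", species, "'; frames contain: ",
         paste(sort(unique(frames[[1]]$species)), collapse = ", "))
  win <- resolve_window(length(frames), window)
  box <- attr(frames[[win[1]]], "box")
  counts <- NULL
  for (i in win[1]:win[2]) {
    f <- frames[[i]]
    sel <- f$species == species & is_reference_bead(f, beads)
    acc <- accumulate_grid(f$x[sel], f$y[sel], rep(0, sum(sel)), box, bin)
    counts <- if (is.null(counts)) acc$counts else counts + acc$counts
  }
  structure(list(species = species, counts = counts, bin = bin,
                 origin = c(0, 0), window = win, box = box[1:2]),
            class = "density_map")
}

#' @export
print.density_map <- function(x, ...) {
  cat(sprintf("<density_map> %s: %d x %d bins of %g A, %d samples\n",
              x$species, nrow(x$counts), ncol(x$counts), x$bin,
              sum(x$counts)))
  invisible(x)
}
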