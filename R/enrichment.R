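## Time-averaged lipid composition within a cutoff of the protein and the
## depletion-enrichment index: index(L) = ratio(L)_shell / ratio(L)_bulk,
## where each ratio is the species' fraction of total lipid counts in the
## shell and in the whole membrane respectively.

# squared minimum-image distances from each row of `a` to each row of `b`;
# returns, for each row of `a`, the minimum over `b` (vectorised over `a`,
# looping over the smaller protein set)
min_dist2_to_set <- function(a, b, box, periodic_z = FALSE) {
  best <- rep(Inf, nrow(a))
  for (j in seq_len(nrow(b))) {
    dx <- minimum_image(a[, 1] - b[j, 1], box[1])
    dy <- minimum_image(a[, 2] - b[j, 2], box[2])
    dz <- a[, 3] - b[j, 3]
    if (periodic_z) dz <- minimum_image(dz, box[3])
    d2 <- dx^2 + dy^2 + dz^2
    best <- pmin(best, d2)
  }
  best
}

# cell-list accelerated shell membership: TRUE for rows of `lip` whose
# minimum-image distance to the nearest protein bead is <= cutoff
shell_mask_cell <- function(lip, prot, box, cutoff, periodic_z = FALSE) {
  # cell edge >= cutoff along each axis
  ncell <- pmax(1L, floor(box / cutoff))
  edge <- box / ncell
  cell_of <- function(m) {
    ix <- pmin(ncell[1] - 1L, floor(wrap_coords(m[, 1], box[1]) / edge[1]))
    iy <- pmin(ncell[2] - 1L, floor(wrap_coords(m[, 2], box[2]) / edge[2]))
    iz <- pmin(ncell[3] - 1L, floor(wrap_coords(m[, 3], box[3]) / edge[3]))
    cbind(ix, iy, iz)
  }
  pc <- cell_of(prot)
  # mark every cell within one cell of a protein-occupied cell
  key <- function(c3) c3[, 1] + ncell[1] * (c3[, 2] + ncell[2] * c3[, 3])
  neigh <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  wrap_cell <- function(i, n, periodic) {
    if (periodic) ((i %% n) + n) %% n else pmin(pmax(i, 0L), n - 1L)
  }
  marked <- new.env(hash = TRUE, size = 4096L)
  for (r in seq_len(nrow(neigh))) {
    cx <- wrap_cell(pc[, 1] + neigh$dx[r], ncell[1], TRUE)
    cy <- wrap_cell(pc[, 2] + neigh$dy[r], ncell[2], TRUE)
    cz <- wrap_cell(pc[, 3] + neigh$dz[r], ncell[3], periodic_z)
    for (k in unique(key(cbind(cx, cy, cz))))
      assign(as.character(k), TRUE, envir = marked)
  }
  lc <- cell_of(lip)
  lk <- key(lc)
  cand <- vapply(as.character(lk), exists, TRUE, envir = marked,
                 inherits = FALSE, USE.NAMES = FALSE)
  mask <- rep(FALSE, nrow(lip))
  if (any(cand)) {
    d2 <- min_dist2_to_set(lip[cand, , drop = FALSE], prot, box, periodic_z)
    mask[cand] <- d2 <= cutoff^2
  }
  mask
}

#' Time-averaged lipid shell composition around the protein
#'
#' A lipid is "in shell" in a frame iff the minimum-image distance from its
#' reference bead (phosphate for phospholipids, hydroxyl for cholesterol)
#' to the nearest protein bead is at most `cutoff`. With several protein
#' copies membership is the union: each lipid counts once per frame.
#' Per-species shell counts are averaged over frames before any ratio is
#' formed.
#'
#' @param frames a `frame_set`.
#' @param protein_species species label of protein beads in the frames
#'   (default "PROT"), or a coordinate matrix/data.frame of protein beads
#'   shared by all frames.
#' @param cutoff shell cutoff, Angstrom (default 7).
#' @param window frame window: "full" (default), "second_half", or
#'   `c(first, last)`.
#' @param method "cell" (cell-list accelerated, default) or "brute"
#'   (all-pairs reference implementation); both give identical results.
#' @param periodic_z also apply minimum image along z (default FALSE: the
#'   bilayer is not periodic across its normal on the scales used here).
#' @param beads reference-bead name sets.
#' @return a `shell_counts` object: data.frame with `species`,
#'   `shell_count` (mean per frame), `total_count` (mean per frame), plus
#'   attributes `cutoff`, `window`, `n_frames`.
#' @export
shell_composition <- function(frames, protein_species = "PROT", cutoff = 7,
                              window = "full", method = c("cell", "brute"),
                              periodic_z = FALSE, beads = bead_config()) {
  stopifnot(inherits(frames, "frame_set"))
  if (cutoff <= 0) stop("cutoff must be > 0")
  method <- match.arg(method)
  win <- resolve_window(length(frames), window)
  species_levels <- NULL
  shell_sum <- NULL; total_sum <- NULL
  for (i in win[1]:win[2]) {
    f <- frames[[i]]
    box <- attr(f, "box")
    if (is.character(protein_species)) {
      prot <- as_coord_matrix(f[f$species %in% protein_species, ,
                                drop = FALSE])
    } else {
      prot <- as_coord_matrix(protein_species)
    }
    if (nrow(prot) == 0) stop("empty protein coordinate set")
    lip_rows <- is_reference_bead(f, beads) &
      !(f$species %in% protein_species)
    lip <- f[lip_rows, , drop = FALSE]
    if (is.null(species_levels)) {
      species_levels <- sort(unique(lip$species))
      shell_sum <- stats::setNames(numeric(length(species_levels)),
                                   species_levels)
      total_sum <- shell_sum
    }
    xyz <- as_coord_matrix(lip)
    mask <- if (method == "brute") {
      min_dist2_to_set(xyz, prot, box, periodic_z) <= cutoff^2
    } else {
      shell_mask_cell(xyz, prot, box, cutoff, periodic_z)
    }
    sp <- factor(lip$species, levels = species_levels)
    shell_sum <- shell_sum + table(sp[mask])
    total_sum <- total_sum + table(sp)
  }
  nf <- win[2] - win[1] + 1L
  out <- data.frame(species = species_levels,
                    shell_count = as.numeric(shell_sum) / nf,
                    total_count = as.numeric(total_sum) / nf,
                    stringsAsFactors = FALSE)
  structure(out, cutoff = cutoff, window = win, n_frames = nf,
            class = c("shell_counts", "data.frame"))
}

#' @export
print.shell_counts <- function(x, ...) {
  cat(sprintf("<shell_counts> cutoff %g A over %d frame(s)\n",
              attr(x, "cutoff"), attr(x, "n_frames")))
  print(as.data.frame(x))
  invisible(x)
}

#' Depletion-enrichment index per lipid species
#'
#' `index(L) = ratio(L)_shell / ratio(L)_bulk` where `ratio(L)_shell` is
#' species L's fraction of all lipids in the shell and `ratio(L)_bulk` its
#' fraction of all lipids in the membrane. 1 is neutral, > 1 enriched,
#' < 1 depleted. Undefined indices (zero bulk ratio, or an entirely empty
#' shell) are `NA` with attribute `undefined` naming the species.
#'
#' @param shell a `shell_counts` object.
#' @return an `enrichment_table`: data.frame with `species`, `shell_ratio`,
#'   `bulk_ratio`, `index`.
#' @export
depletion_enrichment_index <- function(shell) {
  stopifnot(inherits(shell, "shell_counts"))
  tot_bulk <- sum(shell$total_count)
  if (tot_bulk <= 0) stop("no lipids in the membrane")
  tot_shell <- sum(shell$shell_count)
  bulk_ratio <- shell$total_count / tot_bulk
  if (tot_shell <= 0) {
    shell_ratio <- rep(NA_real_, nrow(shell))
    index <- rep(NA_real_, nrow(shell))
    undef <- shell$species
  } else {
    shell_ratio <- shell$shell_count / tot_shell
    index <- ifelse(bulk_ratio > 0, shell_ratio / bulk_ratio, NA_real_)
    undef <- shell$species[bulk_ratio <= 0]
  }
  structure(data.frame(species = shell$species, shell_ratio = shell_ratio,
                       bulk_ratio = bulk_ratio, index = index,
                       stringsAsFactors = FALSE),
            cutoff = attr(shell, "cutoff"), window = attr(shell, "window"),
            undefined = undef,
            class = c("enrichment_table", "data.frame"))
}

#' @export
print.enrichment_table <- function(x, ...) {
  cat(sprintf("<enrichment_table> cutoff %g A\n", attr(x, "cutoff")))
  df <- as.data.frame(x)
  df$index <- round(df$index, 3)
  print(df)
  invisible(x)
}
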