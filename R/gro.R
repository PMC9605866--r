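## Bead membrane frames. Internal unit is Angstrom everywhere; GRO files
## (nm) are converted at the boundary. Coordinates are wrapped into the
## primary box [0, L) on construction.

# default reference-bead names: phosphate for phospholipids, hydroxyl for
# cholesterol (covers Martini and atomistic naming)
.default_beads <- list(
  phosphate = c("PO4", "P", "P8"),
  hydroxyl = c("ROH", "O3", "OH")
)

#' Reference-bead name sets
#'
#' Phosphate bead names identify phospholipids; hydroxyl bead names identify
#' cholesterol. Every geometric analysis uses exactly one reference bead per
#' lipid.
#'
#' @param phosphate character vector of phosphate bead names.
#' @param hydroxyl character vector of cholesterol hydroxyl bead names.
#' @return named list with elements `phosphate`, `hydroxyl`.
#' @export
bead_config <- function(phosphate = .default_beads$phosphate,
                        hydroxyl = .default_beads$hydroxyl) {
  stopifnot(length(phosphate) > 0, length(hydroxyl) > 0)
  list(phosphate = phosphate, hydroxyl = hydroxyl)
}

#' Single membrane frame
#'
#' @param particles data.frame with columns `species`, `molid`, `bead`,
#'   `x`, `y`, `z` (Angstrom).
#' @param box numeric length-3 box `(Lx, Ly, Lz)` in Angstrom.
#' @param time frame time stamp (arbitrary units).
#' @param wrap wrap coordinates into `[0, L)` per axis (default TRUE).
#' @return a `membrane_frame` object.
#' @export
membrane_frame <- function(particles, box, time = 0, wrap = TRUE) {
  req <- c("species", "molid", "bead", "x", "y", "z")
  stopifnot(is.data.frame(particles), all(req %in% names(particles)),
            length(box) == 3, all(box > 0))
  if (wrap) {
    particles$x <- wrap_coords(particles$x, box[1])
    particles$y <- wrap_coords(particles$y, box[2])
    particles$z <- wrap_coords(particles$z, box[3])
  }
  structure(particles, box = as.numeric(box), time = as.numeric(time),
            class = c("membrane_frame", "data.frame"))
}

#' @export
print.membrane_frame <- function(x, ...) {
  cat(sprintf("<membrane_frame> t=%g: %d beads, box %.1f x %.1f x %.1f A\n",
              attr(x, "time"), nrow(x), attr(x, "box")[1],
              attr(x, "box")[2], attr(x, "box")[3]))
  print(table(x$species))
  invisible(x)
}

#' Ordered set of membrane frames
#'
#' All frames must share particle count and species labels (the generator
#' and readers guarantee this); frames are ordered by time.
#'
#' @param frames list of `membrane_frame`.
#' @param composition optional declared species fractions (named numeric).
#' @param source optional source path.
#' @return a `frame_set` object.
#' @export
frame_set <- function(frames, composition = NULL, source = NULL) {
  stopifnot(is.list(frames), length(frames) >= 1,
            all(vapply(frames, inherits, TRUE, "membrane_frame")))
  n <- vapply(frames, nrow, 1L)
  if (length(unique(n)) != 1)
    stop("frames differ in particle count: ", paste(unique(n), collapse = ", "))
  sp0 <- sort(unique(frames[[1]]$species))
  for (f in frames[-1])
    if (!identical(sort(unique(f$species)), sp0))
      stop("frames differ in species labels")
  times <- vapply(frames, attr, 1, "time")
  frames <- frames[order(times)]
  structure(list(frames = frames, composition = composition,
                 source = source),
            class = "frame_set")
}

#' @export
length.frame_set <- function(x) length(x$frames)

#' @export
`[[.frame_set` <- function(x, i) x$frames[[i]]

#' @export
print.frame_set <- function(x, ...) {
  cat(sprintf("<frame_set> %d frame(s) of %d beads%s\n",
              length(x$frames), nrow(x$frames[[1]]),
              if (!is.null(x$source)) paste0(" from ", x$source) else ""))
  invisible(x)
}

#' Read concatenated GRO blocks as a frame set
#'
#' Each block is: title line, particle count, fixed-column particle lines
#' (`resid(5) resname(5) atom(5) index(5) x y z` in nm, `%8.3f`), box line
#' (nm). Positions are converted to Angstrom; the species label is the
#' residue-name field and the molecule id the residue-number field.
#'
#' @param path GRO file (one or more concatenated blocks).
#' @return a `frame_set`.
#' @export
read_gro_frames <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  frames <- list()
  i <- 1L
  t_fallback <- 0
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i])) && i == length(lines)) break
    title <- lines[i]
    if (i + 1L > length(lines)) stop("truncated GRO block at line ", i)
    n <- suppressWarnings(as.integer(trimws(lines[i + 1L])))
    if (is.na(n) || n < 0)
      stop("invalid particle count at line ", i + 1L, ": '", lines[i + 1L], "'")
    if (i + 1L + n + 1L > length(lines))
      stop("GRO block starting at line ", i, " declares ", n,
           " particles but the file ends before its box line")
    pl <- lines[(i + 2L):(i + 1L + n)]
    resid <- suppressWarnings(as.integer(substr(pl, 1, 5)))
    resname <- trimws(substr(pl, 6, 10))
    bead <- trimws(substr(pl, 11, 15))
    xs <- suppressWarnings(as.numeric(substr(pl, 21, 28)))
    ys <- suppressWarnings(as.numeric(substr(pl, 29, 36)))
    zs <- suppressWarnings(as.numeric(substr(pl, 37, 44)))
    bad <- which(is.na(resid) | is.na(xs) | is.na(ys) | is.na(zs))
    if (length(bad))
      stop("malformed GRO particle line ", i + 1L + bad[1], ": '",
           pl[bad[1]], "'")
    box <- suppressWarnings(as.numeric(strsplit(
      trimws(lines[i + 2L + n]), "\\s+")[[1]]))
    if (length(box) < 3 || any(is.na(box[1:3])))
      stop("missing or malformed box line at line ", i + 2L + n)
    tm <- regmatches(title, regexpr("t=\\s*[-0-9.eE+]+", title))
    time <- if (length(tm)) as.numeric(sub("t=\\s*", "", tm)) else t_fallback
    t_fallback <- t_fallback + 1
    frames[[length(frames) + 1L]] <- membrane_frame(
      data.frame(species = resname, molid = resid, bead = bead,
                 x = xs * 10, y = ys * 10, z = zs * 10,
                 stringsAsFactors = FALSE),
      box = box[1:3] * 10, time = time)
    i <- i + n + 3L
    while (i <= length(lines) && !nzchar(trimws(lines[i]))) i <- i + 1L
  }
  if (length(frames) == 0) stop("no GRO blocks found in ", path)
  frame_set(frames, source = path)
}

#' Write a frame set (or single frame) as concatenated GRO blocks
#'
#' @param frames a `frame_set` or `membrane_frame`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_gro_frames <- function(frames, path) {
  if (inherits(frames, "membrane_frame")) frames <- frame_set(list(frames))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in frames$frames) {
    box <- attr(f, "box")
    writeLines(sprintf("synthetic membrane frame t= %g", attr(f, "time")), con)
    writeLines(sprintf("%5d", nrow(f)), con)
    writeLines(sprintf("%5d%-5s%5s%5d%8.3f%8.3f%8.3f",
                       f$molid %% 100000, substr(f$species, 1, 5),
                       substr(f$bead, 1, 5), seq_len(nrow(f)) %% 100000,
                       f$x / 10, f$y / 10, f$z / 10), con)
    writeLines(sprintf("%10.5f%10.5f%10.5f", box[1] / 10, box[2] / 10,
                       box[3] / 10), con)
  }
  invisible(path)
}

# logical mask of reference beads (one per lipid) in a frame
is_reference_bead <- function(frame, beads = bead_config()) {
  frame$bead %in% c(beads$phosphate, beads$hydroxyl)
}

# logical mask of phospholipid phosphate beads
is_phosphate_bead <- function(frame, beads = bead_config()) {
  frame$bead %in% beads$phosphate
}
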