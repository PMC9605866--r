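## Fixed-column PDB reading/writing. Columns follow the PDB v3.3 layout:
##   record 1-6, serial 7-11, name 13-16, altLoc 17, resName 18-20,
##   chainID 22, resSeq 23-26, iCode 27, x 31-38, y 39-46, z 47-54,
##   occupancy 55-60, tempFactor 61-66, element 77-78.

#' Atom model constructor
#'
#' An `atom_model` is a data.frame of atom records with one row per atom
#' and attributes `model_id`. Residue identity is
#' (chain, residue number, insertion code); coordinates are Angstrom.
#'
#' @param atoms data.frame with columns `chain`, `resid`, `inscode`,
#'   `resname`, `atom`, `element`, `x`, `y`, `z`, `occ`, `bfac`.
#' @param model_id integer model number.
#' @return an `atom_model` object.
#' @export
atom_model <- function(atoms, model_id = 1L) {
  req <- c("chain", "resid", "inscode", "resname", "atom", "element",
           "x", "y", "z", "occ", "bfac")
  stopifnot(is.data.frame(atoms), all(req %in% names(atoms)))
  if (nrow(atoms) > 0) {
    if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
      stop("atom coordinates must be finite")
    key <- paste(atoms$chain, atoms$resid, atoms$inscode, atoms$atom)
    if (anyDuplicated(key))
      stop("duplicate (chain, residue, insertion code, atom name) keys ",
           "within one model")
    if (any(!nzchar(atoms$element)))
      stop("element symbols must be non-empty (inference failed)")
  }
  structure(as.data.frame(atoms, stringsAsFactors = FALSE),
            model_id = as.integer(model_id),
            class = c("atom_model", "data.frame"))
}

#' @export
print.atom_model <- function(x, ...) {
  cat(sprintf("<atom_model> model %d: %d atoms, %d chain(s)\n",
              attr(x, "model_id"), nrow(x), length(unique(x$chain))))
  invisible(x)
}

# element from atom name: strip digits/primes, take the leading alphabetic
# character; unambiguous two-letter elements (halides, common metals) are
# recognised when the whole name is that symbol. "CA"/"NA" are left as
# C/N — alpha carbons vastly outnumber calcium ions in these models.
infer_element <- function(atom_name) {
  nm <- toupper(gsub("[^A-Za-z]", "", atom_name))
  known2 <- c("CL", "BR", "FE", "ZN", "MG", "MN", "SE")
  ifelse(nm %in% known2, nm, substr(nm, 1, 1))
}

parse_pdb_block <- function(lines, model_id, line_numbers) {
  sub_ <- function(l, a, b) substr(l, a, b)
  n <- length(lines)
  if (n == 0) return(NULL)
  xs <- suppressWarnings(as.numeric(sub_(lines, 31, 38)))
  ys <- suppressWarnings(as.numeric(sub_(lines, 39, 46)))
  zs <- suppressWarnings(as.numeric(sub_(lines, 47, 54)))
  resid <- suppressWarnings(as.integer(sub_(lines, 23, 26)))
  bad <- which(is.na(xs) | is.na(ys) | is.na(zs) | is.na(resid))
  if (length(bad) > 0)
    stop(sprintf("malformed fixed-width PDB record at line %d: '%s'",
                 line_numbers[bad[1]], lines[bad[1]]))
  occ <- suppressWarnings(as.numeric(sub_(lines, 55, 60)))
  occ[is.na(occ)] <- 1
  bfac <- suppressWarnings(as.numeric(sub_(lines, 61, 66)))
  bfac[is.na(bfac)] <- 0
  atom <- trimws(sub_(lines, 13, 16))
  altloc <- sub_(lines, 17, 17)
  elem <- trimws(sub_(lines, 77, 78))
  no_elem <- !nzchar(elem)
  elem[no_elem] <- infer_element(atom[no_elem])
  df <- data.frame(
    chain = sub_(lines, 22, 22),
    resid = resid,
    inscode = trimws(sub_(lines, 27, 27)),
    resname = trimws(sub_(lines, 18, 20)),
    atom = atom,
    altloc = altloc,
    element = toupper(elem),
    x = xs, y = ys, z = zs,
    occ = occ, bfac = bfac,
    stringsAsFactors = FALSE
  )
  # alternate locations: keep the highest-occupancy record per atom key
  key <- paste(df$chain, df$resid, df$inscode, df$atom)
  if (anyDuplicated(key)) {
    ord <- order(key, -df$occ)
    df <- df[ord, ][!duplicated(key[ord]), ]
    df <- df[order(as.integer(rownames(df))), ]
  }
  df$altloc <- NULL
  rownames(df) <- NULL
  atom_model(df, model_id = model_id)
}

#' Read a PDB file
#'
#' Parses fixed-column ATOM/HETATM records, honouring MODEL/ENDMDL blocks.
#' Insertion codes are kept as part of residue identity; for alternate
#' locations only the highest-occupancy record is retained. Missing element
#' columns are inferred from the atom name.
#'
#' @param path path to a PDB file.
#' @param multi if `TRUE` always return a list of models; by default a
#'   single-model file returns one `atom_model`.
#' @return an `atom_model`, or a list of them for multi-model files.
#' @export
read_pdb <- function(path, multi = FALSE) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  models <- list()
  cur_idx <- integer(0)
  cur_id <- 1L
  seen_model_card <- FALSE
  for (i in seq_along(lines)) {
    r <- rec[i]
    if (startsWith(r, "MODEL")) {
      id <- suppressWarnings(as.integer(substr(lines[i], 7, 14)))
      cur_id <- if (is.na(id)) length(models) + 1L else id
      cur_idx <- integer(0)
      seen_model_card <- TRUE
    } else if (startsWith(r, "ENDMDL")) {
      models[[length(models) + 1L]] <-
        parse_pdb_block(lines[cur_idx], cur_id, cur_idx)
      cur_idx <- integer(0)
    } else if (r == "ATOM  " || r == "HETATM") {
      cur_idx <- c(cur_idx, i)
    }
  }
  if (length(cur_idx) > 0 || length(models) == 0) {
    models[[length(models) + 1L]] <-
      parse_pdb_block(lines[cur_idx],
                      if (seen_model_card) cur_id else 1L, cur_idx)
  }
  models <- Filter(Negate(is.null), models)
  if (length(models) == 0) stop("empty input: no ATOM/HETATM records in ", path)
  if (length(models) == 1 && !multi) models[[1]] else models
}

#' Write models to a PDB file
#'
#' @param model an `atom_model` or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_pdb <- function(model, path) {
  models <- if (inherits(model, "atom_model")) list(model) else model
  con <- file(path, "w")
  on.exit(close(con))
  multi <- length(models) > 1
  for (m in models) {
    if (multi)
      writeLines(sprintf("MODEL     %4d", attr(m, "model_id")), con)
    lines <- sprintf(
      "ATOM  %5d %-4s%1s%-3s %1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      seq_len(nrow(m)) %% 100000,
      ifelse(nchar(m$atom) < 4, paste0(" ", m$atom), m$atom),
      " ", m$resname, m$chain, m$resid,
      ifelse(nzchar(m$inscode), m$inscode, " "),
      m$x, m$y, m$z, m$occ, m$bfac, m$element)
    writeLines(lines, con)
    if (multi) writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
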