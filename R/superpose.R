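## Rigid-body superposition (Kabsch with reflection correction), atom
## pairing between models, domain rotation between conformational states,
## and centroid separation.

#' Least-squares rigid superposition (Kabsch)
#'
#' Finds the proper rotation `R` and translation `t` minimising the RMSD of
#' `mobile %*% t(R) + t` onto `reference` over correspondence-ordered point
#' sets. If the SVD determinant product is negative the smallest singular
#' vector is negated (reflection correction). The rotation angle is
#' `acos((trace(R) - 1) / 2)`.
#'
#' @param reference,mobile equal-length coordinate sets (n x 3 matrix,
#'   data.frame with x/y/z, or `atom_model`), n >= 3, non-collinear.
#' @return a `superposition` object: list with `R` (3 x 3), `t` (length 3),
#'   `rmsd` (Angstrom), `angle` (degrees, in [0, 180]), `n` (points),
#'   `transformed` (mobile after the fit).
#' @export
superpose <- function(reference, mobile) {
  A <- as_coord_matrix(reference)
  B <- as_coord_matrix(mobile)
  if (nrow(A) != nrow(B))
    stop("point sets differ in length (", nrow(A), " vs ", nrow(B), ")")
  if (nrow(A) < 3) stop("need >= 3 points for a rigid superposition")
  ca <- colMeans(A); cb <- colMeans(B)
  A0 <- sweep(A, 2, ca); B0 <- sweep(B, 2, cb)
  s <- svd(crossprod(B0, A0))        # H = B0^T A0; R = V diag(1,1,d) U^T
  if (min(s$d) < 1e-12 * max(s$d, 1) && sum(s$d > 1e-12 * max(s$d, 1)) < 2)
    stop("degenerate geometry: points are collinear or coincident")
  d <- sign(det(s$v %*% t(s$u)))
  if (d == 0) stop("degenerate geometry: singular cross-covariance")
  D <- diag(c(1, 1, d))
  R <- s$v %*% D %*% t(s$u)
  t_vec <- as.numeric(ca - R %*% cb)
  Bt <- B %*% t(R) + matrix(t_vec, nrow(B), 3, byrow = TRUE)
  rmsd <- sqrt(mean(rowSums((Bt - A)^2)))
  structure(list(R = R, t = t_vec, rmsd = rmsd,
                 angle = rotation_angle(R), n = nrow(A), transformed = Bt),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("<superposition> %d atoms: rmsd %.4f A, rotation %.3f deg\n",
              x$n, x$rmsd, x$angle))
  invisible(x)
}

# three-letter -> one-letter residue codes (X for unknowns)
aa321 <- function(resname) {
  tab <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
           GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
           LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
           SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V")
  out <- tab[toupper(resname)]
  out[is.na(out)] <- "X"
  unname(out)
}

# Needleman-Wunsch global alignment over residue letters
# (match 1, mismatch -1, gap -2); returns paired index vectors
nw_align <- function(s1, s2, match = 1, mismatch = -1, gap = -2) {
  n <- length(s1); m <- length(s2)
  F <- matrix(0, n + 1, m + 1)
  F[, 1] <- gap * (0:n)
  F[1, ] <- gap * (0:m)
  P <- matrix(0L, n + 1, m + 1)   # 1 diag, 2 up (gap in s2), 3 left
  for (i in seq_len(n)) {
    sc <- ifelse(s1[i] == s2, match, mismatch)
    for (j in seq_len(m)) {
      diag_ <- F[i, j] + sc[j]
      up <- F[i, j + 1] + gap
      left <- F[i + 1, j] + gap
      best <- max(diag_, up, left)
      F[i + 1, j + 1] <- best
      P[i + 1, j + 1] <- if (best == diag_) 1L else if (best == up) 2L else 3L
    }
  }
  i <- n; j <- m
  p1 <- integer(0); p2 <- integer(0)
  while (i > 0 || j > 0) {
    if (i > 0 && j > 0 && P[i + 1, j + 1] == 1L) {
      p1 <- c(i, p1); p2 <- c(j, p2); i <- i - 1; j <- j - 1
    } else if (i > 0 && (j == 0 || P[i + 1, j + 1] == 2L)) {
      i <- i - 1
    } else {
      j <- j - 1
    }
  }
  list(idx1 = p1, idx2 = p2, score = F[n + 1, m + 1])
}

#' Pair atoms between two models
#'
#' `by_key`: intersect on (residue number + offset, atom name) within the
#' selections. `by_alignment`: globally align the two selections' residue
#' sequences (match/mismatch/gap = 1/-1/-2) and pair CA atoms of aligned
#' (matched or mismatched) positions.
#'
#' @param model_1,model_2 `atom_model`s.
#' @param sel_1,sel_2 `selection_spec`s applied to each model.
#' @param mode "by_key" or "by_alignment".
#' @param offset residue-number offset added to model 2 before key matching.
#' @return list with `xyz_1`, `xyz_2` (paired n x 3 matrices), `n`, and the
#'   paired `keys`.
#' @export
pair_atoms <- function(model_1, sel_1 = selection_spec(),
                       model_2, sel_2 = selection_spec(),
                       mode = c("by_key", "by_alignment"), offset = 0) {
  mode <- match.arg(mode)
  a <- apply_selection(model_1, sel_1)
  b <- apply_selection(model_2, sel_2)
  if (mode == "by_key") {
    ka <- paste(a$resid, a$inscode, a$atom)
    kb <- paste(b$resid + offset, b$inscode, b$atom)
    common <- intersect(ka, kb)
    if (length(common) == 0) stop("no atom pairs under key matching")
    ia <- match(common, ka); ib <- match(common, kb)
    list(xyz_1 = as_coord_matrix(a[ia, ]), xyz_2 = as_coord_matrix(b[ib, ]),
         n = length(common), keys = common)
  } else {
    a <- a[a$atom == "CA", , drop = FALSE]
    b <- b[b$atom == "CA", , drop = FALSE]
    if (nrow(a) == 0 || nrow(b) == 0)
      stop("alignment pairing requires CA atoms in both selections")
    al <- nw_align(aa321(a$resname), aa321(b$resname))
    if (length(al$idx1) == 0) stop("no atom pairs under alignment")
    list(xyz_1 = as_coord_matrix(a[al$idx1, ]),
         xyz_2 = as_coord_matrix(b[al$idx2, ]),
         n = length(al$idx1),
         keys = paste(a$resid[al$idx1], b$resid[al$idx2], sep = "~"))
  }
}

#' Domain rotation angle between two conformational states
#'
#' Superposes model E onto model C over the `anchor` selection, applies the
#' fitted transform to E's `moving` selection, then superposes that onto
#' C's `moving` selection; the rotation angle of this second fit is the
#' hinge rotation of the moving domain relative to the anchor.
#'
#' @param model_e,model_c `atom_model`s of the two states.
#' @param anchor,moving `selection_spec`s naming the fixed and moving parts.
#' @param mode,offset pairing options (see [pair_atoms()]).
#' @return rotation angle in degrees, with attribute `superposition` (the
#'   second fit).
#' @export
domain_rotation <- function(model_e, model_c, anchor, moving,
                            mode = "by_key", offset = 0) {
  anc <- pair_atoms(model_e, anchor, model_c, anchor, mode, offset)
  fit1 <- superpose(anc$xyz_2, anc$xyz_1)     # E onto C over the anchor
  mov <- pair_atoms(model_e, moving, model_c, moving, mode, offset)
  mov_e_aligned <- mov$xyz_1 %*% t(fit1$R) +
    matrix(fit1$t, nrow(mov$xyz_1), 3, byrow = TRUE)
  fit2 <- superpose(mov$xyz_2, mov_e_aligned)
  structure(fit2$angle, superposition = fit2)
}

#' Distance between the centroids of two coordinate sets
#'
#' @param set_1,set_2 coordinate sets (matrix, data.frame, `atom_model`).
#' @return Euclidean distance, Angstrom.
#' @export
centroid_distance <- function(set_1, set_2) {
  a <- as_coord_matrix(set_1)
  b <- as_coord_matrix(set_2)
  if (nrow(a) == 0 || nrow(b) == 0) stop("empty coordinate set")
  sqrt(sum((colMeans(a) - colMeans(b))^2))
}
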