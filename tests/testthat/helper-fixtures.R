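# shared fixture builders; everything is generated in code at test time

# minimal atom_model from coordinate rows
toy_model <- function(xyz, chain = "A", resid = seq_len(nrow(xyz)),
                      atom = "CA", resname = "ALA", element = "C") {
  atom_model(data.frame(
    chain = chain, resid = resid, inscode = "", resname = resname,
    atom = atom, element = element,
    x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
    occ = 1, bfac = 0, stringsAsFactors = FALSE))
}

# random but reproducible blob of n atoms
random_model <- function(n, seed = 42) {
  withr::with_seed(seed, toy_model(matrix(stats::runif(3 * n, -20, 20), n, 3)))
}

# one PE-only flat membrane: exact +/- z0 planes, balanced leaflets
flat_membrane <- function(box = c(100, 100), n_frames = 2, z0 = 19,
                          noise = 0, jitter = 0, seed = 1) {
  build_membrane(synthetic_membrane_spec(
    box = box, z0 = z0, noise_sd = noise, jitter_sd = jitter,
    composition = membrane_composition(c(PE = 1)),
    n_frames = n_frames, seed = seed))
}

# brute-force O(N^2) shell recount, fully independent of the package's
# distance code: plain loops over lipids and protein beads
oracle_shell_counts <- function(frame, cutoff, beads_phos = c("PO4"),
                                beads_chol = c("ROH")) {
  box <- attr(frame, "box")
  prot <- frame[frame$species == "PROT", ]
  lip <- frame[frame$bead %in% c(beads_phos, beads_chol) &
                 frame$species != "PROT", ]
  in_shell <- logical(nrow(lip))
  for (i in seq_len(nrow(lip))) {
    best <- Inf
    for (j in seq_len(nrow(prot))) {
      dx <- lip$x[i] - prot$x[j]; dx <- dx - box[1] * round(dx / box[1])
      dy <- lip$y[i] - prot$y[j]; dy <- dy - box[2] * round(dy / box[2])
      dz <- lip$z[i] - prot$z[j]
      best <- min(best, dx^2 + dy^2 + dz^2)
    }
    in_shell[i] <- best <= cutoff^2
  }
  list(shell = table(factor(lip$species[in_shell],
                            levels = sort(unique(lip$species)))),
       total = table(factor(lip$species,
                            levels = sort(unique(lip$species)))))
}
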