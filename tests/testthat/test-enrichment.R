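test_that("shell membership respects the cutoff and periodic wrap", {
  mk <- function(lip_x) membrane_frame(
    data.frame(species = c("PE", "PROT"), molid = 1:2,
               bead = c("PO4", "BB"),
               x = c(lip_x, 2), y = 0, z = 0),
    box = c(100, 100, 100), wrap = TRUE)
  shell_of <- function(f) {
    sc <- shell_composition(frame_set(list(f)), "PROT", cutoff = 7)
    sc$shell_count[sc$species == "PE"]
  }
  expect_equal(shell_of(mk(7)), 1)    # distance 5 <= 7
  expect_equal(shell_of(mk(10)), 0)   # distance 8 > 7
  expect_equal(shell_of(mk(98)), 1)   # minimum image: |98 - 2| -> 4
})

test_that("cell-list shell counts match the brute-force oracle exactly", {
  spec <- synthetic_membrane_spec(
    box = c(220, 220), protein_radius = 25,
    shell_multipliers = c(CHOL = 2), n_frames = 3, seed = 41)
  m <- build_membrane(spec)
  expect_lt(nrow(m$frames[[1]]), 5000)
  sc_cell <- shell_composition(m$frames, "PROT", cutoff = 7,
                               method = "cell")
  sc_brute <- shell_composition(m$frames, "PROT", cutoff = 7,
                                method = "brute")
  expect_identical(as.data.frame(sc_cell), as.data.frame(sc_brute))
  # and both agree with an independent plain-loop recount, frame by frame
  or <- lapply(1:3, function(i)
    oracle_shell_counts(m$frames[[i]], cutoff = 7))
  shell_mean <- Reduce(`+`, lapply(or, function(o) as.numeric(o$shell))) / 3
  total_mean <- Reduce(`+`, lapply(or, function(o) as.numeric(o$total))) / 3
  expect_equal(sc_cell$shell_count, shell_mean)
  expect_equal(sc_cell$total_count, total_mean)
})

test_that("worked example: 4 CHOL + 6 PC, shell 2 CHOL + 1 PC", {
  df <- data.frame(
    species = c(rep("CHOL", 4), rep("PC", 6), "PROT"),
    molid = 1:11,
    bead = c(rep("ROH", 4), rep("PO4", 6), "BB"),
    x = c(3, 6, 40, 45, 5, 30, 35, 40, 45, 50, 0),
    y = 0, z = 0)
  f <- membrane_frame(df, box = c(100, 100, 100))
  sc <- shell_composition(frame_set(list(f)), "PROT", cutoff = 7)
  et <- depletion_enrichment_index(sc)
  expect_equal(et$index[et$species == "CHOL"], (2 / 3) / (4 / 10),
               tolerance = 1e-12)
  expect_equal(et$index[et$species == "PC"], (1 / 3) / (6 / 10),
               tolerance = 1e-12)
})

test_that("identical shell and bulk composition gives index 1 everywhere", {
  sc <- structure(
    data.frame(species = c("A", "B"), shell_count = c(2, 6),
               total_count = c(10, 30)),
    cutoff = 7, window = c(1L, 1L), n_frames = 1L,
    class = c("shell_counts", "data.frame"))
  et <- depletion_enrichment_index(sc)
  expect_equal(et$index, c(1, 1))
})

test_that("bulk-ratio-weighted mean of indices is exactly 1", {
  m <- build_membrane(synthetic_membrane_spec(
    box = c(150, 150), protein_radius = 20, n_frames = 2, seed = 43))
  et <- depletion_enrichment_index(
    shell_composition(m$frames, "PROT", cutoff = 7))
  expect_equal(sum(et$bulk_ratio * et$index), 1, tolerance = 1e-9)
  expect_equal(sum(et$shell_ratio), 1, tolerance = 1e-9)
  expect_equal(sum(et$bulk_ratio), 1, tolerance = 1e-9)
})

test_that("index is invariant to rigid translation and molid relabeling", {
  m <- build_membrane(synthetic_membrane_spec(
    box = c(150, 150), protein_radius = 20, n_frames = 1, seed = 47))
  et1 <- depletion_enrichment_index(
    shell_composition(m$frames, "PROT", cutoff = 7))
  f <- as.data.frame(m$frames[[1]])
  f$x <- f$x + 33.3; f$y <- f$y - 12.1; f$z <- f$z + 5
  f$molid <- rev(f$molid)
  f2 <- membrane_frame(f, box = attr(m$frames[[1]], "box"))
  et2 <- depletion_enrichment_index(
    shell_composition(frame_set(list(f2)), "PROT", cutoff = 7))
  expect_equal(et1$index, et2$index, tolerance = 1e-12)
})

test_that("growing the cutoff drives every index toward 1", {
  m <- build_membrane(synthetic_membrane_spec(
    box = c(150, 150), protein_radius = 15,
    shell_multipliers = c(CHOL = 3), n_frames = 1, seed = 53))
  dev <- function(cutoff) {
    et <- depletion_enrichment_index(
      shell_composition(m$frames, "PROT", cutoff = cutoff))
    max(abs(et$index - 1))
  }
  # at 70 A the shell covers ~96% of the membrane: indices near 1, with
  # residual small-count noise from the excluded corners
  expect_lt(dev(70), 0.15)
  expect_lt(dev(70), dev(7))
})

test_that("degenerate inputs are flagged, not silently wrong", {
  f <- membrane_frame(
    data.frame(species = c("PE", "PROT"), molid = 1:2,
               bead = c("PO4", "BB"), x = c(0, 50), y = 0, z = 0),
    box = c(100, 100, 100))
  sc <- shell_composition(frame_set(list(f)), "PROT", cutoff = 7)
  et <- depletion_enrichment_index(sc)   # empty shell: all NA, flagged
  expect_true(all(is.na(et$index)))
  expect_equal(attr(et, "undefined"), "PE")
  expect_error(shell_composition(frame_set(list(f)), "NOPE", cutoff = 7),
               "empty protein")
  expect_error(shell_composition(frame_set(list(f)), "PROT", cutoff = -1),
               "cutoff")
})
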