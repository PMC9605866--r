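test_that("midplane is the mean phosphate z (symmetry and arithmetic)", {
  mk <- function(z) membrane_frame(
    data.frame(species = "PE", molid = seq_along(z), bead = "PO4",
               x = 1, y = 1, z = z), box = c(10, 10, 100), wrap = FALSE)
  expect_equal(compute_midplane(mk(c(19, -19, 19, -19))), 0)
  expect_equal(compute_midplane(mk(c(20, 20, 20, -20))), 10)
  f <- mk(c(1, 2))
  f$bead <- c("PO4", "ROH")   # hydroxyls do not define the midplane
  expect_equal(compute_midplane(f), 1)
  f$bead <- "ROH"
  expect_error(compute_midplane(f), "no phosphate")
})

test_that("leaflet assignment by sign, with upper tie-break at z0", {
  f <- membrane_frame(
    data.frame(species = c("PE", "CHOL", "PE"),
               molid = 1:3, bead = c("PO4", "ROH", "PO4"),
               x = 1, y = 1, z = c(19, -14, 0)),
    box = c(10, 10, 100), wrap = FALSE)
  expect_warning(side <- assign_leaflets(f, z0 = 0), "midplane")
  expect_equal(side, c("upper", "lower", "upper"))
})

test_that("synthetic frames: leaflet labels are exact under separation", {
  m <- flat_membrane(box = c(100, 100), n_frames = 1, noise = 1, jitter = 1,
                     seed = 15)
  f <- m$frames[[1]]
  side <- assign_leaflets(f, compute_midplane(f))
  truth_side <- ifelse(seq_len(nrow(f)) <= m$truth$n_lipids_per_leaflet,
                       "upper", "lower")
  expect_identical(side, truth_side)
})

test_that("noiseless flat bilayer maps read exactly z0 in every bin", {
  m <- flat_membrane(box = c(80, 80), n_frames = 4, z0 = 19)
  for (leaf in c("upper", "lower")) {
    tm <- thickness_map(m$frames, leaf, window = "full")
    expect_true(all(is.na(tm$mean) | abs(tm$mean - 19) < 1e-9))
    expect_true(all(tm$counts[!is.na(tm$mean)] > 0))
    expect_true(all(is.na(tm$mean[tm$counts == 0])))
  }
})

test_that("thickness map sees an imposed dip at the right depth", {
  spec <- synthetic_membrane_spec(
    box = c(200, 200), noise_sd = 0.4, jitter_sd = 0.5,
    composition = membrane_composition(c(PE = 0.7, PC = 0.3)),
    field = deformation_field("lower", +6, 100, 100, 15),
    n_frames = 12, seed = 19)
  m <- build_membrane(spec)
  tm <- thickness_map(m$frames, "lower", window = "full")
  # occupied bins against the generator's own field at the bin centers
  # (the jittered lattice leaves inter-site bins permanently empty, so
  # comparisons only make sense on occupied bins)
  nx <- nrow(tm$mean)
  bx <- (seq_len(nx) - 0.5) * tm$bin
  r <- sqrt(outer((bx - 100)^2, (bx - 100)^2, `+`))
  # the global midplane itself shifts by half the leaflet-averaged field
  # (one-sided deformations drag the mean phosphate z along)
  shift <- 6 * 2 * pi * 15^2 / (200 * 200) / 2
  expected <- 19 + shift - 6 * exp(-r^2 / (2 * 15^2))
  occ <- !is.na(tm$mean)
  # dip toward the midplane: ~13 A at the center, 19 A in the far field,
  # per-bin agreement scaled by each bin's sampling error
  expect_gt(sum(occ & r < 8), 0)
  bound <- 4 * 0.4 / sqrt(tm$counts[occ]) + 0.5
  expect_true(all(abs(tm$mean[occ] - expected[occ]) < bound))
  expect_lt(abs(mean((tm$mean - expected)[occ & r < 8])), 0.3)
  expect_lt(abs(mean((tm$mean - expected)[occ & r > 80])), 0.05)
  expect_lt(min(tm$mean[occ]), 13.6)
})

test_that("maps are equivariant under translation by one bin width", {
  m <- flat_membrane(box = c(60, 60), n_frames = 1, noise = 0.5, jitter = 1,
                     seed = 23)
  tm <- thickness_map(m$frames, "upper", window = "full")
  shifted <- lapply(seq_len(length(m$frames)), function(i) {
    f <- m$frames[[i]]
    f2 <- as.data.frame(f)
    f2$x <- f2$x + tm$bin
    membrane_frame(f2, box = attr(f, "box"), time = attr(f, "time"))
  })
  tm2 <- thickness_map(frame_set(shifted), "upper", window = "full")
  nx <- nrow(tm$mean)
  expect_equal(tm2$mean[c(2:nx, 1), ], tm$mean)
  expect_equal(tm2$counts[c(2:nx, 1), ], tm$counts)
})

test_that("relabeling leaflets swaps the two maps exactly", {
  m <- flat_membrane(box = c(60, 60), n_frames = 2, noise = 0.6, jitter = 1,
                     seed = 27)
  up <- thickness_map(m$frames, "upper", window = "full")
  lo <- thickness_map(m$frames, "lower", window = "full")
  # mirror every frame through its own midplane: upper <-> lower
  mirrored <- lapply(seq_len(length(m$frames)), function(i) {
    f <- m$frames[[i]]
    z0 <- compute_midplane(f)
    f2 <- as.data.frame(f)
    f2$z <- 2 * z0 - f2$z
    membrane_frame(f2, box = attr(f, "box"), time = attr(f, "time"))
  })
  up2 <- thickness_map(frame_set(mirrored), "upper", window = "full")
  expect_equal(up2$mean, lo$mean)
  expect_equal(up2$counts, lo$counts)
})

test_that("density maps conserve counts and see uniform coverage", {
  spec <- synthetic_membrane_spec(box = c(200, 200), n_frames = 6, seed = 31)
  m <- build_membrane(spec)
  dm <- density_map(m$frames, "CHOL", window = "full")
  n_chol <- sum(m$frames[[1]]$species == "CHOL")
  expect_equal(sum(dm$counts), n_chol * 6)
  # uniformity: chi-square GOF over coarse 20 A blocks, one frame only
  # (species identity is fixed per site, so frames are not independent
  # draws of the species pattern)
  dm2 <- density_map(m$frames, "PE", bin = 20, window = c(1, 1))
  cnt <- as.vector(dm2$counts)
  chi <- sum((cnt - mean(cnt))^2 / mean(cnt))
  p <- stats::pchisq(chi, df = length(cnt) - 1, lower.tail = FALSE)
  expect_gt(p, 0.01)
  expect_error(density_map(m$frames, "XX"), "unknown species")
})

test_that("default window is the second half of the frame set", {
  m <- flat_membrane(box = c(60, 60), n_frames = 4)
  tm <- thickness_map(m$frames, "upper")
  expect_equal(tm$window, c(3L, 4L))
  n_up <- sum(m$frames[[1]]$z > m$truth$midplane)
  expect_equal(sum(tm$counts), n_up * 2)
})

test_that("grid TSV round-trips maps with metadata", {
  m <- flat_membrane(box = c(60, 60), n_frames = 2, noise = 0.5, seed = 3)
  tm <- thickness_map(m$frames, "lower", window = "full")
  p <- withr::local_tempfile(fileext = ".tsv")
  write_grid_tsv(tm, p)
  back <- read_grid_tsv(p)
  expect_equal(back$leaflet, "lower")
  expect_equal(back$bin, tm$bin)
  expect_equal(back$window, tm$window)
  expect_equal(back$counts, tm$counts)
  expect_equal(back$mean, tm$mean, tolerance = 1e-6)
})
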