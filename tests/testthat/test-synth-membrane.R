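test_that("flat field with zero noise puts every phosphate at +/- z0", {
  m <- flat_membrane(box = c(80, 80), n_frames = 1, z0 = 19)
  f <- m$frames[[1]]
  zmid <- m$truth$midplane
  up <- f$z[f$z > zmid]
  lo <- f$z[f$z < zmid]
  expect_true(all(abs(up - (zmid + 19)) < 1e-9))
  expect_true(all(abs(lo - (zmid - 19)) < 1e-9))
})

test_that("species counts follow the 54:32:8:6 composition within 3 sd", {
  spec <- synthetic_membrane_spec(box = c(420, 420), area_per_lipid = 64,
                                  n_frames = 1, seed = 21)
  m <- build_membrane(spec)
  f <- m$frames[[1]]
  lip <- f[f$species != "PROT", ]
  n <- nrow(lip)
  expect_gt(n, 5000)
  for (sp in names(spec$composition)) {
    p <- spec$composition[[sp]]
    obs <- sum(lip$species == sp)
    expect_lt(abs(obs - n * p), 3 * sqrt(n * p * (1 - p)) + 1e-9)
  }
})

test_that("a -6 A Gaussian dip moves the lower-leaflet plane to -25 A", {
  spec <- synthetic_membrane_spec(
    box = c(200, 200), noise_sd = 0, jitter_sd = 0,
    composition = membrane_composition(c(PE = 1)),
    field = deformation_field("lower", -6, 100, 100, 15),
    n_frames = 1, seed = 2)
  m <- build_membrane(spec)
  f <- m$frames[[1]]
  zmid <- m$truth$midplane
  r <- sqrt((f$x - 100)^2 + (f$y - 100)^2)
  # nearest lattice sites to the field center (lattice constant ~8.6 A)
  center_lo <- f$z < zmid & r < 6
  expect_gt(sum(center_lo), 0)
  # generator's own field formula at the site radius
  expected <- -19 - 6 * exp(-r[center_lo]^2 / (2 * 15^2))
  expect_equal(f$z[center_lo] - zmid, expected, tolerance = 1e-9)
})

test_that("generators are pure functions of (spec, seed)", {
  s <- synthetic_membrane_spec(box = c(100, 100), n_frames = 2, seed = 33)
  a <- build_membrane(s)
  b <- build_membrane(s)
  expect_identical(a, b)
  c2 <- build_membrane(synthetic_membrane_spec(box = c(100, 100),
                                               n_frames = 2, seed = 34))
  expect_false(identical(a$frames[[1]]$z, c2$frames[[1]]$z))
})

test_that("generated membranes are valid reader inputs (round trip)", {
  m <- flat_membrane(box = c(60, 60), n_frames = 2, noise = 0.5, jitter = 1)
  p <- withr::local_tempfile(fileext = ".gro")
  write_gro_frames(m$frames, p)
  back <- read_gro_frames(p)
  expect_equal(length(back), 2L)
  expect_lt(max(abs(back[[1]]$z - m$frames[[1]]$z)), 0.005)
})

test_that("invalid specs are rejected", {
  expect_error(membrane_composition(c(PE = 0.5, PC = 0.4)), "sum to 1")
  expect_error(membrane_composition(c(PE = 1.5, PC = -0.5)), "positive")
  expect_error(synthetic_membrane_spec(box = c(100, 100),
                                       protein_radius = 60),
               "footprint radius")
  expect_error(synthetic_membrane_spec(shell_multipliers = c(XX = 2)),
               "unknown species")
  expect_error(deformation_field("upper", 1, 0, 0, sigma = -1), "sigma")
})

test_that("cholesterol hydroxyls ride below their leaflet's phosphates", {
  spec <- synthetic_membrane_spec(
    box = c(150, 150), noise_sd = 0, jitter_sd = 0, chol_depth = 5,
    n_frames = 1, seed = 8)
  f <- build_membrane(spec)$frames[[1]]
  zmid <- spec$box_lz / 2
  up_chol <- f$z[f$bead == "ROH" & f$z > zmid]
  expect_true(all(abs(up_chol - (zmid + 19 - 5)) < 1e-9))
})
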