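test_that("superposition basics: identity, constructed rotation, symmetry", {
  m <- random_model(40, seed = 5)
  fit <- superpose(m, m)
  expect_equal(fit$rmsd, 0, tolerance = 1e-12)
  expect_equal(fit$angle, 0, tolerance = 1e-9)

  rc <- make_rotated_copy(m, c(1, 1, 0), 8, c(2, 0, -1))
  fit2 <- superpose(m, rc$model)
  expect_lt(fit2$rmsd, 1e-9)
  expect_equal(fit2$angle, 8, tolerance = 1e-9)

  # rmsd is symmetric and invariant to rigid pre-transforms of either side
  n1 <- as.data.frame(m); n1$x <- n1$x + stats::rnorm(40, 0, 0.5)
  noisy <- atom_model(n1)
  expect_equal(superpose(m, noisy)$rmsd, superpose(noisy, m)$rmsd,
               tolerance = 1e-9)
  pre <- make_rotated_copy(noisy, c(0, 1, 0), 77, c(10, 10, 10))$model
  expect_equal(superpose(m, pre)$rmsd, superpose(m, noisy)$rmsd,
               tolerance = 1e-9)
})

test_that("rotation matrices are proper within 1e-9", {
  m <- random_model(30, seed = 6)
  rc <- make_rotated_copy(m, c(2, -1, 3), 113)$model
  fit <- superpose(m, rc)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  expect_equal(crossprod(fit$R), diag(3), tolerance = 1e-9)
  expect_true(fit$angle >= 0 && fit$angle <= 180)
})

test_that("reflection correction handles near-planar point sets", {
  withr::local_seed(8)
  flat <- matrix(c(stats::runif(40, -10, 10), stats::runif(20, -0.01, 0.01)),
                 20, 3)
  m <- toy_model(flat)
  rc <- make_rotated_copy(m, c(0, 0, 1), 45)$model
  fit <- superpose(m, rc)
  expect_equal(det(fit$R), 1, tolerance = 1e-9)
  expect_lt(fit$rmsd, 1e-6)
})

test_that("degenerate geometry is rejected", {
  line <- toy_model(cbind(1:5, 2 * (1:5), -1 * (1:5)))
  expect_error(superpose(line, line), "degenerate|collinear")
  expect_error(superpose(random_model(2, 1)[1:2, ], random_model(2, 1)[1:2, ]),
               ">= 3")
})

test_that("pair_atoms by key honors residue offsets", {
  m <- make_helix(20)
  m2 <- m; m2$resid <- m2$resid + 100
  pr <- pair_atoms(m, selection_spec(), m2, selection_spec(),
                   mode = "by_key", offset = -100)
  expect_equal(pr$n, 20L)
  expect_equal(pr$xyz_1, pr$xyz_2)
  expect_error(pair_atoms(m, selection_spec(), m2, selection_spec(),
                          mode = "by_key"), "no atom pairs")
})

test_that("alignment pairing bridges a 3-residue insertion", {
  # oracle alignment, by hand: s1 = A G V L I F, s2 = A G V (SSS) L I F;
  # NW with match 1 / mismatch -1 / gap -2 pairs all but the insertion
  res1 <- c("ALA", "GLY", "VAL", "LEU", "ILE", "PHE")
  res2 <- c("ALA", "GLY", "VAL", "SER", "SER", "SER", "LEU", "ILE", "PHE")
  mk <- function(res) atom_model(data.frame(
    chain = "A", resid = seq_along(res), inscode = "", resname = res,
    atom = "CA", element = "C", x = seq_along(res), y = 0, z = 0,
    occ = 1, bfac = 0))
  # collinear coords are fine here: pairing does not superpose
  pr <- pair_atoms(mk(res1), selection_spec(), mk(res2), selection_spec(),
                   mode = "by_alignment")
  expect_equal(pr$n, 6L)
  expect_equal(pr$keys, c("1~1", "2~2", "3~3", "4~7", "5~8", "6~9"))
})

test_that("domain rotation recovers a synthetic 8 degree hinge", {
  base <- make_helix(40)
  xyz <- cbind(base$x, base$y, base$z)
  R <- axis_angle_matrix(c(0, 1, 0), 8)
  pivot <- xyz[20, ]
  xyz[21:40, ] <- sweep(sweep(xyz[21:40, ], 2, pivot) %*% t(R), 2, pivot, `+`)
  bent <- base; bent$x <- xyz[, 1]; bent$y <- xyz[, 2]; bent$z <- xyz[, 3]
  anchor <- selection_spec(residues = c(1, 20))
  moving <- selection_spec(residues = c(21, 40))
  expect_equal(as.numeric(domain_rotation(base, bent, anchor, moving)), 8,
               tolerance = 0.01)
  expect_equal(as.numeric(domain_rotation(base, base, anchor, moving)), 0,
               tolerance = 1e-4)
  # symmetry: swapping anchor and moving gives the same relative angle
  expect_equal(as.numeric(domain_rotation(base, bent, moving, anchor)), 8,
               tolerance = 0.01)
  # and so does swapping the two states
  expect_equal(as.numeric(domain_rotation(bent, base, anchor, moving)), 8,
               tolerance = 0.01)
})

test_that("centroid distances: 3-4-5 points, identity, translated helices", {
  a <- toy_model(matrix(c(0, 0, 0), 1, 3))
  b <- toy_model(matrix(c(3, 4, 0), 1, 3))
  expect_equal(centroid_distance(a, b), 5)
  expect_equal(centroid_distance(a, a), 0)
  h <- make_helix(15)
  h2 <- h; h2$x <- h2$x + 11
  expect_equal(centroid_distance(h, h2), 11, tolerance = 1e-12)
})
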