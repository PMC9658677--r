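minimal_pdb <- function(path) {
  writeLines(c(
    "ATOM      1  N   ALA A   1      11.104   6.134  -6.504  1.00  0.00           N",
    "ATOM      2  CA  ALA A   1      11.639   6.071  -5.147  1.00  0.00           C",
    "ATOM      3  C   ALA A   1      12.697   7.155  -4.974  1.00  0.00           C",
    "ATOM      4  O   ALA A   1      13.560   7.331  -5.836  1.00  0.00           O",
    "ATOM      5  CB  ALA A   1      12.217   4.686  -4.880  1.00  0.00           C",
    "END"), path)
  path
}

test_that("a minimal PDB parses into one residue with its atoms", {
  f <- minimal_pdb(withr::local_tempfile(fileext = ".pdb"))
  s <- read_structure(f)
  expect_s3_class(s, "prot3d")
  expect_equal(nrow(residues(s)), 1L)
  expect_equal(residues(s)$aa, "A")
  expect_equal(nrow(s$atoms), 5L)
})

test_that("write/read round-trip preserves coordinates to PDB precision", {
  set.seed(5)
  ca <- matrix(rnorm(30, sd = 8), ncol = 3)
  s <- toy_structure(round(ca, 3), aa = sample(AA20, 10, replace = TRUE))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_structure(s, f)
  s2 <- read_structure(f)
  expect_equal(nrow(s2$atoms), nrow(s$atoms))
  expect_equal(s2$atoms$x, s$atoms$x, tolerance = 1e-8)
  expect_equal(s2$atoms$y, s$atoms$y, tolerance = 1e-8)
  expect_equal(s2$atoms$z, s$atoms$z, tolerance = 1e-8)
  expect_equal(s2$atoms$aa, s$atoms$aa)
})

test_that("the packaged 3S4M-sequence stand-in has 129 chain-A residues", {
  s <- read_structure(conserv3d_example("3s4m_chainA_synthetic_coords.pdb"))
  rs <- residues(s)
  expect_equal(nrow(rs), 129L)
  expect_equal(range(rs$resno), c(82L, 210L))
  expect_equal(sum(rs$aa == "Y"), 7L)
  expect_equal(sum(rs$aa == "W"), 3L)
})

test_that("residue distances honor their modes", {
  s <- toy_structure(rbind(c(0, 0, 0), c(3, 4, 0)))
  expect_equal(residue_distance(s, 1, 1, mode = "ca"), 0)
  expect_equal(residue_distance(s, 1, 2, mode = "ca"), 5)
  expect_equal(residue_distance(s, 1, 2, mode = "min_atom"), 5)
  expect_equal(residue_distance(s, 2, 1, mode = "ca"), 5)  # symmetric
  # ring centroids: two tyrosines whose rings are built around set centers
  sy <- prot3d(rbind(toy_tyrosine(1, c(0, 0, 0)),
                     toy_tyrosine(2, c(0, 0, 7.5))))
  expect_equal(residue_distance(sy, 1, 2, mode = "ring_centroid"), 7.5,
               tolerance = 1e-9)
  expect_error(residue_distance(s, 1, 2, mode = "ring_centroid"),
               "incomplete-residue")
})

test_that("min_atom equals all-pairs enumeration on random residues", {
  set.seed(13)
  for (i in 1:15) {
    n1 <- sample(2:6, 1); n2 <- sample(2:6, 1)
    a1 <- matrix(rnorm(n1 * 3, sd = 3), ncol = 3)
    a2 <- sweep(matrix(rnorm(n2 * 3, sd = 3), ncol = 3), 2, c(8, 0, 0), "+")
    atoms <- data.frame(chain = "A", resno = rep(1:2, c(n1, n2)),
                        insert = "", aa = "A",
                        elety = paste0("C", seq_len(n1 + n2)), elesy = "C",
                        x = c(a1[, 1], a2[, 1]), y = c(a1[, 2], a2[, 2]),
                        z = c(a1[, 3], a2[, 3]), stringsAsFactors = FALSE)
    s <- prot3d(atoms)
    brute <- min(apply(a1, 1, function(p)
      apply(a2, 1, function(q) sqrt(sum((p - q)^2)))))
    expect_equal(residue_distance(s, 1, 2, mode = "min_atom"), brute,
                 tolerance = 1e-12)
  }
})

test_that("single-point distance modes behave as a metric", {
  set.seed(17)
  ca <- matrix(rnorm(24, sd = 6), ncol = 3)
  s <- toy_structure(ca)
  d <- function(i, j) residue_distance(s, i, j, mode = "ca")
  for (k in 1:15) {
    ijk <- sample(8, 3)
    expect_equal(d(ijk[1], ijk[2]), d(ijk[2], ijk[1]))
    expect_gte(d(ijk[1], ijk[2]) + d(ijk[2], ijk[3]) - d(ijk[1], ijk[3]),
               -1e-9)
  }
  expect_equal(d(3, 3), 0)
})

test_that("an isolated residue is fully solvent-exposed", {
  s <- toy_structure(matrix(c(0, 0, 0), ncol = 3), aa = "A")
  rsa <- relative_accessibility(s)
  expect_lt(abs(rsa$rsa - 1) / 1, 0.15)
})

test_that("a residue enclosed by a dense shell is buried", {
  inner <- toy_structure(matrix(c(0, 0, 0), ncol = 3), aa = "A")
  shell <- shell_structure(radius = 4, n_atoms = 300)
  shell$atoms$resno <- shell$atoms$resno + 1L
  s <- prot3d(rbind(inner$atoms[, names(shell$atoms)], shell$atoms))
  rsa <- relative_accessibility(s)
  expect_lt(rsa$rsa[rsa$resno == 1], 0.05)
})

test_that("accessibility is converged in the sphere-point count", {
  set.seed(19)
  ca <- matrix(rnorm(18, sd = 4), ncol = 3)
  s <- toy_structure(ca, aa = sample(AA20, 6, replace = TRUE))
  r1 <- relative_accessibility(s, n_points = 960)
  r2 <- relative_accessibility(s, n_points = 1920)
  expect_true(all(abs(r1$rsa - r2$rsa) < 0.02))
})

test_that("kabsch superposition recovers rigid transforms exactly", {
  set.seed(23)
  P <- matrix(rnorm(30, sd = 5), ncol = 3)
  self <- kabsch_superpose(P, P)
  expect_equal(self$rmsd, 0, tolerance = 1e-10)
  R <- random_rotation()
  Q <- sweep(P %*% t(R), 2, c(4, -2, 9), "+")
  fit <- kabsch_superpose(P, Q)
  expect_lt(fit$rmsd, 1e-6)
  expect_equal(det(fit$rotation), 1, tolerance = 1e-9)
  moved <- sweep(P %*% t(fit$rotation), 2, fit$translation, "+")
  expect_equal(moved, Q, tolerance = 1e-6)
})

test_that("kabsch RMSD matches brute-force rotational search on a toy set", {
  set.seed(29)
  P <- matrix(c(0, 0, 0, 3.8, 0, 0, 3.8, 3.8, 0, 0, 3.8, 2), ncol = 3,
              byrow = TRUE)
  Q <- P %*% t(random_rotation()) + matrix(rnorm(12, sd = 0.4), ncol = 3)
  fit <- kabsch_superpose(P, Q)
  oracle <- grid_superpose_rmsd(P, Q)
  expect_equal(fit$rmsd, oracle, tolerance = 1e-3)
  expect_lte(fit$rmsd, oracle + 1e-8)  # never worse than the search
})

test_that("kabsch RMSD agrees with bio3d's fitting on noisy pairs", {
  set.seed(30)
  for (i in 1:5) {
    n <- sample(5:20, 1)
    P <- matrix(rnorm(n * 3, sd = 5), ncol = 3)
    Q <- sweep(P %*% t(random_rotation()), 2, rnorm(3, sd = 8), "+") +
      matrix(rnorm(n * 3, sd = 0.5), ncol = 3)
    ours <- kabsch_superpose(P, Q)$rmsd
    ref <- bio3d::rmsd(as.numeric(t(Q)), as.numeric(t(P)), fit = TRUE)
    expect_equal(ours, ref, tolerance = 1e-3)  # bio3d rounds to 3 digits
  }
})

test_that("kabsch RMSD is invariant under rigid pre-transforms", {
  set.seed(31)
  P <- matrix(rnorm(21, sd = 5), ncol = 3)
  Q <- matrix(rnorm(21, sd = 5), ncol = 3)
  base <- kabsch_superpose(P, Q)$rmsd
  for (i in 1:5) {
    P2 <- sweep(P %*% t(random_rotation()), 2, rnorm(3, sd = 10), "+")
    expect_equal(kabsch_superpose(P2, Q)$rmsd, base, tolerance = 1e-9)
  }
})

test_that("degenerate point sets are rejected", {
  expect_error(kabsch_superpose(matrix(rnorm(6), 2), matrix(rnorm(6), 2)),
               "degenerate-superposition")
  line <- cbind(1:5, 0, 0)
  expect_error(kabsch_superpose(line, line + 1), "degenerate-superposition")
})
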