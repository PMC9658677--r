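test_that("sequence weights follow the position-based rule", {
  # N identical sequences split the weight evenly
  a <- msa(letters[1:4], rep("MKY", 4))
  expect_equal(sequence_weights(a), rep(0.25, 4))
  expect_equal(sequence_weights(msa("solo", "MKY")), 1)
  # hand computation for a 3-sequence toy with one divergent record:
  # col 1 (A,A,A): each 1/3; col 2 (Y,Y,W): Y -> 1/4 each, W -> 1/2
  b <- msa(c("s1", "s2", "s3"), c("AY", "AY", "AW"))
  raw <- c(1 / 3 + 1 / 4, 1 / 3 + 1 / 4, 1 / 3 + 1 / 2)
  expect_equal(sequence_weights(b), raw / sum(raw))
})

test_that("gap-only alignments are a degenerate input", {
  a <- msa(c("a", "b"), c("-X", "-Z"))  # ambiguity codes are not informative
  expect_error(sequence_weights(a), "degenerate-input")
})

test_that("a column matching the background scores zero divergence", {
  bg <- robinson_background()
  # one record per letter, weighted by the background itself
  expect_equal(column_score(names(bg), unname(bg), bg), 0, tolerance = 1e-12)
})

test_that("an invariant column matches the closed-form point-mass score", {
  u <- rep(1 / 20, 20)
  score <- column_score(rep("Y", 5), rep(0.2, 5), setNames(u, AA20))
  # direct computation: P = point mass on Y, Q = uniform
  p <- setNames(rep(0, 20), AA20); p["Y"] <- 1
  m <- (p + 1 / 20) / 2
  h <- function(v) { v <- v[v > 0]; -sum(v * log2(v)) }
  expected <- h(m) - (h(p) + h(rep(1 / 20, 20))) / 2
  expect_equal(score, expected, tolerance = 1e-12)
})

test_that("column scores agree with an independent KL-form implementation", {
  set.seed(42)
  bgs <- list(setNames(rep(1 / 20, 20), AA20), robinson_background())
  for (i in 1:25) {
    n <- sample(3:20, 1)
    col <- sample(AA20, n, replace = TRUE)
    w <- runif(n, 0.2, 2)
    bg <- bgs[[1 + i %% 2]]
    keep <- rep(TRUE, n)
    p <- vapply(AA20, function(a) sum(w[col == a]), 0)
    p <- p / sum(p)
    expect_equal(column_score(col, w, bg),
                 jsd_kl_oracle(p, unname(bg[AA20])), tolerance = 1e-10)
  }
  # the spec's worked example: [Y, Y, I] with equal weights, uniform bg
  p <- setNames(rep(0, 20), AA20); p[c("Y", "I")] <- c(2 / 3, 1 / 3)
  expect_equal(column_score(c("Y", "Y", "I"), rep(1, 3),
                            setNames(rep(1 / 20, 20), AA20)),
               jsd_kl_oracle(unname(p), rep(1 / 20, 20)), tolerance = 1e-10)
})

test_that("all-gap columns raise an undefined-score error", {
  expect_error(column_score(c("-", "-", "X"), rep(1, 3)), "undefined-score")
})

test_that("homogenizing a column never decreases its score", {
  set.seed(7)
  for (i in 1:40) {
    n <- sample(5:30, 1)
    col <- sample(AA20, n, replace = TRUE)
    w <- rep(1, n)
    tab <- table(col)
    if (length(tab) < 2) next
    major <- names(tab)[which.max(tab)]
    minor <- names(tab)[which.min(tab)]
    col2 <- col
    col2[which(col2 == minor)[1]] <- major
    expect_gte(column_score(col2, w) - column_score(col, w), -1e-12)
  }
})

test_that("duplicating every sequence leaves column scores unchanged", {
  set.seed(8)
  a <- random_msa(6, 15)
  b <- msa(c(a$ids, paste0(a$ids, "_dup")), c(a$seqs, a$seqs))
  wa <- sequence_weights(a)
  wb <- sequence_weights(b)
  for (j in 1:15) {
    ca <- aln_column(a, j)
    if (!any(ca %in% AA20)) next
    expect_equal(column_score(aln_column(b, j), wb, "robinson"),
                 column_score(ca, wa, "robinson"), tolerance = 1e-12)
  }
})

test_that("reliability counts standard letters with an inclusive boundary", {
  expect_equal(reliability(rep("-", 10), 6),
               list(reliable = FALSE, n_informative = 0L))
  expect_equal(reliability(rep("K", 47), 6),
               list(reliable = TRUE, n_informative = 47L))
  expect_true(reliability(c(rep("K", 6), rep("-", 4)), 6)$reliable)
  expect_false(reliability(c(rep("K", 5), "X", rep("-", 4)), 6)$reliable)
})

test_that("grades are equal-count quantile bins with ties to the top", {
  expect_equal(grade_profile(seq(0.1, 0.9, by = 0.1)), 1:9)
  expect_equal(grade_profile(rep(0.5, 7)), rep(9L, 7))
  set.seed(9)
  x <- runif(18)
  g <- grade_profile(x)
  # sort-based oracle: 2 columns per bin
  expect_equal(as.integer(table(g)), rep(2L, 9))
  expect_equal(g, as.integer(ceiling(rank(x) / 2)))
})

test_that("unreliable columns inherit the grade of their score bin", {
  x <- c(seq(0.1, 0.9, by = 0.1), 0.85, 0.05, 0.95)
  rel <- c(rep(TRUE, 9), FALSE, FALSE, FALSE)
  g <- grade_profile(x, reliable = rel)
  expect_equal(g[1:9], 1:9)
  expect_equal(g[10:12], c(9L, 1L, 9L))
})

test_that("conservation_profile assembles scores, grades and mapping", {
  a <- msa(c("ref", "s2", "s3", "s4", "s5", "s6"),
           c("G-AVY", "GTAVY", "GTAVY", "GAAVY", "GTAVW", "GTAVY"))
  m <- map_to_reference(a, "ref", 82)
  p <- conservation_profile(a, m, min_informative = 5)
  expect_s3_class(p, "conservation_profile")
  expect_equal(nrow(p), 5L)
  expect_equal(p$ref_pos, c(82L, NA, 83L, 84L, 85L))
  expect_equal(p$ref_aa[1], "G")
  expect_true(all(p$raw_score >= 0 & p$raw_score <= 1))
  expect_true(all(p$grade[p$reliable] %in% 1:9))
  # column 2 has 5 informative letters (ref gap) -> still reliable at min 5
  expect_true(p$reliable[2])
  p6 <- conservation_profile(a, m, min_informative = 6)
  expect_false(p6$reliable[2])
})
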