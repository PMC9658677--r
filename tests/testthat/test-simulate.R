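test_that("simulation specs validate sizes, rates and feasibility", {
  expect_error(simulation_spec(1, 0, 10), "positive")
  expect_error(simulation_spec(1, 5, 10,
                               conserved_sites = data.frame(pos = 99,
                                                            theta = 1)),
               "outside")
  expect_error(simulation_spec(1, 5, 10, variant_rate = 2), "variant_rate")
  expect_error(simulation_spec(1, 5, 10,
                               taxon_groups = c(a = 2, b = 2)), "sum")
  expect_error(simulation_spec(1, 5, 50, planted_clusters =
                                 list(list(members = c(5, 9), d_plant = 3))),
               "feasibility")
})

test_that("fully conserved sites give invariant columns", {
  spec <- simulation_spec(101, 30, 40,
                          conserved_sites = data.frame(pos = c(5, 21),
                                                       theta = 1))
  aln <- simulate_alignment(spec)
  expect_equal(length(unique(aln_column(aln, 5))), 1L)
  expect_equal(length(unique(aln_column(aln, 21))), 1L)
  expect_equal(aln_column(aln, 5)[1], spec$ref_seq[5])
})

test_that("simulations are deterministic under the seed", {
  spec <- simulation_spec(77, 12, 30, variant_rate = 0.4,
                          planted_clusters = list(list(members = c(4, 18),
                                                       d_plant = 6)))
  expect_identical(simulate_alignment(spec), simulate_alignment(spec))
  s1 <- simulate_structure(spec)
  s2 <- simulate_structure(spec)
  expect_identical(s1$atoms, s2$atoms)
  expect_identical(simulate_variants(spec), simulate_variants(spec))
  # a different seed changes the draw
  spec2 <- simulation_spec(78, 12, 30)
  expect_false(identical(simulate_alignment(spec)$seqs,
                         simulate_alignment(spec2)$seqs))
})

test_that("background columns track the background distribution", {
  spec <- simulation_spec(5, 2000, 3, background = "robinson")
  aln <- simulate_alignment(spec)
  bg <- robinson_background()
  for (j in 1:3) {
    col <- aln_column(aln, j)
    for (a in c("A", "L", "S", "W")) {
      p <- bg[a]
      se <- sqrt(p * (1 - p) / 2000)
      expect_lt(abs(mean(col == a) - p), 3.5 * se + 1e-3)
    }
  }
})

test_that("motif carriers and non-carriers are forced correctly", {
  spec <- simulation_spec(9, 30, 40,
                          taxon_groups = c(euk = 10, bact = 20),
                          planted_motif = list(positions = c(7, 19),
                                               consensus = c("Y", "E"),
                                               carrier_groups = "euk"))
  aln <- simulate_alignment(spec)
  carrier <- aln$taxon_group == "euk"
  expect_true(all(aln_column(aln, 7)[carrier] == "Y"))
  expect_true(all(aln_column(aln, 19)[carrier] == "E"))
  expect_true(all(aln_column(aln, 7)[!carrier] != "Y"))
  expect_true(all(aln_column(aln, 19)[!carrier] != "E"))
})

test_that("planted residue pairs end up within the planting distance", {
  for (seed in 1:5) {
    spec <- simulation_spec(seed, 5, 40,
                            planted_clusters = list(
                              list(members = c(8, 25, 33), d_plant = 6)))
    s <- simulate_structure(spec)
    for (pair in list(c(8, 25), c(8, 33), c(25, 33)))
      expect_lte(residue_distance(s, pair[1], pair[2],
                                  mode = "sidechain_centroid"), 6 + 1e-9)
  }
})

test_that("unplanted walks are self-avoiding with 3.8 A steps", {
  spec <- simulation_spec(31, 5, 60)
  s <- simulate_structure(spec)
  ca <- s$atoms[s$atoms$elety == "CA", c("x", "y", "z")]
  steps <- sqrt(rowSums(diff(as.matrix(ca))^2))
  expect_true(all(abs(steps - 3.8) < 1e-6))
  d <- as.matrix(dist(ca))
  nonadj <- abs(row(d) - col(d)) > 1
  expect_gte(min(d[nonadj]), 3.5)
  # pseudo side chains sit 1.5 A from their alpha carbon
  cb <- s$atoms[s$atoms$elety == "CB", c("x", "y", "z")]
  expect_true(all(abs(sqrt(rowSums((ca - cb)^2)) - 1.5) < 1e-9))
})

test_that("variant simulation respects rates and protected positions", {
  spec0 <- simulation_spec(3, 5, 100, variant_rate = 0)
  expect_equal(nrow(simulate_variants(spec0)), 0L)
  spec1 <- simulation_spec(3, 5, 100, variant_rate = 1)
  expect_equal(residues_with_variants(simulate_variants(spec1)), 1:100)
  specp <- simulation_spec(3, 5, 100, variant_rate = 1,
                           protected_positions = c(10, 50, 90))
  hit <- residues_with_variants(simulate_variants(specp))
  expect_true(all(!c(10, 50, 90) %in% hit))
  expect_equal(length(hit), 97L)
  # binomial sampling bound at rate 0.3 over 1000 sites
  spec3 <- simulation_spec(13, 5, 1000, variant_rate = 0.3)
  n_hit <- length(residues_with_variants(simulate_variants(spec3)))
  se <- sqrt(0.3 * 0.7 * 1000)
  expect_lt(abs(n_hit - 300), 3 * se)
  vt <- simulate_variants(spec3)
  expect_true(all(vt$frequency >= 1e-6 & vt$frequency <= 1e-4))
  expect_true(all(vt$ref_aa != vt$alt_aa))
})

test_that("the pipeline recovers planted signal end to end", {
  n_ok_sites <- 0L
  n_ok_clusters <- 0L
  n_ok_motif <- 0L
  n_ok_protected <- 0L
  n_seeds <- 30L
  clusters_def <- list(list(members = c(10L, 30L, 31L), d_plant = 7),
                       list(members = c(70L, 95L), d_plant = 7))
  sites <- sort(c(10L, 30L, 31L, 70L, 95L, 50L, 55L, 112L))
  for (seed in seq_len(n_seeds)) {
    spec0 <- simulation_spec(1000 + seed, 40, 120,
                             conserved_sites = data.frame(pos = sites,
                                                          theta = 1))
    spec <- simulation_spec(1000 + seed, 40, 120,
                            conserved_sites = data.frame(pos = sites,
                                                         theta = 1),
                            taxon_groups = c(euk = 15, bact = 25),
                            planted_motif = list(
                              positions = c(50L, 55L),
                              consensus = spec0$ref_seq[c(50, 55)],
                              carrier_groups = "euk"),
                            planted_clusters = clusters_def,
                            variant_rate = 0.3,
                            protected_positions = sites)
    aln <- simulate_alignment(spec)
    mapping <- map_to_reference(aln, aln$ids[1], 1)
    prof <- conservation_profile(aln, mapping)
    top <- prof$ref_pos[!is.na(prof$grade) & prof$grade == 9]
    # (a) planted sites reach the top grade (those eligible: non-motif
    # sites are invariant; motif sites are invariant only within carriers)
    invariant_sites <- setdiff(sites, c(50L, 55L))
    if (all(invariant_sites %in% top)) n_ok_sites <- n_ok_sites + 1L
    # (b) planted spatial clusters are recovered exactly
    s <- simulate_structure(spec)
    cl <- spatial_clusters(c(10L, 30L, 31L, 70L, 95L), s, cutoff = 7)
    got <- lapply(cl, `[[`, "members")
    want <- lapply(clusters_def, `[[`, "members")
    if (length(got) == 2 && identical(got, want))
      n_ok_clusters <- n_ok_clusters + 1L
    # (c) carrier groups carry the full motif, others never
    mt <- motif_table(aln, mapping,
                      motif_spec(c(50L, 55L), spec$ref_seq[c(50, 55)]))
    gs <- group_summary(mt)
    if (gs$n_with_full_motif[gs$taxon_group == "euk"] == 15 &&
        gs$n_with_full_motif[gs$taxon_group == "bact"] == 0)
      n_ok_motif <- n_ok_motif + 1L
    # (d) protected positions stay variant-free
    vt <- simulate_variants(spec)
    if (!any(sites %in% residues_with_variants(vt)))
      n_ok_protected <- n_ok_protected + 1L
  }
  expect_gte(n_ok_sites / n_seeds, 0.95)
  expect_gte(n_ok_clusters / n_seeds, 0.95)
  expect_gte(n_ok_motif / n_seeds, 0.95)
  expect_gte(n_ok_protected / n_seeds, 0.95)
})
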