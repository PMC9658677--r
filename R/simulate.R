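#' Specification for planted-signal simulations
#'
#' Defines everything the generators need: alignment size, per-site
#' conservation strength, taxon groups, a planted presence/absence motif,
#' spatially planted residue clusters, and variant parameters. The
#' reference (consensus) sequence and per-site consensus letters are drawn
#' here, deterministically under `seed`, so alignment, structure and
#' variant simulations of the same spec are mutually consistent.
#'
#' @param seed Integer RNG seed (keep below 2^31).
#' @param n_seqs Number of sequences.
#' @param length Alignment length / chain length in residues.
#' @param conserved_sites data.frame with columns `pos` and `theta`
#'   (probability a sequence carries the site's consensus letter); sites not
#'   listed evolve at background. Consensus letters at conserved sites are
#'   drawn excluding G/P so conservation-cluster selection applies to them.
#' @param taxon_groups Named integer vector of group sizes (sums to
#'   `n_seqs`); NULL for one unnamed group.
#' @param planted_motif list(positions, consensus, carrier_groups): carrier
#'   groups always carry the consensus letters, everyone else never does.
#' @param planted_clusters List of list(members, d_plant): residue sets to
#'   relocate within pairwise side-chain-centroid distance `d_plant`
#'   (Angstrom, >= 4).
#' @param variant_rate Per-site probability of at least one simulated
#'   variant.
#' @param protected_positions Positions that never receive variants.
#' @param group_theta Probability of drawing the group-level consensus
#'   letter (two-level structure for exercising sequence weighting); 0 for
#'   plain star-phylogeny i.i.d. sequences.
#' @param background Background distribution (see [column_score()]).
#' @return An object of class `simulation_spec`.
#' @export
simulation_spec <- function(seed, n_seqs, length,
                            conserved_sites = NULL,
                            taxon_groups = NULL,
                            planted_motif = NULL,
                            planted_clusters = list(),
                            variant_rate = 0,
                            protected_positions = integer(0),
                            group_theta = 0,
                            background = "robinson") {
  seed <- as.integer(seed)
  n_seqs <- as.integer(n_seqs)
  length <- as.integer(length)
  if (n_seqs < 1L || length < 1L)
    stop("validation error: n_seqs and length must be positive",
         call. = FALSE)
  bg <- resolve_background(background)
  if (is.null(conserved_sites))
    conserved_sites <- data.frame(pos = integer(0), theta = numeric(0))
  if (!all(c("pos", "theta") %in% names(conserved_sites)))
    stop("validation error: conserved_sites needs pos and theta columns",
         call. = FALSE)
  if (any(conserved_sites$pos < 1L | conserved_sites$pos > length))
    stop("validation error: conserved site positions outside 1..length",
         call. = FALSE)
  if (any(conserved_sites$theta < 0 | conserved_sites$theta > 1))
    stop("validation error: theta outside [0,1]", call. = FALSE)
  if (is.null(taxon_groups))
    taxon_groups <- setNames(n_seqs, "all")
  if (sum(taxon_groups) != n_seqs)
    stop("validation error: taxon group sizes must sum to n_seqs",
         call. = FALSE)
  if (variant_rate < 0 || variant_rate > 1)
    stop("validation error: variant_rate outside [0,1]", call. = FALSE)
  if (any(protected_positions < 1L | protected_positions > length))
    stop("validation error: protected positions outside 1..length",
         call. = FALSE)
  for (cl in planted_clusters) {
    if (is.null(cl$members) || is.null(cl$d_plant))
      stop("validation error: planted cluster needs members and d_plant",
           call. = FALSE)
    if (any(cl$members < 1L | cl$members > length))
      stop("validation error: planted members outside 1..length",
           call. = FALSE)
    if (cl$d_plant < 4)
      stop("feasibility error: d_plant below 4 Angstrom cannot hold two ",
           "chain residues", call. = FALSE)
  }
  if (length(planted_clusters) > 1) {
    rng <- lapply(planted_clusters, function(cl) range(cl$members))
    ord <- order(vapply(rng, `[`, 0, 1))
    rng <- rng[ord]
    for (k in seq_len(length(rng) - 1))
      if (rng[[k]][2] > rng[[k + 1]][1])
        stop("feasibility error: planted clusters interleave along the ",
             "chain", call. = FALSE)
  }
  if (!is.null(planted_motif)) {
    if (is.null(planted_motif$positions) || is.null(planted_motif$consensus))
      stop("validation error: planted_motif needs positions and consensus",
           call. = FALSE)
    if (any(planted_motif$positions < 1L |
            planted_motif$positions > length))
      stop("validation error: motif positions outside 1..length",
           call. = FALSE)
    if (!all(planted_motif$carrier_groups %in% names(taxon_groups)))
      stop("validation error: unknown carrier groups", call. = FALSE)
  }
  # reference/consensus sequence, deterministic under seed
  set.seed(seed)
  ref <- sample(AA_STANDARD, length, replace = TRUE, prob = bg)
  nogp <- setdiff(AA_STANDARD, c("G", "P"))
  if (nrow(conserved_sites)) {
    pgp <- bg[nogp] / sum(bg[nogp])
    ref[conserved_sites$pos] <- sample(nogp, nrow(conserved_sites),
                                       replace = TRUE, prob = pgp)
  }
  if (!is.null(planted_motif))
    ref[planted_motif$positions] <- toupper(planted_motif$consensus)
  structure(list(seed = seed, n_seqs = n_seqs, length = length,
                 conserved_sites = conserved_sites,
                 taxon_groups = taxon_groups,
                 planted_motif = planted_motif,
                 planted_clusters = planted_clusters,
                 variant_rate = variant_rate,
                 protected_positions = as.integer(protected_positions),
                 group_theta = group_theta,
                 background = bg, ref_seq = ref),
            class = "simulation_spec")
}

sim_group_labels <- function(spec) {
  rep(names(spec$taxon_groups), spec$taxon_groups)
}

#' Simulate an alignment with planted conservation and motif signal
#'
#' Each sequence is drawn i.i.d. per column (star phylogeny): the site's
#' consensus letter with probability theta, otherwise a background draw
#' (optionally routed through a group-level consensus with probability
#' `group_theta`). Motif carrier groups are forced to the motif consensus;
#' all other sequences are forced to a non-consensus letter at the motif
#' positions. Deterministic under the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return An [msa] object with taxon groups assigned.
#' @export
simulate_alignment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 1L)
  n <- spec$n_seqs
  L <- spec$length
  bg <- spec$background
  groups <- sim_group_labels(spec)
  theta <- numeric(L)
  theta[spec$conserved_sites$pos] <- spec$conserved_sites$theta
  m <- matrix("", n, L)
  group_names <- names(spec$taxon_groups)
  group_cons <- matrix(sample(AA_STANDARD, length(group_names) * L,
                              replace = TRUE, prob = bg),
                       nrow = length(group_names))
  rownames(group_cons) <- group_names
  for (j in seq_len(L)) {
    cons <- spec$ref_seq[j]
    keep <- runif(n) < theta[j]
    m[keep, j] <- cons
    rest <- which(!keep)
    if (length(rest)) {
      use_grp <- runif(length(rest)) < spec$group_theta
      m[rest[use_grp], j] <- group_cons[groups[rest[use_grp]], j]
      n_bgd <- sum(!use_grp)
      if (n_bgd)
        m[rest[!use_grp], j] <- sample(AA_STANDARD, n_bgd, replace = TRUE,
                                       prob = bg)
    }
  }
  if (!is.null(spec$planted_motif)) {
    pm <- spec$planted_motif
    carrier <- groups %in% pm$carrier_groups
    for (k in seq_along(pm$positions)) {
      j <- pm$positions[k]
      cons <- toupper(pm$consensus[k])
      m[carrier, j] <- cons
      others <- which(!carrier)
      if (length(others)) {
        alt <- setdiff(AA_STANDARD, cons)
        palt <- bg[alt] / sum(bg[alt])
        m[others, j] <- sample(alt, length(others), replace = TRUE,
                               prob = palt)
      }
    }
  }
  ids <- sprintf("%s_%03d", groups, seq_len(n))
  msa(ids, apply(m, 1, paste, collapse = ""), taxon_group = groups)
}

unit_vec <- function(v) {
  nv <- sqrt(sum(v^2))
  if (nv < 1e-12) c(1, 0, 0) else v / nv
}

random_unit <- function() unit_vec(rnorm(3))

#' Simulate a structure with spatially planted residue clusters
#'
#' Generates a C-alpha trace as a self-avoiding random walk (3.8 A steps,
#' minimum 3.5 A separation between non-neighbors) with a pseudo side-chain
#' atom 1.5 A from each C-alpha. Members of each planted cluster are routed
#' to a common spatial target so that all pairwise side-chain-centroid
#' distances stay within `d_plant`; chain connectivity is preserved with
#' steps of at most 4.2 A around relocated residues (self-avoidance is
#' waived inside planted neighborhoods). Deterministic under the spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return A [prot3d] object (chain A, residues numbered 1..length, atoms
#'   CA and CB).
#' @export
simulate_structure <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 2L)
  L <- spec$length
  step <- 3.8
  min_sep <- 3.5
  clusters <- spec$planted_clusters
  ord <- if (length(clusters))
    order(vapply(clusters, function(cl) min(cl$members), 0)) else integer(0)
  clusters <- clusters[ord]
  member_of <- rep(NA_integer_, L)
  for (k in seq_along(clusters))
    member_of[clusters[[k]]$members] <- k
  r_ca <- vapply(clusters, function(cl) max(1.9, cl$d_plant / 2), 0)

  for (attempt in seq_len(30L)) {
    ok <- TRUE
    pos <- matrix(NA_real_, L, 3)
    pos[1, ] <- c(0, 0, 0)
    targets <- vector("list", length(clusters))
    next_member_after <- function(i) {
      j <- which(!is.na(member_of[i:L]))[1]
      if (is.na(j)) NA_integer_ else i + j - 1L
    }
    for (i in seq(2L, length.out = L - 1L)) {
      prev <- pos[i - 1L, ]
      k <- member_of[i]
      if (!is.na(k)) {
        if (is.null(targets[[k]])) {
          # anchor the cluster where the walk arrives at its first member
          cand <- prev + step * random_unit()
          targets[[k]] <- cand
          # keep distinct clusters well apart
          for (kk in seq_len(k - 1L)) {
            sep_needed <- 2.5 * max(clusters[[k]]$d_plant,
                                    clusters[[kk]]$d_plant)
            tries <- 0L
            while (sqrt(sum((targets[[k]] - targets[[kk]])^2)) <
                   sep_needed && tries < 100L) {
              targets[[k]] <- prev + step * random_unit()
              tries <- tries + 1L
            }
            if (tries >= 100L) ok <- FALSE
          }
          pos[i, ] <- targets[[k]]
          next
        }
        t <- targets[[k]]
        placed <- FALSE
        for (try in seq_len(500L)) {
          p <- t + r_ca[k] * runif(1)^(1 / 3) * random_unit()
          d <- sqrt(sum((p - prev)^2))
          if (d >= 2.0 && d <= 4.2) {
            pos[i, ] <- p
            placed <- TRUE
            break
          }
        }
        if (!placed) { ok <- FALSE; break }
        next
      }
      j <- next_member_after(i)
      drift <- c(0, 0, 0)
      forced <- FALSE
      if (!is.na(j)) {
        kj <- member_of[j]
        t <- if (!is.null(targets[[kj]])) targets[[kj]] else NULL
        if (!is.null(t)) {
          needed <- max(0, sqrt(sum((prev - t)^2)) - r_ca[kj])
          avail <- (j - i + 1L) * step
          if (needed >= avail * 0.85) {
            pos[i, ] <- prev + step * unit_vec(t - prev)
            forced <- TRUE
          } else if (avail > 0) {
            drift <- (needed / avail) * unit_vec(t - prev)
          }
        }
      }
      if (!forced) {
        placed <- FALSE
        best <- NULL
        best_d <- -Inf
        for (try in seq_len(60L)) {
          dir <- unit_vec(random_unit() + 1.5 * drift)
          p <- prev + step * dir
          earlier <- pos[seq_len(max(0L, i - 2L)), , drop = FALSE]
          if (nrow(earlier)) {
            d2 <- (earlier[, 1] - p[1])^2 + (earlier[, 2] - p[2])^2 +
                  (earlier[, 3] - p[3])^2
            mind <- sqrt(min(d2))
          } else mind <- Inf
          if (mind > best_d) { best_d <- mind; best <- p }
          if (mind >= min_sep) {
            pos[i, ] <- p
            placed <- TRUE
            break
          }
        }
        if (!placed) {
          if (length(clusters)) {
            pos[i, ] <- best  # planted geometry outranks self-avoidance
          } else { ok <- FALSE; break }
        }
      }
    }
    if (ok && !anyNA(pos)) break
    if (attempt == 30L)
      stop("feasibility error: could not realize the planted clusters; ",
           "reduce members or increase d_plant", call. = FALSE)
  }

  # pseudo side chains: random fixed direction, except planted members
  # whose side chain points at the cluster target
  cb <- matrix(NA_real_, L, 3)
  for (i in seq_len(L)) {
    k <- member_of[i]
    dir <- if (!is.na(k) && !is.null(targets[[k]]))
      unit_vec(targets[[k]] - pos[i, ]) else random_unit()
    cb[i, ] <- pos[i, ] + 1.5 * dir
  }
  atoms <- data.frame(
    chain = "A",
    resno = rep(seq_len(L), each = 2L),
    insert = "",
    aa = rep(spec$ref_seq, each = 2L),
    elety = rep(c("CA", "CB"), L),
    elesy = "C",
    x = as.numeric(rbind(pos[, 1], cb[, 1])),
    y = as.numeric(rbind(pos[, 2], cb[, 2])),
    z = as.numeric(rbind(pos[, 3], cb[, 3])),
    stringsAsFactors = FALSE)
  prot3d(atoms, id = sprintf("sim_seed%d", spec$seed))
}

#' Simulate a missense-variant table
#'
#' Every non-protected position receives at least one variant with
#' probability `variant_rate`; protected positions never appear. Allele
#' frequencies are drawn uniform on (1e-6, 1e-4). Deterministic under the
#' spec seed.
#'
#' @param spec A [simulation_spec()].
#' @return A `variant_table`.
#' @export
simulate_variants <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed + 3L)
  L <- spec$length
  eligible <- setdiff(seq_len(L), spec$protected_positions)
  hit <- eligible[runif(length(eligible)) < spec$variant_rate]
  if (!length(hit))
    return(variant_table(data.frame(ref_pos = integer(0),
                                    ref_aa = character(0),
                                    alt_aa = character(0),
                                    frequency = numeric(0),
                                    dataset = character(0),
                                    pathogenic = logical(0),
                                    rs_id = character(0),
                                    stringsAsFactors = FALSE)))
  ref <- spec$ref_seq[hit]
  alt <- vapply(ref, function(r) sample(setdiff(AA_STANDARD, r), 1L), "")
  variant_table(data.frame(ref_pos = hit, ref_aa = ref, alt_aa = alt,
                           frequency = runif(length(hit), 1e-6, 1e-4),
                           dataset = "simulated", pathogenic = FALSE,
                           rs_id = NA_character_,
                           stringsAsFactors = FALSE))
}

#' Write a variant table as TSV
#'
#' @param t A `variant_table`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variants_tsv <- function(t, path) {
  df <- as.data.frame(t)
  names(df)[names(df) == "ref_pos"] <- "position"
  names(df)[names(df) == "ref_aa"] <- "ref"
  names(df)[names(df) == "alt_aa"] <- "alt"
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
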