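# Builders and independent oracles shared by the test files.

AA20 <- c("A","C","D","E","F","G","H","I","K","L",
          "M","N","P","Q","R","S","T","V","W","Y")

random_msa <- function(n, L, groups = NULL) {
  seqs <- replicate(n, paste(sample(c(AA20, "-"), L, replace = TRUE,
                                    prob = c(rep(0.045, 20), 0.1)),
                             collapse = ""))
  # keep at least one non-gap per row
  seqs <- vapply(seqs, function(s) {
    if (grepl("^[-]+$", s)) sub("-", "A", s) else s
  }, "")
  msa(sprintf("sq%03d", seq_len(n)), unname(seqs), taxon_group = groups)
}

# toy structure from CA coordinates (+ optional CB pseudo side chains)
toy_structure <- function(ca, aa = NULL, cb = NULL, chain = "A",
                          resno = NULL) {
  ca <- as.matrix(ca)
  n <- nrow(ca)
  if (is.null(aa)) aa <- rep("A", n)
  if (is.null(resno)) resno <- seq_len(n)
  if (is.null(cb)) {
    atoms <- data.frame(chain = chain, resno = resno, insert = "",
                        aa = aa, elety = "CA", elesy = "C",
                        x = ca[, 1], y = ca[, 2], z = ca[, 3],
                        stringsAsFactors = FALSE)
  } else {
    cb <- as.matrix(cb)
    atoms <- data.frame(chain = chain, resno = rep(resno, each = 2),
                        insert = "", aa = rep(aa, each = 2),
                        elety = rep(c("CA", "CB"), n), elesy = "C",
                        x = as.numeric(rbind(ca[, 1], cb[, 1])),
                        y = as.numeric(rbind(ca[, 2], cb[, 2])),
                        z = as.numeric(rbind(ca[, 3], cb[, 3])),
                        stringsAsFactors = FALSE)
  }
  prot3d(atoms, id = "toy")
}

# a tyrosine-like residue whose six ring atoms average to `centroid`
toy_tyrosine <- function(resno, centroid, chain = "A") {
  ang <- seq(0, 2 * pi, length.out = 7)[1:6]
  ring <- cbind(centroid[1] + 1.39 * cos(ang),
                centroid[2] + 1.39 * sin(ang),
                centroid[3])
  data.frame(chain = chain, resno = resno, insert = "", aa = "Y",
             elety = c("CA", "CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
             elesy = "C",
             x = c(centroid[1] + 3, ring[, 1]),
             y = c(centroid[2], ring[, 2]),
             z = c(centroid[3], ring[, 3]),
             stringsAsFactors = FALSE)
}

# hollow shell of carbon atoms; with atom centers at `radius`, the probe
# -accessible interior is a ball of radius (radius - 1.7 - probe)
shell_structure <- function(radius = 7.1, n_atoms = 600, center = c(0, 0, 0)) {
  i <- seq_len(n_atoms) - 0.5
  phi <- acos(1 - 2 * i / n_atoms)
  theta <- pi * (1 + sqrt(5)) * i
  xyz <- radius * cbind(sin(phi) * cos(theta), sin(phi) * sin(theta),
                        cos(phi))
  xyz <- sweep(xyz, 2, center, "+")
  toy_structure(xyz, aa = rep("G", n_atoms))
}

random_rotation <- function() {
  q <- rnorm(4)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
           2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
           2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)),
         3, 3, byrow = TRUE)
}

# --- independent oracles -------------------------------------------------

# Jensen-Shannon divergence written as averaged Kullback-Leibler terms
# (different decomposition from the implementation's entropy form)
jsd_kl_oracle <- function(p, q) {
  m <- (p + q) / 2
  kl <- function(a, b) {
    keep <- a > 0
    sum(a[keep] * log2(a[keep] / b[keep]))
  }
  0.5 * kl(p, m) + 0.5 * kl(q, m)
}

# union-find connected components
uf_components <- function(n, edges) {
  parent <- seq_len(n)
  find <- function(i) {
    while (parent[i] != i) i <- parent[i]
    i
  }
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    ri <- find(edges[e, 1]); rj <- find(edges[e, 2])
    if (ri != rj) parent[rj] <- ri
  }
  vapply(seq_len(n), find, 0L)
}

# breadth-first hop distance over an edge list
bfs_hops <- function(n, edges, from) {
  adj <- vector("list", n)
  if (nrow(edges)) for (e in seq_len(nrow(edges))) {
    adj[[edges[e, 1]]] <- c(adj[[edges[e, 1]]], edges[e, 2])
    adj[[edges[e, 2]]] <- c(adj[[edges[e, 2]]], edges[e, 1])
  }
  dist <- rep(NA_integer_, n)
  dist[from] <- 0L
  frontier <- from
  while (length(frontier)) {
    nxt <- integer(0)
    for (v in frontier) for (u in adj[[v]]) {
      if (is.na(dist[u])) {
        dist[u] <- dist[v] + 1L
        nxt <- c(nxt, u)
      }
    }
    frontier <- nxt
  }
  dist
}

# brute-force rigid superposition: coarse Euler grid then local refinement
grid_superpose_rmsd <- function(P, Q, step_deg = 15) {
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  rot <- function(a, b, c) {
    Rz <- matrix(c(cos(a), -sin(a), 0, sin(a), cos(a), 0, 0, 0, 1), 3, 3,
                 byrow = TRUE)
    Ry <- matrix(c(cos(b), 0, sin(b), 0, 1, 0, -sin(b), 0, cos(b)), 3, 3,
                 byrow = TRUE)
    Rz2 <- matrix(c(cos(c), -sin(c), 0, sin(c), cos(c), 0, 0, 0, 1), 3, 3,
                  byrow = TRUE)
    Rz %*% Ry %*% Rz2
  }
  obj <- function(ang) {
    R <- rot(ang[1], ang[2], ang[3])
    sqrt(mean(rowSums((Pc %*% t(R) - Qc)^2)))
  }
  best <- NULL; best_val <- Inf
  step <- step_deg * pi / 180
  for (a in seq(0, 2 * pi - step / 2, by = step))
    for (b in seq(0, pi, by = step))
      for (c in seq(0, 2 * pi - step / 2, by = step)) {
        v <- obj(c(a, b, c))
        if (v < best_val) { best_val <- v; best <- c(a, b, c) }
      }
  ref <- optim(best, obj, method = "Nelder-Mead",
               control = list(reltol = 1e-12, maxit = 5000))
  min(best_val, ref$value)
}
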