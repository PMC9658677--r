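VDW_RADII <- c(C = 1.70, N = 1.55, O = 1.52, S = 1.80)
VDW_DEFAULT <- 1.70

BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

# aromatic ring heavy atoms per residue type (W: both rings)
RING_ATOMS <- list(
  Y = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  F = c("CG", "CD1", "CD2", "CE1", "CE2", "CZ"),
  H = c("CG", "ND1", "CD2", "CE1", "NE2"),
  W = c("CG", "CD1", "CD2", "NE1", "CE2", "CE3", "CZ2", "CZ3", "CH2")
)

# theoretical maximum accessible surface areas (Tien et al. 2013), A^2
MAX_ASA <- c(A = 129, R = 274, N = 195, D = 193, C = 167, Q = 225, E = 223,
             G = 104, H = 224, I = 197, L = 201, K = 236, M = 224, F = 240,
             P = 159, S = 155, T = 172, W = 285, Y = 263, V = 174)

atom_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

element_from_name <- function(elety) {
  e <- toupper(gsub("[^A-Za-z].*$", "", gsub("^[0-9]+", "", elety)))
  substr(e, 1L, 1L)
}

#' Protein structure container
#'
#' A `prot3d` object is a flat atom table: one row per heavy atom with chain,
#' residue number (plus insertion code), residue type (1-letter), atom name,
#' element and coordinates in Angstrom. Only polymer (`ATOM`) records of the
#' first model are kept; waters, heteroatoms and hydrogens are excluded and
#' alternate locations are resolved to the highest occupancy.
#'
#' @param atoms A data.frame with columns `chain`, `resno`, `insert`, `aa`,
#'   `elety`, `elesy`, `x`, `y`, `z` (and optionally `o`, `b`).
#' @param id Structure identifier.
#' @return An object of class `prot3d`.
#' @export
prot3d <- function(atoms, id = "structure") {
  need <- c("chain", "resno", "insert", "aa", "elety", "elesy", "x", "y", "z")
  miss <- setdiff(need, names(atoms))
  if (length(miss)) stop("atom table lacks columns: ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!nrow(atoms)) stop("empty-structure error: no protein atoms",
                         call. = FALSE)
  if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
    stop("non-finite atom coordinates", call. = FALSE)
  if (is.null(atoms$o)) atoms$o <- 1
  if (is.null(atoms$b)) atoms$b <- 0
  atoms$insert <- ifelse(is.na(atoms$insert) | atoms$insert == "",
                         "", as.character(atoms$insert))
  rownames(atoms) <- NULL
  structure(list(id = id, atoms = atoms), class = "prot3d")
}

#' @export
print.prot3d <- function(x, ...) {
  rs <- residues(x)
  cat("prot3d '", x$id, "': ", nrow(x$atoms), " atoms, ", nrow(rs),
      " residues, chains ", paste(unique(rs$chain), collapse = ","),
      "\n", sep = "")
  invisible(x)
}

#' Residue table of a structure
#'
#' @param s A [prot3d] object.
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `aa`, in atom-record order.
#' @export
residues <- function(s) {
  stopifnot(inherits(s, "prot3d"))
  a <- s$atoms
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  first <- !duplicated(key)
  data.frame(chain = a$chain[first], resno = a$resno[first],
             insert = a$insert[first], aa = a$aa[first],
             stringsAsFactors = FALSE)
}

#' Read a protein structure (PDB or mmCIF)
#'
#' Parses with bio3d; keeps model 1 polymer heavy atoms, drops waters,
#' heteroatoms and hydrogens, and resolves alternate locations to the
#' highest-occupancy copy.
#'
#' @param path Path to the structure file.
#' @param format `"pdb"` or `"mmcif"`.
#' @param chain Optional chain id(s) to keep.
#' @return A [prot3d] object.
#' @export
read_structure <- function(path, format = c("pdb", "mmcif"), chain = NULL) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("structure file not found: ", path,
                               call. = FALSE)
  pdb <- if (format == "pdb") {
    suppressWarnings(bio3d::read.pdb(path, multi = FALSE, rm.alt = FALSE))
  } else {
    suppressWarnings(bio3d::read.cif(path, multi = FALSE, rm.alt = FALSE))
  }
  a <- pdb$atom
  a <- a[a$type == "ATOM", , drop = FALSE]
  if (!is.null(chain)) a <- a[a$chain %in% chain, , drop = FALSE]
  if (!nrow(a)) stop("empty-structure error: no protein atoms in ", path,
                     call. = FALSE)
  elesy <- a$elesy
  if (is.null(elesy) || all(is.na(elesy)) || all(elesy == ""))
    elesy <- element_from_name(a$elety)
  elesy[is.na(elesy) | elesy == ""] <- element_from_name(
    a$elety[is.na(elesy) | elesy == ""])
  a$elesy <- toupper(trimws(elesy))
  a <- a[a$elesy != "H" & a$elesy != "D", , drop = FALSE]
  # resolve altlocs: highest occupancy per (chain, resno, insert, atom name)
  o <- a$o
  o[is.na(o)] <- 1
  key <- paste(a$chain, a$resno, a$insert, a$elety, sep = "|")
  ord <- order(key, -o)
  a <- a[ord, , drop = FALSE]
  a <- a[!duplicated(key[ord]), , drop = FALSE]
  a <- a[order(match(a$chain, unique(a$chain)), a$resno, a$insert), ,
         drop = FALSE]
  aa1 <- suppressWarnings(bio3d::aa321(a$resid))
  aa1[is.na(aa1) | !(aa1 %in% AA_STANDARD)] <- "X"
  atoms <- data.frame(chain = as.character(a$chain), resno = a$resno,
                      insert = a$insert, aa = aa1, elety = a$elety,
                      elesy = a$elesy, x = a$x, y = a$y, z = a$z,
                      o = o[ord][!duplicated(key[ord])] , b = a$b,
                      stringsAsFactors = FALSE)
  prot3d(atoms, id = tools::file_path_sans_ext(basename(path)))
}

#' Write a structure as PDB
#'
#' The B-factor column can carry an arbitrary per-residue value — typically
#' the conservation grade, giving a grade-colored PDB for molecular viewers.
#'
#' @param s A [prot3d] object.
#' @param path Output path.
#' @param b_residue Optional named numeric vector of per-residue B values,
#'   names being residue numbers (`resno`), applied to every atom of the
#'   residue; unnamed residues keep their stored B.
#' @return `path`, invisibly.
#' @export
write_structure <- function(s, path, b_residue = NULL) {
  stopifnot(inherits(s, "prot3d"))
  a <- s$atoms
  b <- a$b
  if (!is.null(b_residue)) {
    idx <- match(as.character(a$resno), names(b_residue))
    b[!is.na(idx)] <- b_residue[idx[!is.na(idx)]]
  }
  aa3 <- names(bio3d::aa.table$aa1)
  map3 <- setNames(rownames(bio3d::aa.table), bio3d::aa.table$aa1)
  resid3 <- unname(map3[a$aa])
  resid3[is.na(resid3)] <- "UNK"
  bio3d::write.pdb(file = path,
                   xyz = as.numeric(t(as.matrix(a[, c("x", "y", "z")]))),
                   resno = a$resno, chain = a$chain, resid = resid3,
                   elety = a$elety, eleno = seq_len(nrow(a)),
                   o = a$o, b = b)
  invisible(path)
}

# atom rows of one residue; res = resno or list(chain=, resno=, insert=)
residue_atoms <- function(s, res, chain = NULL) {
  a <- s$atoms
  if (is.list(res)) {
    chain <- res$chain %||% chain
    insert <- res$insert %||% ""
    resno <- res$resno
  } else {
    resno <- res
    insert <- ""
  }
  if (is.null(chain)) chain <- a$chain[1]
  rows <- a[a$chain == chain & a$resno == resno & a$insert == insert, ,
            drop = FALSE]
  if (!nrow(rows))
    stop("mapping error: residue ", chain, ":", resno, " not in structure",
         call. = FALSE)
  rows
}

residue_point <- function(rows, mode) {
  xyz <- as.matrix(rows[, c("x", "y", "z")])
  aa <- rows$aa[1]
  switch(mode,
    ca = {
      i <- which(rows$elety == "CA")
      if (!length(i))
        stop("incomplete-residue error: no CA atom for mode 'ca'",
             call. = FALSE)
      xyz[i[1], ]
    },
    sidechain_centroid = {
      i <- which(!(rows$elety %in% BACKBONE_ATOMS))
      if (!length(i)) i <- which(rows$elety == "CA")  # glycine fallback
      if (!length(i))
        stop("incomplete-residue error: no atoms for mode ",
             "'sidechain_centroid'", call. = FALSE)
      colMeans(xyz[i, , drop = FALSE])
    },
    ring_centroid = {
      ring <- RING_ATOMS[[aa]]
      if (is.null(ring))
        stop("incomplete-residue error: mode 'ring_centroid' requires ",
             "F/Y/W/H, got ", aa, call. = FALSE)
      i <- which(rows$elety %in% ring)
      if (length(i) < length(ring))
        stop("incomplete-residue error: missing ring atoms for mode ",
             "'ring_centroid' in ", aa, rows$resno[1], call. = FALSE)
      colMeans(xyz[i, , drop = FALSE])
    },
    stop("unknown distance mode: ", mode, call. = FALSE)
  )
}

#' Distance between two residues
#'
#' @param s A [prot3d] object.
#' @param r1,r2 Residue selectors: a residue number (first chain assumed) or
#'   `list(chain =, resno =, insert =)`.
#' @param mode `"ca"` (alpha carbons), `"sidechain_centroid"` (mean of
#'   side-chain heavy atoms, CA for glycine), `"min_atom"` (closest heavy
#'   atom pair), or `"ring_centroid"` (mean of the aromatic ring atoms;
#'   F/Y/W/H only).
#' @param chain Default chain for bare residue numbers.
#' @return Distance in Angstrom (symmetric, non-negative).
#' @export
residue_distance <- function(s, r1, r2,
                             mode = c("ca", "sidechain_centroid",
                                      "min_atom", "ring_centroid"),
                             chain = NULL) {
  mode <- match.arg(mode)
  a1 <- residue_atoms(s, r1, chain)
  a2 <- residue_atoms(s, r2, chain)
  if (mode == "min_atom") {
    x1 <- as.matrix(a1[, c("x", "y", "z")])
    x2 <- as.matrix(a2[, c("x", "y", "z")])
    d2 <- outer(rowSums(x1^2), rowSums(x2^2), "+") - 2 * x1 %*% t(x2)
    return(sqrt(max(min(d2), 0)))
  }
  p1 <- residue_point(a1, mode)
  p2 <- residue_point(a2, mode)
  sqrt(sum((p1 - p2)^2))
}

# near-uniform points on the unit sphere (golden-spiral construction)
sphere_points <- function(n) {
  i <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * i / n)
  theta <- pi * (1 + sqrt(5)) * i
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}

#' Relative solvent accessibility (Shrake-Rupley)
#'
#' Accessible surface area with a rolling probe, computed by testing points
#' on each atom's expanded sphere against all neighboring atoms, summed per
#' residue and divided by the residue-type theoretical maximum (Tien et al.
#' 2013). Values can slightly exceed 1 for very exposed termini.
#'
#' @param s A [prot3d] object.
#' @param probe Probe radius in Angstrom (water: 1.4).
#' @param n_points Sphere test points per atom (>= 960 recommended).
#' @return data.frame with one row per residue: `chain`, `resno`, `insert`,
#'   `aa`, `asa` (A^2) and `rsa`.
#' @export
relative_accessibility <- function(s, probe = 1.4, n_points = 960L) {
  stopifnot(inherits(s, "prot3d"))
  a <- s$atoms
  xyz <- as.matrix(a[, c("x", "y", "z")])
  r <- atom_radius(a$elesy) + probe
  n <- nrow(xyz)
  pts <- sphere_points(n_points)
  # neighbor lists from the pairwise cutoff r_i + r_j
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * xyz %*% t(xyz)
  asa_atom <- numeric(n)
  for (i in seq_len(n)) {
    cut2 <- (r[i] + r)^2
    nb <- which(d2[i, ] < cut2 & seq_len(n) != i)
    if (!length(nb)) {
      asa_atom[i] <- 4 * pi * r[i]^2
      next
    }
    p <- sweep(pts * r[i], 2, xyz[i, ], "+")     # n_points x 3
    free <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(free)) break
      dj2 <- (p[free, 1] - xyz[j, 1])^2 + (p[free, 2] - xyz[j, 2])^2 +
             (p[free, 3] - xyz[j, 3])^2
      free[free] <- dj2 > r[j]^2
    }
    asa_atom[i] <- 4 * pi * r[i]^2 * sum(free) / n_points
  }
  key <- paste(a$chain, a$resno, a$insert, sep = "|")
  res <- residues(s)
  res_key <- paste(res$chain, res$resno, res$insert, sep = "|")
  res$asa <- as.numeric(tapply(asa_atom, factor(key, levels = res_key), sum))
  max_asa <- MAX_ASA[res$aa]
  if (any(is.na(max_asa))) {
    warning("unknown residue type(s) ",
            paste(unique(res$aa[is.na(max_asa)]), collapse = ", "),
            ": using the glycine maximum ASA")
    max_asa[is.na(max_asa)] <- MAX_ASA["G"]
  }
  res$rsa <- res$asa / unname(max_asa)
  res
}

#' Optimal rigid-body superposition (Kabsch)
#'
#' Least-squares superposition of paired coordinate sets via singular value
#' decomposition, constrained to a proper rotation (determinant +1).
#'
#' @param mobile,reference n x 3 coordinate matrices of paired points
#'   (n >= 3, not collinear).
#' @return List of class `superposition`: `rotation` (3 x 3, det +1),
#'   `translation` (length 3; transformed = mobile %*% t(rotation) +
#'   translation), and `rmsd` in Angstrom, the global minimum over rigid
#'   transforms.
#' @export
kabsch_superpose <- function(mobile, reference) {
  P <- as.matrix(mobile)
  Q <- as.matrix(reference)
  if (ncol(P) != 3L || ncol(Q) != 3L || nrow(P) != nrow(Q))
    stop("mobile and reference must be paired n x 3 matrices", call. = FALSE)
  if (nrow(P) < 3L)
    stop("degenerate-superposition error: need at least 3 paired points",
         call. = FALSE)
  cp <- colMeans(P); cq <- colMeans(Q)
  Pc <- sweep(P, 2, cp); Qc <- sweep(Q, 2, cq)
  if (svd(Pc)$d[2] < 1e-8 || svd(Qc)$d[2] < 1e-8)
    stop("degenerate-superposition error: points are collinear",
         call. = FALSE)
  H <- t(Pc) %*% Qc
  sv <- svd(H)
  d <- sign(det(sv$v %*% t(sv$u)))
  R <- sv$v %*% diag(c(1, 1, d)) %*% t(sv$u)
  moved <- Pc %*% t(R)
  rmsd <- sqrt(mean(rowSums((moved - Qc)^2)))
  structure(list(rotation = R, translation = as.numeric(cq - R %*% cp),
                 rmsd = rmsd),
            class = "superposition")
}

#' @export
print.superposition <- function(x, ...) {
  cat(sprintf("superposition: rmsd %.4f A\n", x$rmsd))
  invisible(x)
}
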