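#' Select maximally conserved residues
#'
#' Positions with a reliable score in the top grade(s), excluding residue
#' types that are conserved for folding rather than function (glycine and
#' proline by default, which enable turns and break helices).
#'
#' @param profile A [conservation_profile()] with mapped reference positions.
#' @param grade_min Minimum grade to keep (default 9, the top grade).
#' @param exclude_aa Residue letters to drop (default G and P); use
#'   `character(0)` to keep everything.
#' @return Sorted integer vector of reference positions (possibly empty).
#' @export
select_conserved <- function(profile, grade_min = 9L,
                             exclude_aa = c("G", "P")) {
  stopifnot(inherits(profile, "conservation_profile"))
  if (all(is.na(profile$ref_pos)))
    stop("profile has no mapped reference positions; supply a mapping to ",
         "conservation_profile()", call. = FALSE)
  keep <- profile$reliable & !is.na(profile$grade) &
    profile$grade >= grade_min & !is.na(profile$ref_pos) &
    !(profile$ref_aa %in% exclude_aa)
  sort(profile$ref_pos[keep])
}

#' Spatial clusters of conserved residues
#'
#' Single-linkage connected components of the graph whose edges join
#' residue pairs at distance <= `cutoff` on the structure. Reproduces the
#' grouping of maximally conserved residues into spatial conservation
#' clusters (including singletons such as an isolated conserved glutamate).
#'
#' @param positions Integer vector of residue numbers (reference numbering
#'   must match the structure's `resno`).
#' @param s A [prot3d] object.
#' @param cutoff Linkage distance in Angstrom (default 8).
#' @param mode Distance mode (see [residue_distance()]); side-chain
#'   centroids by default.
#' @param chain Chain to use (first chain when NULL).
#' @return List of `conservation_cluster` objects ordered by smallest
#'   member, each with `members` (sorted positions), `singleton`,
#'   `orientation` (NA until [classify_orientation()]), `mean_rsa`.
#' @export
spatial_clusters <- function(positions, s, cutoff = 8,
                             mode = "sidechain_centroid", chain = NULL) {
  stopifnot(inherits(s, "prot3d"))
  positions <- sort(unique(as.integer(positions)))
  if (!length(positions)) return(list())
  if (is.null(chain)) chain <- s$atoms$chain[1]
  present <- residues(s)
  present <- present$resno[present$chain == chain]
  missing <- setdiff(positions, present)
  if (length(missing))
    stop("mapping error: positions absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  n <- length(positions)
  pts <- lapply(positions, function(p)
    residue_point(residue_atoms(s, p, chain), mode))
  edges <- matrix(integer(0), ncol = 2)
  dmat <- matrix(0, n, n)
  if (n > 1) {
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      if (mode == "min_atom") {
        d <- residue_distance(s, positions[i], positions[j],
                              mode = "min_atom", chain = chain)
      } else {
        d <- sqrt(sum((pts[[i]] - pts[[j]])^2))
      }
      dmat[i, j] <- dmat[j, i] <- d
      if (d <= cutoff) edges <- rbind(edges, c(i, j))
    }
  }
  g <- igraph::make_empty_graph(n, directed = FALSE)
  if (nrow(edges)) g <- igraph::add_edges(g, t(edges))
  comp <- igraph::components(g)$membership
  clusters <- lapply(unique(comp), function(k) {
    mem <- sort(positions[comp == k])
    structure(list(members = mem, singleton = length(mem) == 1L,
                   orientation = NA_character_, mean_rsa = NA_real_),
              class = "conservation_cluster")
  })
  ord <- order(vapply(clusters, function(cl) min(cl$members), 0L))
  clusters[ord]
}

#' @export
print.conservation_cluster <- function(x, ...) {
  cat("conservation_cluster: {", paste(x$members, collapse = ", "), "}",
      if (!is.na(x$orientation)) paste0(" [", x$orientation, "]"), "\n",
      sep = "")
  invisible(x)
}

#' Classify a cluster as buried, exposed or mixed
#'
#' Mean relative solvent accessibility of the members against two
#' thresholds; both boundaries are inclusive toward their class.
#'
#' @param cluster A `conservation_cluster`.
#' @param rsa Either the data.frame from [relative_accessibility()] or a
#'   numeric vector named by residue number.
#' @param buried_max Mean RSA at or below which the cluster is buried
#'   (oriented to the hydrophobic core).
#' @param exposed_min Mean RSA at or above which it is exposed (oriented to
#'   the protein exterior).
#' @return The cluster with `orientation` and `mean_rsa` filled in.
#' @export
classify_orientation <- function(cluster, rsa, buried_max = 0.2,
                                 exposed_min = 0.35) {
  stopifnot(inherits(cluster, "conservation_cluster"))
  if (is.data.frame(rsa)) rsa <- setNames(rsa$rsa, rsa$resno)
  vals <- rsa[as.character(cluster$members)]
  if (any(is.na(vals)))
    stop("incomplete-input error: RSA missing for positions ",
         paste(cluster$members[is.na(vals)], collapse = ", "), call. = FALSE)
  m <- mean(vals)
  cluster$mean_rsa <- m
  cluster$orientation <- if (m <= buried_max) "buried"
                         else if (m >= exposed_min) "exposed"
                         else "mixed"
  cluster
}

#' Tabulate clusters as a data.frame
#'
#' @param clusters List of `conservation_cluster` objects.
#' @return data.frame with `cluster`, `members`, `n`, `orientation`,
#'   `mean_rsa`.
#' @export
cluster_report <- function(clusters) {
  if (!length(clusters))
    return(data.frame(cluster = integer(0), members = character(0),
                      n = integer(0), orientation = character(0),
                      mean_rsa = numeric(0)))
  data.frame(
    cluster = seq_along(clusters),
    members = vapply(clusters, function(cl)
      paste(cl$members, collapse = ","), ""),
    n = vapply(clusters, function(cl) length(cl$members), 0L),
    orientation = vapply(clusters, function(cl)
      cl$orientation %||% NA_character_, ""),
    mean_rsa = vapply(clusters, function(cl) cl$mean_rsa, 0),
    stringsAsFactors = FALSE)
}
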