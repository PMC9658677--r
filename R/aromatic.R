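#' Aromatic (redox-active) residue composition of a sequence
#'
#' Counts the tyrosines and tryptophans (by default) of a sequence and
#' reports their combined frequency as a percentage rounded to one decimal —
#' the enrichment statistic compared against the ~4.5% eukaryotic average.
#'
#' @param sequence Character vector of residue letters, or a single string.
#' @param aromatic_set Letters counted (default Y and W, the redox-active
#'   pair; F/H can be added but are excluded from the headline statistic by
#'   convention).
#' @return List with `counts` (named per letter), `n` (sequence length) and
#'   `frequency_pct` (percent, one decimal, round-half-up).
#' @export
#' @examples
#' aromatic_composition("YWYW")$frequency_pct   # 100
aromatic_composition <- function(sequence, aromatic_set = c("Y", "W")) {
  if (length(sequence) == 1L && nchar(sequence) > 1L)
    sequence <- strsplit(sequence, "")[[1]]
  sequence <- toupper(sequence)
  sequence <- sequence[sequence != GAP]
  if (!length(sequence)) stop("empty sequence", call. = FALSE)
  counts <- vapply(aromatic_set, function(a) sum(sequence == a), 0L)
  freq <- 100 * sum(counts) / length(sequence)
  list(counts = counts, n = length(sequence),
       frequency_pct = floor(freq * 10 + 0.5) / 10)
}

#' Electron-transfer distance network of aromatic residues
#'
#' Nodes are the structure's Tyr/Trp residues (configurable); edges join
#' pairs whose ring-centroid distance is at most `cutoff` — close enough
#' for electron (radical) hopping. Designated site residues (e.g. putative
#' iron-binding positions such as an acidic-ridge glutamate or D167) are
#' attached as extra nodes with aromatic-to-site edges measured by closest
#' heavy atoms.
#'
#' @param s A [prot3d] object.
#' @param cutoff Edge distance threshold in Angstrom. Default 10.5 so pairs
#'   described as "~10 A" connect; use 10.0 for a strict "less than 10 A"
#'   reading.
#' @param mode Distance mode for aromatic-aromatic edges.
#' @param aromatic_set Residue letters treated as network nodes.
#' @param site_positions Integer residue numbers of target sites.
#' @param chain Chain to use (first chain when NULL).
#' @return Object of class `transfer_network`: an igraph graph (`graph`)
#'   with vertex attributes `pos`, `aa`, `type` ("aromatic"/"site") and
#'   edge attribute `distance`, plus the parameters used.
#' @export
build_transfer_network <- function(s, cutoff = 10.5, mode = "ring_centroid",
                                   aromatic_set = c("Y", "W"),
                                   site_positions = integer(0),
                                   chain = NULL) {
  stopifnot(inherits(s, "prot3d"))
  if (is.null(chain)) chain <- s$atoms$chain[1]
  res <- residues(s)
  res <- res[res$chain == chain, , drop = FALSE]
  arom <- res[res$aa %in% aromatic_set, , drop = FALSE]
  site_positions <- sort(unique(as.integer(site_positions)))
  missing <- setdiff(site_positions, res$resno)
  if (length(missing))
    stop("mapping error: site positions absent from structure: ",
         paste(missing, collapse = ", "), call. = FALSE)
  nodes <- data.frame(
    pos = c(arom$resno, site_positions),
    aa = c(arom$aa, res$aa[match(site_positions, res$resno)]),
    type = c(rep("aromatic", nrow(arom)),
             rep("site", length(site_positions))),
    stringsAsFactors = FALSE)
  # a residue that is both aromatic and a designated site stays one node
  dup <- duplicated(nodes$pos)
  nodes <- nodes[!dup, , drop = FALSE]
  nodes$type[nodes$pos %in% site_positions & nodes$aa %in% aromatic_set] <-
    "aromatic"
  nodes$is_site <- nodes$pos %in% site_positions
  g <- igraph::make_empty_graph(nrow(nodes), directed = FALSE)
  igraph::V(g)$name <- as.character(nodes$pos)
  igraph::V(g)$pos <- nodes$pos
  igraph::V(g)$aa <- nodes$aa
  igraph::V(g)$type <- nodes$type
  igraph::V(g)$is_site <- nodes$is_site
  n <- nrow(nodes)
  if (n > 1) {
    ep <- integer(0)
    ed <- numeric(0)
    for (i in seq_len(n - 1)) for (j in (i + 1):n) {
      ti <- nodes$type[i]; tj <- nodes$type[j]
      if (ti == "site" && tj == "site") next
      m <- if (ti == "aromatic" && tj == "aromatic") mode else "min_atom"
      d <- residue_distance(s, nodes$pos[i], nodes$pos[j], mode = m,
                            chain = chain)
      if (d <= cutoff) {
        ep <- c(ep, i, j)
        ed <- c(ed, d)
      }
    }
    if (length(ep)) g <- igraph::add_edges(g, ep, distance = ed)
  }
  structure(list(graph = g, cutoff = cutoff, mode = mode,
                 aromatic_set = aromatic_set,
                 site_positions = site_positions),
            class = "transfer_network")
}

#' @export
print.transfer_network <- function(x, ...) {
  cat("transfer_network: ", igraph::vcount(x$graph), " nodes, ",
      igraph::ecount(x$graph), " edges (cutoff ", x$cutoff, " A, ",
      x$mode, ")\n", sep = "")
  invisible(x)
}

#' Shortest electron-transfer path
#'
#' Shortest path by hop count from a source residue to any of a set of
#' targets; ties are broken by the smaller total distance. A source that is
#' itself a target is reachable in 0 hops.
#'
#' @param net A [build_transfer_network()] result.
#' @param source Source residue number (must be a network node).
#' @param targets Integer vector of target residue numbers.
#' @return List: `reachable`, `path` (residue numbers, empty when
#'   unreachable), `hop_count`, `max_edge_length` (A; NA for 0 hops).
#' @export
transfer_path <- function(net, source, targets) {
  stopifnot(inherits(net, "transfer_network"))
  g <- net$graph
  nodes <- igraph::V(g)$pos
  if (!(source %in% nodes))
    stop("lookup error: source not in network: ", source, call. = FALSE)
  targets <- intersect(as.integer(targets), nodes)
  if (!length(targets))
    return(list(reachable = FALSE, path = integer(0), hop_count = NA_integer_,
                max_edge_length = NA_real_))
  if (source %in% targets)
    return(list(reachable = TRUE, path = source, hop_count = 0L,
                max_edge_length = NA_real_))
  best <- NULL
  for (t in targets) {
    sp <- suppressWarnings(igraph::all_shortest_paths(
      g, from = as.character(source), to = as.character(t)))$vpaths
    for (p in sp) {
      if (length(p) < 2) next
      eids <- igraph::get_edge_ids(g, rep(as.integer(p),
                                          c(1, rep(2, length(p) - 2), 1)))
      dists <- igraph::E(g)$distance[eids]
      cand <- list(path = nodes[as.integer(p)], hops = length(p) - 1L,
                   total = sum(dists), maxd = max(dists))
      if (is.null(best) || cand$hops < best$hops ||
          (cand$hops == best$hops && cand$total < best$total))
        best <- cand
    }
  }
  if (is.null(best))
    return(list(reachable = FALSE, path = integer(0), hop_count = NA_integer_,
                max_edge_length = NA_real_))
  list(reachable = TRUE, path = best$path, hop_count = best$hops,
       max_edge_length = best$maxd)
}

#' Edge list of a transfer network
#'
#' @param net A [build_transfer_network()] result.
#' @return data.frame with `source`, `target` (residue numbers) and
#'   `distance` (A).
#' @export
network_edges <- function(net) {
  stopifnot(inherits(net, "transfer_network"))
  g <- net$graph
  if (!igraph::ecount(g))
    return(data.frame(source = integer(0), target = integer(0),
                      distance = numeric(0)))
  el <- igraph::as_edgelist(g, names = FALSE)
  pos <- igraph::V(g)$pos
  data.frame(source = pos[el[, 1]], target = pos[el[, 2]],
             distance = igraph::E(g)$distance)
}
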