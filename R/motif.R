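#' Residue-motif specification
#'
#' An ordered set of reference positions with the expected (consensus)
#' residue at each — e.g. the frataxin cluster-3 tetrad Y143/S158/S161/E189.
#'
#' @param positions Strictly increasing integer reference positions.
#' @param consensus Character vector of expected residue letters, one per
#'   position.
#' @return An object of class `motif_spec`.
#' @export
#' @examples
#' motif_spec(c(143, 158, 161, 189), c("Y", "S", "S", "E"))
motif_spec <- function(positions, consensus) {
  positions <- as.integer(positions)
  consensus <- toupper(as.character(consensus))
  if (length(positions) != length(consensus))
    stop("positions and consensus must have equal length", call. = FALSE)
  if (length(positions) && any(diff(positions) <= 0))
    stop("positions must be strictly increasing", call. = FALSE)
  if (!all(consensus %in% AA_STANDARD))
    stop("consensus letters must be standard amino acids", call. = FALSE)
  structure(list(positions = positions, consensus = consensus),
            class = "motif_spec")
}

#' Tabulate a motif across every sequence of an alignment
#'
#' For each record, the observed letter at each motif position (read through
#' the reference mapping) and a presence flag: present means exact identity
#' with the consensus letter. A gap in a sequence at a motif position is
#' recorded as `-` and counts as absent. With
#' `conservative = TRUE`, substitutions within the same exchange group
#' (e.g. S/T, D/E, Y/F/W) also count as present.
#'
#' @param aln An [msa] object.
#' @param mapping A [map_to_reference()] result.
#' @param spec A [motif_spec()].
#' @param conservative Accept conservative substitutions as present
#'   (default FALSE: exact match only).
#' @return data.frame of class `motif_table`: one row per record with `id`,
#'   `taxon_group`, then `obs_<pos>` and `present_<pos>` per position.
#' @export
motif_table <- function(aln, mapping, spec, conservative = FALSE) {
  stopifnot(inherits(aln, "msa"), inherits(mapping, "residue_mapping"),
            inherits(spec, "motif_spec"))
  cols <- ref_col(mapping, spec$positions)
  out <- data.frame(id = aln$ids, taxon_group = aln$taxon_group,
                    stringsAsFactors = FALSE)
  groups <- list(c("S", "T"), c("D", "E"), c("K", "R"), c("Y", "F", "W"),
                 c("I", "L", "V", "M"), c("N", "Q"))
  is_present <- function(obs, cons) {
    if (obs == cons) return(TRUE)
    if (!conservative) return(FALSE)
    any(vapply(groups, function(g) all(c(obs, cons) %in% g), TRUE))
  }
  for (k in seq_along(spec$positions)) {
    obs <- aln_column(aln, cols[k])
    out[[paste0("obs_", spec$positions[k])]] <- obs
    out[[paste0("present_", spec$positions[k])]] <-
      vapply(obs, is_present, TRUE, cons = spec$consensus[k])
  }
  class(out) <- c("motif_table", "data.frame")
  attr(out, "positions") <- spec$positions
  attr(out, "consensus") <- spec$consensus
  out
}

#' Presence/absence matrix of a motif table
#'
#' @param table A [motif_table()] result.
#' @return Logical matrix, rows = sequences, columns = motif positions.
#' @export
motif_presence_matrix <- function(table) {
  pos <- attr(table, "positions")
  if (!length(pos))
    return(matrix(logical(0), nrow = nrow(table), ncol = 0))
  m <- as.matrix(as.data.frame(table)[, paste0("present_", pos),
                                      drop = FALSE])
  rownames(m) <- table$id
  colnames(m) <- pos
  m
}

#' Number of motif positions present in one sequence
#'
#' @param table A [motif_table()] result.
#' @param seq_id Record identifier.
#' @return Integer count in 0..n_positions.
#' @export
presence_count <- function(table, seq_id) {
  stopifnot(inherits(table, "motif_table"))
  i <- match(seq_id, table$id)
  if (is.na(i)) stop("lookup error: unknown sequence id: ", seq_id,
                     call. = FALSE)
  sum(motif_presence_matrix(table)[i, ])
}

#' Co-occurrence of two motif positions
#'
#' 2x2 presence counts over the (optionally filtered) rows — the analysis
#' behind statements like "one or two of these amino acids, but never Y143
#' and E189 simultaneously".
#'
#' @param table A [motif_table()] result.
#' @param posA,posB Two reference positions from the motif.
#' @param group_filter Optional: character vector of taxon groups to keep,
#'   or a predicate function over group labels.
#' @return Named integer vector: `both`, `A_only`, `B_only`, `neither`
#'   (summing to the number of filtered rows).
#' @export
cooccurrence <- function(table, posA, posB, group_filter = NULL) {
  stopifnot(inherits(table, "motif_table"))
  pos <- attr(table, "positions")
  if (!all(c(posA, posB) %in% pos))
    stop("spec error: positions not in motif: ",
         paste(setdiff(c(posA, posB), pos), collapse = ", "), call. = FALSE)
  keep <- rep(TRUE, nrow(table))
  if (!is.null(group_filter)) {
    keep <- if (is.function(group_filter)) {
      vapply(table$taxon_group, function(g) isTRUE(group_filter(g)), TRUE)
    } else {
      table$taxon_group %in% group_filter
    }
  }
  m <- motif_presence_matrix(table)[keep, , drop = FALSE]
  a <- m[, as.character(posA)]
  b <- m[, as.character(posB)]
  c(both = sum(a & b), A_only = sum(a & !b), B_only = sum(!a & b),
    neither = sum(!a & !b))
}

#' Per-taxon-group motif summary
#'
#' @param table A [motif_table()] result with taxon groups assigned for
#'   every row.
#' @return data.frame per group (in order of first appearance):
#'   `taxon_group`, `n_sequences`, `n_with_full_motif`, then
#'   `present_<pos>` counts.
#' @export
group_summary <- function(table) {
  stopifnot(inherits(table, "motif_table"))
  if (any(is.na(table$taxon_group)))
    stop("taxon_group must be assigned for every row", call. = FALSE)
  pos <- attr(table, "positions")
  m <- motif_presence_matrix(table)
  groups <- unique(table$taxon_group)
  res <- lapply(groups, function(g) {
    rows <- table$taxon_group == g
    mg <- m[rows, , drop = FALSE]
    out <- data.frame(taxon_group = g, n_sequences = sum(rows),
                      n_with_full_motif =
                        if (ncol(mg)) sum(rowSums(mg) == ncol(mg))
                        else sum(rows),
                      stringsAsFactors = FALSE)
    for (p in pos) out[[paste0("present_", p)]] <- sum(mg[, as.character(p)])
    out
  })
  do.call(rbind, res)
}

#' Write a motif table as TSV
#'
#' Layout mirrors the published presence table: "yes" where the consensus
#' residue is present, otherwise the observed letter (or `-` at a gap).
#'
#' @param table A [motif_table()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_motif_tsv <- function(table, path) {
  pos <- attr(table, "positions")
  out <- data.frame(sequence = table$id, stringsAsFactors = FALSE)
  for (p in pos) {
    obs <- table[[paste0("obs_", p)]]
    pres <- table[[paste0("present_", p)]]
    out[[as.character(p)]] <- ifelse(pres, "yes", obs)
  }
  out$taxon_group <- table$taxon_group
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
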