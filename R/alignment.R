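#' Multiple sequence alignments and reference numbering
#'
#' An `msa` object holds an ordered set of identically long gapped amino-acid
#' sequences with unique identifiers and an optional taxon-group label per
#' record (e.g. "eukaryote" / "rickettsia" / "bacteria"). Gap characters are
#' normalized to `-`, letters are upper-cased; the ambiguity codes X/B/Z are
#' accepted but treated as missing data by the scoring functions.
#'
#' @param ids Character vector of unique record identifiers.
#' @param seqs Character vector of gapped sequences, all the same length.
#' @param taxon_group Optional character vector of group labels (NA allowed).
#' @return An object of class `msa` with elements `ids`, `seqs`,
#'   `taxon_group` and `length` (number of columns).
#' @export
#' @examples
#' msa(c("a", "b"), c("MK-Y", "MKAY"))
msa <- function(ids, seqs, taxon_group = NULL) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  seqs <- gsub(".", "-", seqs, fixed = TRUE)
  if (length(ids) != length(seqs))
    stop("ids and seqs must have equal length", call. = FALSE)
  if (length(seqs) == 0L)
    stop("alignment must contain at least one record", call. = FALSE)
  widths <- nchar(seqs)
  if (length(unique(widths)) != 1L)
    stop("alignment-shape error: rows have unequal lengths (",
         paste(unique(widths), collapse = ", "), ")", call. = FALSE)
  if (widths[1] < 1L)
    stop("alignment-shape error: zero-length sequences", call. = FALSE)
  if (anyDuplicated(ids))
    stop("identifier error: duplicate ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  ok <- c(AA_STANDARD, AA_AMBIGUOUS, GAP)
  letters_seen <- unique(strsplit(paste(seqs, collapse = ""), "")[[1]])
  bad <- setdiff(letters_seen, ok)
  if (length(bad))
    stop("alphabet error: unknown letters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (is.null(taxon_group)) taxon_group <- rep(NA_character_, length(ids))
  taxon_group <- as.character(taxon_group)
  if (length(taxon_group) != length(ids))
    stop("taxon_group must match the number of records", call. = FALSE)
  structure(list(ids = ids, seqs = seqs, taxon_group = taxon_group,
                 length = widths[1]),
            class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("msa: ", length(x$ids), " sequences x ", x$length, " columns\n",
      sep = "")
  n_grp <- sum(!is.na(x$taxon_group))
  if (n_grp) cat("  taxon groups assigned for", n_grp, "records\n")
  invisible(x)
}

#' @export
length.msa <- function(x) length(x$ids)

# character matrix view (records x columns), used internally by scoring
msa_matrix <- function(aln) {
  m <- do.call(rbind, strsplit(aln$seqs, ""))
  rownames(m) <- aln$ids
  m
}

#' Read a multiple sequence alignment
#'
#' Parses FASTA, Clustal or Stockholm alignments (via Biostrings). For FASTA
#' input the first whitespace-separated token of each header is the record id
#' and, when present, the second token is taken as the taxon-group label.
#'
#' @param path Path to the alignment file.
#' @param format One of `"fasta"`, `"clustal"`, `"stockholm"`.
#' @return An [msa] object; record order is preserved and gaps are
#'   normalized to `-`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal", "stockholm")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("alignment file not found: ", path,
                               call. = FALSE)
  raw <- Biostrings::readAAMultipleAlignment(path, format = format)
  seqs <- as.character(raw)
  headers <- names(seqs)
  if (is.null(headers)) headers <- paste0("seq", seq_along(seqs))
  toks <- strsplit(trimws(headers), "\\s+")
  ids <- vapply(toks, `[`, "", 1L)
  grp <- vapply(toks, function(t) if (length(t) >= 2L) t[2L] else NA_character_,
                "")
  if (format != "fasta") grp <- rep(NA_character_, length(ids))
  msa(ids, unname(seqs), taxon_group = grp)
}

#' Write an alignment to FASTA
#'
#' Taxon-group labels, when present, are appended to the header after the id
#' so that [read_alignment()] round-trips them.
#'
#' @param aln An [msa] object.
#' @param path Output file path.
#' @param width Line width for wrapped sequence lines.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path, width = 70L) {
  stopifnot(inherits(aln, "msa"))
  con <- file(path, "w")
  on.exit(close(con))
  for (i in seq_along(aln$ids)) {
    hdr <- aln$ids[i]
    if (!is.na(aln$taxon_group[i])) hdr <- paste(hdr, aln$taxon_group[i])
    writeLines(paste0(">", hdr), con)
    s <- aln$seqs[i]
    starts <- seq(1L, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, nchar(s))), con)
  }
  invisible(path)
}

#' Extract one alignment column
#'
#' @param aln An [msa] object.
#' @param col 1-based column index.
#' @return Character vector of one letter per record, in record order.
#' @export
aln_column <- function(aln, col) {
  stopifnot(inherits(aln, "msa"))
  col <- as.integer(col)
  if (length(col) != 1L || is.na(col) || col < 1L || col > aln$length)
    stop("bounds error: column ", col, " outside 1..", aln$length,
         call. = FALSE)
  substring(aln$seqs, col, col)
}

#' Map alignment columns to reference residue numbering
#'
#' Assigns consecutive reference numbers, starting at `start_number`, to the
#' non-gap columns of a chosen reference record. This expresses conventions
#' such as human mature frataxin (Fxn81-210) or the 3S4M chain A sequence
#' that begins at residue 82 without hard-coding either.
#'
#' @param aln An [msa] object.
#' @param ref_id Id of the reference record.
#' @param start_number Reference number given to its first non-gap residue.
#' @return An object of class `residue_mapping` with `ref_id`,
#'   `start_number`, `col_to_ref` (integer vector over columns, NA at
#'   reference gaps) and `ref_to_col` (named inverse).
#' @export
#' @examples
#' a <- msa(c("hs", "ec"), c("G-AV", "GTAV"))
#' map_to_reference(a, "hs", 82)$col_to_ref
map_to_reference <- function(aln, ref_id, start_number) {
  stopifnot(inherits(aln, "msa"))
  idx <- match(ref_id, aln$ids)
  if (is.na(idx))
    stop("lookup error: reference id not in alignment: ", ref_id,
         call. = FALSE)
  letters_ref <- strsplit(aln$seqs[idx], "")[[1]]
  nongap <- which(letters_ref != GAP)
  if (!length(nongap))
    stop("empty-reference error: reference sequence is all gaps",
         call. = FALSE)
  col_to_ref <- rep(NA_integer_, aln$length)
  refnums <- seq.int(start_number, length.out = length(nongap))
  col_to_ref[nongap] <- refnums
  ref_to_col <- setNames(nongap, refnums)
  structure(list(ref_id = ref_id, start_number = as.integer(start_number),
                 col_to_ref = col_to_ref, ref_to_col = ref_to_col,
                 ref_aa = setNames(letters_ref[nongap], refnums)),
            class = "residue_mapping")
}

#' @export
print.residue_mapping <- function(x, ...) {
  rng <- range(as.integer(names(x$ref_to_col)))
  cat("residue_mapping: ", x$ref_id, ", residues ", rng[1], "-", rng[2],
      " over ", length(x$col_to_ref), " columns\n", sep = "")
  invisible(x)
}

# column index for a reference position, with a clear error
ref_col <- function(mapping, pos) {
  cl <- mapping$ref_to_col[as.character(pos)]
  if (any(is.na(cl)))
    stop("mapping error: reference position(s) not mapped: ",
         paste(pos[is.na(cl)], collapse = ", "), call. = FALSE)
  unname(cl)
}
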