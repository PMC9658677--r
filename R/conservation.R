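#' Henikoff position-based sequence weights
#'
#' Compensates for uneven taxon sampling: in each column, each of the k
#' distinct standard letters receives weight 1/k, split equally among the
#' sequences carrying it. Gaps and ambiguity codes contribute nothing.
#' Per-sequence totals are normalized to sum to 1.
#'
#' @param aln An [msa] object.
#' @return Numeric vector of positive weights, one per record, summing to 1.
#' @export
#' @examples
#' sequence_weights(msa(c("a", "b", "c"), c("MKY", "MKY", "MKW")))
sequence_weights <- function(aln) {
  stopifnot(inherits(aln, "msa"))
  m <- msa_matrix(aln)
  n <- nrow(m)
  w <- numeric(n)
  informative <- FALSE
  for (j in seq_len(ncol(m))) {
    colj <- m[, j]
    keep <- colj %in% AA_STANDARD
    if (!any(keep)) next
    informative <- TRUE
    tab <- table(colj[keep])
    k <- length(tab)
    w[keep] <- w[keep] + 1 / (k * as.numeric(tab[colj[keep]]))
  }
  if (!informative)
    stop("degenerate-input error: alignment has no informative columns",
         call. = FALSE)
  # sequences made entirely of gaps would get zero weight; give them the
  # smallest positive share before normalizing so weights stay positive
  if (any(w == 0)) w[w == 0] <- min(w[w > 0]) * 1e-6
  w / sum(w)
}

entropy2 <- function(p) {
  p <- p[p > 0]
  -sum(p * log2(p))
}

#' Conservation score of one alignment column
#'
#' The score is the Jensen-Shannon divergence (base 2, lambda = 1/2) between
#' the sequence-weighted observed amino-acid distribution of the column
#' (gaps and ambiguity codes excluded, weights renormalized) and a background
#' distribution, divided by its 1-bit maximum so the result lies in [0, 1].
#' A column identical to the background scores 0; an invariant column of a
#' rare residue approaches 1.
#'
#' @param column Character vector of residue letters (one per record).
#' @param weights Positive per-record weights (same length as `column`).
#' @param background Named frequency 20-vector over the standard amino acids
#'   (must sum to 1), or `"robinson"`/`"uniform"`.
#' @return Numeric score in [0, 1].
#' @export
column_score <- function(column, weights, background = "robinson") {
  if (length(column) != length(weights))
    stop("column and weights must have equal length", call. = FALSE)
  bg <- resolve_background(background)
  keep <- column %in% AA_STANDARD
  if (!any(keep))
    stop("undefined-score error: column has no standard residues",
         call. = FALSE)
  w <- weights[keep]
  p <- vapply(split(w, factor(column[keep], levels = AA_STANDARD)), sum, 0)
  p <- p / sum(p)
  m <- (p + bg) / 2
  jsd <- entropy2(m) - (entropy2(p) + entropy2(bg)) / 2
  min(max(jsd, 0), 1)
}

#' Count informative residues in a column
#'
#' @param column Character vector of residue letters.
#' @param min_informative Minimum number of standard (non-gap, non-ambiguous)
#'   letters for the column's score to be considered reliable.
#' @return List with `reliable` (logical) and `n_informative` (integer).
#'   The boundary is inclusive: exactly `min_informative` letters is reliable.
#' @export
reliability <- function(column, min_informative = 6L) {
  n <- sum(column %in% AA_STANDARD)
  list(reliable = n >= min_informative, n_informative = as.integer(n))
}

#' Discretize raw conservation scores to 1-9 grades
#'
#' Quantile binning of the reliable columns into `n_bins` equal-count bins;
#' grade `n_bins` (9) is the most conserved. Tied scores share the higher
#' grade, so a degenerate profile in which every column scores the same is
#' all grade 9. Unreliable columns are graded by where their score falls
#' among the reliable ones but should be reported with `reliable = FALSE`.
#'
#' @param raw_scores Numeric vector of per-column scores (NA allowed for
#'   unscored columns; returned as NA grade).
#' @param n_bins Number of grades (default 9).
#' @param reliable Logical vector marking which columns define the bins;
#'   defaults to all scored columns.
#' @return Integer vector of grades in 1..n_bins (NA where score is NA).
#' @export
#' @examples
#' grade_profile(seq(0.1, 0.9, by = 0.1))   # 1:9
grade_profile <- function(raw_scores, n_bins = 9L, reliable = NULL) {
  n_bins <- as.integer(n_bins)
  if (is.null(reliable)) reliable <- !is.na(raw_scores)
  reliable <- reliable & !is.na(raw_scores)
  if (!any(reliable))
    stop("at least one reliable scored column is required", call. = FALSE)
  grades <- rep(NA_integer_, length(raw_scores))
  rel_scores <- raw_scores[reliable]
  n <- length(rel_scores)
  r <- rank(rel_scores, ties.method = "max")  # ties share the higher grade
  grades[reliable] <- as.integer(ceiling(n_bins * r / n))
  # place unreliable-but-scored columns into the bins defined by the
  # reliable ones: grade of the smallest reliable score >= x (ties higher),
  # or the top grade if above all reliable scores
  rest <- which(!reliable & !is.na(raw_scores))
  if (length(rest)) {
    ord <- order(rel_scores)
    s_sorted <- rel_scores[ord]
    g_sorted <- grades[reliable][ord]
    pos <- findInterval(raw_scores[rest], s_sorted, left.open = TRUE) + 1L
    grades[rest] <- ifelse(pos > n, n_bins, g_sorted[pmin(pos, n)])
  }
  grades
}

#' Per-column conservation profile of an alignment
#'
#' Runs sequence weighting, per-column Jensen-Shannon scoring, reliability
#' flagging and 9-grade binning, and attaches reference numbering.
#'
#' @param aln An [msa] object.
#' @param mapping Optional [map_to_reference()] result; when supplied the
#'   profile carries `ref_pos`/`ref_aa` columns in reference numbering.
#' @param background Background distribution (see [column_score()]).
#' @param min_informative Reliability threshold (see [reliability()]).
#' @param n_bins Number of conservation grades.
#' @param weights Optional per-record weights; computed by
#'   [sequence_weights()] when NULL.
#' @return A `data.frame` of class `conservation_profile` with columns
#'   `col`, `ref_pos`, `ref_aa`, `raw_score`, `grade`, `reliable`,
#'   `n_informative`.
#' @export
conservation_profile <- function(aln, mapping = NULL,
                                 background = "robinson",
                                 min_informative = 6L, n_bins = 9L,
                                 weights = NULL) {
  stopifnot(inherits(aln, "msa"))
  bg <- resolve_background(background)
  if (is.null(weights)) weights <- sequence_weights(aln)
  m <- msa_matrix(aln)
  L <- ncol(m)
  raw <- rep(NA_real_, L)
  rel <- logical(L)
  n_inf <- integer(L)
  for (j in seq_len(L)) {
    colj <- m[, j]
    r <- reliability(colj, min_informative)
    rel[j] <- r$reliable
    n_inf[j] <- r$n_informative
    if (r$n_informative > 0L) raw[j] <- column_score(colj, weights, bg)
  }
  if (!any(rel & !is.na(raw)))
    stop("no reliable columns: lower min_informative or check the alignment",
         call. = FALSE)
  grade <- grade_profile(raw, n_bins = n_bins, reliable = rel)
  ref_pos <- rep(NA_integer_, L)
  ref_aa <- rep(NA_character_, L)
  if (!is.null(mapping)) {
    stopifnot(inherits(mapping, "residue_mapping"))
    ref_pos <- mapping$col_to_ref
    nz <- !is.na(ref_pos)
    ref_aa[nz] <- unname(mapping$ref_aa[as.character(ref_pos[nz])])
  }
  out <- data.frame(col = seq_len(L), ref_pos = ref_pos, ref_aa = ref_aa,
                    raw_score = raw, grade = grade, reliable = rel,
                    n_informative = n_inf, stringsAsFactors = FALSE)
  class(out) <- c("conservation_profile", "data.frame")
  attr(out, "min_informative") <- as.integer(min_informative)
  attr(out, "n_bins") <- as.integer(n_bins)
  out
}

#' Write a conservation profile as TSV
#'
#' @param profile A [conservation_profile()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_profile_tsv <- function(profile, path) {
  df <- as.data.frame(profile)
  df$raw_score <- ifelse(is.na(df$raw_score), NA,
                         sprintf("%.6f", df$raw_score))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "")
  invisible(path)
}
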