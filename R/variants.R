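#' Read a missense-variant table
#'
#' Parses a delimited export in the style of a gnomAD download: one row per
#' observed alternate allele with protein position, reference and alternate
#' residues, optional allele frequency, source dataset, pathogenicity flag
#' and rs identifier. Column names are mapped through `dialect`, so exports
#' with different headers can be read without editing the file. Duplicate
#' (position, alternate) pairs are collapsed keeping the maximum frequency.
#'
#' @param path Path to the delimited file.
#' @param dialect Named list mapping the canonical fields `position`,
#'   `ref`, `alt`, `frequency`, `dataset`, `pathogenic`, `rs_id` to column
#'   names in the file (fields absent from the list or the file are filled
#'   with defaults). `sep` (default tab) selects the delimiter.
#' @param offset Integer added to positions on input — converts e.g.
#'   precursor numbering to mature-protein numbering.
#' @return data.frame of class `variant_table` with columns `ref_pos`,
#'   `ref_aa`, `alt_aa`, `frequency`, `dataset`, `pathogenic`, `rs_id`.
#' @export
read_variants <- function(path, dialect = list(), offset = 0L) {
  if (!file.exists(path)) stop("variant file not found: ", path,
                               call. = FALSE)
  sep <- dialect$sep %||% "\t"
  raw <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
  get_col <- function(field, default = NULL) {
    nm <- dialect[[field]] %||% field
    if (nm %in% names(raw)) raw[[nm]] else default
  }
  pos <- get_col("position")
  ref <- get_col("ref")
  alt <- get_col("alt")
  if (is.null(pos) || is.null(ref) || is.null(alt))
    stop("dialect error: could not locate position/ref/alt columns in ",
         path, call. = FALSE)
  n <- nrow(raw)
  freq <- get_col("frequency", rep(NA_real_, n))
  dataset <- as.character(get_col("dataset", rep("default", n)))
  pathog <- get_col("pathogenic", rep(FALSE, n))
  rs <- as.character(get_col("rs_id", rep(NA_character_, n)))
  pos_num <- suppressWarnings(as.integer(pos))
  ref <- toupper(trimws(as.character(ref)))
  alt <- toupper(trimws(as.character(alt)))
  if (is.character(pathog))
    pathog <- toupper(trimws(pathog)) %in% c("YES", "TRUE", "1", "Y")
  pathog <- as.logical(pathog)
  freq <- suppressWarnings(as.numeric(freq))
  for (i in seq_len(n)) {
    line <- i + 1L  # header is line 1
    if (is.na(pos_num[i]) || pos_num[i] < 1L)
      stop("row-level error at line ", line, ": malformed position '",
           pos[i], "'", call. = FALSE)
    if (!(ref[i] %in% AA_STANDARD))
      stop("row-level error at line ", line, ": unknown reference residue '",
           ref[i], "'", call. = FALSE)
    if (!(alt[i] %in% AA_STANDARD))
      stop("row-level error at line ", line, ": unknown alternate residue '",
           alt[i], "'", call. = FALSE)
    if (ref[i] == alt[i])
      stop("row-level error at line ", line,
           ": reference and alternate residues are identical", call. = FALSE)
    if (!is.na(freq[i]) && (freq[i] < 0 || freq[i] > 1))
      stop("row-level error at line ", line, ": frequency outside [0,1]",
           call. = FALSE)
  }
  out <- data.frame(ref_pos = pos_num + as.integer(offset), ref_aa = ref,
                    alt_aa = alt, frequency = freq, dataset = dataset,
                    pathogenic = pathog, rs_id = rs,
                    stringsAsFactors = FALSE)
  variant_table(out)
}

#' Construct a variant table from a data.frame
#'
#' @param df data.frame with columns `ref_pos`, `ref_aa`, `alt_aa` and
#'   optionally `frequency`, `dataset`, `pathogenic`, `rs_id`.
#' @return data.frame of class `variant_table` with duplicate
#'   (position, alternate) pairs collapsed keeping the maximum frequency
#'   (a pathogenic flag on any duplicate is kept).
#' @export
variant_table <- function(df) {
  n <- nrow(df)
  df$frequency <- df$frequency %||% rep(NA_real_, n)
  df$dataset <- df$dataset %||% rep("default", n)
  df$pathogenic <- df$pathogenic %||% rep(FALSE, n)
  df$rs_id <- df$rs_id %||% rep(NA_character_, n)
  if (n) {
    key <- paste(df$ref_pos, df$alt_aa, df$dataset, sep = "|")
    ord <- order(key, -ifelse(is.na(df$frequency), -Inf, df$frequency))
    df <- df[ord, , drop = FALSE]
    keyo <- key[ord]
    agg_path <- tapply(df$pathogenic, keyo, any)
    df <- df[!duplicated(keyo), , drop = FALSE]
    df$pathogenic <- as.logical(agg_path[unique(keyo)][
      match(paste(df$ref_pos, df$alt_aa, df$dataset, sep = "|"),
            unique(keyo))])
    df <- df[order(df$ref_pos, df$alt_aa, df$dataset), , drop = FALSE]
  }
  rownames(df) <- NULL
  class(df) <- c("variant_table", "data.frame")
  df
}

#' Positions carrying at least one variant
#'
#' @param t A `variant_table`.
#' @param positions Optional set of positions to intersect with.
#' @param pathogenic_only Count only pathogenic rows.
#' @return Sorted integer vector of distinct positions.
#' @export
residues_with_variants <- function(t, positions = NULL,
                                   pathogenic_only = FALSE) {
  stopifnot(inherits(t, "variant_table"))
  rows <- if (pathogenic_only) t[t$pathogenic, , drop = FALSE] else t
  hit <- sort(unique(rows$ref_pos))
  if (!is.null(positions)) hit <- intersect(hit, as.integer(positions))
  as.integer(hit)
}

#' Overlap between conservation clusters and a variant table
#'
#' How many residues of the clusters carry at least one (optionally
#' pathogenic-only) variant — the statistic behind "only 4 from the 17
#' residues presented variations" and "7 of the 12 residues from these
#' clusters presented pathological variants".
#'
#' @param clusters List of `conservation_cluster` objects, or a list of
#'   integer vectors of residue positions.
#' @param t A `variant_table`.
#' @param pathogenic_only Restrict to rows flagged pathogenic.
#' @return List: `n_hit`, `n_total` (size of the union of members),
#'   `hit_positions`, and `per_cluster` data.frame breakdown.
#' @export
cluster_overlap <- function(clusters, t, pathogenic_only = FALSE) {
  stopifnot(inherits(t, "variant_table"))
  if (!length(clusters)) stop("clusters must be non-empty", call. = FALSE)
  member_sets <- lapply(clusters, function(cl)
    if (inherits(cl, "conservation_cluster")) cl$members
    else as.integer(cl))
  all_members <- sort(unique(unlist(member_sets)))
  hits <- residues_with_variants(t, all_members,
                                 pathogenic_only = pathogenic_only)
  per <- data.frame(
    cluster = seq_along(member_sets),
    n_members = vapply(member_sets, length, 0L),
    n_hit = vapply(member_sets, function(m)
      length(intersect(m, hits)), 0L),
    hit_positions = vapply(member_sets, function(m)
      paste(intersect(m, hits), collapse = ","), ""),
    stringsAsFactors = FALSE)
  list(n_hit = length(hits), n_total = length(all_members),
       hit_positions = hits, per_cluster = per)
}
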