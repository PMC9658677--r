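#' Path to a packaged example data file
#'
#' The package ships plain-text fixtures for the frataxin/CyaY analyses:
#' the mature human frataxin sequence (Fxn81-210, verified against 31
#' published residue-identity anchors), a synthetic 47-sequence family
#' alignment whose motif columns reproduce the published presence table, a
#' transcription of that table, the gnomAD cluster-variant and pathogenic
#' mutation tables, and a synthetic-coordinates stand-in structure carrying
#' the 3S4M chain-A sequence and numbering (coordinates are simulated, not
#' crystallographic — files are named accordingly).
#'
#' @param file File name within `inst/extdata`; empty to list all.
#' @return Absolute path (or a vector of available file names).
#' @export
conserv3d_example <- function(file = "") {
  if (!nzchar(file))
    return(dir(system.file("extdata", package = "conserv3d")))
  path <- system.file("extdata", file, package = "conserv3d")
  if (!nzchar(path)) stop("no packaged file named '", file, "'",
                          call. = FALSE)
  path
}

#' Mature human frataxin sequence
#'
#' The processed mitochondrial form. `start = 81` gives Fxn81-210 (130
#' residues, beginning at S81); `start = 82` gives the 3S4M chain-A
#' sequence (129 residues, beginning at G82).
#'
#' @param start First residue number, 81 or 82.
#' @return Single character string.
#' @export
frataxin_mature_seq <- function(start = 81) {
  path <- conserv3d_example("frataxin_mature_human.fasta")
  seq <- as.character(Biostrings::readAAStringSet(path))[[1]]
  if (start == 81) seq
  else if (start == 82) substring(seq, 2)
  else stop("start must be 81 or 82", call. = FALSE)
}

#' Published frataxin conservation clusters
#'
#' The four spatial clusters of maximally conserved residues identified on
#' human mature frataxin (numbering of the mature protein): cluster 1,
#' non-polar residues facing the hydrophobic core; cluster 2, beta-sheet
#' residues facing the exterior; cluster 3, the Y/S/S/E tetrad; cluster 4,
#' the single acidic-ridge glutamate E111.
#'
#' @return Named list of integer vectors (`c1`..`c4`), 17 residues total.
#' @export
frataxin_clusters <- function() {
  list(c1 = c(145L, 154L, 173L, 182L, 186L),
       c2 = c(131L, 133L, 144L, 146L, 148L, 155L, 157L),
       c3 = c(143L, 158L, 161L, 189L),
       c4 = 111L)
}

#' The frataxin cluster-3 tetrad motif
#'
#' @return A [motif_spec()] for Y143/S158/S161/E189.
#' @export
frataxin_tetrad <- function() {
  motif_spec(c(143L, 158L, 161L, 189L), c("Y", "S", "S", "E"))
}
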