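pipeline_defaults <- function() {
  list(
    alignment = NULL, alignment_format = "fasta",
    structure = NULL, structure_format = "pdb", chain = NULL,
    variants = NULL, variant_dialect = list(), variant_offset = 0L,
    reference = list(id = NULL, start_number = 1L),
    scoring = list(background = "robinson", min_informative = 6L,
                   n_bins = 9L),
    clustering = list(grade_min = 9L, cutoff = 8.0,
                      mode = "sidechain_centroid",
                      exclude_aa = c("G", "P"),
                      buried_max = 0.2, exposed_min = 0.35),
    motif = NULL,
    network = list(cutoff = 10.5, mode = "ring_centroid",
                   aromatic_set = c("Y", "W"),
                   site_positions = integer(0)),
    cavities = list(grid_spacing = 0.7, probe = 1.4),
    variants_pathogenic_only = FALSE,
    output_dir = "conserv3d_out",
    seed = 1L,
    provenance = list())
}

merge_defaults <- function(cfg, def) {
  for (nm in names(def)) {
    if (is.null(cfg[[nm]])) {
      cfg[[nm]] <- def[[nm]]
    } else if (is.list(def[[nm]]) && is.list(cfg[[nm]])) {
      cfg[[nm]] <- merge_defaults(cfg[[nm]], def[[nm]])
    }
  }
  cfg
}

#' Validate a pipeline configuration
#'
#' Reads a YAML file (or takes a list), fills documented defaults, and
#' checks paths and parameter ranges. All problems are reported at once,
#' not fail-fast.
#'
#' @param config Path to a YAML config file, or a named list.
#' @param stop_on_error Stop with an aggregated message (default) or return
#'   the error list.
#' @return Validated config of class `pipeline_config` (defaults filled),
#'   or — when `stop_on_error = FALSE` and problems exist — a list with
#'   elements `errors` and `config`.
#' @export
validate_config <- function(config, stop_on_error = TRUE) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- yaml::read_yaml(config)
  }
  cfg <- merge_defaults(config, pipeline_defaults())
  errors <- character(0)
  add <- function(msg) errors <<- c(errors, msg)
  if (is.null(cfg$alignment)) {
    add("alignment: path is required")
  } else if (!file.exists(cfg$alignment)) {
    add(paste0("alignment: file not found: ", cfg$alignment))
  }
  for (field in c("structure", "variants"))
    if (!is.null(cfg[[field]]) && !file.exists(cfg[[field]]))
      add(paste0(field, ": file not found: ", cfg[[field]]))
  if (is.null(cfg$reference$id))
    add("reference$id is required")
  sc <- cfg$scoring
  if (sc$min_informative < 0) add("scoring$min_informative must be >= 0")
  if (sc$n_bins < 1 || sc$n_bins > 20) add("scoring$n_bins outside 1..20")
  cl <- cfg$clustering
  if (cl$cutoff <= 0) add("clustering$cutoff must be positive")
  if (cl$grade_min < 1 || cl$grade_min > sc$n_bins)
    add("clustering$grade_min outside 1..n_bins")
  if (cl$buried_max < 0 || cl$buried_max > cl$exposed_min)
    add("clustering$buried_max must lie in [0, exposed_min]")
  if (!cl$mode %in% c("ca", "sidechain_centroid", "min_atom"))
    add("clustering$mode must be ca, sidechain_centroid or min_atom")
  nw <- cfg$network
  if (nw$cutoff <= 0) add("network$cutoff must be positive")
  cv <- cfg$cavities
  if (cv$grid_spacing <= 0 || cv$grid_spacing > 3)
    add("cavities$grid_spacing outside (0, 3]")
  if (cv$probe < 0) add("cavities$probe must be >= 0")
  if (!is.null(cfg$motif)) {
    ms <- try(motif_spec(cfg$motif$positions, cfg$motif$consensus),
              silent = TRUE)
    if (inherits(ms, "try-error"))
      add(paste0("motif: ", attr(ms, "condition")$message))
  }
  if (length(errors)) {
    if (stop_on_error)
      stop("invalid configuration:\n  - ",
           paste(errors, collapse = "\n  - "), call. = FALSE)
    return(list(errors = errors, config = cfg))
  }
  class(cfg) <- c("pipeline_config", "list")
  cfg
}

fmt_num <- function(x, digits = 6) {
  ifelse(is.na(x), NA, sprintf(paste0("%.", digits, "f"), x))
}

#' Run the full conservation-mapping pipeline
#'
#' Executes the stages in order — conservation profile, grade-annotated
#' structure, spatial clusters with orientation, motif table and
#' co-occurrence, cavities, aromatic transfer network, variant overlap —
#' and writes one artifact per stage plus a run manifest (config echo,
#' versions, seed, input checksums). Stages whose inputs are absent from
#' the config are skipped and recorded as skipped in the manifest. Outputs
#' are deterministic: identical inputs and config give byte-identical
#' files.
#'
#' @param config A validated [validate_config()] result, a config list, or
#'   a YAML path.
#' @return Invisible list of the in-memory stage results, with
#'   `output_files` and `skipped` attached.
#' @export
run_pipeline <- function(config) {
  if (!inherits(config, "pipeline_config")) config <- validate_config(config)
  out_dir <- config$output_dir
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  results <- list()
  skipped <- character(0)
  outputs <- character(0)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE))
  }
  emit <- function(name) outputs <<- c(outputs, name)

  # conservation scoring
  aln <- stage("alignment", read_alignment(config$alignment,
                                           config$alignment_format))
  mapping <- stage("mapping", map_to_reference(
    aln, config$reference$id, config$reference$start_number))
  profile <- stage("conservation", conservation_profile(
    aln, mapping, background = config$scoring$background,
    min_informative = config$scoring$min_informative,
    n_bins = config$scoring$n_bins))
  write_profile_tsv(profile, file.path(out_dir, "conservation.tsv"))
  emit("conservation.tsv")
  results$profile <- profile

  have_structure <- !is.null(config[["structure"]])
  s <- NULL
  rsa <- NULL
  if (have_structure) {
    s <- stage("structure", read_structure(config[["structure"]],
                                           config[["structure_format"]],
                                           chain = config$chain))
    rsa <- stage("accessibility", relative_accessibility(s))
    grades <- setNames(profile$grade[!is.na(profile$ref_pos)],
                       profile$ref_pos[!is.na(profile$ref_pos)])
    stage("graded_structure", write_structure(
      s, file.path(out_dir, "structure_graded.pdb"),
      b_residue = grades[!is.na(grades)]))
    emit("structure_graded.pdb")
    results$structure <- s
    results$rsa <- rsa
  } else {
    skipped <- c(skipped, "graded_structure")
  }

  # spatial conservation clusters
  if (have_structure) {
    cl <- config$clustering
    selected <- stage("selection", select_conserved(
      profile, grade_min = cl$grade_min, exclude_aa = cl$exclude_aa))
    present <- residues(s)
    chain1 <- if (!is.null(config$chain)) config$chain[1] else
      present$chain[1]
    selected <- intersect(selected,
                          present$resno[present$chain == chain1])
    clusters <- stage("clusters", spatial_clusters(
      selected, s, cutoff = cl$cutoff, mode = cl$mode, chain = chain1))
    clusters <- lapply(clusters, classify_orientation, rsa = rsa,
                       buried_max = cl$buried_max,
                       exposed_min = cl$exposed_min)
    rep_df <- cluster_report(clusters)
    rep_df$mean_rsa <- fmt_num(rep_df$mean_rsa, 4)
    write.table(rep_df, file.path(out_dir, "clusters.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    emit("clusters.tsv")
    results$clusters <- clusters
  } else {
    skipped <- c(skipped, "clusters")
  }

  # motif coevolution
  if (!is.null(config$motif)) {
    spec <- motif_spec(config$motif$positions, config$motif$consensus)
    mt <- stage("motif", motif_table(aln, mapping, spec))
    write_motif_tsv(mt, file.path(out_dir, "motif_table.tsv"))
    emit("motif_table.tsv")
    pos <- spec$positions
    cooc <- list()
    if (length(pos) > 1) {
      for (i in seq_len(length(pos) - 1)) for (j in (i + 1):length(pos)) {
        key <- paste0(pos[i], "_", pos[j])
        cooc[[key]] <- as.list(cooccurrence(mt, pos[i], pos[j]))
      }
    }
    summary_df <- if (all(!is.na(mt$taxon_group))) group_summary(mt)
                  else NULL
    jsonlite::write_json(
      list(positions = pos, consensus = spec$consensus,
           cooccurrence = cooc, group_summary = summary_df),
      file.path(out_dir, "cooccurrence.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    emit("cooccurrence.json")
    results$motif_table <- mt
  } else {
    skipped <- c(skipped, "motif")
  }

  # cavities
  if (have_structure) {
    cavs <- stage("cavities", find_cavities(
      s, grid_spacing = config$cavities$grid_spacing,
      probe = config$cavities$probe))
    cav_df <- cavity_report(cavs)
    cav_df$volume <- fmt_num(cav_df$volume, 3)
    write.table(cav_df, file.path(out_dir, "cavities.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE, na = "")
    emit("cavities.tsv")
    results$cavities <- cavs
  } else {
    skipped <- c(skipped, "cavities")
  }

  # aromatic transfer network
  if (have_structure) {
    nw <- config$network
    net <- stage("network", build_transfer_network(
      s, cutoff = nw$cutoff, mode = nw$mode,
      aromatic_set = nw$aromatic_set,
      site_positions = nw$site_positions %||% integer(0)))
    edges <- network_edges(net)
    edges$distance <- fmt_num(edges$distance, 3)
    write.table(edges, file.path(out_dir, "network_edges.tsv"),
                sep = "\t", quote = FALSE, row.names = FALSE, na = "")
    emit("network_edges.tsv")
    results$network <- net
  } else {
    skipped <- c(skipped, "network")
  }

  # variant overlap
  if (!is.null(config[["variants"]])) {
    vt <- stage("variants", read_variants(
      config[["variants"]], dialect = config$variant_dialect,
      offset = config$variant_offset))
    results$variants <- vt
    if (!is.null(results$clusters) && length(results$clusters)) {
      ov_all <- cluster_overlap(results$clusters, vt,
                                pathogenic_only = FALSE)
      ov_path <- cluster_overlap(results$clusters, vt,
                                 pathogenic_only = TRUE)
      jsonlite::write_json(
        list(population = ov_all[c("n_hit", "n_total", "hit_positions")],
             pathogenic = ov_path[c("n_hit", "n_total", "hit_positions")],
             per_cluster = ov_all$per_cluster),
        file.path(out_dir, "variant_overlap.json"),
        auto_unbox = TRUE, digits = NA, pretty = TRUE)
      emit("variant_overlap.json")
      results$overlap <- ov_all
    } else {
      skipped <- c(skipped, "variant_overlap")
    }
  } else {
    skipped <- c(skipped, "variant_overlap")
  }

  # manifest
  inputs <- Filter(Negate(is.null),
                   list(alignment = config$alignment,
                        structure = config[["structure"]],
                        variants = config[["variants"]]))
  manifest <- list(
    package = "conserv3d",
    version = as.character(utils::packageVersion("conserv3d")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    config = unclass(config),
    input_checksums = lapply(inputs, function(p) unname(tools::md5sum(p))),
    outputs = outputs,
    skipped_stages = skipped)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  attr(results, "output_files") <- c(outputs, "manifest.json")
  attr(results, "skipped") <- skipped
  invisible(results)
}
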