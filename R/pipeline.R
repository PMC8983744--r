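# End-to-end demo pipeline: simulate -> annotate -> repertoire statistics
# -> clonal analysis (-> divergence when a second sample is configured),
# with a JSON run manifest. Every stochastic stage consumes a named
# sub-seed derived from the global seed, so reruns with the same
# configuration reproduce byte-identical TSV outputs.

#' Assemble and validate a pipeline configuration
#'
#' @param germline_fasta,germline_metadata Paths to the germline reference;
#'   both `NULL` (default) selects the bundled toy reference.
#' @param simulate Named list of [sim_config()] arguments for sample 1.
#' @param simulate2 Optional second sample (enables the divergence stage).
#' @param annotate Named list of [annotate_reads()] arguments
#'   (thresholds etc.).
#' @param top_n_lineages Lineages to profile and draw (default 3).
#' @param min_copies,p_cutoff Divergence-stage parameters.
#' @param seed Global seed; stage sub-seeds are derived from it.
#' @return Validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(germline_fasta = NULL, germline_metadata = NULL,
                            simulate = list(), simulate2 = NULL,
                            annotate = list(), top_n_lineages = 3L,
                            min_copies = 100L, p_cutoff = 0.01,
                            seed = 1L) {
  if (is.null(germline_fasta) != is.null(germline_metadata))
    stop("provide both germline_fasta and germline_metadata, or neither",
         call. = FALSE)
  if (!is.null(germline_fasta)) {
    for (p in c(germline_fasta, germline_metadata))
      if (!file.exists(p)) stop("path does not exist: ", p, call. = FALSE)
  }
  known_sim <- names(formals(sim_config))
  for (nm in names(simulate))
    if (!nm %in% known_sim)
      stop("unknown simulate parameter: ", nm, call. = FALSE)
  if (!is.null(simulate2))
    for (nm in names(simulate2))
      if (!nm %in% known_sim)
        stop("unknown simulate2 parameter: ", nm, call. = FALSE)
  known_ann <- setdiff(names(formals(annotate_reads)), c("reads", "db"))
  for (nm in names(annotate))
    if (!nm %in% known_ann)
      stop("unknown annotate parameter: ", nm, call. = FALSE)
  structure(list(germline_fasta = germline_fasta,
                 germline_metadata = germline_metadata,
                 simulate = simulate, simulate2 = simulate2,
                 annotate = annotate,
                 top_n_lineages = as.integer(top_n_lineages),
                 min_copies = as.integer(min_copies), p_cutoff = p_cutoff,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML or JSON
#'
#' @param path Path to a YAML (needs the `yaml` package) or JSON file whose
#'   top-level keys are [pipeline_config()] arguments.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  lst <- if (grepl("\\.ya?ml$", path)) {
    if (!requireNamespace("yaml", quietly = TRUE))
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    yaml::read_yaml(path)
  } else jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, lst)
}

#' Run the full repertoire analysis pipeline
#'
#' Executes simulate -> annotate -> stats -> clonal (-> divergence) as
#' configured, writing TSV/FASTA/Newick/Circos outputs plus a JSON manifest
#' (`manifest.json`) recording package and R versions, the global seed, the
#' named stage sub-seeds, a configuration hash, and the files written.
#' Rerunning with the same configuration and seed reproduces every
#' non-manifest output byte-identically (the manifest differs only in its
#' timestamp).
#'
#' @param config A `pipeline_config`.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, the manifest as a list.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  emit <- function(p) { paths[length(paths) + 1L] <<- p; p }

  db <- if (is.null(config$germline_fasta)) toy_germline()
        else load_germline(config$germline_fasta, config$germline_metadata)

  sub_seeds <- c(simulate = .derive_seed(config$seed, "simulate"),
                 stats = .derive_seed(config$seed, "stats"))

  run_sample <- function(sim_args, tag, sim_seed) {
    sim_args$seed <- sim_seed
    scfg <- do.call(sim_config, sim_args)
    sim <- simulate_repertoire(db, scfg)
    for (p in write_repertoire(sim, file.path(out_dir, paste0("sim", tag))))
      emit(p)
    tab <- do.call(annotate_reads,
                   c(list(reads = sim$reads, db = db, locus = scfg$locus),
                     config$annotate))
    emit(write_rearrangement_tsv(
      tab, file.path(out_dir, paste0("rearrangements", tag, ".tsv"))))
    tab
  }

  tab1 <- run_sample(config$simulate, "", sub_seeds[["simulate"]])

  # ---- repertoire statistics
  wtsv <- function(df, name) {
    p <- file.path(out_dir, name)
    utils::write.table(df, p, sep = "\t", quote = FALSE, row.names = FALSE)
    emit(p)
  }
  for (st in c("V", "D", "J")) {
    col <- paste0(tolower(st), "_call")
    if (col %in% names(tab1) && any(!is.na(tab1[[col]])))
      wtsv(usage_frequencies(tab1, st),
           paste0("usage_", tolower(st), ".tsv"))
  }
  links <- vdj_links(tab1)
  wtsv(links, "vdj_links.tsv")
  for (p in circos_export(links, file.path(out_dir, "circos"))) emit(p)
  has_prod_cdr3 <- any(isTRUE_v(tab1$productive) & !is.na(tab1$cdr3_aa) &
                       nzchar(tab1$cdr3_aa))
  cl <- NULL
  if (has_prod_cdr3) {
    cl <- cdr3_length_distribution(tab1)
    wtsv(cl$histogram, "cdr3_length.tsv")
    wtsv(aa_composition(tab1), "cdr3_aa_composition.tsv")
  }
  np <- np_addition_distribution(tab1)
  wtsv(data.frame(end = names(np$means), mean_length = unname(np$means)),
       "np_means.tsv")
  clonotypes <- group_clonotypes(tab1)
  div <- shannon_index(clonotypes$copy_count)
  set.seed(sub_seeds[["stats"]])
  depths <- unique(pmin(nrow(tab1), c(10L, 50L, 100L, 500L, 1000L,
                                      nrow(tab1))))
  wtsv(rarefaction_curve(tab1, depths), "rarefaction.tsv")
  summary_json <- file.path(out_dir, "summary.json")
  jsonlite::write_json(list(
    n_annotated = nrow(tab1),
    n_unannotatable = attr(tab1, "qc")$n_unannotatable,
    productive_percent = productive_fraction(tab1),
    mean_cdr3_length_aa = if (has_prod_cdr3) cl$mean_length else NA,
    shannon_H = div$H_prime, n_clonotypes = div$S),
    summary_json, auto_unbox = TRUE, digits = NA)
  emit(summary_json)

  # ---- clonal analysis
  wtsv(clonotypes, "clonotypes.tsv")
  lineages <- group_lineages(tab1)
  wtsv(lineages, "lineages.tsv")
  for (nm in top_lineages(lineages, config$top_n_lineages)$name) {
    members <- lineage_reads(tab1, lineages, nm)
    prof <- normalize_profile(shm_position_profile(members, db), db)
    wtsv(as.data.frame(prof), paste0("shm_profile_", nm, ".tsv"))
    ct <- group_clonotypes(members)
    cdr3s <- vapply(strsplit(ct$clonotype_key, "|", fixed = TRUE),
                    function(x) x[3], character(1))
    keep <- !is.na(cdr3s) & nzchar(cdr3s)
    if (sum(keep) >= 1L) {
      tr <- nj_tree(stats::setNames(cdr3s[keep],
                                    sprintf("ct%03d", which(keep))),
                    ct$copy_count[keep])
      emit(write_clonal_tree(tr, file.path(out_dir,
                                           paste0("tree_", nm, ".nwk"))))
      wtsv(tr$overlay, paste0("tree_overlay_", nm, ".csv"))
    }
  }

  # ---- divergence (two-sample) stage
  if (!is.null(config$simulate2)) {
    tab2 <- run_sample(config$simulate2, "2",
                       .derive_seed(config$seed + 1L, "simulate"))
    dv <- divergence_odds(tab1, tab2, min_copies = config$min_copies,
                          p_cutoff = config$p_cutoff)
    wtsv(dv$lineages, "divergence.tsv")
    odds_json <- file.path(out_dir, "odds.json")
    jsonlite::write_json(list(odds_score = dv$odds_score,
                              group_counts = as.list(dv$group_counts),
                              continuity_corrected = dv$continuity_corrected,
                              p_cutoff = dv$p_cutoff),
                         odds_json, auto_unbox = TRUE, digits = NA)
    emit(odds_json)
  }

  cfg_file <- tempfile(fileext = ".json")
  jsonlite::write_json(unclass(config), cfg_file, auto_unbox = TRUE,
                       null = "null", digits = NA, force = TRUE)
  manifest <- list(
    package = "vdjrep",
    package_version = as.character(utils::packageVersion("vdjrep")),
    r_version = paste(R.version$major, R.version$minor, sep = "."),
    seed = config$seed,
    sub_seeds = as.list(sub_seeds),
    config_hash = unname(tools::md5sum(cfg_file)),
    outputs = sort(basename(paths)),
    timestamp = format(Sys.time(), tz = "UTC"))
  unlink(cfg_file)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
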