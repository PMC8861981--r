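#' Run the full analysis pipeline from a declarative configuration
#'
#' Orchestrates the stages — simulate, de-screen, cluster, crosstab, enrich,
#' sesame-scan — as toggled in the configuration, writes every result table
#' under \code{out_dir}, and finishes with a provenance manifest (inputs,
#' parameters, derived stage seeds, package version, output checksums).
#' Every stage draws its seed deterministically from the master seed via
#' [stage_seed()], so runs are byte-reproducible and adding a stage never
#' perturbs another stage's randomness.
#'
#' @param config a named list, or the path to a YAML file holding one.
#'   Recognized entries (all optional unless a stage needs them):
#'   \describe{
#'     \item{out_dir}{output directory (created if absent).}
#'     \item{seed}{master seed (default 1).}
#'     \item{stages}{character vector among \code{"simulate"},
#'       \code{"de_screen"}, \code{"cluster"}, \code{"crosstab"},
#'       \code{"enrich"}, \code{"sesame_scan"}.}
#'     \item{matrix, annot}{paths to an expression matrix and annotation TSV;
#'       required when \code{"simulate"} is not among the stages.}
#'     \item{gene_sets}{path to a GMT file (for \code{"enrich"}).}
#'     \item{simulate}{list of [sim_config()] arguments.}
#'     \item{q_threshold}{signature FDR threshold (default 0.1).}
#'     \item{k_max, lambda, n_restarts, max_iter}{clustering parameters.}
#'     \item{strong_quantile, min_coverage}{scan parameters.}
#'     \item{compendium}{list of [simulate_compendium()] arguments
#'       (\code{n_datasets}, \code{n_embedded}, \code{n_samples},
#'       \code{effect_delta}) for the scan stage.}
#'   }
#' @return Invisibly, the manifest list (also written as
#'   \code{manifest.json}).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) fail("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  if (is.null(config$out_dir)) fail("config must name an out_dir")
  stages <- config$stages
  if (is.null(stages))
    stages <- c("simulate", "de_screen", "cluster", "crosstab", "enrich",
                "sesame_scan")
  known <- c("simulate", "de_screen", "cluster", "crosstab", "enrich",
             "sesame_scan")
  bad <- setdiff(stages, known)
  if (length(bad) > 0L) fail("unknown stage: '%s'", bad[1L])
  master_seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)

  # validate referenced inputs before any stage runs
  for (key in c("matrix", "annot", "gene_sets")) {
    if (!is.null(config[[key]]) && !file.exists(config[[key]]))
      fail("config path for '%s' does not exist: %s", key, config[[key]])
  }
  if (!("simulate" %in% stages) &&
      any(c("de_screen", "cluster") %in% stages) &&
      (is.null(config$matrix) || is.null(config$annot)))
    fail("config must provide 'matrix' and 'annot' paths when not simulating")

  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- character(0)
  seeds <- list()
  emit <- function(name) {
    outputs[[length(outputs) + 1L]] <<- file.path(config$out_dir, name)
    file.path(config$out_dir, name)
  }
  run_stage <- function(stage, expr) {
    tryCatch(expr, error = function(e)
      fail("stage '%s' failed: %s", stage, conditionMessage(e)))
  }

  mat <- NULL; annot <- NULL; truth <- NULL
  if ("simulate" %in% stages) {
    seeds$simulate <- stage_seed(master_seed, "simulate")
    run_stage("simulate", {
      sim_args <- if (is.null(config$simulate)) list() else config$simulate
      sim_args$seed <- seeds$simulate
      cfg <- do.call(sim_config, sim_args)
      sim <- simulate_timecourse_study(cfg)
      mat <- sim$matrix; annot <- sim$annotation; truth <- sim$truth
      meta <- c(seed = as.character(seeds$simulate))
      write_expression_matrix(mat, emit("matrix.tsv"), metadata = meta)
      write_sample_annotation(annot, emit("annotation.tsv"), metadata = meta)
      utils::write.table(truth, emit("truth.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
    })
  } else if (!is.null(config$matrix)) {
    mat <- read_expression_matrix(config$matrix)
    annot <- read_sample_annotation(config$annot)
  }

  signature <- NULL
  if ("de_screen" %in% stages) {
    run_stage("de_screen", {
      de <- sex_ttest(mat, annot)
      utils::write.table(de, emit("de_records.tsv"), sep = "\t", quote = FALSE,
                         row.names = FALSE)
      qthr <- if (is.null(config$q_threshold)) 0.1 else config$q_threshold
      signature <- extract_signature(de, qthr)
      write_signature(signature, emit("signature.tsv"))
    })
  }

  model <- NULL; assignments <- NULL
  if ("cluster" %in% stages) {
    seeds$cluster <- stage_seed(master_seed, "cluster")
    run_stage("cluster", {
      profiles <- standardize_profiles(collapse_replicates(mat, annot))
      ctl <- epem_control(
        lambda = if (is.null(config$lambda)) 0.1 else config$lambda,
        n_restarts = if (is.null(config$n_restarts)) 10L else config$n_restarts,
        max_iter = if (is.null(config$max_iter)) 200L else config$max_iter)
      model <- epem(profiles,
                     K_max = if (is.null(config$k_max)) 10L else config$k_max,
                     control = ctl, seed = seeds$cluster)
      assignments <- assign_labels(model, profiles)
      write_cluster_model(model, emit("cluster_model.json"))
      utils::write.table(assignments, emit("cluster_labels.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  partition <- NULL
  if ("crosstab" %in% stages) {
    run_stage("crosstab", {
      if (is.null(assignments)) fail("crosstab requires the cluster stage")
      partition <- partition_genes(assignments)
      labs <- partition$labels
      tab <- cross_tabulate(stats::setNames(labs$male_label, labs$gene_id),
                            stats::setNames(labs$female_label, labs$gene_id),
                            K = model$K)
      write_crosstab(tab, emit("crosstab.tsv"))
      s <- summarize_crosstab(tab)
      utils::write.table(
        data.frame(diagonal_total = s$diagonal_total,
                   offdiagonal_total = s$offdiagonal_total,
                   grand_total = s$grand_total),
        emit("crosstab_summary.tsv"), sep = "\t", quote = FALSE,
        row.names = FALSE)
    })
  }

  if ("enrich" %in% stages) {
    run_stage("enrich", {
      if (is.null(partition)) fail("enrich requires the crosstab stage")
      if (is.null(config$gene_sets)) fail("enrich requires a gene_sets GMT path")
      sets <- read_gene_sets(config$gene_sets)
      utils::write.table(gene_set_summary(partition, sets),
                         emit("gene_set_summary.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
      enr <- overrepresentation_test(partition$discordant_genes, sets,
                                     background = partition$labels$gene_id)
      utils::write.table(enr, emit("enrichment.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  if ("sesame_scan" %in% stages) {
    seeds$sesame_scan <- stage_seed(master_seed, "sesame_scan")
    run_stage("sesame_scan", {
      if (is.null(signature)) fail("sesame_scan requires the de_screen stage")
      if (length(signature$entries) == 0L)
        fail("the extracted signature is empty; raise q_threshold")
      comp_args <- if (is.null(config$compendium)) list() else config$compendium
      defaults <- list(n_datasets = 10L, n_embedded = 1L, n_samples = 20L,
                       effect_delta = 5)
      for (nm in names(defaults))
        if (is.null(comp_args[[nm]])) comp_args[[nm]] <- defaults[[nm]]
      comp_args$signature <- signature
      comp_args$seed <- seeds$sesame_scan
      compendium <- do.call(simulate_compendium, comp_args)
      res <- scan_compendium(
        compendium, signature,
        strong_quantile = if (is.null(config$strong_quantile)) 0.90
        else config$strong_quantile,
        min_coverage = if (is.null(config$min_coverage)) 0.5
        else config$min_coverage)
      utils::write.table(res, emit("sesame_scan.tsv"), sep = "\t",
                         quote = FALSE, row.names = FALSE)
    })
  }

  manifest <- list(
    package = "epemix",
    version = as.character(utils::packageVersion("epemix")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    master_seed = master_seed,
    stage_seeds = seeds,
    stages = stages,
    parameters = config[setdiff(names(config), c("out_dir", "stages"))],
    outputs = lapply(outputs, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f))))
  )
  jsonlite::write_json(manifest, file.path(config$out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}
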