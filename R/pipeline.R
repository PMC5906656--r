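#' Assemble a pipeline run configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#' Configurations can also be read from a YAML file with
#' [read_run_config()]; explicit arguments override file values.
#'
#' @param disease_genes path to the disease gene list (one symbol per line).
#' @param pathways path to the pathway collection (GMT).
#' @param chemical_genes path to the chemical-gene table (TSV).
#' @param known_positives optional path to the known-positive list (TSV).
#' @param phenotype_annotations optional path to the mouse gene-phenotype
#'   table (TSV).
#' @param homolog_map optional path to the human-mouse homolog map (TSV).
#' @param out_dir output directory.
#' @param measure similarity measure: jaccard, overlap or cosine.
#' @param alpha significance threshold in (0, 1).
#' @param n_resamples null draws per enrichment test.
#' @param seed integer seed.
#' @param score_cutoff chemical-gene confidence cutoff (default keep all).
#' @param top_k number of top-ranked chemicals characterized by shared
#'   pathways/phenotypes.
#' @param quiet suppress progress logging.
#' @return object of class \code{run_config} (validated list).
#' @export
run_config <- function(disease_genes, pathways, chemical_genes,
                       known_positives = NULL, phenotype_annotations = NULL,
                       homolog_map = NULL, out_dir = "metaprof_out",
                       measure = c("jaccard", "overlap", "cosine"),
                       alpha = 0.05, n_resamples = 1000, seed = 1,
                       score_cutoff = 0, top_k = 5, quiet = FALSE) {
  measure <- match.arg(measure)
  if (alpha <= 0 || alpha >= 1) stop("alpha must lie in (0, 1)", call. = FALSE)
  need <- c(disease_genes = disease_genes, pathways = pathways,
            chemical_genes = chemical_genes)
  missing_files <- need[!file.exists(need)]
  if (length(missing_files)) {
    stop("input file(s) not found: ",
         paste(names(missing_files), missing_files, sep = " = ",
               collapse = "; "), call. = FALSE)
  }
  for (p in c(known_positives, phenotype_annotations, homolog_map)) {
    if (!is.null(p) && !file.exists(p)) {
      stop("input file not found: ", p, call. = FALSE)
    }
  }
  structure(list(disease_genes = disease_genes, pathways = pathways,
                 chemical_genes = chemical_genes,
                 known_positives = known_positives,
                 phenotype_annotations = phenotype_annotations,
                 homolog_map = homolog_map, out_dir = out_dir,
                 measure = measure, alpha = alpha,
                 n_resamples = as.integer(n_resamples),
                 seed = as.integer(seed), score_cutoff = score_cutoff,
                 top_k = as.integer(top_k), quiet = isTRUE(quiet)),
            class = "run_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [run_config()]; values in \code{...}
#' override the file.
#'
#' @param path YAML file.
#' @param ... overrides passed to [run_config()].
#' @return a \code{run_config}.
#' @export
read_run_config <- function(path, ...) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  vals <- yaml::read_yaml(path)
  overrides <- list(...)
  vals[names(overrides)] <- overrides
  known <- names(formals(run_config))
  bad <- setdiff(names(vals), known)
  if (length(bad)) {
    stop("unknown config key(s): ", paste(bad, collapse = ", "), call. = FALSE)
  }
  do.call(run_config, vals)
}

#' Run the full prioritization pipeline
#'
#' Executes profile construction (disease, then every chemical), similarity
#' ranking, evaluation against known positives (overall and per category),
#' and shared-pathway / shared-phenotype characterization of the top-ranked
#' chemicals, writing each stage's TSV into \code{config$out_dir} together
#' with a plain-text summary. Staged outputs equal direct module calls with
#' the same parameters and seed.
#'
#' @param config a [run_config()].
#' @return invisibly, a list with the stage results (\code{disease_profile},
#'   \code{profiles}, \code{ranked}, \code{evaluation},
#'   \code{evaluation_by_category}, \code{shared_pathways},
#'   \code{shared_phenotypes}, \code{files}, \code{timings}).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  old <- options(metaprof.quiet = config$quiet)
  on.exit(options(old), add = TRUE)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  out <- function(f) file.path(config$out_dir, f)
  files <- character(0)
  timings <- c()
  stage <- function(name, expr) {
    mp_log("stage ", name, " (seed ", config$seed, ")")
    t0 <- proc.time()[["elapsed"]]
    res <- force(expr)
    timings[[name]] <<- proc.time()[["elapsed"]] - t0
    mp_log("stage ", name, " done in ",
           sprintf("%.1fs", timings[[name]]))
    res
  }

  inputs <- stage("read", {
    list(disease = read_gene_list(config$disease_genes, "disease"),
         collection = read_gene_set_collection(config$pathways),
         chemicals = read_chemical_gene_table(config$chemical_genes,
                                              config$score_cutoff),
         known = if (!is.null(config$known_positives))
           read_known_positives(config$known_positives))
  })

  disease_profile <- stage("disease_profile",
    build_profile("disease", inputs$disease, inputs$collection,
                  alpha = config$alpha, n_resamples = config$n_resamples,
                  seed = derive_seed(config$seed, "disease")))
  write_profiles(disease_profile, out("disease_profile.tsv"))
  files <- c(files, "disease_profile.tsv")

  profiles <- stage("chemical_profiles",
    build_profiles_bulk(inputs$chemicals, inputs$collection,
                        alpha = config$alpha,
                        n_resamples = config$n_resamples,
                        seed = config$seed))
  write_profiles(profiles, out("chemical_profiles.tsv"))
  files <- c(files, "chemical_profiles.tsv")

  ranked <- stage("rank",
    rank_chemicals(disease_profile, profiles, measure = config$measure))
  write_ranked(ranked, out("ranked_chemicals.tsv"))
  files <- c(files, "ranked_chemicals.tsv")

  evaluation <- NULL
  evaluation_by_category <- NULL
  if (!is.null(inputs$known)) {
    evaluation <- stage("evaluate", evaluate_known(ranked, inputs$known))
    write_evaluation(evaluation, out("evaluation.tsv"))
    files <- c(files, "evaluation.tsv")
    if (any(nzchar(inputs$known$category))) {
      evaluation_by_category <- stage("evaluate_stratified",
        evaluate_stratified(ranked, inputs$known))
      write_evaluation(evaluation_by_category,
                       out("evaluation_by_category.tsv"))
      files <- c(files, "evaluation_by_category.tsv")
    }
  }

  top <- utils::head(ranked$chemical, config$top_k)
  shared_pw <- stage("shared_pathways", {
    res <- lapply(top, function(chem) {
      if (length(profiles[[chem]]$feature_names) == 0L) return(NULL)
      shared_pathways(disease_profile, profiles[[chem]])
    })
    names(res) <- top
    res
  })
  for (chem in top) {
    if (!is.null(shared_pw[[chem]])) {
      f <- paste0("shared_pathways_", chem, ".tsv")
      write_shared_features(shared_pw[[chem]], out(f))
      files <- c(files, f)
    }
  }

  shared_ph <- NULL
  if (!is.null(config$phenotype_annotations) && !is.null(config$homolog_map)) {
    annotations <- read_phenotype_annotations(config$phenotype_annotations)
    homologs <- read_homolog_map(config$homolog_map)
    shared_ph <- stage("shared_phenotypes", {
      res <- lapply(top, function(chem) {
        genes <- gene_set(chem, inputs$chemicals$chemicals[[chem]])
        tryCatch(shared_phenotypes(inputs$disease, genes, homologs,
                                   annotations, alpha = config$alpha,
                                   n_resamples = config$n_resamples,
                                   seed = config$seed),
                 error = function(e) NULL)
      })
      names(res) <- top
      res
    })
    for (chem in top) {
      if (!is.null(shared_ph[[chem]])) {
        f <- paste0("shared_phenotypes_", chem, ".tsv")
        write_shared_features(shared_ph[[chem]], out(f))
        files <- c(files, f)
      }
    }
  }

  summary_lines <- c(
    sprintf("measure\t%s", config$measure),
    sprintf("alpha\t%g", config$alpha),
    sprintf("n_resamples\t%d", config$n_resamples),
    sprintf("seed\t%d", config$seed),
    sprintf("disease_profile_size\t%d", nrow(disease_profile$features)),
    sprintf("n_chemicals\t%d", length(profiles)))
  if (!is.null(evaluation)) {
    summary_lines <- c(summary_lines,
      sprintf("recall\t%.3f", round_half_away(evaluation$recall, 3)),
      sprintf("mean_ranking_top_pct\t%s", fmt6(evaluation$mean_percentile)),
      sprintf("median_ranking_top_pct\t%s", fmt6(evaluation$median_percentile)),
      sprintf("p_value\t%s", fmt6(evaluation$p_value)),
      sprintf("decile_counts\t%s",
              paste(evaluation$decile_counts, collapse = ",")))
  }
  writeLines(summary_lines, out("summary.txt"))
  files <- c(files, "summary.txt")

  invisible(list(disease_profile = disease_profile, profiles = profiles,
                 ranked = ranked, evaluation = evaluation,
                 evaluation_by_category = evaluation_by_category,
                 shared_pathways = shared_pw, shared_phenotypes = shared_ph,
                 files = file.path(config$out_dir, files), timings = timings))
}
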