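#' Configuration of a synthetic prioritization universe
#'
#' Describes a complete toy universe — genes, overlapping pathways, a
#' sparse chemical-gene table, a disease gene set, mouse phenotype
#' annotations with a case-convention homolog map, and a planted set of
#' disease-associated chemicals — that emulates the statistical structure
#' of the real inputs (GWAS/OMIM/TCGA gene lists, MSigDB pathways, a
#' STITCH-style table, MGD phenotypes) at desk scale. The defaults are the
#' study conditions used throughout the package's tests: 1000 genes, 200
#' pathways, 500 chemicals, 30 planted positives with 80\% of their genes
#' drawn from disease-pathway genes.
#'
#' @param n_genes size of the human gene universe.
#' @param n_pathways number of pathways.
#' @param pathway_size_range integer (min, max) of pathway sizes.
#' @param n_chemicals number of chemicals.
#' @param chemical_genes_range integer (min, max) genes per chemical.
#' @param n_disease_genes number of disease-associated genes.
#' @param n_disease_pathways pathways seeded with the disease genes.
#' @param n_positive_chemicals planted disease-associated chemicals.
#' @param signal_strength fraction in [0, 1] of a positive chemical's genes
#'   drawn from disease-pathway genes (0 = null universe).
#' @param n_phenotypes number of mouse mutational phenotypes.
#' @param seed integer seed; all randomness flows from it through named
#'   substreams (pathways, chemicals, phenotypes, disease).
#' @return object of class \code{synthetic_config} (validated list).
#' @export
synthetic_config <- function(n_genes = 1000,
                             n_pathways = 200,
                             pathway_size_range = c(10, 50),
                             n_chemicals = 500,
                             chemical_genes_range = c(5, 30),
                             n_disease_genes = 30,
                             n_disease_pathways = 20,
                             n_positive_chemicals = 30,
                             signal_strength = 0.8,
                             n_phenotypes = 100,
                             seed = 1) {
  cfg <- list(n_genes = as.integer(n_genes),
              n_pathways = as.integer(n_pathways),
              pathway_size_range = as.integer(pathway_size_range),
              n_chemicals = as.integer(n_chemicals),
              chemical_genes_range = as.integer(chemical_genes_range),
              n_disease_genes = as.integer(n_disease_genes),
              n_disease_pathways = as.integer(n_disease_pathways),
              n_positive_chemicals = as.integer(n_positive_chemicals),
              signal_strength = as.numeric(signal_strength),
              n_phenotypes = as.integer(n_phenotypes),
              seed = as.integer(seed))
  counts <- cfg[c("n_genes", "n_pathways", "n_chemicals", "n_disease_genes",
                  "n_disease_pathways", "n_positive_chemicals", "n_phenotypes")]
  if (any(unlist(counts) < 1L)) stop("all counts must be positive", call. = FALSE)
  for (rng in list(cfg$pathway_size_range, cfg$chemical_genes_range)) {
    if (length(rng) != 2L || rng[1L] < 1L || rng[1L] > rng[2L]) {
      stop("size ranges must be ordered positive pairs", call. = FALSE)
    }
  }
  if (cfg$signal_strength < 0 || cfg$signal_strength > 1) {
    stop("signal_strength must lie in [0, 1]", call. = FALSE)
  }
  if (cfg$n_disease_genes > cfg$n_genes) {
    stop("more disease genes than genes", call. = FALSE)
  }
  if (cfg$n_disease_pathways > cfg$n_pathways) {
    stop("more disease pathways than pathways", call. = FALSE)
  }
  if (cfg$pathway_size_range[2L] < cfg$n_disease_genes) {
    stop("infeasible config: disease pathways (max size ",
         cfg$pathway_size_range[2L], ") cannot hold the ",
         cfg$n_disease_genes, " seeded disease genes", call. = FALSE)
  }
  if (cfg$n_positive_chemicals > cfg$n_chemicals) {
    stop("more positive chemicals than chemicals", call. = FALSE)
  }
  if (cfg$pathway_size_range[2L] > cfg$n_genes ||
      cfg$chemical_genes_range[2L] > cfg$n_genes) {
    stop("set sizes exceed the gene universe", call. = FALSE)
  }
  structure(cfg, class = "synthetic_config")
}

#' @export
print.synthetic_config <- function(x, ...) {
  cat("<synthetic_config> ", x$n_genes, " genes, ", x$n_pathways,
      " pathways, ", x$n_chemicals, " chemicals (", x$n_positive_chemicals,
      " planted positives, signal ", x$signal_strength, "), seed ",
      x$seed, "\n", sep = "")
  invisible(x)
}

# uniform draw from lo:hi, safe against lo == hi (sample() would treat a
# scalar as 1:n)
sample_size <- function(lo, hi) if (lo >= hi) lo else sample(lo:hi, 1L)

# human symbol -> mouse symbol under the MGI-style case convention
mouse_symbol <- function(human) {
  paste0(substr(human, 1, 1), tolower(substr(human, 2, nchar(human))))
}

positive_categories <- c("SCFAs", "Bile acids", "Indoles", "Cresols",
                         "Phenolic acids", "Polyamines")

#' Generate a complete synthetic universe
#'
#' Pathways are random gene subsets (overlap allowed); the designated
#' disease pathways additionally contain every disease gene, making them
#' genuinely enriched for the disease gene set. Positive chemicals draw a
#' \code{signal_strength} fraction of their genes from the pooled
#' disease-pathway genes and the rest uniformly; background chemicals draw
#' uniformly. Phenotype annotations mirror this structure over mouse
#' symbols (case-convention homologs of the human universe), with the
#' first tenth of phenotypes seeded with the disease genes' homologs so
#' the phenotype pipeline has signal to find. Everything is reproducible
#' from \code{config$seed} via named substreams, so regenerating one stage
#' never perturbs another's draws.
#'
#' @param config a [synthetic_config()].
#' @return list with elements \code{collection}
#'   ([gene_set_collection()]), \code{chemical_table}
#'   ([chemical_gene_table()]), \code{disease_genes} ([gene_set()]),
#'   \code{annotations} ([phenotype_annotation_table()]), \code{homologs}
#'   ([homolog_map()]), \code{known_positives} ([known_positive_list()]),
#'   \code{ground_truth} (list of \code{positive_chemicals} and
#'   \code{disease_pathways}), and \code{config}.
#' @export
generate_universe <- function(config) {
  stopifnot(inherits(config, "synthetic_config"))
  genes <- sprintf("GENE%04d", seq_len(config$n_genes))

  disease_genes <- with_seed(derive_seed(config$seed, "disease"),
                             sort(sample(genes, config$n_disease_genes)))

  pathway_names <- sprintf("PW%04d", seq_len(config$n_pathways))
  disease_pathways <- pathway_names[seq_len(config$n_disease_pathways)]
  pathways <- with_seed(derive_seed(config$seed, "pathways"), {
    lapply(seq_len(config$n_pathways), function(i) {
      if (i <= config$n_disease_pathways) {
        size <- sample_size(max(config$pathway_size_range[1L],
                                config$n_disease_genes),
                            config$pathway_size_range[2L])
        fill <- sample(setdiff(genes, disease_genes),
                       size - config$n_disease_genes)
        sort(c(disease_genes, fill))
      } else {
        size <- sample_size(config$pathway_size_range[1L],
                            config$pathway_size_range[2L])
        sort(sample(genes, size))
      }
    })
  })
  names(pathways) <- pathway_names
  collection <- gene_set_collection(pathways)

  dp_pool <- sort(unique(unlist(pathways[disease_pathways], use.names = FALSE)))
  chem_ids <- sprintf("CHEM%04d", seq_len(config$n_chemicals))
  positives <- chem_ids[seq_len(config$n_positive_chemicals)]
  chems <- with_seed(derive_seed(config$seed, "chemicals"), {
    lapply(seq_len(config$n_chemicals), function(i) {
      size <- sample_size(config$chemical_genes_range[1L],
                          config$chemical_genes_range[2L])
      if (i <= config$n_positive_chemicals) {
        n_sig <- min(round(config$signal_strength * size), length(dp_pool))
        sig <- if (n_sig > 0) sample(dp_pool, n_sig) else character(0)
        bg <- sample(setdiff(genes, sig), size - n_sig)
        sort(c(sig, bg))
      } else {
        sort(sample(genes, size))
      }
    })
  })
  names(chems) <- chem_ids
  chemical_table <- chemical_gene_table(chems)

  mouse <- mouse_symbol(genes)
  homologs <- homolog_map(stats::setNames(as.list(mouse), genes))
  mouse_disease <- mouse_symbol(disease_genes)
  n_seeded_phen <- max(1L, ceiling(config$n_phenotypes / 10))
  annotations <- with_seed(derive_seed(config$seed, "phenotypes"), {
    ann <- lapply(seq_len(config$n_phenotypes), function(i) {
      size <- sample_size(config$pathway_size_range[1L],
                          config$pathway_size_range[2L])
      if (i <= n_seeded_phen) {
        size <- max(size, config$n_disease_genes)
        fill <- sample(setdiff(mouse, mouse_disease),
                       size - length(mouse_disease))
        sort(c(mouse_disease, fill))
      } else {
        sort(sample(mouse, size))
      }
    })
    names(ann) <- sprintf("phenotype %03d", seq_len(config$n_phenotypes))
    ann
  })
  annotations <- phenotype_annotation_table(annotations)

  known <- known_positive_list(
    positives,
    positive_categories[(seq_along(positives) - 1L) %%
                          length(positive_categories) + 1L])

  list(collection = collection,
       chemical_table = chemical_table,
       disease_genes = gene_set("disease", disease_genes),
       annotations = annotations,
       homologs = homologs,
       known_positives = known,
       ground_truth = list(positive_chemicals = positives,
                           disease_pathways = disease_pathways),
       config = config)
}

#' Write a synthetic universe to disk
#'
#' Emits the six pipeline inputs plus the ground truth, all as plain text
#' (GMT and TSV), and a manifest recording the configuration and seed.
#' Files written through this function re-read through the data_io readers
#' into objects equal to the in-memory originals.
#'
#' @param universe output of [generate_universe()].
#' @param directory output directory (created if needed).
#' @return character vector of the 7 data files written (the manifest is
#'   written alongside), invisibly.
#' @export
write_universe <- function(universe, directory) {
  dir.create(directory, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(directory, f)
  write_gene_set_collection(universe$collection, p("pathways.gmt"))
  write_chemical_gene_table(universe$chemical_table, p("chemical_genes.tsv"))
  writeLines(universe$disease_genes$genes, p("disease_genes.txt"))
  ann <- universe$annotations$annotations
  utils::write.table(
    data.frame(gene = unlist(ann, use.names = FALSE),
               phenotype = rep(names(ann), lengths(ann))),
    p("phenotype_annotations.tsv"), sep = "\t", quote = FALSE,
    row.names = FALSE)
  hm <- universe$homologs$pairs
  utils::write.table(
    data.frame(human_gene = rep(names(hm), lengths(hm)),
               mouse_gene = unlist(hm, use.names = FALSE)),
    p("homolog_map.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  write_known_positives(universe$known_positives, p("known_positives.tsv"))
  gt <- universe$ground_truth
  utils::write.table(
    data.frame(kind = c(rep("positive_chemical", length(gt$positive_chemicals)),
                        rep("disease_pathway", length(gt$disease_pathways))),
               id = c(gt$positive_chemicals, gt$disease_pathways)),
    p("ground_truth.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  files <- c("pathways.gmt", "chemical_genes.tsv", "disease_genes.txt",
             "phenotype_annotations.tsv", "homolog_map.tsv",
             "known_positives.tsv", "ground_truth.tsv")
  cfg <- universe$config
  manifest <- c(
    sprintf("file\t%s", files),
    sprintf("config.%s\t%s", names(unclass(cfg)),
            vapply(unclass(cfg), function(v) paste(v, collapse = ","), "")))
  writeLines(c("key\tvalue", manifest), p("manifest.tsv"))
  invisible(file.path(directory, files))
}
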