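#' Position-based rank score
#'
#' Converts a feature's position within a profile (1 = most significant)
#' into a score in (0, 1] where larger is better: the top feature of a
#' profile of size N scores 1, the bottom feature 1/N. These oriented
#' scores feed the harmonic combined ranking, which then rewards features
#' only when they stand high in \emph{both} profiles.
#'
#' @param position integer position, 1-based.
#' @param profile_size number of features in the profile.
#' @return \code{(profile_size - position + 1) / profile_size}.
#' @export
rank_score <- function(position, profile_size) {
  if (any(profile_size < 1) || any(position < 1) || any(position > profile_size)) {
    stop("position must lie in [1, profile_size]", call. = FALSE)
  }
  (profile_size - position + 1) / profile_size
}

#' Harmonic combined ranking of a shared feature
#'
#' \deqn{ranking_{combined} = \frac{2\, ranking_d\, ranking_m}{ranking_d + ranking_m}}
#'
#' The harmonic mean of the disease-side and metabolite-side rank scores:
#' symmetric, bounded by its two arguments, equal to them when they agree,
#' and high only when both are high.
#'
#' @param ranking_d rank score from the disease profile, in (0, 1].
#' @param ranking_m rank score from the metabolite profile, in (0, 1].
#' @return combined rank score in (0, 1].
#' @export
combined_ranking <- function(ranking_d, ranking_m) {
  if (any(ranking_d <= 0) || any(ranking_m <= 0)) {
    stop("rank scores must be positive", call. = FALSE)
  }
  2 * (ranking_d * ranking_m) / (ranking_d + ranking_m)
}

new_shared_features <- function(df, n_disease, kind) {
  structure(df,
            n_shared = nrow(df),
            n_disease_features = n_disease,
            shared_fraction = if (n_disease > 0) 100 * nrow(df) / n_disease else NA_real_,
            kind = kind,
            class = c("shared_features", "data.frame"))
}

#' Prioritize pathways shared by a disease and a metabolite profile
#'
#' Intersects the two profiles' feature sets and scores every shared
#' feature by the harmonic mean of its [rank_score()] in each profile, so
#' a feature ranks highly if and only if it ranks highly for both the
#' metabolite and the disease. The shared fraction is reported relative to
#' the disease profile.
#'
#' @param profile_d disease \code{molecular_profile} (non-empty).
#' @param profile_m metabolite \code{molecular_profile} (non-empty).
#' @return object of class \code{shared_features}: data.frame with columns
#'   \code{feature}, \code{ranking_d}, \code{ranking_m},
#'   \code{ranking_combined}, sorted by descending combined score (ties by
#'   feature name), with attributes \code{n_shared},
#'   \code{n_disease_features} and \code{shared_fraction} (percent of the
#'   disease profile shared).
#' @export
shared_pathways <- function(profile_d, profile_m) {
  stopifnot(inherits(profile_d, "molecular_profile"),
            inherits(profile_m, "molecular_profile"))
  nd <- length(profile_d$feature_names)
  nm <- length(profile_m$feature_names)
  if (nd == 0L || nm == 0L) {
    stop("both profiles must be non-empty", call. = FALSE)
  }
  shared <- intersect(profile_d$feature_names, profile_m$feature_names)
  if (length(shared) == 0L) {
    mp_log("no shared features between '", profile_d$entity, "' and '",
           profile_m$entity, "'")
    df <- data.frame(feature = character(), ranking_d = numeric(),
                     ranking_m = numeric(), ranking_combined = numeric(),
                     stringsAsFactors = FALSE)
    return(new_shared_features(df, nd, "pathway"))
  }
  pos_d <- match(shared, profile_d$features$feature)
  pos_m <- match(shared, profile_m$features$feature)
  rd <- rank_score(pos_d, nd)
  rm_ <- rank_score(pos_m, nm)
  df <- data.frame(feature = shared, ranking_d = rd, ranking_m = rm_,
                   ranking_combined = combined_ranking(rd, rm_),
                   stringsAsFactors = FALSE)
  df <- df[order(-df$ranking_combined, df$feature), , drop = FALSE]
  rownames(df) <- NULL
  new_shared_features(df, nd, "pathway")
}

#' @export
print.shared_features <- function(x, n = 10, ...) {
  frac <- attr(x, "shared_fraction")
  digits <- if (identical(attr(x, "kind"), "phenotype")) 0 else 1
  cat("<shared_features> ", attr(x, "n_shared"), " of ",
      attr(x, "n_disease_features"), " disease ", attr(x, "kind"),
      "s shared (", format(round_half_away(frac, digits),
                           nsmall = digits), "%)\n", sep = "")
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n")
  invisible(x)
}

#' Write shared features as TSV with a summary line
#' @param shared a \code{shared_features} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_shared_features <- function(shared, path) {
  df <- as.data.frame(shared)
  for (cc in c("ranking_d", "ranking_m", "ranking_combined")) {
    df[[cc]] <- fmt6(df[[cc]])
  }
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# shared: %d of %d disease features (%s%%)",
                     attr(shared, "n_shared"),
                     attr(shared, "n_disease_features"),
                     fmt6(attr(shared, "shared_fraction"))), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map human genes onto mouse phenotype gene sets
#'
#' Translates human query genes to mouse homologs (collapsing duplicates)
#' and pairs them with the mouse mutational-phenotype annotation table
#' turned into a [gene_set_collection()] over mouse genes, the inputs for
#' phenotype-profile enrichment. Human genes with no homolog entry are
#' dropped and counted.
#'
#' @param genes a human [gene_set()].
#' @param homologs a [homolog_map()].
#' @param annotations a [phenotype_annotation_table()].
#' @return list with \code{query} (mouse [gene_set()]),
#'   \code{collection} (phenotype [gene_set_collection()]) and
#'   \code{n_unmapped} (human genes without a homolog).
#' @export
map_genes_to_phenotype_sets <- function(genes, homologs, annotations) {
  stopifnot(inherits(genes, "gene_set"),
            inherits(homologs, "homolog_map"),
            inherits(annotations, "phenotype_annotation_table"))
  hit <- genes$genes %in% names(homologs$pairs)
  n_unmapped <- sum(!hit)
  if (n_unmapped > 0) {
    mp_log(n_unmapped, " human gene(s) without a mouse homolog dropped")
  }
  mouse <- sort(unique(unlist(homologs$pairs[genes$genes[hit]],
                              use.names = FALSE)))
  if (length(mouse) == 0L) {
    stop("no query gene maps to any mouse gene", call. = FALSE)
  }
  collection <- gene_set_collection(annotations$annotations, normalize = "none")
  list(query = gene_set(genes$name, mouse, normalize = "none"),
       collection = collection,
       n_unmapped = n_unmapped)
}

#' Prioritize mouse phenotypes shared by a disease and a metabolite
#'
#' Builds a mutational-phenotype profile for the disease gene set and for
#' the metabolite gene set (human genes mapped to mouse homologs, then
#' resampling enrichment over the phenotype annotation collection),
#' intersects the two profiles, and applies the harmonic combined ranking
#' exactly as [shared_pathways()]. The shared fraction is relative to the
#' disease phenotype profile.
#'
#' @param disease_genes human [gene_set()] of disease-associated genes.
#' @param metabolite_genes human [gene_set()] of metabolite-associated genes.
#' @param homologs a [homolog_map()].
#' @param annotations a [phenotype_annotation_table()].
#' @inheritParams build_profile
#' @return a \code{shared_features} object (kind \code{"phenotype"}).
#' @export
shared_phenotypes <- function(disease_genes, metabolite_genes, homologs,
                              annotations, alpha = 0.05, n_resamples = 1000,
                              seed = 1) {
  md <- map_genes_to_phenotype_sets(disease_genes, homologs, annotations)
  mm <- map_genes_to_phenotype_sets(metabolite_genes, homologs, annotations)
  prof_d <- build_profile(disease_genes$name, md$query, md$collection,
                          alpha = alpha, n_resamples = n_resamples,
                          seed = derive_seed(seed, disease_genes$name))
  prof_m <- build_profile(metabolite_genes$name, mm$query, mm$collection,
                          alpha = alpha, n_resamples = n_resamples,
                          seed = derive_seed(seed, metabolite_genes$name))
  out <- shared_pathways(prof_d, prof_m)
  attr(out, "kind") <- "phenotype"
  out
}
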