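#' Exact hypergeometric overlap tail probability
#'
#' Probability of observing at least \code{overlap} query genes inside a
#' feature when \code{query_size} genes are drawn without replacement from
#' a universe of \code{universe_size} genes of which \code{feature_size}
#' belong to the feature. This is the exact counterpart of the resampling
#' test in [enrich_feature()] and serves as its cross-check.
#'
#' @param overlap observed overlap count.
#' @param query_size number of query genes.
#' @param feature_size number of feature genes.
#' @param universe_size number of genes in the universe.
#' @return \eqn{P(X \ge overlap)} for \eqn{X} hypergeometric.
#' @export
hypergeometric_tail <- function(overlap, query_size, feature_size, universe_size) {
  if (overlap < 0 || overlap > min(query_size, feature_size) ||
      feature_size > universe_size || query_size > universe_size ||
      query_size < 0 || feature_size < 0) {
    stop("inconsistent sizes for hypergeometric tail", call. = FALSE)
  }
  stats::phyper(overlap - 1, feature_size, universe_size - feature_size,
                query_size, lower.tail = FALSE)
}

# Draw n_resamples random gene index sets of size k from 1..n.
# The sequence depends only on (seed, n, k, n_resamples) so that a profile
# built feature-by-feature and one built in bulk see identical nulls.
null_draws <- function(seed, n, k, n_resamples) {
  with_seed(seed, {
    m <- matrix(0L, nrow = k, ncol = n_resamples)
    for (j in seq_len(n_resamples)) m[, j] <- sample.int(n, k)
    m
  })
}

# p-value of the observed fraction scored against the resampled null
# distribution: t = (obs - mean)/sd with df = R - 1, one-sided towards
# enrichment. Degenerate null (sd = 0): p = 0 if obs exceeds the null
# mean, else 1.
null_p_value <- function(obs, null_mean, null_sd, n_resamples) {
  ifelse(null_sd == 0,
         ifelse(obs > null_mean, 0, 1),
         stats::pt((obs - null_mean) / null_sd, df = n_resamples - 1,
                   lower.tail = FALSE))
}

null_fold <- function(obs, null_mean) {
  ifelse(null_mean > 0, obs / null_mean, ifelse(obs > 0, Inf, 1))
}

#' Resampling enrichment of a query gene set in one feature
#'
#' The observed statistic is the fraction of query genes inside the
#' feature. Its null distribution is obtained by drawing
#' \code{n_resamples} gene sets of the same size uniformly without
#' replacement from the universe and recomputing the fraction for each
#' draw. The observed fraction is scored against this null sample with a
#' t-distributed standardized score (one-sided towards enrichment), and
#' fold enrichment is the observed fraction over the null mean fraction.
#'
#' @param query a [gene_set()]; genes outside the universe are dropped with
#'   a warning.
#' @param feature a [gene_set()] (or character vector of genes).
#' @param universe character vector of all annotatable genes.
#' @param n_resamples number of null draws (>= 2; default 1000).
#' @param seed integer seed for the null draws.
#' @return one-row data.frame with columns \code{feature},
#'   \code{overlap_count}, \code{observed_fraction},
#'   \code{null_mean_fraction}, \code{fold_enrichment}, \code{p_value}.
#' @export
enrich_feature <- function(query, feature, universe, n_resamples = 1000, seed = 1) {
  stopifnot(inherits(query, "gene_set"))
  if (n_resamples < 2) stop("n_resamples must be at least 2", call. = FALSE)
  fname <- if (inherits(feature, "gene_set")) feature$name else "feature"
  fgenes <- if (inherits(feature, "gene_set")) feature$genes else as.character(feature)
  universe <- sort(unique(universe))
  q <- intersect(query$genes, universe)
  if (length(q) < length(query$genes)) {
    warning(length(query$genes) - length(q),
            " query gene(s) outside the universe dropped", call. = FALSE)
  }
  k <- length(q)
  if (k == 0L) stop("no query genes in the universe", call. = FALSE)
  inf <- universe %in% fgenes
  obs_count <- sum(q %in% fgenes)
  obs <- obs_count / k
  draws <- null_draws(seed, length(universe), k, n_resamples)
  null_counts <- colSums(matrix(inf[draws], nrow = k))
  x <- null_counts / k
  m <- mean(x)
  s <- stats::sd(x)
  data.frame(feature = fname,
             overlap_count = obs_count,
             observed_fraction = obs,
             null_mean_fraction = m,
             fold_enrichment = null_fold(obs, m),
             p_value = null_p_value(obs, m, s, n_resamples),
             stringsAsFactors = FALSE)
}

new_molecular_profile <- function(entity, features, alpha, n_resamples,
                                  n_query_genes, status = "ok") {
  structure(list(entity = entity, features = features,
                 feature_names = features$feature, alpha = alpha,
                 n_resamples = n_resamples, n_query_genes = n_query_genes,
                 status = status),
            class = "molecular_profile")
}

empty_enrichment_frame <- function() {
  data.frame(feature = character(), overlap_count = integer(),
             observed_fraction = numeric(), null_mean_fraction = numeric(),
             fold_enrichment = numeric(), p_value = numeric(),
             rank = integer(), stringsAsFactors = FALSE)
}

#' Build the molecular profile of an entity
#'
#' Applies the resampling enrichment test to every feature of the
#' collection and retains features with \code{p_value < alpha} and
#' \code{fold_enrichment > 1}, ordered by ascending p-value, then
#' descending fold enrichment, then feature name. The null gene-set draws
#' are made once per entity (they depend only on the query size and the
#' universe) and shared across features, so the profile does not depend on
#' feature evaluation order; [enrich_feature()] with the same seed
#' reproduces any single row.
#'
#' @param entity identifier for the profiled entity.
#' @param genes a [gene_set()] (or character vector) of associated genes.
#' @param collection a [gene_set_collection()] of pathways or phenotypes.
#' @param alpha significance threshold (default 0.05).
#' @param n_resamples number of null draws (default 1000).
#' @param seed integer seed.
#' @param p_adjust multiple-testing correction applied before the alpha
#'   filter: \code{"none"} (default) or \code{"BH"}.
#' @return object of class \code{molecular_profile}. If no query gene is in
#'   the collection universe an empty profile with
#'   \code{status = "no_universe_overlap"} is returned with a warning.
#' @export
build_profile <- function(entity, genes, collection, alpha = 0.05,
                          n_resamples = 1000, seed = 1,
                          p_adjust = c("none", "BH")) {
  stopifnot(inherits(collection, "gene_set_collection"))
  p_adjust <- match.arg(p_adjust)
  if (n_resamples < 2) stop("n_resamples must be at least 2", call. = FALSE)
  if (!inherits(genes, "gene_set")) genes <- gene_set(entity, genes)
  universe <- collection$universe
  q <- intersect(genes$genes, universe)
  if (length(q) == 0L) {
    warning("entity '", entity, "': no genes overlap the collection universe; ",
            "returning an empty profile", call. = FALSE)
    return(new_molecular_profile(entity, empty_enrichment_frame(), alpha,
                                 n_resamples, 0L, "no_universe_overlap"))
  }
  res <- enrichment_table(q, collection, n_resamples, seed)
  p <- if (p_adjust == "BH") stats::p.adjust(res$p_value, "BH") else res$p_value
  keep <- p < alpha & res$fold_enrichment > 1
  res <- res[keep, , drop = FALSE]
  ord <- order(res$p_value, -res$fold_enrichment, res$feature)
  res <- res[ord, , drop = FALSE]
  res$rank <- seq_len(nrow(res))
  rownames(res) <- NULL
  new_molecular_profile(entity, res, alpha, n_resamples, length(q))
}

# Enrichment of a query (already inside the universe) against every
# feature at once. One sparse indicator matrix of the null draws
# multiplied by the gene x feature membership matrix yields all null
# overlap counts in a single product.
enrichment_table <- function(q, collection, n_resamples, seed) {
  universe <- collection$universe
  n <- length(universe)
  k <- length(q)
  fmat <- membership_matrix(collection)
  qidx <- match(q, universe)
  obs_counts <- as.integer(Matrix::colSums(fmat[qidx, , drop = FALSE]))
  obs <- obs_counts / k
  draws <- null_draws(seed, n, k, n_resamples)
  smat <- Matrix::sparseMatrix(i = rep(seq_len(n_resamples), each = k),
                               j = as.vector(draws), x = 1,
                               dims = c(n_resamples, n))
  counts <- as.matrix(smat %*% fmat) / k       # n_resamples x n_features
  m <- colMeans(counts)
  s <- sqrt(colSums(sweep(counts, 2, m)^2) / (n_resamples - 1))
  data.frame(feature = names(collection$sets),
             overlap_count = obs_counts,
             observed_fraction = obs,
             null_mean_fraction = m,
             fold_enrichment = null_fold(obs, m),
             p_value = null_p_value(obs, m, s, n_resamples),
             stringsAsFactors = FALSE, row.names = NULL)
}

# gene x feature sparse 0/1 membership matrix, cached on the collection
membership_matrix <- function(collection) {
  cached <- attr(collection, "membership_matrix")
  if (!is.null(cached)) return(cached)
  universe <- collection$universe
  sizes <- lengths(collection$sets)
  Matrix::sparseMatrix(
    i = match(unlist(collection$sets, use.names = FALSE), universe),
    j = rep(seq_along(sizes), sizes),
    x = 1,
    dims = c(length(universe), length(sizes)),
    dimnames = list(NULL, names(collection$sets)))
}

#' Build molecular profiles for every chemical in a table
#'
#' One profile per chemical. Each chemical gets its own reproducible
#' substream derived from \code{seed} and the chemical id, so the bulk
#' result for a chemical is identical to [build_profile()] run on that
#' chemical alone with [derive_seed()]\code{(seed, chemical_id)}, and is
#' unaffected by the other chemicals in the table.
#'
#' @param table a [chemical_gene_table()].
#' @param collection a [gene_set_collection()].
#' @inheritParams build_profile
#' @param progress_every log progress every this many chemicals (0 = silent).
#' @return named list of \code{molecular_profile} objects.
#' @export
build_profiles_bulk <- function(table, collection, alpha = 0.05,
                                n_resamples = 1000, seed = 1,
                                p_adjust = c("none", "BH"),
                                progress_every = 100) {
  stopifnot(inherits(table, "chemical_gene_table"))
  p_adjust <- match.arg(p_adjust)
  ids <- names(table$chemicals)
  if (length(ids) == 0L) stop("empty chemical-gene table", call. = FALSE)
  attr(collection, "membership_matrix") <- membership_matrix(collection)
  profiles <- vector("list", length(ids))
  names(profiles) <- ids
  for (i in seq_along(ids)) {
    profiles[[i]] <- withCallingHandlers(
      build_profile(ids[i], table$chemicals[[ids[i]]], collection,
                    alpha = alpha, n_resamples = n_resamples,
                    seed = derive_seed(seed, ids[i]), p_adjust = p_adjust),
      warning = function(w) invokeRestart("muffleWarning"))
    if (progress_every > 0 && i %% progress_every == 0) {
      mp_log("profiled ", i, "/", length(ids), " chemicals")
    }
  }
  profiles
}

#' @export
print.molecular_profile <- function(x, n = 6, ...) {
  cat("<molecular_profile> ", x$entity, ": ", nrow(x$features),
      " significant feature(s) of alpha=", x$alpha,
      ", ", x$n_resamples, " resamples, ", x$n_query_genes,
      " query genes in universe\n", sep = "")
  if (x$status != "ok") cat("  status: ", x$status, "\n", sep = "")
  if (nrow(x$features)) {
    print(utils::head(x$features[, c("feature", "overlap_count",
                                     "fold_enrichment", "p_value", "rank")], n),
          row.names = FALSE)
    if (nrow(x$features) > n) cat("  ... ", nrow(x$features) - n, " more\n")
  }
  invisible(x)
}

#' @export
summary.molecular_profile <- function(object, ...) {
  cat("Molecular profile of", object$entity, "\n")
  cat("  significant features:", nrow(object$features), "\n")
  cat("  alpha:", object$alpha, " resamples:", object$n_resamples, "\n")
  if (nrow(object$features)) {
    finite <- object$features$fold_enrichment[is.finite(object$features$fold_enrichment)]
    if (length(finite)) cat("  median fold enrichment:", stats::median(finite), "\n")
    cat("  top feature:", object$features$feature[1L], "\n")
  }
  invisible(object)
}

#' Write one or more molecular profiles as TSV
#'
#' Columns: entity, feature, overlap_count, fold_enrichment, p_value, rank;
#' floating point values with 6 significant digits.
#'
#' @param profiles a \code{molecular_profile} or list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_profiles <- function(profiles, path) {
  if (inherits(profiles, "molecular_profile")) profiles <- list(profiles)
  rows <- lapply(profiles, function(p) {
    if (nrow(p$features) == 0L) return(NULL)
    data.frame(entity = p$entity,
               feature = p$features$feature,
               overlap_count = p$features$overlap_count,
               fold_enrichment = fmt6(p$features$fold_enrichment),
               p_value = fmt6(p$features$p_value),
               rank = p$features$rank,
               stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, c(rows, list(
    data.frame(entity = character(), feature = character(),
               overlap_count = integer(), fold_enrichment = character(),
               p_value = character(), rank = integer(),
               stringsAsFactors = FALSE))))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
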