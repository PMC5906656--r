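#' Set-similarity measures on feature-name sets
#'
#' The three measures used to compare a chemical's molecular profile with
#' the disease profile, computed on the sets of significant feature names:
#' \itemize{
#'   \item overlap: \eqn{|A \cap B|}
#'   \item Jaccard: \eqn{|A \cap B| / |A \cup B|} (0 when both sets empty)
#'   \item cosine: \eqn{|A \cap B| / \sqrt{|A||B|}} on binary membership
#'     vectors (0 when either set is empty)
#' }
#'
#' @param A,B character vectors treated as sets (duplicates ignored).
#' @return a non-negative number; Jaccard and cosine lie in [0, 1].
#' @export
overlap_similarity <- function(A, B) {
  length(intersect(unique(A), unique(B)))
}

#' @rdname overlap_similarity
#' @export
jaccard_similarity <- function(A, B) {
  A <- unique(A); B <- unique(B)
  u <- length(union(A, B))
  if (u == 0L) return(0)
  length(intersect(A, B)) / u
}

#' @rdname overlap_similarity
#' @export
cosine_similarity <- function(A, B) {
  A <- unique(A); B <- unique(B)
  if (length(A) == 0L || length(B) == 0L) return(0)
  length(intersect(A, B)) / sqrt(length(A) * length(B))
}

similarity_fun <- function(measure) {
  switch(measure,
         overlap = overlap_similarity,
         jaccard = jaccard_similarity,
         cosine = cosine_similarity)
}

#' Rank chemicals by profile similarity to a disease profile
#'
#' Similarity is computed between the disease profile's feature-name set
#' and each chemical profile's feature-name set; chemicals with empty
#' profiles score 0. Chemicals are ordered by descending similarity with
#' ties broken by chemical id; tied similarities receive the average of
#' the rank positions they span, so the percentile (\code{100 * rank /
#' total}, smaller = better) is unbiased under full ties.
#'
#' @param disease_profile a non-empty \code{molecular_profile}.
#' @param profiles named list of \code{molecular_profile}s, one per chemical.
#' @param measure \code{"overlap"}, \code{"jaccard"} or \code{"cosine"}.
#' @return object of class \code{ranked_chemicals}: data.frame with columns
#'   \code{chemical}, \code{similarity}, \code{rank}, \code{percentile}.
#' @export
rank_chemicals <- function(disease_profile,
                           profiles,
                           measure = c("jaccard", "overlap", "cosine")) {
  measure <- match.arg(measure)
  stopifnot(inherits(disease_profile, "molecular_profile"))
  if (length(disease_profile$feature_names) == 0L) {
    stop("disease profile is empty; inspect build_profile() output ",
         "(alpha, resamples, gene/universe overlap) before ranking",
         call. = FALSE)
  }
  if (length(profiles) == 0L) stop("no chemical profiles to rank", call. = FALSE)
  f <- similarity_fun(measure)
  D <- disease_profile$feature_names
  sim <- vapply(profiles, function(p) f(D, p$feature_names), 0)
  r <- rank(-sim, ties.method = "average")
  n <- length(sim)
  out <- data.frame(chemical = names(profiles),
                    similarity = sim,
                    rank = r,
                    percentile = 100 * r / n,
                    stringsAsFactors = FALSE, row.names = NULL)
  out <- out[order(-out$similarity, out$chemical), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, measure = measure, disease = disease_profile$entity,
            class = c("ranked_chemicals", "data.frame"))
}

#' @export
print.ranked_chemicals <- function(x, n = 10, ...) {
  cat("<ranked_chemicals> ", nrow(x), " chemicals vs '",
      attr(x, "disease"), "' (", attr(x, "measure"), " similarity)\n", sep = "")
  print(utils::head(as.data.frame(x), n), row.names = FALSE)
  if (nrow(x) > n) cat("  ... ", nrow(x) - n, " more\n")
  invisible(x)
}

#' Write a ranked chemical list as TSV
#' @param ranked a \code{ranked_chemicals} object.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_ranked <- function(ranked, path) {
  df <- as.data.frame(ranked)
  df$similarity <- fmt6(df$similarity)
  df$percentile <- fmt6(df$percentile)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

new_evaluation_report <- function(n_found, n_known, percentiles, alternative) {
  p_value <- NA_real_
  if (n_found >= 2) {
    p_value <- if (stats::sd(percentiles) == 0) 1
               else stats::t.test(percentiles, mu = 50,
                                  alternative = alternative)$p.value
  }
  decile_counts <- as.integer(table(cut(percentiles, breaks = seq(0, 100, 10),
                                        right = TRUE)))
  structure(list(recall = n_found / n_known,
                 n_found = n_found,
                 n_known = n_known,
                 mean_percentile = if (n_found) mean(percentiles) else NA_real_,
                 median_percentile = if (n_found) stats::median(percentiles) else NA_real_,
                 p_value = p_value,
                 decile_counts = decile_counts,
                 percentiles = percentiles),
            class = "evaluation_report")
}

#' Evaluate a ranking against known positives
#'
#' Recall is the fraction of known chemicals present anywhere in the ranked
#' list (coverage-limited); mean and median percentile summarize how highly
#' the found positives rank (random expectation: 50\%); the p-value is a
#' one-sample t-test of the found percentiles against 50 (two-sided by
#' default); decile counts histogram the found percentiles over (0,10],
#' (10,20], ..., (90,100].
#'
#' @param ranked a \code{ranked_chemicals} object.
#' @param known a [known_positive_list()].
#' @param alternative \code{"two.sided"} (default) or \code{"less"} for a
#'   one-sided test of ranking better than chance.
#' @return object of class \code{evaluation_report}.
#' @export
evaluate_known <- function(ranked, known, alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(ranked, "ranked_chemicals"), nrow(ranked) > 0)
  if (!inherits(known, "known_positive_list")) known <- known_positive_list(known)
  hit <- match(known$chemical, ranked$chemical)
  found <- which(!is.na(hit))
  if (length(found) == 0L) {
    stop("none of the ", nrow(known), " known chemicals appear in the ranked ",
         "list; no statistics computable", call. = FALSE)
  }
  new_evaluation_report(length(found), nrow(known),
                        ranked$percentile[hit[found]], alternative)
}

#' Stratified evaluation by known-positive category
#'
#' [evaluate_known()] applied per category label; categories with no found
#' member are reported with recall 0 and no rank statistics.
#'
#' @inheritParams evaluate_known
#' @return named list of \code{evaluation_report}s, one per category.
#' @export
evaluate_stratified <- function(ranked, known,
                                alternative = c("two.sided", "less")) {
  alternative <- match.arg(alternative)
  stopifnot(inherits(known, "known_positive_list"))
  cats <- unique(known$category[nzchar(known$category)])
  if (length(cats) == 0L) {
    stop("no category labels in the known-positive list", call. = FALSE)
  }
  reports <- lapply(cats, function(cc) {
    sub <- known[known$category == cc, , drop = FALSE]
    hit <- match(sub$chemical, ranked$chemical)
    found <- which(!is.na(hit))
    if (length(found) == 0L) {
      new_evaluation_report(0L, nrow(sub), numeric(0), alternative)
    } else {
      new_evaluation_report(length(found), nrow(sub),
                            ranked$percentile[hit[found]], alternative)
    }
  })
  names(reports) <- cats
  reports
}

#' @export
print.evaluation_report <- function(x, ...) {
  cat("<evaluation_report> ", x$n_found, " of ", x$n_known,
      " known chemicals found\n", sep = "")
  cat(sprintf("  Recall: %.3f\n", round_half_away(x$recall, 3)))
  if (x$n_found > 0) {
    cat(sprintf("  Mean ranking (top %%):   %.2f%%\n", x$mean_percentile))
    cat(sprintf("  Median ranking (top %%): %.2f%%\n", x$median_percentile))
    cat("  P-value: ",
        if (is.na(x$p_value)) "NA (needs >= 2 found)" else
          format(x$p_value, digits = 3), "\n", sep = "")
    cat("  Decile counts (top 10% ... bottom 10%):",
        paste(x$decile_counts, collapse = " "), "\n")
  }
  invisible(x)
}

#' Write an evaluation report (or a stratified list of them) as TSV
#'
#' Mirrors the columns Recall, Mean Ranking (top \%), Median ranking
#' (top \%), P-value, plus found/known counts and the 10 decile counts.
#'
#' @param report an \code{evaluation_report} or named list of them.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_evaluation <- function(report, path) {
  if (inherits(report, "evaluation_report")) report <- list(all = report)
  rows <- lapply(names(report), function(nm) {
    r <- report[[nm]]
    data.frame(category = nm,
               recall = sprintf("%.3f", round_half_away(r$recall, 3)),
               n_found = r$n_found, n_known = r$n_known,
               mean_percentile = fmt6(r$mean_percentile),
               median_percentile = fmt6(r$median_percentile),
               p_value = fmt6(r$p_value),
               deciles = paste(r$decile_counts, collapse = ","),
               stringsAsFactors = FALSE)
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
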