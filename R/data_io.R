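#' Read a gene-set collection from a GMT file
#'
#' GMT is the MSigDB carrier format: one feature per line, tab-separated
#' \code{name<TAB>description<TAB>gene1<TAB>gene2...}. Gene symbols are
#' uppercased (human convention) unless \code{normalize = "none"} (mouse
#' phenotype collections); duplicates within a line are removed.
#'
#' @param path GMT file path.
#' @param normalize symbol normalization, see [gene_set()].
#' @return a [gene_set_collection()].
#' @export
read_gene_set_collection <- function(path, normalize = c("upper", "none")) {
  normalize <- match.arg(normalize)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("empty GMT file: ", path, call. = FALSE)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(fields) < 3L)
  if (length(bad)) {
    stop("malformed GMT line ", bad[1L], " (fewer than 3 tab-separated fields) in ",
         path, call. = FALSE)
  }
  sets <- lapply(fields, function(f) f[-(1:2)])
  names(sets) <- vapply(fields, `[[`, "", 1L)
  gene_set_collection(sets, normalize = normalize)
}

#' Write a gene-set collection to a GMT file
#'
#' @param collection a [gene_set_collection()].
#' @param path output path.
#' @param descriptions optional named character vector of descriptions;
#'   defaults to \code{"na"}.
#' @return \code{path}, invisibly.
#' @export
write_gene_set_collection <- function(collection, path, descriptions = NULL) {
  stopifnot(inherits(collection, "gene_set_collection"))
  nm <- names(collection$sets)
  desc <- rep("na", length(nm))
  if (!is.null(descriptions)) {
    hit <- nm %in% names(descriptions)
    desc[hit] <- descriptions[nm[hit]]
  }
  lines <- vapply(seq_along(nm), function(i) {
    paste(c(nm[i], desc[i], collection$sets[[i]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Read a chemical-gene association table
#'
#' STITCH-style TSV with a header and columns \code{chemical_id},
#' \code{gene}, and optionally \code{score} (STITCH confidence, 0-1000).
#' Pairs scoring below \code{score_cutoff} are dropped before grouping;
#' the default keeps everything.
#'
#' @param path TSV path.
#' @param score_cutoff minimum confidence score to keep a pair (default 0).
#' @return a [chemical_gene_table()].
#' @export
read_chemical_gene_table <- function(path, score_cutoff = 0) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  need <- c("chemical_id", "gene")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) return(chemical_gene_table(list()))
  if ("score" %in% names(df)) {
    score <- suppressWarnings(as.numeric(df$score))
    if (anyNA(score)) {
      stop("non-numeric score at data row ", which(is.na(score))[1L],
           " of ", path, call. = FALSE)
    }
    df <- df[score >= score_cutoff, , drop = FALSE]
  } else if (score_cutoff > 0) {
    stop("score_cutoff > 0 but ", path, " has no score column", call. = FALSE)
  }
  if (nrow(df) == 0L) return(chemical_gene_table(list()))
  chemical_gene_table(split(df$gene, df$chemical_id))
}

#' Write a chemical-gene table as TSV
#'
#' @param table a [chemical_gene_table()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_chemical_gene_table <- function(table, path) {
  stopifnot(inherits(table, "chemical_gene_table"))
  df <- data.frame(
    chemical_id = rep(names(table$chemicals), lengths(table$chemicals)),
    gene = unlist(table$chemicals, use.names = FALSE),
    stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a known-positive metabolite list
#'
#' TSV with columns \code{chemical_id} and optionally \code{category};
#' file order is preserved.
#'
#' @param path TSV path.
#' @return a [known_positive_list()].
#' @export
read_known_positives <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.delim(path, header = TRUE, colClasses = "character",
                          check.names = FALSE)
  if (!"chemical_id" %in% names(df)) {
    stop("missing mandatory column 'chemical_id' in ", path, call. = FALSE)
  }
  known_positive_list(df$chemical_id,
                      if ("category" %in% names(df)) df$category else NULL)
}

#' Write a known-positive list as TSV
#' @param known a [known_positive_list()].
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_known_positives <- function(known, path) {
  stopifnot(inherits(known, "known_positive_list"))
  df <- as.data.frame(known)
  names(df) <- c("chemical_id", "category")
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# shared two-column TSV reader with per-line validation
read_two_column_tsv <- function(path, col1, col2) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path)
  if (length(lines) <= 1L || all(!nzchar(lines[-1L]))) {
    stop("empty file (no data rows): ", path, call. = FALSE)
  }
  header <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  miss <- setdiff(c(col1, col2), header)
  if (length(miss)) {
    stop("missing mandatory column(s) in ", path, ": ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  i1 <- match(col1, header); i2 <- match(col2, header)
  rows <- which(nzchar(lines))[-1L]
  fields <- strsplit(lines[rows], "\t", fixed = TRUE)
  ok <- lengths(fields) >= max(i1, i2)
  v1 <- ifelse(ok, vapply(fields, function(f) f[min(i1, length(f))], ""), "")
  v2 <- ifelse(ok, vapply(fields, function(f) f[min(i2, length(f))], ""), "")
  bad <- which(!ok | !nzchar(trimws(v1)) | !nzchar(trimws(v2)))
  if (length(bad)) {
    stop("malformed row at line ", rows[bad[1L]], " of ", path,
         " (blank or missing field)", call. = FALSE)
  }
  data.frame(a = trimws(v1), b = trimws(v2), stringsAsFactors = FALSE)
}

#' Read mouse gene-phenotype annotations
#'
#' TSV with columns \code{gene} (mouse symbol, case-sensitive) and
#' \code{phenotype}; rows are grouped into one gene set per phenotype.
#'
#' @param path TSV path.
#' @return a [phenotype_annotation_table()].
#' @export
read_phenotype_annotations <- function(path) {
  df <- read_two_column_tsv(path, "gene", "phenotype")
  phenotype_annotation_table(split(df$a, df$b))
}

#' Read a human-to-mouse homolog map
#'
#' TSV with columns \code{human_gene} and \code{mouse_gene}; one human
#' symbol may map to several mouse symbols.
#'
#' @param path TSV path.
#' @return a [homolog_map()].
#' @export
read_homolog_map <- function(path) {
  df <- read_two_column_tsv(path, "human_gene", "mouse_gene")
  homolog_map(split(df$b, toupper(df$a)))
}

#' Read a plain disease gene list
#'
#' One human gene symbol per line; blank lines and \code{#} comments are
#' ignored.
#'
#' @param path text file path.
#' @param name identifier for the resulting set (default the file name).
#' @return a [gene_set()].
#' @export
read_gene_list <- function(path, name = basename(path)) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0L) stop("no gene symbols in ", path, call. = FALSE)
  gene_set(name, lines)
}
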