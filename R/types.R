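#' Create a gene set
#'
#' A named set of gene symbols. Human symbols (HGNC convention) are
#' normalized to uppercase; mouse symbols (MGI convention, mixed case)
#' are kept verbatim with \code{normalize = "none"}.
#'
#' @param name identifier of the set.
#' @param genes character vector of gene symbols.
#' @param normalize \code{"upper"} (default, human) or \code{"none"} (mouse).
#' @return object of class \code{gene_set}: list with \code{name} and
#'   \code{genes} (unique, whitespace-free symbols).
#' @export
gene_set <- function(name, genes, normalize = c("upper", "none")) {
  normalize <- match.arg(normalize)
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  genes <- as.character(genes)
  if (normalize == "upper") genes <- toupper(genes)
  genes <- unique(genes)
  if (length(genes) == 0L) {
    stop("gene set '", name, "' is empty", call. = FALSE)
  }
  if (any(!nzchar(genes)) || any(grepl("[[:space:]]", genes))) {
    stop("gene set '", name, "' contains empty or whitespace-bearing symbols",
         call. = FALSE)
  }
  structure(list(name = name, genes = genes), class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat("<gene_set> ", x$name, ": ", length(x$genes), " genes\n", sep = "")
  invisible(x)
}

#' Create a gene-set collection
#'
#' A collection of named features (pathways or mutational phenotypes), each
#' holding a set of gene symbols. The gene universe is the union of all
#' member sets and is stored sorted so that resampling from it is
#' reproducible regardless of input order.
#'
#' @param sets named list of character vectors (feature name -> genes).
#' @param normalize symbol normalization passed to [gene_set()].
#' @return object of class \code{gene_set_collection}: list with \code{sets}
#'   (named list of sorted unique symbol vectors) and \code{universe}.
#' @export
gene_set_collection <- function(sets, normalize = c("upper", "none")) {
  normalize <- match.arg(normalize)
  if (length(sets) == 0L) stop("collection has no sets", call. = FALSE)
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every set must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  sets <- lapply(nm, function(n) sort(gene_set(n, sets[[n]], normalize)$genes))
  names(sets) <- nm
  structure(list(sets = sets, universe = sort(unique(unlist(sets, use.names = FALSE)))),
            class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  sz <- lengths(x$sets)
  cat("<gene_set_collection> ", length(x$sets), " sets over ",
      length(x$universe), " genes (set sizes ", min(sz), "-", max(sz), ")\n",
      sep = "")
  invisible(x)
}

#' Create a chemical-gene association table
#'
#' Bipartite mapping from chemical identifiers to their associated human
#' genes, the STITCH-style input of the prioritization pipeline.
#'
#' @param chemicals named list: chemical id -> character vector of gene
#'   symbols (uppercased, deduplicated).
#' @return object of class \code{chemical_gene_table}.
#' @export
chemical_gene_table <- function(chemicals) {
  nm <- names(chemicals)
  if (length(chemicals) && (is.null(nm) || any(!nzchar(nm)))) {
    stop("every chemical must have an id", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate chemical id(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "), call. = FALSE)
  }
  chemicals <- lapply(chemicals, function(g) {
    g <- unique(toupper(as.character(g)))
    if (length(g) == 0L) stop("chemical with no genes", call. = FALSE)
    sort(g)
  })
  names(chemicals) <- nm
  structure(list(chemicals = chemicals), class = "chemical_gene_table")
}

#' @export
print.chemical_gene_table <- function(x, ...) {
  cat("<chemical_gene_table> ", length(x$chemicals), " chemicals, ",
      sum(lengths(x$chemicals)), " chemical-gene pairs\n", sep = "")
  invisible(x)
}

#' Create a phenotype annotation table
#'
#' Mouse mutational-phenotype annotations: phenotype name -> set of mouse
#' gene symbols (MGD-style). Mouse symbols are case-sensitive.
#'
#' @param annotations named list: phenotype -> character vector of mouse genes.
#' @return object of class \code{phenotype_annotation_table}.
#' @export
phenotype_annotation_table <- function(annotations) {
  nm <- names(annotations)
  if (length(annotations) == 0L) stop("no phenotype annotations", call. = FALSE)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every phenotype must be named", call. = FALSE)
  }
  if (anyDuplicated(nm)) {
    stop("duplicate phenotype name(s)", call. = FALSE)
  }
  annotations <- lapply(annotations, function(g) {
    g <- unique(as.character(g))
    if (length(g) == 0L) stop("phenotype with no genes", call. = FALSE)
    sort(g)
  })
  names(annotations) <- nm
  structure(list(annotations = annotations),
            class = "phenotype_annotation_table")
}

#' @export
print.phenotype_annotation_table <- function(x, ...) {
  cat("<phenotype_annotation_table> ", length(x$annotations), " phenotypes, ",
      sum(lengths(x$annotations)), " gene-phenotype associations\n", sep = "")
  invisible(x)
}

#' Create a human-to-mouse homolog map
#'
#' One-to-many mapping from human gene symbols (uppercased) to mouse gene
#' symbols (verbatim case).
#'
#' @param pairs named list: human symbol -> character vector of mouse symbols.
#' @return object of class \code{homolog_map}.
#' @export
homolog_map <- function(pairs) {
  nm <- names(pairs)
  if (length(pairs) == 0L) stop("empty homolog map", call. = FALSE)
  if (is.null(nm) || any(!nzchar(nm))) {
    stop("every human gene must be named", call. = FALSE)
  }
  names(pairs) <- toupper(nm)
  pairs <- lapply(pairs, function(m) {
    m <- unique(as.character(m))
    if (length(m) == 0L) stop("human gene with no mouse homolog", call. = FALSE)
    sort(m)
  })
  # collapse duplicate human symbols created by case-folding
  pairs <- tapply(pairs, names(pairs), function(x) sort(unique(unlist(x))),
                  simplify = FALSE)
  structure(list(pairs = pairs[order(names(pairs))]), class = "homolog_map")
}

#' @export
print.homolog_map <- function(x, ...) {
  cat("<homolog_map> ", length(x$pairs), " human genes -> ",
      length(unique(unlist(x$pairs))), " mouse genes\n", sep = "")
  invisible(x)
}

#' Create a known-positive metabolite list
#'
#' Chemicals with literature support for disease association, optionally
#' labelled with a category (e.g. SCFAs, bile acids) for stratified
#' evaluation.
#'
#' @param chemical character vector of chemical ids (unique).
#' @param category optional character vector of category labels (recycled
#'   empty string when absent).
#' @return object of class \code{known_positive_list}: data.frame with
#'   columns \code{chemical} and \code{category}, in input order.
#' @export
known_positive_list <- function(chemical, category = NULL) {
  chemical <- as.character(chemical)
  if (anyDuplicated(chemical)) {
    stop("duplicate chemical id(s) in known-positive list: ",
         paste(unique(chemical[duplicated(chemical)]), collapse = ", "),
         call. = FALSE)
  }
  if (is.null(category)) category <- rep("", length(chemical))
  category <- as.character(category)
  stopifnot(length(category) == length(chemical))
  structure(data.frame(chemical = chemical, category = category,
                       stringsAsFactors = FALSE),
            class = c("known_positive_list", "data.frame"))
}

#' @export
print.known_positive_list <- function(x, ...) {
  ncat <- length(unique(x$category[nzchar(x$category)]))
  cat("<known_positive_list> ", nrow(x), " chemicals",
      if (ncat) paste0(", ", ncat, " categories"), "\n", sep = "")
  invisible(x)
}
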