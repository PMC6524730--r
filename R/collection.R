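#' Construct a pathway
#'
#' A pathway is treated throughout as a named gene set: an identifier, a
#' human-readable name, a source label (which database the annotation came
#' from, or \code{"merged"} after condensation), the set of member genes, and
#' a provenance list recording the ids of any pathways that were merged into
#' this one.
#'
#' Gene identifiers are opaque, case-sensitive text (symbols or numeric ids);
#' the only normalization applied is whitespace stripping. Duplicate genes are
#' collapsed.
#'
#' @param id Pathway identifier, unique within a collection.
#' @param genes Character vector of gene identifiers; duplicates are dropped.
#' @param name Human-readable pathway name (defaults to the id).
#' @param source Source label, e.g. the originating database.
#' @param provenance Character vector of ids of pathways merged into this one.
#' @return An object of class \code{"pathway"}.
#' @examples
#' pathway("P1", c("TP53", "EGFR"))
#' @export
pathway <- function(id, genes, name = id, source = "unknown",
                    provenance = character()) {
  id <- normalize_gene_ids(id)
  if (length(id) != 1L || !nzchar(id)) {
    stop("pathway id must be a single non-empty string", call. = FALSE)
  }
  genes <- unique(normalize_gene_ids(genes))
  if (any(!nzchar(genes))) {
    stop("gene identifiers must be non-empty", call. = FALSE)
  }
  provenance <- as.character(provenance)
  if (id %in% provenance) {
    stop("pathway provenance cannot include its own id: ", id, call. = FALSE)
  }
  structure(
    list(id = id, name = as.character(name)[1L], source = as.character(source)[1L],
         genes = genes, provenance = provenance),
    class = "pathway"
  )
}

#' @export
print.pathway <- function(x, ...) {
  cat("<pathway> ", x$id, " (", x$source, "): ", length(x$genes), " genes",
      sep = "")
  if (length(x$provenance)) {
    cat(", merged from", length(x$provenance), "pathways")
  }
  cat("\n")
  invisible(x)
}

# strip leading/trailing whitespace, keep case
normalize_gene_ids <- function(x) {
  trimws(as.character(x))
}

#' Construct a pathway collection
#'
#' An ordered list of pathways over a shared gene universe. The universe
#' defaults to the union of all member genes; it is the background population
#' for the Fisher's exact tests used by \code{\link{merge_decision}} and
#' \code{\link{enrich}}.
#'
#' @param pathways List of \code{\link{pathway}} objects with distinct ids.
#' @param universe Optional character vector of gene identifiers; must contain
#'   every pathway gene.
#' @return An object of class \code{"pathway_collection"}.
#' @examples
#' pathway_collection(list(pathway("P1", c("A", "B")), pathway("P2", "B")))
#' @export
pathway_collection <- function(pathways = list(), universe = NULL) {
  if (inherits(pathways, "pathway")) pathways <- list(pathways)
  stopifnot(is.list(pathways))
  for (p in pathways) {
    if (!inherits(p, "pathway")) {
      stop("all elements of `pathways` must be pathway objects", call. = FALSE)
    }
  }
  ids <- vapply(pathways, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  names(pathways) <- ids
  gene_union <- unique(unlist(lapply(pathways, `[[`, "genes"), use.names = FALSE))
  if (is.null(gene_union)) gene_union <- character()
  if (is.null(universe)) {
    universe <- gene_union
  } else {
    universe <- unique(normalize_gene_ids(universe))
    missing <- setdiff(gene_union, universe)
    if (length(missing)) {
      stop("universe is missing ", length(missing),
           " pathway gene(s), e.g. ", missing[1L], call. = FALSE)
    }
  }
  structure(list(pathways = pathways, universe = universe),
            class = "pathway_collection")
}

#' @export
length.pathway_collection <- function(x) length(x$pathways)

#' @export
print.pathway_collection <- function(x, ...) {
  sizes <- pathway_sizes(x)
  cat("<pathway_collection> ", length(x), " pathways, ",
      length(x$universe), " genes in universe\n", sep = "")
  if (length(x)) {
    cat("  gene-set sizes: min ", min(sizes), ", median ",
        stats::median(sizes), ", max ", max(sizes), "\n", sep = "")
  }
  invisible(x)
}

#' @export
`[.pathway_collection` <- function(x, i) {
  pathway_collection(x$pathways[i], universe = x$universe)
}

#' Pathway ids of a collection
#' @param x A \code{pathway_collection}.
#' @return Character vector of pathway ids, in collection order.
#' @export
pathway_ids <- function(x) {
  stopifnot(inherits(x, "pathway_collection"))
  names(x$pathways)
}

#' Gene-set sizes of a collection
#' @param x A \code{pathway_collection}.
#' @return Integer vector of gene counts, named by pathway id.
#' @export
pathway_sizes <- function(x) {
  stopifnot(inherits(x, "pathway_collection"))
  vapply(x$pathways, function(p) length(p$genes), integer(1))
}

# pathways x universe binary incidence matrix (dense; collections here are
# at most a few thousand pathways over ~1e4 genes)
incidence_matrix <- function(x) {
  stopifnot(inherits(x, "pathway_collection"))
  n <- length(x)
  m <- matrix(0L, nrow = n, ncol = length(x$universe),
              dimnames = list(pathway_ids(x), NULL))
  uni <- x$universe
  for (i in seq_len(n)) {
    m[i, match(x$pathways[[i]]$genes, uni)] <- 1L
  }
  m
}

# shared-gene count matrix (n x n), diagonal = set sizes
shared_count_matrix <- function(x) {
  inc <- incidence_matrix(x)
  tcrossprod(inc)
}
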