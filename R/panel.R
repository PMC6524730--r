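#' Rank genes by pathway participation
#'
#' Genes are ranked so that genes appearing in more pathways, and in smaller
#' pathways, come first: the sort key is (assay availability descending, when
#' assay annotations are supplied; number of containing pathways descending;
#' mean size of containing pathways ascending; gene id ascending). The result
#' is a deterministic total order.
#'
#' @param x A non-empty \code{\link{pathway_collection}}.
#' @param assays Optional assay-availability annotations: a data frame with a
#'   \code{gene} column (as from
#'   \code{\link{read_annotation_table}(kind = "assay")}) or a character
#'   vector of assayable gene ids. When given, assayable genes outrank
#'   non-assayable ones regardless of participation counts.
#' @return A data frame, one row per gene appearing in at least one pathway,
#'   in rank order: \code{gene}, \code{n_pathways}, \code{mean_pathway_size},
#'   \code{has_assay}.
#' @export
rank_genes <- function(x, assays = NULL) {
  stopifnot(inherits(x, "pathway_collection"))
  if (!length(x)) stop("cannot rank genes of an empty collection", call. = FALSE)
  genes <- unlist(lapply(x$pathways, `[[`, "genes"), use.names = FALSE)
  sizes <- rep(pathway_sizes(x), pathway_sizes(x))
  n_pathways <- tapply(sizes, genes, length)
  mean_size <- tapply(sizes, genes, mean)
  g <- names(n_pathways)
  has_assay <- if (is.null(assays)) {
    rep(FALSE, length(g))
  } else {
    assay_genes <- if (is.data.frame(assays)) assays$gene else as.character(assays)
    g %in% normalize_gene_ids(assay_genes)
  }
  ord <- order(if (is.null(assays)) rep(0L, length(g)) else !has_assay,
               -as.integer(n_pathways), as.numeric(mean_size), g)
  data.frame(gene = g[ord],
             n_pathways = as.integer(n_pathways)[ord],
             mean_pathway_size = as.numeric(mean_size)[ord],
             has_assay = has_assay[ord],
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Greedy minimal gene panel covering a collection
#'
#' Builds a gene panel such that every pathway contains at least one panel
#' gene. The default mode scans the static \code{\link{rank_genes}} order
#' once, collecting each gene that covers at least one not-yet-covered
#' pathway, and stops when all coverable pathways are covered. The adaptive
#' mode re-ranks at each step by residual coverage (classic greedy set
#' cover: pick the gene covering the most uncovered pathways, ties broken by
#' the static key then gene id); it carries the usual
#' \eqn{H_d}-approximation guarantee.
#'
#' Pathways with zero genes cannot be covered; they are reported in
#' \code{uncoverable} rather than raising an error.
#'
#' @inheritParams rank_genes
#' @param adaptive Use residual-coverage greedy instead of the static scan.
#' @return An object of class \code{"cover_result"}: \code{selected} (ordered
#'   gene ids), \code{covered} (named character vector mapping each non-empty
#'   pathway id to the selected gene that first covered it),
#'   \code{n_selected}, \code{uncoverable} (ids of zero-gene pathways),
#'   \code{new_per_gene} (pathways newly covered at each selection), and
#'   \code{adaptive}.
#' @export
greedy_cover <- function(x, assays = NULL, adaptive = FALSE) {
  stopifnot(inherits(x, "pathway_collection"))
  if (!length(x)) stop("cannot cover an empty collection", call. = FALSE)
  sizes <- pathway_sizes(x)
  uncoverable <- pathway_ids(x)[sizes == 0L]
  target_ids <- pathway_ids(x)[sizes > 0L]
  members <- lapply(x$pathways[target_ids], `[[`, "genes")
  ranking <- rank_genes(x, assays)

  covered <- stats::setNames(rep(NA_character_, length(target_ids)), target_ids)
  selected <- character()
  new_per_gene <- integer()
  gene_paths <- split(rep(target_ids, lengths(members)),
                      unlist(members, use.names = FALSE))
  if (!adaptive) {
    for (gi in seq_len(nrow(ranking))) {
      g <- ranking$gene[gi]
      ps <- gene_paths[[g]]
      newly <- ps[is.na(covered[ps])]
      if (length(newly)) {
        selected <- c(selected, g)
        new_per_gene <- c(new_per_gene, length(newly))
        covered[newly] <- g
      }
      if (!anyNA(covered)) break
    }
  } else {
    # residual-coverage greedy: ties broken by the static ranking position
    rank_pos <- stats::setNames(seq_len(nrow(ranking)), ranking$gene)
    repeat {
      left <- names(covered)[is.na(covered)]
      if (!length(left)) break
      gains <- vapply(gene_paths, function(ps) sum(ps %in% left), integer(1))
      best <- max(gains)
      if (best == 0L) break
      cand <- names(gains)[gains == best]
      g <- cand[order(rank_pos[cand])][1L]
      newly <- intersect(gene_paths[[g]], left)
      selected <- c(selected, g)
      new_per_gene <- c(new_per_gene, length(newly))
      covered[newly] <- g
    }
  }
  structure(list(selected = selected,
                 covered = covered,
                 n_selected = length(selected),
                 uncoverable = uncoverable,
                 new_per_gene = new_per_gene,
                 adaptive = adaptive),
            class = "cover_result")
}

#' @export
print.cover_result <- function(x, ...) {
  cat("<cover_result> ", x$n_selected, " genes cover ",
      length(x$covered), " pathways",
      if (x$adaptive) " (adaptive greedy)" else " (static-rank scan)",
      "\n", sep = "")
  if (length(x$uncoverable)) {
    cat("  uncoverable (zero-gene) pathways:",
        paste(x$uncoverable, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exhaustive minimum gene cover (small-instance oracle)
#'
#' Enumerates gene subsets in increasing size (and lexicographic order within
#' a size) and returns the first subset hitting every non-empty pathway —
#' a provably minimum-cardinality cover with lexicographic tie-breaking.
#' Only intended as a correctness oracle: refuses instances with more than
#' \code{max_genes} genes.
#'
#' @param x A non-empty \code{\link{pathway_collection}}.
#' @param max_genes Enumeration bound on the number of distinct genes
#'   (default 20).
#' @return A \code{"cover_result"} as in \code{\link{greedy_cover}}, with
#'   \code{adaptive = NA} and the \code{selected} genes sorted.
#' @export
brute_force_cover <- function(x, max_genes = 20L) {
  stopifnot(inherits(x, "pathway_collection"))
  if (!length(x)) stop("cannot cover an empty collection", call. = FALSE)
  sizes <- pathway_sizes(x)
  uncoverable <- pathway_ids(x)[sizes == 0L]
  target_ids <- pathway_ids(x)[sizes > 0L]
  members <- lapply(x$pathways[target_ids], `[[`, "genes")
  genes <- sort(unique(unlist(members, use.names = FALSE)))
  if (length(genes) > max_genes) {
    stop("exhaustive cover refuses instances with > ", max_genes,
         " genes (got ", length(genes), ")", call. = FALSE)
  }
  best <- NULL
  if (!length(target_ids)) best <- character()
  for (size in seq_len(length(genes))) {
    if (!is.null(best)) break
    combos <- utils::combn(genes, size, simplify = FALSE)
    for (combo in combos) {
      hit <- vapply(members, function(gs) any(combo %in% gs), logical(1))
      if (all(hit)) { best <- combo; break }
    }
  }
  if (is.null(best)) best <- genes  # unreachable: full gene set always covers
  covered <- vapply(members, function(gs) best[best %in% gs][1L], character(1))
  structure(list(selected = best,
                 covered = covered,
                 n_selected = length(best),
                 uncoverable = uncoverable,
                 new_per_gene = rep(NA_integer_, length(best)),
                 adaptive = NA),
            class = "cover_result")
}
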