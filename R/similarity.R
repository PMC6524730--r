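#' Gene-component similarity between two pathways
#'
#' The similarity score between two pathways is the number of genes they share
#' divided by the total number of unique genes they contain — the Jaccard
#' index of their gene sets. It is 1 exactly when the gene sets are equal and
#' 0 when they are disjoint; \code{1 - similarity} is a metric (the Jaccard
#' distance).
#'
#' @param a,b \code{\link{pathway}} objects, or plain character vectors of
#'   gene identifiers.
#' @return A single number in \code{[0, 1]}.
#' @examples
#' pathway_similarity(pathway("A", c("g1", "g2", "g3")),
#'                    pathway("B", c("g2", "g3", "g4")))  # 0.5
#' @export
pathway_similarity <- function(a, b) {
  ga <- if (inherits(a, "pathway")) a$genes else unique(normalize_gene_ids(a))
  gb <- if (inherits(b, "pathway")) b$genes else unique(normalize_gene_ids(b))
  set_jaccard(ga, gb)
}

set_jaccard <- function(ga, gb) {
  if (!length(ga) && !length(gb)) {
    stop("similarity is undefined for two empty gene sets", call. = FALSE)
  }
  shared <- length(intersect(ga, gb))
  shared / (length(ga) + length(gb) - shared)
}

# n x n Jaccard similarity matrix from shared counts; diag = 1
similarity_matrix <- function(x) {
  k <- shared_count_matrix(x)
  sizes <- diag(k)
  un <- outer(sizes, sizes, `+`) - k
  s <- k / un
  s[un == 0] <- NA_real_  # pairs of empty sets
  s
}

#' Collection-level redundancy and size statistics
#'
#' For each pathway, finds the best-matching other pathway by similarity
#' score, then summarises: the fraction of pathways with at least one complete
#' duplicate (best match exactly 1), the fraction with at least one close
#' match (best match strictly above \code{close_threshold}, i.e. sharing over
#' 90\% of genes at the default), and the distribution of gene-set sizes.
#'
#' @param x A \code{\link{pathway_collection}} with at least 2 pathways.
#' @param close_threshold Best-match similarity above which a pathway counts
#'   as having a close match (strict inequality). Default 0.9.
#' @param exclude_same_source If \code{TRUE}, a pathway's best match is
#'   restricted to pathways carrying a different source label. Default
#'   \code{FALSE}.
#' @return An object of class \code{"redundancy_stats"}: a list with
#'   \code{frac_exact_duplicate}, \code{frac_close_match},
#'   \code{size_histogram}, \code{frac_le5}, \code{frac_single_gene},
#'   \code{n_pathways}, and \code{best_match} (a data frame with one row per
#'   pathway: id, best-matching id, similarity).
#' @export
redundancy_stats <- function(x, close_threshold = 0.9,
                             exclude_same_source = FALSE) {
  stopifnot(inherits(x, "pathway_collection"))
  n <- length(x)
  if (n < 2L) {
    stop("redundancy statistics need at least 2 pathways", call. = FALSE)
  }
  s <- similarity_matrix(x)
  diag(s) <- NA_real_  # best match excludes self
  if (exclude_same_source) {
    src <- vapply(x$pathways, `[[`, character(1), "source")
    same <- outer(src, src, `==`)
    s[same] <- NA_real_
  }
  ids <- pathway_ids(x)
  best_s <- apply(s, 1L, function(row) {
    if (all(is.na(row))) NA_real_ else max(row, na.rm = TRUE)
  })
  best_id <- vapply(seq_len(n), function(i) {
    row <- s[i, ]
    if (all(is.na(row))) NA_character_ else ids[which.max(row)]
  }, character(1))

  sizes <- pathway_sizes(x)
  breaks <- c(0, 1, 2, 3, 4, 5, 10, 20, 50, 100, Inf)
  labels <- c("1", "2", "3", "4", "5", "6-10", "11-20", "21-50", "51-100",
              ">100")
  hist <- table(cut(sizes, breaks = breaks, labels = labels, right = TRUE))

  structure(list(
    frac_exact_duplicate = mean(best_s == 1, na.rm = TRUE),
    frac_close_match = mean(best_s > close_threshold, na.rm = TRUE),
    size_histogram = hist,
    frac_le5 = mean(sizes <= 5),
    frac_single_gene = mean(sizes == 1),
    n_pathways = n,
    close_threshold = close_threshold,
    exclude_same_source = exclude_same_source,
    best_match = data.frame(id = ids, best_match = best_id,
                            similarity = best_s, stringsAsFactors = FALSE,
                            row.names = NULL)
  ), class = "redundancy_stats")
}

#' @export
print.redundancy_stats <- function(x, ...) {
  cat("<redundancy_stats> over", x$n_pathways, "pathways\n")
  cat(sprintf("  with a complete duplicate:      %5.1f%%\n",
              100 * x$frac_exact_duplicate))
  cat(sprintf("  with a close match (s > %.2f):  %5.1f%%\n",
              x$close_threshold, 100 * x$frac_close_match))
  cat(sprintf("  with <=5 genes:                 %5.1f%%\n", 100 * x$frac_le5))
  cat(sprintf("  with a single gene:             %5.1f%%\n",
              100 * x$frac_single_gene))
  invisible(x)
}
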