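#' Gene-list pathway enrichment (Fisher's exact test)
#'
#' For each pathway, tests over-representation of the query gene list by the
#' one-sided Fisher's exact test: with a universe of \eqn{N} genes, a pathway
#' of \eqn{K} genes, a query of \eqn{m} genes and an overlap of \eqn{k}
#' genes, the p-value is the hypergeometric upper tail
#' \eqn{P(X \ge k)} for \eqn{X \sim \mathrm{Hypergeom}(N, K, m)}.
#' Benjamini-Hochberg q-values are computed across all pathways tested.
#'
#' Query genes absent from the universe are dropped with a warning and the
#' effective query size is reported; pathway genes outside the universe
#' (possible only with a user-supplied universe) are likewise not counted.
#'
#' @param query Character vector of gene identifiers.
#' @param x A \code{\link{pathway_collection}}.
#' @param universe Optional background gene set; defaults to the collection
#'   universe.
#' @return A data frame sorted by ascending p then pathway id, one row per
#'   pathway: \code{pathway_id}, \code{name}, \code{k}, \code{m}, \code{K},
#'   \code{N}, \code{p}, \code{q}, \code{genes} (the overlapping genes,
#'   \code{";"}-joined). The effective query size is in
#'   \code{attr(, "m_effective")} and the number of dropped query genes in
#'   \code{attr(, "n_dropped")}.
#' @examples
#' x <- pathway_collection(list(pathway("P1", c("A", "B", "C")),
#'                              pathway("P2", c("C", "D", "E", "F"))))
#' enrich(c("A", "B"), x)
#' @export
enrich <- function(query, x, universe = NULL) {
  stopifnot(inherits(x, "pathway_collection"))
  if (is.null(universe)) universe <- x$universe
  universe <- unique(normalize_gene_ids(universe))
  query <- unique(normalize_gene_ids(query))
  in_universe <- query %in% universe
  n_dropped <- sum(!in_universe)
  if (n_dropped) {
    warning(n_dropped, " query gene(s) not in the universe were dropped",
            call. = FALSE)
  }
  query <- query[in_universe]
  if (!length(query)) {
    stop("query is empty after intersecting with the universe", call. = FALSE)
  }
  N <- length(universe)
  m <- length(query)
  rows <- lapply(x$pathways, function(p) {
    pg <- intersect(p$genes, universe)
    hits <- intersect(query, pg)
    data.frame(pathway_id = p$id, name = p$name,
               k = length(hits), m = m, K = length(pg), N = N,
               p = hyper_tail_p(length(hits), length(pg), m, N),
               genes = paste(sort(hits), collapse = ";"),
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(rows, make.row.names = FALSE))
  res$q <- stats::p.adjust(res$p, method = "BH")
  res <- res[order(res$p, res$pathway_id),
             c("pathway_id", "name", "k", "m", "K", "N", "p", "q", "genes")]
  rownames(res) <- NULL
  attr(res, "m_effective") <- m
  attr(res, "n_dropped") <- n_dropped
  res
}
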