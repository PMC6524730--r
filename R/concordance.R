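#' Compound-activity overlap between two assays
#'
#' The ratio of compounds active in both assays to compounds active in either
#' — the Jaccard index of the two active-compound sets.
#'
#' @param a,b Character vectors of active compound ids (or logical/0-1
#'   vectors of equal length, interpreted positionally).
#' @return A number in \code{[0, 1]}.
#' @export
activity_overlap <- function(a, b) {
  a <- as_active_set(a); b <- as_active_set(b)
  if (!length(a) && !length(b)) {
    stop("activity overlap is undefined when no compound is active in either assay",
         call. = FALSE)
  }
  set_jaccard(a, b)
}

as_active_set <- function(v) {
  if (is.logical(v) || all(v %in% c(0, 1))) {
    if (is.null(names(v))) names(v) <- seq_along(v)
    names(v)[as.logical(v)]
  } else {
    unique(as.character(v))
  }
}

#' Correlation between assay activity overlap and pathway gene sharing
#'
#' For every unordered pair of assays, computes (i) the gene sharing of the
#' two pathways the assays probe (Jaccard similarity of their gene sets) and
#' (ii) the compound-activity overlap of the two assays. Pairs in which no
#' compound is active in either assay are excluded (their count is reported).
#' Reports the correlation over all usable pairs and, separately, over the
#' pairs whose gene sharing exceeds \code{threshold}, with a two-sided
#' p-value for the overall correlation.
#'
#' @param m Binary activity matrix, compounds in rows, assays in columns.
#' @param assay_pathways Named character vector (or 2-column data frame
#'   \code{assay}, \code{pathway}) mapping every assay column to a pathway id
#'   in \code{x}.
#' @param x The \code{\link{pathway_collection}} the assays probe.
#' @param threshold Gene-sharing cutoff for the conditional correlation
#'   (strict \code{>}; default 0.2).
#' @param method \code{"pearson"} (default) or \code{"spearman"}.
#' @return An object of class \code{"concordance_result"}: \code{r},
#'   \code{p_value}, \code{r_conditional}, \code{threshold}, \code{n_pairs},
#'   \code{n_pairs_conditional}, \code{n_excluded}, \code{method}, and
#'   \code{pairs} (data frame with one row per usable assay pair:
#'   \code{assay_a}, \code{assay_b}, \code{gene_sharing},
#'   \code{activity_overlap}).
#' @export
sharing_activity_correlation <- function(m, assay_pathways, x,
                                         threshold = 0.2,
                                         method = c("pearson", "spearman")) {
  method <- match.arg(method)
  validate_activity_matrix(m)
  stopifnot(inherits(x, "pathway_collection"))
  if (is.data.frame(assay_pathways)) {
    assay_pathways <- stats::setNames(as.character(assay_pathways$pathway),
                                      as.character(assay_pathways$assay))
  }
  assays <- colnames(m)
  missing_map <- setdiff(assays, names(assay_pathways))
  if (length(missing_map)) {
    stop("assay(s) not mapped to a pathway: ",
         paste(missing_map, collapse = ", "), call. = FALSE)
  }
  bad_pw <- setdiff(assay_pathways[assays], pathway_ids(x))
  if (length(bad_pw)) {
    stop("assay map names pathway(s) absent from the collection: ",
         paste(bad_pw, collapse = ", "), call. = FALSE)
  }

  n_assay <- length(assays)
  # activity overlaps for all pairs in one pass
  act <- m == 1L
  both <- crossprod(act)            # actives in both
  n_act <- diag(both)
  either <- outer(n_act, n_act, `+`) - both
  s <- similarity_matrix(x)
  pw <- assay_pathways[assays]
  gene_sharing_mat <- s[pw, pw, drop = FALSE]

  ut <- which(upper.tri(both), arr.ind = TRUE)
  keep <- either[ut] > 0
  n_excluded <- sum(!keep)
  if (n_excluded) {
    warning(n_excluded,
            " assay pair(s) with no active compound in either assay excluded",
            call. = FALSE)
  }
  pairs <- data.frame(
    assay_a = assays[ut[keep, 1L]],
    assay_b = assays[ut[keep, 2L]],
    gene_sharing = gene_sharing_mat[ut][keep],
    activity_overlap = (both[ut] / pmax(either[ut], 1))[keep],
    stringsAsFactors = FALSE)

  if (nrow(pairs) < 3L) {
    stop("need at least 3 usable assay pairs (got ", nrow(pairs), ")",
         call. = FALSE)
  }
  if (stats::sd(pairs$gene_sharing) == 0 || stats::sd(pairs$activity_overlap) == 0) {
    stop("degenerate correlation: zero variance in gene sharing or activity overlap",
         call. = FALSE)
  }
  ct <- stats::cor.test(pairs$gene_sharing, pairs$activity_overlap,
                        method = method, alternative = "two.sided",
                        exact = FALSE)
  cond <- pairs[pairs$gene_sharing > threshold, , drop = FALSE]
  r_cond <- if (nrow(cond) >= 3L &&
                stats::sd(cond$gene_sharing) > 0 &&
                stats::sd(cond$activity_overlap) > 0) {
    stats::cor(cond$gene_sharing, cond$activity_overlap, method = method)
  } else NA_real_

  structure(list(r = unname(ct$estimate),
                 p_value = ct$p.value,
                 r_conditional = r_cond,
                 threshold = threshold,
                 n_pairs = nrow(pairs),
                 n_pairs_conditional = nrow(cond),
                 n_excluded = n_excluded,
                 method = method,
                 pairs = pairs),
            class = "concordance_result")
}

#' @export
print.concordance_result <- function(x, ...) {
  cat("<concordance_result> ", x$method, " r = ", signif(x$r, 3),
      " (p = ", format(x$p_value, digits = 3), ") over ", x$n_pairs,
      " assay pairs\n", sep = "")
  cat("  gene sharing > ", x$threshold, ": r = ",
      ifelse(is.na(x$r_conditional), "NA", signif(x$r_conditional, 3)),
      " over ", x$n_pairs_conditional, " pairs\n", sep = "")
  if (x$n_excluded) {
    cat("  ", x$n_excluded, " pair(s) excluded (no actives in either assay)\n",
        sep = "")
  }
  invisible(x)
}
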