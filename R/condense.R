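#' Evaluate the four merge criteria for a pathway pair
#'
#' Two pathways qualify for merging when any one of four criteria holds:
#' \enumerate{
#'   \item their overlap (shared genes over total unique genes) is > 0.9;
#'   \item they differ by only one gene (symmetric difference of size 1);
#'   \item one pathway has fewer than 3 genes, all contained in the other;
#'   \item their overlap is > 0.5 and a one-sided Fisher's exact test of
#'     gene-set association over the universe gives p < 0.05.
#' }
#' The Fisher test uses the 2x2 table (in A / not in A) x (in B / not in B)
#' over a background of \code{universe_size} genes and tests over-enrichment
#' of shared genes; its p-value is the hypergeometric upper tail. The p-value
#' is only computed when the overlap exceeds \code{overlap_low} (it is
#' \code{NA} otherwise).
#'
#' @param a,b \code{\link{pathway}} objects with non-empty gene sets.
#' @param universe_size Number of genes in the background universe; must be at
#'   least the size of the union of the two gene sets.
#' @param overlap_high Threshold for criterion 1 (strict; default 0.9).
#' @param overlap_low Overlap threshold for criterion 4 (strict; default 0.5).
#' @param alpha Significance level for criterion 4 (strict; default 0.05).
#' @param criterion2_mode \code{"symmetric"} reads "differ by only one gene"
#'   as symmetric difference of size 1; \code{"containment"} reads it as
#'   containment with a size gap of 1. The two readings coincide (a symmetric
#'   difference of 1 forces one set to be the other plus a single gene); both
#'   spellings are accepted.
#' @return An object of class \code{"merge_decision"}: a list with the pair of
#'   ids, logical flags \code{c1_overlap_gt_90}, \code{c2_differ_by_one},
#'   \code{c3_small_subset}, \code{c4_overlap_gt_50_and_significant}, the
#'   \code{overlap} score, Fisher \code{p} (or NA), and \code{mergeable}.
#' @examples
#' a <- pathway("A", paste0("g", 1:10))
#' b <- pathway("B", paste0("g", 1:11))
#' merge_decision(a, b, universe_size = 100)$c2_differ_by_one  # TRUE
#' @export
merge_decision <- function(a, b, universe_size,
                           overlap_high = 0.9, overlap_low = 0.5,
                           alpha = 0.05,
                           criterion2_mode = c("symmetric", "containment")) {
  stopifnot(inherits(a, "pathway"), inherits(b, "pathway"))
  criterion2_mode <- match.arg(criterion2_mode)
  na <- length(a$genes); nb <- length(b$genes)
  if (na == 0L || nb == 0L) {
    stop("merge criteria are undefined for empty pathways", call. = FALSE)
  }
  k <- length(intersect(a$genes, b$genes))
  union_size <- na + nb - k
  if (universe_size < union_size) {
    stop("universe_size (", universe_size, ") smaller than the gene-set union (",
         union_size, ")", call. = FALSE)
  }
  flags <- criteria_flags(k, na, nb, universe_size, overlap_high, overlap_low,
                          alpha, criterion2_mode)
  structure(list(
    pair = c(a$id, b$id),
    c1_overlap_gt_90 = flags$c1,
    c2_differ_by_one = flags$c2,
    c3_small_subset = flags$c3,
    c4_overlap_gt_50_and_significant = flags$c4,
    overlap = flags$s,
    p = flags$p,
    mergeable = flags$c1 || flags$c2 || flags$c3 || flags$c4
  ), class = "merge_decision")
}

#' @export
print.merge_decision <- function(x, ...) {
  crit <- c("c1" = x$c1_overlap_gt_90, "c2" = x$c2_differ_by_one,
            "c3" = x$c3_small_subset, "c4" = x$c4_overlap_gt_50_and_significant)
  cat("<merge_decision> ", x$pair[1], " ~ ", x$pair[2],
      ": overlap = ", signif(x$overlap, 4), sep = "")
  if (!is.na(x$p)) cat(", p =", signif(x$p, 4))
  cat("\n  ", if (x$mergeable) {
    paste("mergeable by", paste(names(crit)[crit], collapse = ", "))
  } else "not mergeable", "\n", sep = "")
  invisible(x)
}

# Vectorised criteria evaluation from shared count k and set sizes. Returns
# flags plus overlap s and Fisher p (NA when not needed for c4).
criteria_flags <- function(k, na, nb, N, overlap_high, overlap_low, alpha,
                           criterion2_mode = "symmetric") {
  s <- k / (na + nb - k)
  c1 <- s > overlap_high
  c2 <- if (criterion2_mode == "containment") {
    abs(na - nb) == 1L & k == pmin(na, nb)
  } else {
    (na + nb - 2L * k) == 1L
  }
  c3 <- pmin(na, nb) < 3L & k == pmin(na, nb)
  need_p <- s > overlap_low
  p <- rep(NA_real_, length(s))
  if (any(need_p)) {
    p[need_p] <- hyper_tail_p(k[need_p], na[need_p], nb[need_p], N)
  }
  c4 <- need_p & !is.na(p) & p < alpha
  list(c1 = c1, c2 = c2, c3 = c3, c4 = c4, s = s, p = p)
}

# One-sided Fisher's exact p for observing >= k shared genes between sets of
# sizes na and nb drawn from a universe of N genes: hypergeometric upper tail.
hyper_tail_p <- function(k, na, nb, N) {
  stats::phyper(k - 1L, na, N - na, nb, lower.tail = FALSE)
}

first_criterion <- function(c1, c2, c3, c4) {
  ifelse(c1, "c1", ifelse(c2, "c2", ifelse(c3, "c3", ifelse(c4, "c4", NA))))
}

#' Condense a collection by iterative merging
#'
#' Repeatedly merges the pathway pair that qualifies under
#' \code{\link{merge_decision}} until no pair meets any criterion (a
#' fixpoint). At each step, among all currently mergeable pairs the pair with
#' the highest overlap is merged (ties broken by the lexicographically
#' smallest id pair), the merged gene set is the union, and the merged
#' pathway keeps the id and name of the larger member (ties broken by the
#' lexicographically smaller id); the absorbed pathway's id and its own
#' provenance accumulate in the survivor's provenance. The union of all genes
#' is conserved, and the result is deterministic and independent of input
#' order.
#'
#' The Fisher background for criterion 4 is the collection's gene universe.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @inheritParams merge_decision
#' @return A list with components \code{collection} (the condensed
#'   \code{pathway_collection}) and \code{report} (class
#'   \code{"condensation_report"}: input/output counts, the ordered merge log
#'   with surviving id, absorbed id, triggering criterion — the first
#'   qualifying criterion in order 1..4 — overlap and p, and the iteration
#'   count).
#' @examples
#' x <- pathway_collection(list(
#'   pathway("A", paste0("g", 1:10)),
#'   pathway("B", paste0("g", 1:11)),
#'   pathway("C", paste0("g", 1:12))))
#' condense_collection(x)$report
#' @export
condense_collection <- function(x, overlap_high = 0.9, overlap_low = 0.5,
                                alpha = 0.05,
                                criterion2_mode = c("symmetric", "containment")) {
  stopifnot(inherits(x, "pathway_collection"))
  criterion2_mode <- match.arg(criterion2_mode)
  n_input <- length(x)
  N <- length(x$universe)
  if (n_input < 2L) {
    report <- new_condensation_report(n_input, n_input, empty_merge_log(), 0L)
    return(list(collection = x, report = report))
  }

  pws <- x$pathways
  ids <- names(pws)
  sizes <- pathway_sizes(x)
  K <- shared_count_matrix(x)  # shared gene counts, maintained incrementally
  active <- rep(TRUE, n_input)
  log_surv <- log_abs <- log_crit <- character()
  log_s <- log_p <- numeric()
  n_iter <- 0L

  repeat {
    n_iter <- n_iter + 1L
    idx <- which(active)
    if (length(idx) < 2L) break
    # evaluate all active pairs at once
    ut <- which(upper.tri(matrix(0, length(idx), length(idx))), arr.ind = TRUE)
    i <- idx[ut[, 1L]]; j <- idx[ut[, 2L]]
    fl <- criteria_flags(K[cbind(i, j)], sizes[i], sizes[j], N,
                         overlap_high, overlap_low, alpha, criterion2_mode)
    mergeable <- fl$c1 | fl$c2 | fl$c3 | fl$c4
    if (!any(mergeable)) break
    # highest overlap first; ties by lexicographic (min id, max id)
    cand <- which(mergeable)
    id_lo <- pmin(ids[i[cand]], ids[j[cand]])
    id_hi <- pmax(ids[i[cand]], ids[j[cand]])
    ord <- order(-fl$s[cand], id_lo, id_hi)
    pick <- cand[ord[1L]]
    a <- i[pick]; b <- j[pick]
    # survivor: larger gene set, ties to lexicographically smaller id
    if (sizes[a] > sizes[b] || (sizes[a] == sizes[b] && ids[a] <= ids[b])) {
      surv <- a; absd <- b
    } else {
      surv <- b; absd <- a
    }
    crit <- first_criterion(fl$c1[pick], fl$c2[pick], fl$c3[pick], fl$c4[pick])
    log_surv <- c(log_surv, ids[surv]); log_abs <- c(log_abs, ids[absd])
    log_crit <- c(log_crit, crit)
    log_s <- c(log_s, fl$s[pick]); log_p <- c(log_p, fl$p[pick])

    merged_genes <- union(pws[[surv]]$genes, pws[[absd]]$genes)
    pws[[surv]]$genes <- merged_genes
    pws[[surv]]$provenance <- unique(c(pws[[surv]]$provenance,
                                       pws[[absd]]$provenance,
                                       pws[[absd]]$id))
    sizes[surv] <- length(merged_genes)
    active[absd] <- FALSE
    # refresh shared counts for the survivor against all still-active sets
    others <- which(active)
    K[surv, others] <- vapply(others, function(o) {
      length(intersect(merged_genes, pws[[o]]$genes))
    }, integer(1))
    K[others, surv] <- K[surv, others]
    K[surv, surv] <- sizes[surv]
  }

  out <- pathway_collection(pws[active], universe = x$universe)
  log <- data.frame(surviving = log_surv, absorbed = log_abs,
                    criterion = log_crit, overlap = log_s, p = log_p,
                    stringsAsFactors = FALSE)
  report <- new_condensation_report(n_input, length(out), log, n_iter)
  list(collection = out, report = report)
}

empty_merge_log <- function() {
  data.frame(surviving = character(), absorbed = character(),
             criterion = character(), overlap = numeric(), p = numeric(),
             stringsAsFactors = FALSE)
}

new_condensation_report <- function(n_input, n_output, merge_log, n_iterations) {
  structure(list(n_input = n_input, n_output = n_output,
                 merge_log = merge_log, n_iterations = n_iterations),
            class = "condensation_report")
}

#' @export
print.condensation_report <- function(x, ...) {
  cat("<condensation_report> ", x$n_input, " -> ", x$n_output, " pathways (",
      nrow(x$merge_log), " merges, ", x$n_iterations, " iterations)\n",
      sep = "")
  if (nrow(x$merge_log)) {
    tab <- table(x$merge_log$criterion)
    cat("  merges by criterion:",
        paste(names(tab), tab, sep = ": ", collapse = ", "), "\n")
  }
  invisible(x)
}

#' Exclude small pathways
#'
#' Removes pathways with fewer than \code{min_genes} genes. With the default
#' threshold, pathways with fewer than three genes are removed — such sparse
#' annotations usually reflect incomplete curation rather than real one- or
#' two-gene processes. Run after \code{\link{condense_collection}} so the
#' small-subset merge criterion can absorb small pathways into larger ones
#' first.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @param min_genes Minimum gene count a pathway must have to be retained
#'   (default 3).
#' @return The filtered \code{pathway_collection}, with the ids of removed
#'   pathways in \code{attr(, "removed")}. The universe is unchanged.
#' @export
exclude_small <- function(x, min_genes = 3L) {
  stopifnot(inherits(x, "pathway_collection"), min_genes >= 1L)
  sizes <- pathway_sizes(x)
  keep <- sizes >= min_genes
  out <- pathway_collection(x$pathways[keep], universe = x$universe)
  attr(out, "removed") <- pathway_ids(x)[!keep]
  out
}
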