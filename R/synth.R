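#' Configuration for the synthetic-data generator
#'
#' Bundles all knobs of \code{\link{generate_collection}} and
#' \code{\link{generate_activity}}. Defaults emulate the redundancy structure
#' of a multi-source pathway compendium and the activity structure of a
#' quantitative high-throughput screen:
#' \itemize{
#'   \item 100 base ("ground truth") pathways of 5-50 genes over a universe
#'     of 2,000 genes, with a small hub-gene pool shared across pathways;
#'   \item planted redundant pathways of four classes — exact duplicates
#'     (similarity 1), near duplicates (similarity drawn in (0.9, 1)),
#'     one-gene-difference variants, and 1-2-gene subset pathways;
#'   \item a compound x assay binary activity matrix in which each compound
#'     carries a latent target gene and is active in an assay with
#'     probability \code{baseline_rate}, raised by \code{sharing_effect} when
#'     its target belongs to the probed pathway (2,000 compounds, 25 assays,
#'     baseline 0.02, effect 0.5 by default).
#' }
#'
#' @param seed Integer seed; all generation is deterministic given it.
#' @param n_base Number of ground-truth base pathways.
#' @param universe_size Number of genes in the universe.
#' @param size_range Length-2 integer vector, min/max genes per base pathway
#'   (min must be >= 3).
#' @param n_exact_dup,n_near_dup,n_one_off,n_small_subset Planted counts per
#'   redundancy class. Each planted pathway derives from a distinct base, so
#'   their total must not exceed \code{n_base}. Near duplicates need bases
#'   with >= 20 genes; subsets need bases with >= 5 genes.
#' @param hub_size,hub_frac Size of the shared hub-gene pool and the fraction
#'   of each base pathway drawn from it (controls base-pathway overlap and
#'   makes the minimum cover nontrivial).
#' @param tag_prob Probability that a base pathway gets a planted tag (its
#'   genes are annotated so the 10\%/>=4 rule holds by construction).
#' @param n_compounds,n_assays Activity-matrix dimensions.
#' @param baseline_rate,sharing_effect Activity model parameters (see above);
#'   \code{baseline_rate + sharing_effect} must lie in [0, 1].
#' @param n_targets Latent targets per compound (default 1; compounds are
#'   active via any of their targets).
#' @return A list of class \code{"synth_config"}.
#' @export
synth_config <- function(seed = 1L, n_base = 100L, universe_size = 2000L,
                         size_range = c(5L, 50L),
                         n_exact_dup = 15L, n_near_dup = 15L,
                         n_one_off = 15L, n_small_subset = 15L,
                         hub_size = 50L, hub_frac = 0.2,
                         tag_prob = 0.5,
                         n_compounds = 2000L, n_assays = 25L,
                         baseline_rate = 0.02, sharing_effect = 0.5,
                         n_targets = 1L) {
  cfg <- list(seed = as.integer(seed), n_base = as.integer(n_base),
              universe_size = as.integer(universe_size),
              size_range = as.integer(size_range),
              n_exact_dup = as.integer(n_exact_dup),
              n_near_dup = as.integer(n_near_dup),
              n_one_off = as.integer(n_one_off),
              n_small_subset = as.integer(n_small_subset),
              hub_size = as.integer(hub_size), hub_frac = hub_frac,
              tag_prob = tag_prob,
              n_compounds = as.integer(n_compounds),
              n_assays = as.integer(n_assays),
              baseline_rate = baseline_rate,
              sharing_effect = sharing_effect,
              n_targets = as.integer(n_targets))
  with(cfg, {
    stopifnot(n_base >= 0L, universe_size >= 1L,
              length(size_range) == 2L, size_range[1L] >= 3L,
              size_range[2L] >= size_range[1L],
              n_exact_dup >= 0L, n_near_dup >= 0L, n_one_off >= 0L,
              n_small_subset >= 0L,
              hub_size >= 0L, hub_frac >= 0, hub_frac <= 1,
              tag_prob >= 0, tag_prob <= 1,
              n_compounds >= 0L, n_assays >= 0L, n_targets >= 1L,
              baseline_rate >= 0, baseline_rate <= 1,
              baseline_rate + sharing_effect >= 0,
              baseline_rate + sharing_effect <= 1)
  })
  structure(cfg, class = "synth_config")
}

#' Generate a synthetic pathway collection with a ground-truth ledger
#'
#' Samples \code{n_base} base pathways over the gene universe and plants
#' redundant derivatives of four classes (see \code{\link{synth_config}}),
#' each derived from a distinct base pathway so that condensation should
#' recover exactly the base pathways. Planted relations hold exactly by
#' construction and are re-asserted before returning. Optionally plants
#' gene-tag structure: a tagged base pathway has
#' \code{max(4, ceiling(0.1 * size))} of its private genes annotated with one
#' vocabulary tag, so the gene-based tagging rule fires by construction.
#'
#' @param cfg A \code{\link{synth_config}}.
#' @return A list with \code{collection} (the
#'   \code{\link{pathway_collection}}), \code{ledger} (data frame: pathway
#'   id, planted class — \code{base}, \code{exact_dup}, \code{near_dup},
#'   \code{one_off}, \code{small_subset} — the base id it derives from, its
#'   similarity to that base, and the merge criterion its planted relation
#'   triggers first), \code{gene_tags} (data frame \code{gene}, \code{tag} of
#'   planted annotations), and \code{planted_tags} (named list: pathway id ->
#'   expected tag set under the 10\%/>=4 rule, computed arithmetically from
#'   the plant records).
#' @export
generate_collection <- function(cfg) {
  stopifnot(inherits(cfg, "synth_config"))
  n_planted <- cfg$n_exact_dup + cfg$n_near_dup + cfg$n_one_off +
    cfg$n_small_subset
  if (n_planted > cfg$n_base) {
    stop("infeasible config: planted pathways (", n_planted,
         ") exceed base pathways (", cfg$n_base, ")", call. = FALSE)
  }
  if (cfg$universe_size < cfg$size_range[2L] + cfg$hub_size) {
    stop("infeasible config: universe too small for the pathway size range",
         call. = FALSE)
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(cfg$seed)

  universe <- sprintf("G%05d", seq_len(cfg$universe_size))
  hub <- universe[seq_len(min(cfg$hub_size, cfg$universe_size))]
  body_pool <- setdiff(universe, hub)
  sources <- c("sourceA", "sourceB", "sourceC", "sourceD")

  # fresh genes for near-duplicate swaps / one-off additions: drawn from
  # universe genes not used by any base pathway
  bases <- vector("list", cfg$n_base)
  base_ids <- sprintf("B%03d", seq_len(cfg$n_base))
  used <- character()
  for (i in seq_len(cfg$n_base)) {
    n <- sample(cfg$size_range[1L]:cfg$size_range[2L], 1L)
    n_hub <- min(round(cfg$hub_frac * n), length(hub))
    genes <- c(if (n_hub > 0L) sample(hub, n_hub),
               sample(body_pool, n - n_hub))
    bases[[i]] <- pathway(base_ids[i], genes,
                          name = paste("Synthetic pathway", base_ids[i]),
                          source = sample(sources, 1L))
    used <- union(used, genes)
  }
  fresh_pool <- setdiff(universe, used)
  base_sizes <- vapply(bases, function(p) length(p$genes), integer(1))

  # assign each planted pathway a distinct eligible base
  classes <- c(rep("near_dup", cfg$n_near_dup),
               rep("small_subset", cfg$n_small_subset),
               rep("exact_dup", cfg$n_exact_dup),
               rep("one_off", cfg$n_one_off))
  eligible <- function(class, free) {
    switch(class,
           near_dup = free[base_sizes[free] >= 20L],
           small_subset = free[base_sizes[free] >= 5L],
           one_off = free[base_sizes[free] >= 4L],
           free)
  }
  free <- seq_len(cfg$n_base)
  assignment <- integer(length(classes))
  for (ci in seq_along(classes)) {
    ok <- eligible(classes[ci], free)
    if (!length(ok)) {
      stop("infeasible config: no eligible base pathway left for class ",
           classes[ci], call. = FALSE)
    }
    pick <- if (length(ok) == 1L) ok else sample(ok, 1L)
    assignment[ci] <- pick
    free <- setdiff(free, pick)
  }

  derived <- vector("list", length(classes))
  led_class <- led_base <- led_crit <- character(length(classes))
  led_sim <- numeric(length(classes))
  for (ci in seq_along(classes)) {
    bi <- assignment[ci]
    base <- bases[[bi]]
    n <- length(base$genes)
    cls <- classes[ci]
    genes <- switch(cls,
      exact_dup = base$genes,
      near_dup = {
        # swap k genes keeping similarity (n-k)/(n+k) > 0.9
        k_max <- max(1L, floor(n / 19.5))
        k <- sample(seq_len(k_max), 1L)
        if (length(fresh_pool) < k) {
          stop("infeasible config: fresh-gene pool exhausted", call. = FALSE)
        }
        add <- fresh_pool[seq_len(k)]
        fresh_pool <- fresh_pool[-seq_len(k)]
        c(setdiff(base$genes, sample(base$genes, k)), add)
      },
      one_off = {
        if (stats::runif(1) < 0.5 && length(fresh_pool) >= 1L) {
          add <- fresh_pool[1L]
          fresh_pool <- fresh_pool[-1L]
          c(base$genes, add)
        } else {
          setdiff(base$genes, sample(base$genes, 1L))
        }
      },
      small_subset = sample(base$genes, sample(1:2, 1L)))
    id <- sprintf("D%03d_%s", ci, cls)
    derived[[ci]] <- pathway(id, genes,
                             name = paste("Synthetic variant of", base$id),
                             source = sample(setdiff(sources, base$source), 1L))
    s <- set_jaccard(genes, base$genes)
    symdiff <- length(setdiff(genes, base$genes)) +
      length(setdiff(base$genes, genes))
    led_class[ci] <- cls
    led_base[ci] <- base$id
    led_sim[ci] <- s
    # expected first-firing criterion, by the same 1..4 precedence the
    # condenser uses, computed from the planted relation itself
    led_crit[ci] <- if (s > 0.9) "c1" else if (symdiff == 1L) "c2"
      else if (length(genes) < 3L) "c3" else "c4"
  }

  all_pws <- c(bases, derived)
  collection <- pathway_collection(all_pws, universe = universe)
  ledger <- data.frame(
    pathway_id = c(base_ids, vapply(derived, `[[`, character(1), "id")),
    class = c(rep("base", cfg$n_base), led_class),
    base_id = c(base_ids, led_base),
    similarity_to_base = c(rep(1, cfg$n_base), led_sim),
    expected_criterion = c(rep(NA_character_, cfg$n_base), led_crit),
    stringsAsFactors = FALSE)

  # planted relations must hold exactly in the emitted collection
  assert_ledger(collection, ledger)

  # planted tag structure: tag private (non-hub, base-exclusive) genes
  vocab <- default_tag_vocabulary()$tag
  gene_tags <- data.frame(gene = character(), tag = character(),
                          stringsAsFactors = FALSE)
  planted_tag <- stats::setNames(rep(NA_character_, cfg$n_base), base_ids)
  if (cfg$tag_prob > 0 && cfg$n_base > 0L) {
    counts <- table(unlist(lapply(bases, `[[`, "genes"), use.names = FALSE))
    exclusive <- names(counts)[counts == 1L]
    for (i in seq_len(cfg$n_base)) {
      if (stats::runif(1) >= cfg$tag_prob) next
      n <- base_sizes[i]
      need <- max(4L, ceiling(0.1 * n))
      priv <- intersect(bases[[i]]$genes, exclusive)
      if (length(priv) < need) next
      tg <- sample(vocab, 1L)
      planted_tag[i] <- tg
      gene_tags <- rbind(gene_tags,
                         data.frame(gene = sample(priv, need), tag = tg,
                                    stringsAsFactors = FALSE))
    }
  }
  planted_tags <- expected_tag_sets(collection, gene_tags)

  list(collection = collection, ledger = ledger, gene_tags = gene_tags,
       planted_tags = planted_tags)
}

# expected tag set per pathway under the 10% / >=4 rule, computed directly
# from the plant table (simple arithmetic, independent of the tagging module)
expected_tag_sets <- function(collection, gene_tags) {
  tags_of <- split(gene_tags$tag, gene_tags$gene)
  out <- lapply(collection$pathways, function(p) {
    n <- length(p$genes)
    if (n == 0L) return(character())
    counts <- table(unlist(tags_of[intersect(p$genes, names(tags_of))],
                           use.names = FALSE))
    sort(as.character(names(counts)[counts >= 4L & counts / n >= 0.10]))
  })
  names(out) <- pathway_ids(collection)
  out
}

assert_ledger <- function(collection, ledger) {
  pws <- collection$pathways
  for (ri in which(ledger$class != "base")) {
    d <- pws[[ledger$pathway_id[ri]]]
    b <- pws[[ledger$base_id[ri]]]
    s <- set_jaccard(d$genes, b$genes)
    ok <- switch(ledger$class[ri],
      exact_dup = s == 1,
      near_dup = s > 0.9 && s < 1,
      one_off = (length(setdiff(d$genes, b$genes)) +
                 length(setdiff(b$genes, d$genes))) == 1L,
      small_subset = length(d$genes) < 3L && all(d$genes %in% b$genes))
    if (!ok) {
      stop("internal error: planted relation violated for ",
           ledger$pathway_id[ri], call. = FALSE)
    }
  }
  invisible(TRUE)
}

#' Generate a synthetic compound x assay activity matrix
#'
#' Each compound carries \code{cfg$n_targets} latent target gene(s) drawn
#' uniformly from the collection universe. A compound is called active in an
#' assay with probability \code{baseline_rate + sharing_effect} when any of
#' its targets belongs to the pathway the assay probes, and
#' \code{baseline_rate} otherwise. With \code{sharing_effect = 0} activity is
#' independent of the pathway structure (the null model).
#'
#' @param cfg A \code{\link{synth_config}}; \code{n_compounds},
#'   \code{baseline_rate}, \code{sharing_effect}, \code{n_targets} are used.
#' @param assay_pathways Named character vector mapping assay ids to pathway
#'   ids in \code{x}.
#' @param x The \code{\link{pathway_collection}} the assays probe.
#' @param seed Integer seed for the activity draw; defaults to
#'   \code{cfg$seed + 1} so collection and activity draws are decoupled.
#' @return A binary integer matrix (compounds x assays) with the latent
#'   target genes in \code{attr(, "targets")}.
#' @export
generate_activity <- function(cfg, assay_pathways, x, seed = cfg$seed + 1L) {
  stopifnot(inherits(cfg, "synth_config"), inherits(x, "pathway_collection"))
  bad <- setdiff(assay_pathways, pathway_ids(x))
  if (length(bad)) {
    stop("assay map names pathway(s) absent from the collection: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  if (is.null(names(assay_pathways))) {
    names(assay_pathways) <- sprintf("assay%02d", seq_along(assay_pathways))
  }
  old_seed <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) {
    assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  n_c <- cfg$n_compounds
  compounds <- sprintf("C%04d", seq_len(n_c))
  n_a <- length(assay_pathways)
  targets <- matrix(sample(x$universe, n_c * cfg$n_targets, replace = TRUE),
                    nrow = n_c)
  hit <- matrix(FALSE, nrow = n_c, ncol = n_a)
  for (j in seq_len(n_a)) {
    genes <- x$pathways[[assay_pathways[j]]]$genes
    hit[, j] <- rowSums(matrix(targets %in% genes, nrow = n_c)) > 0L
  }
  prob <- cfg$baseline_rate + cfg$sharing_effect * hit
  prob <- pmin(pmax(prob, 0), 1)
  calls <- matrix(as.integer(stats::runif(n_c * n_a) < prob),
                  nrow = n_c, ncol = n_a,
                  dimnames = list(compounds, names(assay_pathways)))
  attr(calls, "targets") <- apply(targets, 1L, paste, collapse = ";")
  calls
}

#' Map synthetic assays onto collection pathways
#'
#' Convenience helper pairing \code{n_assays} assays with pathways of the
#' collection (the first \code{n_assays} base pathways in collection order),
#' for use with \code{\link{generate_activity}} and
#' \code{\link{sharing_activity_correlation}}.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @param n_assays Number of assays; must not exceed the collection size.
#' @return Named character vector assay id -> pathway id.
#' @export
synth_assay_map <- function(x, n_assays) {
  stopifnot(inherits(x, "pathway_collection"), n_assays <= length(x))
  stats::setNames(pathway_ids(x)[seq_len(n_assays)],
                  sprintf("assay%02d", seq_len(n_assays)))
}
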