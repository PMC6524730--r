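#' Default tag vocabulary
#'
#' The shipped vocabulary of 51 functional-category tags grouped into seven
#' categories (Major Systems, Metabolism, Signaling, Genetic Information
#' Processing, Cell Cycle, Development, Disease). The tags descend from GO
#' Slim biological-process terms plus top-level Disease Ontology categories
#' and source-database groupings.
#'
#' @return A data frame with columns \code{tag} and \code{category}; 51 rows,
#'   unique tags.
#' @export
default_tag_vocabulary <- function() {
  v <- list(
    "Major Systems" = c(
      "Circulatory system", "Digestive system", "Endocrine system",
      "Excretory system", "Immune system", "Musculoskeletal system",
      "Nervous system", "Sensory system"),
    "Metabolism" = c(
      "Nucleic acid metabolism", "Carbohydrate metabolism",
      "Protein metabolism", "Lipid metabolism",
      "Vitamin and cofactor metabolism", "Small molecule metabolism",
      "Xenobiotic metabolism", "Energy metabolism",
      "Protein folding, sorting, and degradation", "Protein modification"),
    "Signaling" = c(
      "Cell signaling", "G-protein coupled receptor", "Nuclear receptor",
      "Transcriptional regulation", "Stress response",
      "Environmental adaptation", "Chronology", "Transport"),
    "Genetic Information Processing" = c(
      "DNA replication", "DNA repair", "Transcription", "RNA processing",
      "Translation"),
    "Cell Cycle" = c(
      "Cell cycle", "Cell growth", "Cell death", "Cell division",
      "Cell proliferation", "Reproduction"),
    "Development" = c(
      "Development", "Adhesion", "Cell differentiation", "Cell motility"),
    "Disease" = c(
      "Cancer", "Cardiovascular disease", "Genetic disease", "Immune disease",
      "Infectious disease", "Neurological disease", "Physical disorder",
      "Endocrine and metabolic disease", "Sepsis", "Substance dependence")
  )
  data.frame(tag = unlist(v, use.names = FALSE),
             category = rep(names(v), lengths(v)),
             stringsAsFactors = FALSE)
}

#' Default keyword lexicon for title-based tagging
#'
#' A starter keyword-to-tag lexicon for \code{\link{tag_by_keywords}}. Each
#' keyword, matched case-insensitively on word boundaries in a pathway title,
#' assigns its tag. The lexicon is intentionally small and conservative;
#' users are expected to extend it for their collections. Note "T cell" maps
#' to "Immune system" — the vocabulary has no separate immune-response tag.
#'
#' @return A data frame with columns \code{keyword} and \code{tag}.
#' @export
default_keyword_lexicon <- function() {
  entries <- c(
    "Nucleobase" = "Nucleic acid metabolism",
    "Nucleotide" = "Nucleic acid metabolism",
    "Nucleoside" = "Nucleic acid metabolism",
    "Purine" = "Nucleic acid metabolism",
    "Pyrimidine" = "Nucleic acid metabolism",
    "apoptosis" = "Cell death",
    "apoptotic" = "Cell death",
    "cell death" = "Cell death",
    "cell cycle" = "Cell cycle",
    "mitotic" = "Cell division",
    "mitosis" = "Cell division",
    "meiosis" = "Reproduction",
    "T cell" = "Immune system",
    "B cell" = "Immune system",
    "interleukin" = "Immune system",
    "cytokine" = "Immune system",
    "HIV" = "Infectious disease",
    "influenza" = "Infectious disease",
    "bacterial" = "Infectious disease",
    "viral" = "Infectious disease",
    "cancer" = "Cancer",
    "carcinoma" = "Cancer",
    "leukemia" = "Cancer",
    "glycolysis" = "Carbohydrate metabolism",
    "gluconeogenesis" = "Carbohydrate metabolism",
    "fatty acid" = "Lipid metabolism",
    "cholesterol" = "Lipid metabolism",
    "lipid" = "Lipid metabolism",
    "translation" = "Translation",
    "ribosome" = "Translation",
    "transcription" = "Transcription",
    "DNA repair" = "DNA repair",
    "DNA replication" = "DNA replication",
    "splicing" = "RNA processing",
    "proteasome" = "Protein folding, sorting, and degradation",
    "ubiquitin" = "Protein folding, sorting, and degradation",
    "phosphorylation" = "Protein modification",
    "glycosylation" = "Protein modification",
    "GPCR" = "G-protein coupled receptor",
    "G protein" = "G-protein coupled receptor",
    "nuclear receptor" = "Nuclear receptor",
    "estrogen" = "Nuclear receptor",
    "androgen" = "Nuclear receptor",
    "oxidative stress" = "Stress response",
    "hypoxia" = "Stress response",
    "heat shock" = "Stress response",
    "circadian" = "Chronology",
    "transporter" = "Transport",
    "adhesion" = "Adhesion",
    "differentiation" = "Cell differentiation",
    "migration" = "Cell motility",
    "neuronal" = "Nervous system",
    "synaptic" = "Nervous system",
    "cardiac" = "Circulatory system",
    "insulin" = "Endocrine system"
  )
  data.frame(keyword = names(entries), tag = unname(entries),
             stringsAsFactors = FALSE)
}

#' Tag pathways from per-gene annotations
#'
#' A tag is assigned to a pathway when enough of its genes carry that tag:
#' at least 10\% of the pathway's genes (by default) and at least four genes
#' (by default) must share the tag. Both thresholds are evaluated per tag;
#' genes carrying several tags contribute to each tag's count independently.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @param gene_tags Data frame with columns \code{gene} and \code{tag} (one
#'   row per gene-tag pair), as returned by
#'   \code{\link{read_annotation_table}(kind = "gene_tag")}.
#' @param vocabulary Data frame with a \code{tag} column; every tag in
#'   \code{gene_tags} must appear in it. Defaults to
#'   \code{\link{default_tag_vocabulary}}.
#' @param min_frac Minimum fraction of pathway genes sharing the tag
#'   (default 0.10; the comparison is \code{>=}).
#' @param min_genes Minimum number of pathway genes sharing the tag
#'   (default 4; the comparison is \code{>=}).
#' @return A data frame of assignments: \code{pathway_id}, \code{tag},
#'   \code{method} (\code{"gene_based"}), \code{n_tagged_genes},
#'   \code{frac_tagged}.
#' @export
tag_by_gene_annotations <- function(x, gene_tags,
                                    vocabulary = default_tag_vocabulary(),
                                    min_frac = 0.10, min_genes = 4L) {
  stopifnot(inherits(x, "pathway_collection"),
            is.data.frame(gene_tags),
            all(c("gene", "tag") %in% colnames(gene_tags)))
  bad <- setdiff(unique(gene_tags$tag), vocabulary$tag)
  if (length(bad)) {
    stop("tag(s) outside the vocabulary: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  gene_tags <- unique(gene_tags[, c("gene", "tag")])
  tags_of <- split(gene_tags$tag, gene_tags$gene)
  out <- lapply(x$pathways, function(p) {
    n <- length(p$genes)
    if (n == 0L) return(NULL)
    counts <- table(unlist(tags_of[intersect(p$genes, names(tags_of))],
                           use.names = FALSE))
    if (!length(counts)) return(NULL)
    hit <- counts >= min_genes & counts / n >= min_frac
    if (!any(hit)) return(NULL)
    data.frame(pathway_id = p$id, tag = names(counts)[hit],
               method = "gene_based",
               n_tagged_genes = as.integer(counts[hit]),
               frac_tagged = as.numeric(counts[hit]) / n,
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(empty_tag_frame(gene_based = TRUE))))
  res <- res[order(res$pathway_id, res$tag), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Tag pathways from title keywords
#'
#' Each lexicon keyword is matched case-insensitively against pathway names
#' on word boundaries; hyphen and slash count as boundaries, so "HIV" matches
#' inside "HIV-induced". Every matching keyword assigns its tag.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @param lexicon Data frame with columns \code{keyword} and \code{tag};
#'   defaults to \code{\link{default_keyword_lexicon}}.
#' @return A data frame of assignments: \code{pathway_id}, \code{tag},
#'   \code{method} (\code{"keyword"}), \code{matched_keyword}.
#' @export
tag_by_keywords <- function(x, lexicon = default_keyword_lexicon()) {
  stopifnot(inherits(x, "pathway_collection"),
            is.data.frame(lexicon),
            all(c("keyword", "tag") %in% colnames(lexicon)))
  lexicon <- lexicon[nzchar(lexicon$keyword), , drop = FALSE]
  if (!nrow(lexicon)) return(empty_tag_frame(gene_based = FALSE))
  # word-boundary regexes; \b already treats '-' and '/' as boundaries
  patterns <- paste0("\\b", escape_regex(lexicon$keyword), "\\b")
  names_vec <- vapply(x$pathways, `[[`, character(1), "name")
  ids <- pathway_ids(x)
  out <- lapply(seq_len(nrow(lexicon)), function(i) {
    hit <- grepl(patterns[i], names_vec, ignore.case = TRUE, perl = TRUE)
    if (!any(hit)) return(NULL)
    data.frame(pathway_id = ids[hit], tag = lexicon$tag[i],
               method = "keyword", matched_keyword = lexicon$keyword[i],
               stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, c(out, list(empty_tag_frame(gene_based = FALSE))))
  res <- unique(res)
  res <- res[order(res$pathway_id, res$tag, res$matched_keyword), ,
             drop = FALSE]
  rownames(res) <- NULL
  res
}

escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

empty_tag_frame <- function(gene_based) {
  if (gene_based) {
    data.frame(pathway_id = character(), tag = character(),
               method = character(), n_tagged_genes = integer(),
               frac_tagged = numeric(), stringsAsFactors = FALSE)
  } else {
    data.frame(pathway_id = character(), tag = character(),
               method = character(), matched_keyword = character(),
               stringsAsFactors = FALSE)
  }
}

#' Combined automated tagging
#'
#' Runs gene-annotation tagging and keyword tagging and unions their
#' assignments per pathway, retaining which method(s) produced each tag.
#'
#' @inheritParams tag_by_gene_annotations
#' @inheritParams tag_by_keywords
#' @return An object of class \code{"tag_assignments"}: a list with
#'   \code{assignments} (data frame \code{pathway_id}, \code{tag},
#'   \code{methods}, \code{evidence}), \code{tags} (named list mapping each
#'   pathway id to its tag set; pathways with no tag map to an empty vector),
#'   \code{frac_tagged_pathways} (fraction of pathways with at least one
#'   tag), and the per-method raw assignment tables.
#' @export
assign_tags <- function(x, gene_tags = NULL, lexicon = NULL,
                        vocabulary = default_tag_vocabulary(),
                        min_frac = 0.10, min_genes = 4L) {
  stopifnot(inherits(x, "pathway_collection"))
  gb <- if (is.null(gene_tags) || !nrow(gene_tags)) {
    empty_tag_frame(gene_based = TRUE)
  } else {
    tag_by_gene_annotations(x, gene_tags, vocabulary, min_frac, min_genes)
  }
  kw <- if (is.null(lexicon) || !nrow(lexicon)) {
    empty_tag_frame(gene_based = FALSE)
  } else {
    tag_by_keywords(x, lexicon)
  }
  gb_ev <- if (nrow(gb)) {
    sprintf("%d genes (%.0f%%)", gb$n_tagged_genes, 100 * gb$frac_tagged)
  } else character()
  kw_ev <- if (nrow(kw)) {
    paste0("keyword '", kw$matched_keyword, "'")
  } else character()
  both <- rbind(
    data.frame(pathway_id = gb$pathway_id, tag = gb$tag, method = gb$method,
               evidence = gb_ev, stringsAsFactors = FALSE),
    data.frame(pathway_id = kw$pathway_id, tag = kw$tag, method = kw$method,
               evidence = kw_ev, stringsAsFactors = FALSE))
  key <- paste(both$pathway_id, both$tag, sep = "\r")
  agg <- if (nrow(both)) {
    data.frame(
      pathway_id = as.character(tapply(both$pathway_id, key, `[`, 1L)),
      tag = as.character(tapply(both$tag, key, `[`, 1L)),
      methods = as.character(tapply(both$method, key, function(m) {
        paste(sort(unique(m)), collapse = "+")
      })),
      evidence = as.character(tapply(both$evidence, key, paste,
                                     collapse = "; ")),
      stringsAsFactors = FALSE, row.names = NULL)
  } else {
    data.frame(pathway_id = character(), tag = character(),
               methods = character(), evidence = character(),
               stringsAsFactors = FALSE)
  }
  agg <- agg[order(agg$pathway_id, agg$tag), , drop = FALSE]
  rownames(agg) <- NULL
  ids <- pathway_ids(x)
  tags <- lapply(ids, function(id) sort(agg$tag[agg$pathway_id == id]))
  names(tags) <- ids
  structure(list(
    assignments = agg,
    tags = tags,
    frac_tagged_pathways = if (length(ids)) {
      mean(vapply(tags, length, integer(1)) > 0L)
    } else NA_real_,
    gene_based = gb, keyword = kw
  ), class = "tag_assignments")
}

#' @export
print.tag_assignments <- function(x, ...) {
  cat("<tag_assignments> ", nrow(x$assignments), " assignments over ",
      length(x$tags), " pathways; ",
      sprintf("%.1f%%", 100 * x$frac_tagged_pathways),
      " of pathways have >=1 tag\n", sep = "")
  invisible(x)
}
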