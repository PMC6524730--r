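#' Read a GMT gene-set file
#'
#' GMT is the de facto tab-separated gene-set exchange format: one gene set per
#' line, fields \code{id <TAB> description <TAB> gene1 <TAB> gene2 ...}. The
#' description field is used to carry merge provenance written by
#' \code{\link{write_gmt}}: a description of the form
#' \code{"merged:ID1;ID2"} restores the provenance list.
#'
#' @param path Path to a GMT file.
#' @return A \code{\link{pathway_collection}}; the universe is the union of
#'   all genes read. Duplicate genes within a line are collapsed; line order is
#'   preserved.
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- lines[nzchar(lines)]
  pws <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1L]]
    fields <- trimws(fields)
    fields <- fields[nzchar(fields) | seq_along(fields) <= 2L]
    if (length(fields) < 3L) {
      stop("malformed GMT line ", i, ": expected id, description and >=1 gene",
           call. = FALSE)
    }
    desc <- fields[2L]
    prov <- character()
    name <- desc
    if (startsWith(desc, "merged:")) {
      prov <- strsplit(sub("^merged:", "", desc), ";", fixed = TRUE)[[1L]]
      prov <- prov[nzchar(prov)]
      name <- fields[1L]
    }
    pws[[i]] <- pathway(fields[1L], fields[-(1:2)],
                        name = if (nzchar(name)) name else fields[1L],
                        source = "gmt", provenance = prov)
  }
  ids <- vapply(pws, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate pathway id(s) in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  pathway_collection(pws)
}

#' Write a collection to a GMT gene-set file
#'
#' Genes within each line are written in lexicographic order so output is
#' deterministic and diff-friendly. Merge provenance, when present, is
#' serialized into the description field as \code{"merged:ID1;ID2"};
#' otherwise the description holds the pathway name. Reading the file back
#' with \code{\link{read_gmt}} reproduces ids, gene sets, and provenance.
#'
#' @param x A \code{\link{pathway_collection}}.
#' @param path Output file path (UTF-8, LF line endings).
#' @return \code{path}, invisibly.
#' @export
write_gmt <- function(x, path) {
  stopifnot(inherits(x, "pathway_collection"))
  lines <- vapply(x$pathways, function(p) {
    desc <- if (length(p$provenance)) {
      paste0("merged:", paste(sort(p$provenance), collapse = ";"))
    } else if (nzchar(p$name)) p$name else p$id
    paste(c(p$id, desc, sort(p$genes)), collapse = "\t")
  }, character(1))
  write_atomic(unname(lines), path)
  invisible(path)
}

ASSAY_SOURCES <- c("TOX21", "NCATS", "PUBCHEM", "COMMERCIAL")

#' Read a typed annotation table
#'
#' All annotation inputs travel as tab-separated tables with a header row;
#' `kind` selects the schema:
#' \describe{
#'   \item{\code{"assay"}}{columns \code{gene}, \code{sources}; sources is a
#'     \code{";"}-separated subset of \code{TOX21, NCATS, PUBCHEM, COMMERCIAL}
#'     (fixed decreasing priority). Returns a data frame with a list-column
#'     \code{sources}.}
#'   \item{\code{"gene_tag"}}{columns \code{gene}, \code{tag}; one row per
#'     gene-tag pair. Returns a data frame.}
#'   \item{\code{"keyword_lexicon"}}{columns \code{keyword}, \code{tag}.
#'     Returns a data frame.}
#'   \item{\code{"activity"}}{first column \code{compound}, remaining columns
#'     one per assay holding 0/1 calls. Returns a binary integer matrix with
#'     compound row names and assay column names.}
#' }
#'
#' @param path Path to a TSV file with a header.
#' @param kind One of \code{"assay"}, \code{"gene_tag"},
#'   \code{"keyword_lexicon"}, \code{"activity"}.
#' @return See Details; type depends on \code{kind}.
#' @export
read_annotation_table <- function(path,
                                  kind = c("assay", "gene_tag",
                                           "keyword_lexicon", "activity")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE, check.names = FALSE,
                           colClasses = "character")
  switch(kind,
    assay = {
      require_columns(tab, c("gene", "sources"), path)
      src <- strsplit(tab$sources, ";", fixed = TRUE)
      src <- lapply(src, function(s) {
        s <- toupper(trimws(s))
        s <- s[nzchar(s)]
        bad <- setdiff(s, ASSAY_SOURCES)
        if (length(bad)) {
          stop("unknown assay source label(s): ", paste(bad, collapse = ", "),
               call. = FALSE)
        }
        if (!length(s)) stop("empty assay source list in ", path, call. = FALSE)
        # keep fixed priority order
        ASSAY_SOURCES[ASSAY_SOURCES %in% s]
      })
      out <- data.frame(gene = normalize_gene_ids(tab$gene),
                        stringsAsFactors = FALSE)
      out$sources <- src
      out
    },
    gene_tag = {
      require_columns(tab, c("gene", "tag"), path)
      data.frame(gene = normalize_gene_ids(tab$gene), tag = trimws(tab$tag),
                 stringsAsFactors = FALSE)
    },
    keyword_lexicon = {
      require_columns(tab, c("keyword", "tag"), path)
      data.frame(keyword = trimws(tab$keyword), tag = trimws(tab$tag),
                 stringsAsFactors = FALSE)
    },
    activity = {
      if (ncol(tab) < 2L) {
        stop("activity table needs a compound column plus >=1 assay column",
             call. = FALSE)
      }
      compounds <- trimws(tab[[1L]])
      if (anyDuplicated(compounds)) {
        stop("duplicate compound id(s) in ", path, call. = FALSE)
      }
      vals <- as.matrix(tab[, -1L, drop = FALSE])
      suppressWarnings(storage <- matrix(as.numeric(vals), nrow = nrow(vals)))
      if (anyNA(storage) || !all(storage %in% c(0, 1))) {
        stop("activity calls must all be 0 or 1 in ", path, call. = FALSE)
      }
      m <- matrix(as.integer(storage), nrow = nrow(vals),
                  dimnames = list(compounds, colnames(tab)[-1L]))
      validate_activity_matrix(m)
      m
    })
}

#' Write an activity matrix as TSV
#' @param m Binary integer matrix, compounds in rows, assays in columns.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
write_activity_table <- function(m, path) {
  validate_activity_matrix(m)
  df <- data.frame(compound = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_atomic(df, path)
}

validate_activity_matrix <- function(m) {
  if (!is.matrix(m) || is.null(rownames(m)) || is.null(colnames(m))) {
    stop("activity matrix must have compound row names and assay column names",
         call. = FALSE)
  }
  if (anyDuplicated(rownames(m)) || anyDuplicated(colnames(m))) {
    stop("duplicate compound or assay ids in activity matrix", call. = FALSE)
  }
  if (length(m) && !all(m %in% c(0L, 1L))) {
    stop("activity calls must all be 0 or 1", call. = FALSE)
  }
  invisible(m)
}

require_columns <- function(tab, cols, path) {
  missing <- setdiff(cols, colnames(tab))
  if (length(missing)) {
    stop("table ", path, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

# Atomic writes: everything lands via a temp file in the destination
# directory followed by rename, so failed runs never leave partial output.
write_atomic <- function(lines, path) {
  dir <- dirname(path)
  if (!dir.exists(dir)) stop("directory does not exist: ", dir, call. = FALSE)
  tmp <- tempfile(tmpdir = dir, fileext = ".tmp")
  con <- file(tmp, open = "wb")
  ok <- FALSE
  tryCatch({
    writeLines(lines, con, sep = "\n", useBytes = TRUE)
    close(con)
    ok <- TRUE
  }, finally = {
    if (!ok) {
      try(close(con), silent = TRUE)
      unlink(tmp)
    }
  })
  if (!file.rename(tmp, path)) {
    unlink(tmp)
    stop("could not write ", path, call. = FALSE)
  }
  invisible(path)
}

write_tsv_atomic <- function(df, path, header_comments = character()) {
  lines <- character()
  if (length(header_comments)) lines <- paste0("# ", header_comments)
  cells <- vapply(df, function(col) {
    if (is.list(col)) vapply(col, paste, character(1), collapse = ";")
    else as.character(col)
  }, FUN.VALUE = character(nrow(df)))
  if (nrow(df) == 1L) cells <- matrix(cells, nrow = 1L)
  if (nrow(df) == 0L) cells <- matrix(character(), ncol = ncol(df))
  body <- apply(cells, 1L, paste, collapse = "\t")
  lines <- c(lines, paste(colnames(df), collapse = "\t"), body)
  write_atomic(lines, path)
  invisible(path)
}
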