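#' Build an annotation map
#'
#' An annotation map holds gene-to-term memberships for one namespace (GO or
#' pathway) as a pair of exactly inverse indexes. Genes absent from a given
#' network are retained here; they are ignored at enrichment time.
#'
#' @param pairs A data frame with columns `gene` and `term` (extra columns
#'   ignored); duplicated pairs are collapsed.
#' @param namespace `"GO"` or `"pathway"`.
#' @return An `annotation_map` object.
#' @export
annotation_map <- function(pairs, namespace = c("GO", "pathway")) {
  namespace <- match.arg(namespace)
  stopifnot(is.data.frame(pairs))
  gene <- as.character(pairs[["gene"]])
  term <- as.character(pairs[["term"]])
  stopifnot(length(gene) == length(term))
  keep <- !duplicated(paste(gene, term, sep = "\r"))
  gene <- gene[keep]; term <- term[keep]
  structure(list(
    namespace = namespace,
    term_to_genes = split(gene, term),
    gene_to_terms = split(term, gene)
  ), class = "annotation_map")
}

#' @export
print.annotation_map <- function(x, ...) {
  cat(sprintf("<annotation_map: %s> %d terms, %d genes\n", x$namespace,
              length(x$term_to_genes), length(x$gene_to_terms)))
  invisible(x)
}

#' Annotation map as a tibble
#'
#' @param ann An [annotation_map()].
#' @return A tibble with columns `gene`, `term`.
#' @export
as_annotation_tibble <- function(ann) {
  stopifnot(inherits(ann, "annotation_map"))
  tibble::tibble(
    gene = rep(names(ann$gene_to_terms), lengths(ann$gene_to_terms)),
    term = unlist(ann$gene_to_terms, use.names = FALSE)
  )
}

#' Read annotations from GMT or two-column TSV
#'
#' GMT lines are `term <TAB> description <TAB> gene1 <TAB> gene2 ...`; the
#' two-column format is `gene <TAB> term` per line.
#'
#' @param path File path.
#' @param fmt `"gmt"` or `"tsv2col"`.
#' @param namespace `"GO"` or `"pathway"`.
#' @return An [annotation_map()].
#' @export
read_annotations <- function(path, fmt = c("gmt", "tsv2col"),
                             namespace = c("GO", "pathway")) {
  fmt <- match.arg(fmt)
  namespace <- match.arg(namespace)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[!grepl("^\\s*(#|$)", lines)]
  if (fmt == "gmt") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(fields) < 3)
    if (length(bad) > 0) {
      stop(sprintf("GMT line %d of %s has fewer than 3 fields", bad[1], path))
    }
    pairs <- purrr::map_dfr(fields, function(f) {
      tibble::tibble(gene = f[-(1:2)], term = f[[1]])
    })
  } else {
    fields <- strsplit(lines, "\\s+")
    bad <- which(lengths(fields) < 2)
    if (length(bad) > 0) {
      stop(sprintf("annotation line %d of %s has fewer than 2 fields", bad[1], path))
    }
    pairs <- tibble::tibble(gene = vapply(fields, `[[`, "", 1L),
                            term = vapply(fields, `[[`, "", 2L))
  }
  annotation_map(pairs, namespace)
}

#' Write an annotation map as GMT
#'
#' @param ann An [annotation_map()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(ann, path) {
  stopifnot(inherits(ann, "annotation_map"))
  lines <- vapply(names(ann$term_to_genes), function(tm) {
    paste(c(tm, ann$namespace, ann$term_to_genes[[tm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}
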