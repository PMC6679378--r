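# Hypergeometric pathway/GO enrichment against the detected-expression
# background.

#' Read a GMT gene-set file
#'
#' One set per line: set id, description, then tab-separated member gene
#' ids.
#'
#' @param path File path.
#' @return Named list of class `"gene_set_collection"`; each element is a
#'   character vector of gene ids with a `description` attribute.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  sets <- list()
  for (ln in lines) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1]]
    if (length(parts) < 3) stopf("malformed GMT line: '%s'", substr(ln, 1, 60))
    members <- unique(parts[-(1:2)])
    attr(members, "description") <- parts[2]
    sets[[parts[1]]] <- members
  }
  structure(sets, class = "gene_set_collection")
}

#' Write a GMT gene-set file
#' @param sets Named list of character vectors (optionally with
#'   `description` attributes).
#' @param path File path.
#' @export
write_gmt <- function(sets, path) {
  lines <- vapply(names(sets), function(nm) {
    desc <- attr(sets[[nm]], "description")
    if (is.null(desc)) desc <- nm
    paste(c(nm, desc, sets[[nm]]), collapse = "\t")
  }, "")
  writeLines(lines, path)
  invisible(path)
}

#' Hypergeometric gene-set enrichment
#'
#' For each set, tests over-representation of the query genes (typically
#' the eQTL-controlled genes) among the set members, relative to the
#' background of genes with detectable expression:
#' `p = P(X >= k)` with `X ~ Hypergeometric(N = |background|,
#' K = |set ∩ background|, n = |query|)`.  Genes are deduplicated and sets
#' are intersected with the background before testing; sets with no
#' background members are skipped.
#'
#' @param query Character vector of gene ids (must be a subset of
#'   `background`).
#' @param collection A `"gene_set_collection"` (or plain named list of gene
#'   id vectors).
#' @param background Character vector: the gene universe.
#' @return Data frame sorted by p: `set`, `description`, `k` (query hits),
#'   `K` (set size in background), `n` (query size), `N` (background
#'   size), `p`, and BH `q`.
#' @export
hypergeom_enrich <- function(query, collection, background) {
  query <- unique(query)
  background <- unique(background)
  bad <- setdiff(query, background)
  if (length(bad)) {
    stopf("query genes not in background: %s",
          paste(utils::head(bad, 10), collapse = ", "))
  }
  N <- length(background)
  n <- length(query)
  rows <- list()
  for (nm in names(collection)) {
    members <- intersect(collection[[nm]], background)
    K <- length(members)
    if (K == 0) next
    k <- length(intersect(members, query))
    desc <- attr(collection[[nm]], "description")
    rows[[length(rows) + 1L]] <- data.frame(
      set = nm, description = if (is.null(desc)) nm else desc,
      k = k, K = K, n = n, N = N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      stringsAsFactors = FALSE
    )
  }
  out <- if (length(rows)) do.call(rbind, rows) else
    data.frame(set = character(0), description = character(0), k = integer(0),
               K = integer(0), n = integer(0), N = integer(0), p = numeric(0),
               stringsAsFactors = FALSE)
  out <- out[order(out$p, out$set), , drop = FALSE]
  out$q <- adjust_enrichment(out$p)
  rownames(out) <- NULL
  out
}

#' FDR adjustment of enrichment p-values
#'
#' Benjamini-Hochberg correction over the tested sets; identical to
#' [fdr_adjust()].
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values.
#' @export
adjust_enrichment <- function(p) {
  if (!length(p)) return(numeric(0))
  fdr_adjust(p)
}
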