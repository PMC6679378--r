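# Cross-tissue and cross-population eQTL conservation.

#' Cross-tissue eQTL conservation
#'
#' A gene's eQTL is conserved between two tissues when the gene has a
#' declared eQTL in both tables, the peaks lie on the same chromosome
#' within `window_cM`, and the allelic effects have the same sign
#' (consistent direction of the GK-allele effect).  When a gene has
#' several eQTLs, conservation is satisfied if any pair matches.
#'
#' @param records_A,records_B eQTL record tables sharing gene identifiers
#'   (columns `gene`, `chr`, `cM`, `ER`, `lod`).
#' @param window_cM Maximum peak distance in cM (default 15).
#' @return Data frame of conserved pairs with positions, ERs and LODs from
#'   both tables.
#' @export
conserved_crosstissue <- function(records_A, records_B, window_cM = 15) {
  conserved_pairs(records_A, records_B, window = window_cM, unit = "cM",
                  require_sign = TRUE)
}

#' Cross-population eQTL conservation
#'
#' Conservation between two mapping systems (e.g. an F2 cross and a
#' recombinant-inbred panel) compared on physical peak positions: a gene is
#' conserved when it has an eQTL in both systems with peaks on the same
#' chromosome within `window_Mb`.  Allele-effect direction agreement is
#' reported but not required (the wider window absorbs the lower marker
#' resolution across systems).
#'
#' @param records_f2,records_ri eQTL record tables (columns `gene`, `chr`,
#'   `Mb`, `ER`, `lod`).
#' @param window_Mb Maximum peak distance in Mb (default 10).
#' @return Data frame of conserved pairs with a `direction_consistent`
#'   column.
#' @export
conserved_crossmodel <- function(records_f2, records_ri, window_Mb = 10) {
  conserved_pairs(records_f2, records_ri, window = window_Mb, unit = "Mb",
                  require_sign = FALSE)
}

conserved_pairs <- function(A, B, window, unit, require_sign) {
  poscol <- unit
  out <- list()
  for (g in intersect(unique(A$gene), unique(B$gene))) {
    a <- A[A$gene == g, , drop = FALSE]
    b <- B[B$gene == g, , drop = FALSE]
    best <- NULL
    for (i in seq_len(nrow(a))) for (j in seq_len(nrow(b))) {
      if (a$chr[i] != b$chr[j]) next
      d <- abs(a[[poscol]][i] - b[[poscol]][j])
      if (d > window) next
      if (require_sign && sign(a$ER[i]) != sign(b$ER[j])) next
      if (is.null(best) || d < best$dist) {
        best <- data.frame(
          gene = g, chr = a$chr[i],
          pos_A = a[[poscol]][i], pos_B = b[[poscol]][j], dist = d,
          ER_A = a$ER[i], ER_B = b$ER[j],
          lod_A = a$lod[i], lod_B = b$lod[j],
          direction_consistent = sign(a$ER[i]) == sign(b$ER[j]),
          stringsAsFactors = FALSE
        )
      }
    }
    if (!is.null(best)) out[[length(out) + 1L]] <- best
  }
  res <- if (length(out)) do.call(rbind, out) else
    data.frame(gene = character(0), chr = character(0), pos_A = numeric(0),
               pos_B = numeric(0), dist = numeric(0), ER_A = numeric(0),
               ER_B = numeric(0), lod_A = numeric(0), lod_B = numeric(0),
               direction_consistent = logical(0), stringsAsFactors = FALSE)
  names(res)[names(res) == "pos_A"] <- paste0(unit, "_A")
  names(res)[names(res) == "pos_B"] <- paste0(unit, "_B")
  rownames(res) <- NULL
  res
}

#' One-sided enrichment of eQTL-set overlap
#'
#' Tests whether the overlap between two eQTL gene sets exceeds chance on a
#' common background universe: a one-sided Fisher's exact test of the 2x2
#' table {in A, not in A} x {in B, not in B}, i.e. the hypergeometric upper
#' tail `P(X >= n_conserved)`.
#'
#' @param n_conserved Number of genes with an eQTL in both sets.
#' @param n_A,n_B eQTL gene counts in each set.
#' @param n_background Size of the common gene universe.
#' @return One-sided p-value.
#' @export
overlap_enrichment <- function(n_conserved, n_A, n_B, n_background) {
  counts <- c(n_conserved, n_A, n_B, n_background)
  if (any(counts < 0) || n_conserved > min(n_A, n_B) ||
      max(n_A, n_B) > n_background ||
      n_background - n_A - n_B + n_conserved < 0) {
    stopf("inconsistent counts: need n_conserved <= min(n_A, n_B) <= n_background")
  }
  stats::phyper(n_conserved - 1, n_A, n_background - n_A, n_B,
                lower.tail = FALSE)
}
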