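# Post-scan eQTL architecture analysis: cis/trans assignment, trans-hotspot
# detection, polygeny, allelic-direction summaries.

#' Classify an eQTL as cis or trans
#'
#' Compares the peak position with the physical position of the regulated
#' gene.  A peak on a different chromosome is unambiguously `trans`; on the
#' gene's own chromosome, peaks within 5 Mb are `cis_5Mb`, within 10 Mb
#' `cis_10Mb`, and farther away `same_chrom_distant` (not separable from
#' linked trans regulation at F2 resolution).  Genes without a unique
#' physical position are `unassigned`.
#'
#' @param gene_chr,gene_Mb Gene position (vectors; NA = unmapped).
#' @param peak_chr,peak_Mb Peak position (vectors).
#' @param window_strict_Mb,window_Mb The strict and permissive cis windows
#'   (defaults 5 and 10 Mb).
#' @return Character vector of class labels.
#' @export
classify_eqtl <- function(gene_chr, gene_Mb, peak_chr, peak_Mb,
                          window_strict_Mb = 5, window_Mb = 10) {
  n <- length(peak_chr)
  out <- character(n)
  for (i in seq_len(n)) {
    if (is.na(gene_chr[i]) || is.na(gene_Mb[i])) {
      out[i] <- "unassigned"
    } else if (gene_chr[i] != peak_chr[i]) {
      out[i] <- "trans"
    } else {
      d <- abs(peak_Mb[i] - gene_Mb[i])
      out[i] <- if (d <= window_strict_Mb) "cis_5Mb"
        else if (d <= window_Mb) "cis_10Mb"
        else "same_chrom_distant"
    }
  }
  out
}

#' Classify a table of declared eQTLs
#'
#' Joins gene annotation onto an eQTL record table (from
#' [declare_eqtls()]) and adds the cis/trans class label.
#'
#' @param records eQTL records with columns `gene`, `chr`, `Mb`.
#' @param annot Annotation data frame (`gene`, `chr`, `Mb`).
#' @inheritParams classify_eqtl
#' @return `records` with added `gene_chr`, `gene_Mb`, `class`.
#' @export
classify_eqtls <- function(records, annot, window_strict_Mb = 5, window_Mb = 10) {
  i <- match(records$gene, annot$gene)
  records$gene_chr <- annot$chr[i]
  records$gene_Mb <- annot$Mb[i]
  records$class <- classify_eqtl(records$gene_chr, records$gene_Mb,
                                 records$chr, records$Mb,
                                 window_strict_Mb, window_Mb)
  records
}

#' Detect trans-eQTL hotspots
#'
#' Partitions the genome into `bin_cM` bins, counts the non-local eQTL
#' peaks (classes `trans` and `same_chrom_distant`) per bin, and flags bins
#' whose count exceeds the upper-alpha Poisson quantile under a homogeneous
#' null (mean = total count / number of bins), Bonferroni-corrected over
#' bins.  For each hotspot the member transcripts and the fraction with a
#' negative allelic effect (GK allele downregulating) are reported.
#'
#' @param records Classified eQTL records (need `chr`, `cM`, `class`, `ER`,
#'   `gene`).
#' @param map The genetic map (defines chromosome extents).
#' @param bin_cM Bin width in cM (default 5).
#' @param alpha Family-wise false-positive rate for the Poisson test
#'   (default 0.001).
#' @return Data frame of hotspot bins (`chr`, `start_cM`, `end_cM`,
#'   `count`, `threshold`, `frac_gk_down`, `genes`), empty if none.
#' @export
detect_hotspots <- function(records, map, bin_cM = 5, alpha = 0.001) {
  empty <- data.frame(chr = character(0), start_cM = numeric(0),
                      end_cM = numeric(0), count = integer(0),
                      threshold = numeric(0), frac_gk_down = numeric(0),
                      genes = character(0), stringsAsFactors = FALSE)
  if (!nrow(records)) return(empty)
  lens <- map_chr_lengths(map)
  bins <- do.call(rbind, lapply(names(lens), function(ch) {
    starts <- seq(0, lens[[ch]], by = bin_cM)
    data.frame(chr = ch, start_cM = starts, end_cM = starts + bin_cM,
               stringsAsFactors = FALSE)
  }))
  nonlocal <- records[records$class %in% c("trans", "same_chrom_distant"), ,
                      drop = FALSE]
  if (!nrow(nonlocal)) return(empty)
  bin_of <- function(chr, cM) {
    which(bins$chr == chr & cM >= bins$start_cM & cM < bins$end_cM)[1]
  }
  b <- mapply(bin_of, nonlocal$chr, nonlocal$cM)
  counts <- tabulate(b, nbins = nrow(bins))
  lambda <- nrow(nonlocal) / nrow(bins)
  thr <- stats::qpois(1 - alpha / nrow(bins), lambda)
  hot <- which(counts > thr)
  if (!length(hot)) return(empty)
  out <- bins[hot, , drop = FALSE]
  out$count <- counts[hot]
  out$threshold <- thr
  out$frac_gk_down <- NA_real_
  out$genes <- NA_character_
  for (k in seq_along(hot)) {
    members <- nonlocal[which(b == hot[k]), , drop = FALSE]
    er <- members$ER[members$ER != 0]
    out$frac_gk_down[k] <- if (length(er)) mean(er < 0) else NA_real_
    out$genes[k] <- paste(members$gene, collapse = ",")
  }
  rownames(out) <- NULL
  out
}

#' Genes under polygenic control
#'
#' Genes carrying two or more declared eQTLs on distinct chromosomes
#' (within-chromosome secondary peaks are not separable at F2 mapping
#' resolution and do not count).
#'
#' @param records eQTL records (primary and secondary; columns `gene`,
#'   `chr`).
#' @return Character vector of gene ids.
#' @export
polygenic_genes <- function(records) {
  if (!nrow(records)) return(character(0))
  nchr <- tapply(records$chr, records$gene, function(ch) length(unique(ch)))
  sort(names(nchr)[nchr >= 2])
}

#' Allelic-direction summary
#'
#' Fraction of eQTLs whose GK allele downregulates the transcript
#' (`ER < 0`) in a subset of records; records with `ER` exactly 0 are
#' excluded from the denominator and counted separately.
#'
#' @param records eQTL records with `ER`.
#' @param subset Optional logical or integer index into `records`.
#' @return List with `frac_gk_down`, `n`, `n_ties`; `frac_gk_down` is NA
#'   (with a zero `n`) for an empty subset.
#' @export
direction_summary <- function(records, subset = NULL) {
  er <- records$ER
  if (!is.null(subset)) er <- er[subset]
  ties <- sum(er == 0, na.rm = TRUE)
  er <- er[!is.na(er) & er != 0]
  list(frac_gk_down = if (length(er)) mean(er < 0) else NA_real_,
       n = length(er), n_ties = ties)
}
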