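# Microarray preprocessing: normexp background correction, quantile
# normalization, detection filtering, SNP-probe exclusion.
#
# The normexp convolution model (observed = Normal background +
# Exponential signal) and its fit/decorrection are delegated to limma,
# the standard implementation for Illumina-style arrays; this module wraps
# them behind a plain parameter list and adds the validation and filtering
# rules used by the pipeline.

#' Fit the normexp background model
#'
#' Maximum-likelihood fit of the convolution model
#' `observed = Normal(mu_b, sigma_b^2) + Exponential(mean alpha)`
#' to one array's intensities (moment-based start, then ML; via
#' `limma::normexp.fit`).
#'
#' @param x Intensity vector (>= 100 finite values, non-degenerate).
#' @return List of class `"normexp_params"` with `mu`, `sigma`, `alpha`.
#' @export
normexp_fit <- function(x) {
  x <- as.numeric(x)
  if (length(x) < 100 || any(!is.finite(x))) {
    stopf("normexp_fit needs at least 100 finite values")
  }
  if (stats::sd(x) == 0) stopf("degenerate input: zero variance")
  par <- limma::normexp.fit(x, method = "mle")$par
  structure(list(mu = par[1], sigma = exp(par[2]), alpha = exp(par[3])),
            class = "normexp_params")
}

#' Normexp background correction
#'
#' Posterior mean of the true signal given an observed intensity under the
#' fitted normexp model, `E[signal | observed = x]`; strictly positive and
#' monotone in `x`, computed in log space for stability
#' (`limma::normexp.signal`).
#'
#' @param x Observed intensities.
#' @param params A `"normexp_params"` from [normexp_fit()].
#' @return Corrected intensities (same shape as `x`), all > 0.
#' @export
normexp_correct <- function(x, params) {
  stopifnot(inherits(params, "normexp_params"))
  par <- c(params$mu, log(params$sigma), log(params$alpha))
  out <- limma::normexp.signal(par, as.vector(x))
  if (is.matrix(x)) out <- matrix(out, nrow(x), ncol(x), dimnames = dimnames(x))
  out
}

#' Quantile normalization
#'
#' Forces every column (array) to share the same distribution: the
#' row-wise mean of the sorted columns.  Ties within a column receive the
#' mean of their reference quantiles (`limma::normalizeQuantiles` with
#' `ties = TRUE`).  Idempotent.
#'
#' @param m Numeric matrix (probes x arrays) without missing values.
#' @return Normalized matrix of the same shape.
#' @export
quantile_normalize <- function(m) {
  if (anyNA(m)) stopf("quantile_normalize does not accept missing values")
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  out
}

#' Detection filter
#'
#' Removes probes that detect only background: a probe is dropped when its
#' detection score falls below `score_threshold` in more than
#' `sample_fraction` of the samples (strictly more — a probe failing in
#' exactly half the samples under the defaults is retained).
#'
#' @param m Expression matrix (probes x arrays).
#' @param detection Detection-score matrix of the same shape.
#' @param score_threshold Detection score cutoff (default 0.5).
#' @param sample_fraction Fraction of samples allowed below the cutoff
#'   (default 0.5).
#' @return The filtered matrix (probe order preserved).
#' @export
detection_filter <- function(m, detection, score_threshold = 0.5,
                             sample_fraction = 0.5) {
  if (is.null(detection)) stopf("detection scores are required")
  stopifnot(all(dim(m) == dim(detection)))
  frac_low <- rowMeans(detection < score_threshold)
  m[frac_low <= sample_fraction, , drop = FALSE]
}

#' Exclude probes carrying DNA variants
#'
#' Drops the listed probes (those whose target sequence contains a
#' polymorphism between the two strains, which produces allele-dependent
#' hybridization artifacts and spurious cis signals).  Unknown ids produce
#' a warning, not an error.
#'
#' @param m Expression matrix with probe rownames.
#' @param exclude Character vector of probe/gene ids to remove.
#' @return The matrix without the listed probes (order preserved).
#' @export
exclude_snp_probes <- function(m, exclude) {
  if (!length(exclude)) return(m)
  unknown <- setdiff(exclude, rownames(m))
  if (length(unknown)) {
    warnf("%d ids in the exclusion list are not in the matrix", length(unknown))
  }
  found <- intersect(rownames(m), exclude)
  message(sprintf("excluding %d SNP-carrying probes", length(found)))
  m[!(rownames(m) %in% exclude), , drop = FALSE]
}

#' Full preprocessing of raw intensities
#'
#' Per-array normexp background correction, quantile normalization across
#' arrays, log2 transform, detection filtering and SNP-probe exclusion —
#' the preprocessing chain applied before scanning.
#'
#' @param raw Raw intensity matrix (probes x arrays).
#' @param detection Optional detection-score matrix (same shape).
#' @param exclude Optional probe exclusion list.
#' @inheritParams detection_filter
#' @return Log2-scale normalized, filtered expression matrix.
#' @export
preprocess_intensities <- function(raw, detection = NULL, exclude = character(0),
                                   score_threshold = 0.5, sample_fraction = 0.5) {
  corrected <- raw
  for (i in seq_len(ncol(raw))) {
    corrected[, i] <- normexp_correct(raw[, i], normexp_fit(raw[, i]))
  }
  normed <- quantile_normalize(corrected)
  out <- log2(normed)
  if (!is.null(detection)) {
    keep <- rownames(detection_filter(out, detection, score_threshold,
                                      sample_fraction))
    detection <- detection[keep, , drop = FALSE]
    out <- out[keep, , drop = FALSE]
  }
  if (length(exclude)) out <- exclude_snp_probes(out, exclude)
  out
}
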