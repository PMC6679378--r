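# Haley-Knott regression genome scans.
#
# The engine works on orthonormal bases: for each grid locus the design
# matrix (intercept + additive covariates + expected genotype scores, plus
# genotype-by-covariate products for interactive scans) is reduced by QR to
# an orthonormal basis Q, and for any phenotype matrix Y the residual sum
# of squares is  RSS = y'y - ||Q'y||^2.  Stacking the per-locus bases into
# one matrix turns a whole genome scan over thousands of permuted
# phenotypes into a single matrix product, which is what makes
# per-transcript permutation testing affordable.

# Orthonormal basis of the column space of X, robust to collinearity:
# rank-deficient designs silently drop redundant directions.
ortho_basis <- function(X) {
  qrx <- qr(X, tol = 1e-10)
  qr.Q(qrx)[, seq_len(qrx$rank), drop = FALSE]
}

# Expected genotype scores from probabilities: additive a = P_BB - P_AA
# (signed GK dosage), dominance h = P_AB.
geno_scores <- function(probs) {
  if (length(dim(probs)) == 3L) {
    d <- dim(probs)[1:2]
    list(a = matrix(probs[, , 3] - probs[, , 1], d[1], d[2]),
         h = matrix(probs[, , 2], d[1], d[2]))
  } else {
    list(a = probs[, 3] - probs[, 1], h = probs[, 2])
  }
}

# Precompute stacked per-locus bases for a scan.
# mode: "additive" or interactive ("sex_int" / "cross_int"), in which case
# bases for both the additive model H_add and the interactive model H_int
# are returned.  covar is a numeric matrix (may be NULL); for interactive
# scans it must contain the interacting column ("sex" or "cross").
hk_designs <- function(gp, covar = NULL, mode = "additive", dominance = TRUE,
                       rows = NULL) {
  probs <- gp$probs
  if (!is.null(rows)) probs <- probs[rows, , , drop = FALSE]
  n <- dim(probs)[1]
  L <- dim(probs)[2]
  sc <- geno_scores(probs)
  if (!is.null(rows) && !is.null(covar)) covar <- covar[rows, , drop = FALSE]
  X0 <- cbind(rep(1, n), covar)
  inter <- NULL
  if (mode != "additive") {
    nm <- if (mode == "sex_int") "sex" else "cross"
    if (is.null(covar) || !(nm %in% colnames(X0))) {
      stopf("interactive scan '%s' needs a covariate column '%s'", mode, nm)
    }
    inter <- X0[, nm]
  }
  qadd <- qint <- vector("list", L)
  for (j in seq_len(L)) {
    G <- if (dominance) cbind(sc$a[, j], sc$h[, j]) else cbind(sc$a[, j])
    qadd[[j]] <- ortho_basis(cbind(X0, G))
    if (!is.null(inter)) qint[[j]] <- ortho_basis(cbind(X0, G, inter * G))
  }
  des <- list(
    n = n, L = L, grid = gp$grid, mode = mode,
    Q0 = ortho_basis(X0),
    Qadd = do.call(cbind, qadd),
    grp_add = rep(seq_len(L), vapply(qadd, ncol, 0L))
  )
  if (!is.null(inter)) {
    des$Qint <- do.call(cbind, qint)
    des$grp_int <- rep(seq_len(L), vapply(qint, ncol, 0L))
  }
  des
}

# LOD matrix (loci x phenotype columns) from a stacked basis.
lod_from_basis <- function(Q, grp, rss0, yy, Y, n, L, cap) {
  P <- crossprod(Q, Y)
  rss <- matrix(yy, L, length(yy), byrow = TRUE) - rowsum(P * P, grp)
  rss <- pmax(rss, 0)
  lod <- (n / 2) * (matrix(log10(rss0), L, length(rss0), byrow = TRUE) -
                      log10(rss))
  lod[is.nan(lod)] <- 0
  pmin(pmax(lod, 0), cap)
}

# Run the engine: Y is an n x m phenotype matrix.  Returns list of LOD
# matrices (loci x m): $lod for additive scans; $lod_add, $lod_int and
# $lodf for interactive scans.
hk_engine <- function(des, Y, cap = 300) {
  Y <- as.matrix(Y)
  yy <- colSums(Y^2)
  P0 <- crossprod(des$Q0, Y)
  rss0 <- pmax(yy - colSums(P0^2), 0)
  lod_add <- lod_from_basis(des$Qadd, des$grp_add, rss0, yy, Y, des$n, des$L, cap)
  if (des$mode == "additive") return(list(lod = lod_add))
  lod_int <- lod_from_basis(des$Qint, des$grp_int, rss0, yy, Y, des$n, des$L, cap)
  list(lod_add = lod_add, lod_int = lod_int,
       lodf = pmax(lod_int - lod_add, 0))
}

#' Haley-Knott LOD score at a single locus
#'
#' Compares the full model (intercept + covariates + expected genotype
#' scores) with the null model (intercept + covariates) by least squares:
#' `LOD = (n/2) log10(RSS_null / RSS_full)`.  The additive score is
#' `P_BB - P_AA` (signed GK-allele dosage) and the dominance score `P_AB`.
#'
#' @param y Phenotype vector (no missing values; drop them first).
#' @param probs n x 3 genotype probability matrix at the locus.
#' @param covar Optional numeric covariate matrix.
#' @param dominance Include the dominance score (default TRUE, a 2-df test).
#' @param cap Maximum LOD reported for (numerically) perfect fits.
#' @return The LOD score (non-negative scalar).
#' @export
hk_lod <- function(y, probs, covar = NULL, dominance = TRUE, cap = 300) {
  stopifnot(!anyNA(y))
  n <- length(y)
  sc <- geno_scores(probs)
  X0 <- cbind(rep(1, n), covar)
  G <- if (dominance) cbind(sc$a, sc$h) else cbind(sc$a)
  Q0 <- ortho_basis(X0)
  Q1 <- ortho_basis(cbind(X0, G))
  rss0 <- max(sum(y^2) - sum(crossprod(Q0, y)^2), 0)
  rss1 <- max(sum(y^2) - sum(crossprod(Q1, y)^2), 0)
  lod <- (n / 2) * (log10(rss0) - log10(rss1))
  if (is.nan(lod)) lod <- 0
  min(max(lod, 0), cap)
}

#' Interaction LOD (LODf) at a single locus
#'
#' Fits the interactive model H_int, which adds genotype-by-covariate
#' products to the additive model H_add, and returns both the interactive
#' LOD (H_int vs the covariate-only null) and the interaction LOD
#' `LODf = LOD_int - LOD_add`, the evidence for a genotype effect that
#' differs between the two levels of the interacting covariate.
#'
#' @inheritParams hk_lod
#' @param interacting `"sex"` or `"cross"`; `covar` must contain a column
#'   of that name.
#' @return Named vector `c(lod_add, lod_int, lodf)`.
#' @export
hk_lod_interactive <- function(y, probs, covar, interacting = c("sex", "cross"),
                               dominance = TRUE, cap = 300) {
  interacting <- match.arg(interacting)
  if (!(interacting %in% colnames(covar))) {
    stopf("covariate matrix has no column '%s'", interacting)
  }
  stopifnot(!anyNA(y))
  n <- length(y)
  sc <- geno_scores(probs)
  X0 <- cbind(rep(1, n), covar)
  G <- if (dominance) cbind(sc$a, sc$h) else cbind(sc$a)
  w <- covar[, interacting]
  rssq <- function(X) {
    Q <- ortho_basis(X)
    max(sum(y^2) - sum(crossprod(Q, y)^2), 0)
  }
  rss0 <- rssq(X0); rssa <- rssq(cbind(X0, G)); rssi <- rssq(cbind(X0, G, w * G))
  lod <- function(r0, r1) {
    v <- (n / 2) * (log10(r0) - log10(r1))
    if (is.nan(v)) v <- 0
    min(max(v, 0), cap)
  }
  c(lod_add = lod(rss0, rssa), lod_int = lod(rss0, rssi),
    lodf = max(lod(rss0, rssi) - lod(rss0, rssa), 0))
}

#' Genome scan for one transcript
#'
#' Applies Haley-Knott regression at every grid locus.  In interactive
#' modes the scan statistic is LODf (see [hk_lod_interactive()]).  The peak
#' is the argmax of the scan statistic; ties are broken in favour of the
#' lowest chromosome, then the lowest cM position.
#'
#' @param y Phenotype vector (individuals in genoprobs order; NAs dropped).
#' @param gp A `"genoprobs"` object.
#' @param covar Optional covariate matrix (columns `sex`, `cross`).
#' @param mode `"additive"`, `"sex_int"` or `"cross_int"`.
#' @inheritParams hk_lod
#' @return List with `curve` (grid data frame plus `lod` — and `lod_add`,
#'   `lod_int` in interactive modes) and `peak` (one-row data frame).
#' @export
genome_scan <- function(y, gp, covar = NULL, mode = "additive",
                        dominance = TRUE, cap = 300) {
  ok <- !is.na(y)
  rows <- if (all(ok)) NULL else which(ok)
  des <- hk_designs(gp, covar, mode, dominance, rows = rows)
  res <- hk_engine(des, matrix(y[ok], ncol = 1), cap = cap)
  curve <- gp$grid
  if (mode == "additive") {
    curve$lod <- res$lod[, 1]
  } else {
    curve$lod_add <- res$lod_add[, 1]
    curve$lod_int <- res$lod_int[, 1]
    curve$lod <- res$lodf[, 1]
  }
  pk <- which.max(curve$lod)  # grid ordered chr, cM: first max = tie rule
  list(curve = curve, peak = curve[pk, , drop = FALSE])
}

# stratified permutation index matrix (n x n_perm)
perm_indices <- function(strata, n_perm, seed) {
  n <- length(strata)
  groups <- split(seq_len(n), strata)
  with_seed(seed, {
    idx <- matrix(0L, n, n_perm)
    for (p in seq_len(n_perm)) {
      for (g in groups) idx[g, p] <- g[sample.int(length(g))]
    }
    idx
  })
}

default_strata <- function(covar, n) {
  if (is.null(covar)) return(factor(rep(1L, n)))
  keep <- intersect(c("sex", "cross"), colnames(covar))
  if (!length(keep)) return(factor(rep(1L, n)))
  cols <- lapply(keep, function(k) factor(covar[, k]))
  do.call(interaction, c(cols, list(drop = TRUE)))
}

col_max <- function(m) apply(m, 2, max)

#' Permutation genome-scan-adjusted p-value for one transcript
#'
#' Permutes the phenotype within strata defined by the sex-by-cross cells
#' (genotypes and covariates stay fixed), recomputes the genome-wide
#' maximum LOD for each permutation, and reports
#' `p = (1 + #\{perm max >= observed max\}) / (n_perm + 1)`.
#' For interactive modes the permuted quantity is the residual from the
#' additive model at the additive-scan peak (fitted values are kept), and
#' the scan statistic is the maximum LODf.
#'
#' @inheritParams genome_scan
#' @param n_perm Number of permutations (>= 100 recommended; < 10 is an
#'   error).
#' @param seed Seed for the permutation stream.
#' @param strata Optional factor defining permutation strata; defaults to
#'   the sex-by-cross cells of `covar`.
#' @param .des Internal: precomputed scan designs (complete-case only).
#' @return List with `p_adj`, `obs_max`, `perm_max` (the null sample of
#'   genome-wide maxima), `threshold` (its 95th percentile) and `peak`.
#' @export
perm_adjusted_p <- function(y, gp, covar = NULL, mode = "additive",
                            n_perm = 1000, seed = 1L, strata = NULL,
                            dominance = TRUE, cap = 300, .des = NULL) {
  if (n_perm < 10) stopf("n_perm < 10 gives a meaningless permutation p-value")
  if (n_perm < 100) warnf("n_perm < 100: adjusted p-values will be coarse")
  ok <- !is.na(y)
  rows <- if (all(ok)) NULL else which(ok)
  yv <- y[ok]
  n <- length(yv)
  des <- if (is.null(rows) && !is.null(.des)) .des else
    hk_designs(gp, covar, mode, dominance, rows = rows)
  if (is.null(strata)) {
    strata <- default_strata(covar, length(y))
  }
  strata <- factor(strata[ok])
  idx <- perm_indices(strata, n_perm, seed)

  if (mode == "additive") {
    Y <- cbind(yv, matrix(yv[idx], n, n_perm))
    res <- hk_engine(des, Y, cap = cap)
    lods <- res$lod
  } else {
    # null for the interaction: keep the additive fit at the additive peak,
    # permute its residuals within strata
    res_obs <- hk_engine(des, matrix(yv, ncol = 1), cap = cap)
    pk_add <- which.max(res_obs$lod_add[, 1])
    pr_pk <- gp$probs[, pk_add, ]
    cv <- covar
    if (!is.null(rows)) {
      pr_pk <- pr_pk[rows, , drop = FALSE]
      if (!is.null(cv)) cv <- cv[rows, , drop = FALSE]
    }
    sc <- geno_scores(pr_pk)
    X0 <- cbind(rep(1, n), cv)
    X <- if (dominance) cbind(X0, sc$a, sc$h) else cbind(X0, sc$a)
    fit <- stats::lm.fit(X, yv)
    Y <- cbind(yv, fit$fitted.values + matrix(fit$residuals[idx], n, n_perm))
    res <- hk_engine(des, Y, cap = cap)
    lods <- res$lodf
  }
  maxes <- col_max(lods)
  obs_max <- maxes[1]
  perm_max <- maxes[-1]
  pk <- which.max(lods[, 1])
  list(
    p_adj = (1 + sum(perm_max >= obs_max)) / (n_perm + 1),
    obs_max = obs_max,
    perm_max = perm_max,
    threshold = unname(stats::quantile(perm_max, 0.95, type = 1)),
    peak = cbind(gp$grid[pk, , drop = FALSE], lod = obs_max)
  )
}

#' Benjamini-Hochberg q-values
#'
#' Step-up false-discovery-rate adjustment across transcripts, applied to
#' the per-transcript permutation-adjusted p-values.
#'
#' @param p Vector of p-values in (0, 1].
#' @return q-values (monotone in p).
#' @export
fdr_adjust <- function(p) {
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1)) {
    stopf("p-values must lie in (0, 1]")
  }
  stats::p.adjust(p, method = "BH")
}

#' Allelic effect at a locus
#'
#' Fits the full additive+dominance model at a (peak) locus and reports the
#' fitted means of the three genotype classes at the average covariate
#' values, together with the expression ratio
#' `ER = mean(GK/GK) - mean(BN/BN)` — the log2-scale allelic effect, whose
#' sign says whether GK alleles up- (positive) or downregulate (negative)
#' the transcript.
#'
#' @inheritParams hk_lod
#' @return List with `means` (named AA/AB/BB), `ER` and `flagged` (TRUE if
#'   some genotype class has essentially no representatives, so its mean is
#'   a model extrapolation).
#' @export
allele_effect <- function(y, probs, covar = NULL, dominance = TRUE) {
  ok <- !is.na(y)
  y <- y[ok]
  probs <- probs[ok, , drop = FALSE]
  if (!is.null(covar)) covar <- covar[ok, , drop = FALSE]
  n <- length(y)
  sc <- geno_scores(probs)
  X <- cbind(rep(1, n), covar, a = sc$a, h = if (dominance) sc$h else NULL)
  fit <- stats::lm.fit(X, y)
  cf <- fit$coefficients
  cf[is.na(cf)] <- 0
  base <- cf[1] + if (!is.null(covar)) sum(colMeans(covar) * cf[1 + seq_len(ncol(covar))]) else 0
  b_a <- cf[["a"]]
  b_d <- if (dominance) cf[["h"]] else 0
  means <- c(AA = base - b_a, AB = base + b_d, BB = base + b_a)
  flagged <- any(colSums(probs > 0.5) == 0)
  list(means = means, ER = unname(2 * b_a), flagged = flagged)
}

#' Batch LOD scan without permutations
#'
#' Computes the genome-scan statistic (LOD, or LODf in interactive modes)
#' for every transcript in one pass of the engine.  Useful when only the
#' LOD curves are needed — e.g. for diagnostics of probe artifacts —
#' without the cost of permutation p-values.  Requires a complete
#' expression matrix (no NAs).
#'
#' @inheritParams scan_transcripts
#' @return Matrix of scan statistics, grid loci x transcripts.
#' @export
scan_lod <- function(expr, gp, covar = NULL, mode = "additive",
                     dominance = TRUE, cap = 300) {
  stopifnot(is.matrix(expr), ncol(expr) == dim(gp$probs)[1], !anyNA(expr))
  des <- hk_designs(gp, covar, mode, dominance)
  res <- hk_engine(des, t(expr), cap = cap)
  out <- if (mode == "additive") res$lod else res$lodf
  dimnames(out) <- list(gp$grid$locus, rownames(expr))
  out
}

#' Scan a whole expression matrix with per-transcript permutations
#'
#' Runs a genome scan for every transcript, computes the per-transcript
#' genome-scan-adjusted p-value by stratified permutation, the
#' per-transcript 95% permutation threshold, and the allelic effect at the
#' peak.  This is the main mapping entry point.
#'
#' @param expr Expression matrix, transcripts x individuals (columns in the
#'   order of the genoprobs individuals).  NAs are allowed and drop the
#'   individual for that transcript only.
#' @inheritParams perm_adjusted_p
#' @return Object of class `"eqtl_scan"`: list with `table` (one row per
#'   transcript: peak position, `lod`, `p_adj`, `threshold`, `ER`,
#'   `flagged`), `lod` (grid loci x transcripts matrix of observed scan
#'   statistics), `grid`, and the scan parameters.
#' @export
scan_transcripts <- function(expr, gp, covar = NULL, mode = "additive",
                             n_perm = 1000, seed = 1L, strata = NULL,
                             dominance = TRUE, cap = 300) {
  stopifnot(is.matrix(expr), ncol(expr) == dim(gp$probs)[1])
  G <- nrow(expr)
  n <- ncol(expr)
  if (is.null(strata)) strata <- default_strata(covar, n)
  complete <- !apply(expr, 1, anyNA)
  des <- hk_designs(gp, covar, mode, dominance)
  L <- des$L

  lodmat <- matrix(NA_real_, L, G, dimnames = list(gp$grid$locus, rownames(expr)))
  tab <- data.frame(
    gene = rownames(expr), peak_locus = NA_character_, chr = NA_character_,
    cM = NA_real_, Mb = NA_real_, lod = NA_real_, p_adj = NA_real_,
    threshold = NA_real_, ER = NA_real_, flagged = FALSE,
    stringsAsFactors = FALSE
  )
  for (g in seq_len(G)) {
    y <- expr[g, ]
    pr <- perm_adjusted_p(y, gp, covar, mode = mode, n_perm = n_perm,
                          seed = substream_seed(seed, g), strata = strata,
                          dominance = dominance, cap = cap, .des = des)
    # observed curve (recompute cheaply for transcripts with NAs; reuse the
    # shared design otherwise)
    if (complete[g]) {
      obs <- hk_engine(des, matrix(y, ncol = 1), cap = cap)
      lodmat[, g] <- if (mode == "additive") obs$lod[, 1] else obs$lodf[, 1]
    } else {
      sc <- genome_scan(y, gp, covar, mode, dominance, cap)
      lodmat[, g] <- sc$curve$lod
    }
    pk <- which.max(lodmat[, g])
    ae <- allele_effect(y, gp$probs[, pk, ], covar, dominance)
    tab$peak_locus[g] <- gp$grid$locus[pk]
    tab$chr[g] <- gp$grid$chr[pk]
    tab$cM[g] <- gp$grid$cM[pk]
    tab$Mb[g] <- gp$grid$Mb[pk]
    tab$lod[g] <- lodmat[pk, g]
    tab$p_adj[g] <- pr$p_adj
    tab$threshold[g] <- pr$threshold
    tab$ER[g] <- ae$ER
    tab$flagged[g] <- ae$flagged
  }
  structure(
    list(table = tab, lod = lodmat, grid = gp$grid,
         params = list(mode = mode, n_perm = n_perm, seed = seed,
                       dominance = dominance, cap = cap)),
    class = "eqtl_scan"
  )
}

#' @export
print.eqtl_scan <- function(x, ...) {
  cat(sprintf("eQTL scan (%s): %d transcripts x %d grid loci, %d permutations each\n",
              x$params$mode, ncol(x$lod), nrow(x$lod), x$params$n_perm))
  invisible(x)
}

#' Declare significant eQTLs
#'
#' Two-stage significance: per-transcript permutation-adjusted p-values are
#' corrected across transcripts by Benjamini-Hochberg, and a transcript is
#' declared an eQTL gene when its q-value falls below `fdr`.  For declared
#' transcripts, secondary eQTLs are reported on every other chromosome
#' whose maximum LOD exceeds the transcript's own 95% permutation
#' threshold, so a gene can carry several (polygenic) eQTL records on
#' distinct chromosomes.
#'
#' @param scan An `"eqtl_scan"` from [scan_transcripts()].
#' @param fdr FDR threshold across transcripts (default 0.05).
#' @return Data frame of eQTL records (one row per declared eQTL; columns
#'   `gene`, `chr`, `cM`, `Mb`, `lod`, `p_adj`, `q`, `ER`, `secondary`).
#' @export
declare_eqtls <- function(scan, fdr = 0.05) {
  tab <- scan$table
  tab$q <- fdr_adjust(tab$p_adj)
  keep <- which(tab$q < fdr)
  recs <- list()
  for (g in keep) {
    row <- tab[g, c("gene", "chr", "cM", "Mb", "lod", "p_adj", "q", "ER")]
    row$secondary <- FALSE
    recs[[length(recs) + 1L]] <- row
    other <- setdiff(unique(scan$grid$chr), tab$chr[g])
    for (ch in other) {
      sel <- which(scan$grid$chr == ch)
      lmax <- max(scan$lod[sel, g])
      if (lmax >= tab$threshold[g] && lmax > 0) {
        pk <- sel[which.max(scan$lod[sel, g])]
        recs[[length(recs) + 1L]] <- data.frame(
          gene = tab$gene[g], chr = ch, cM = scan$grid$cM[pk],
          Mb = scan$grid$Mb[pk], lod = lmax, p_adj = tab$p_adj[g],
          q = tab$q[g], ER = tab$ER[g], secondary = TRUE,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  out <- if (length(recs)) do.call(rbind, recs) else
    data.frame(gene = character(0), chr = character(0), cM = numeric(0),
               Mb = numeric(0), lod = numeric(0), p_adj = numeric(0),
               q = numeric(0), ER = numeric(0), secondary = logical(0))
  rownames(out) <- NULL
  out
}
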