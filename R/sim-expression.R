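#' Simulate expression phenotypes with a known eQTL architecture
#'
#' Generates one phenotype vector per gene record from the generative model
#' described in [sim_architecture()].  The true genotype at each gene's
#' eQTL locus is taken at the map marker nearest to the requested position
#' (recorded in the truth table); a locus on an unknown chromosome or
#' outside the chromosome is an error.
#'
#' @param cross An `"f2cross"` from [sim_f2_cross()].
#' @param map The genetic map.
#' @param arch The `"sim_architecture"` whose `genes` table to realize.
#' @return A list with `expr` (genes x individuals matrix, log2-scale
#'   intensities), `truth` (the truth table: gene, true locus, effects,
#'   `is_null` flag) and `annot` (gene, chr, Mb annotation table).
#' @export
sim_expression <- function(cross, map, arch) {
  validate_map(map)
  genes <- validate_gene_records(arch$genes)
  n <- nrow(cross$geno)
  s <- as.numeric(cross$sex)
  cc <- as.numeric(cross$cross)

  expr <- matrix(NA_real_, nrow(genes), n,
                 dimnames = list(genes$gene, cross$id))
  truth <- genes
  truth$eqtl_marker <- NA_character_
  for (j in seq_len(nrow(genes))) {
    g <- rep(0, n); h <- rep(0, n)
    if (!is.na(genes$eqtl_chr[j])) {
      mi <- nearest_marker(map, genes$eqtl_chr[j], genes$eqtl_cM[j])
      truth$eqtl_marker[j] <- map$marker[mi]
      truth$eqtl_cM[j] <- map$cM[mi]
      dose <- cross$geno[, mi] - 1L       # GK-allele dosage 0/1/2
      dose[is.na(dose)] <- 1L             # missing genotypes act as average
      g <- as.numeric(dose) - 1           # signed dosage -1/0/1
      h <- as.numeric(dose == 1L)
    }
    e <- with_seed(substream_seed(arch$seed, 1000000L + j), stats::rnorm(n))
    expr[j, ] <- genes$m[j] + genes$b_c[j] * cc + genes$b_s[j] * s +
      genes$b_g[j] * g + genes$b_d[j] * h +
      genes$gs[j] * s * g + genes$gc[j] * cc * g +
      genes$sd[j] * e
  }
  truth$is_null <- is.na(truth$eqtl_chr) |
    (truth$b_g == 0 & truth$b_d == 0 & truth$gs == 0 & truth$gc == 0)
  annot <- data.frame(gene = genes$gene, chr = genes$gene_chr,
                      Mb = genes$gene_Mb, stringsAsFactors = FALSE)
  list(expr = expr, truth = truth, annot = annot)
}

# index of map marker nearest to (chr, cM); errors if off-map
nearest_marker <- function(map, chr, cM) {
  idx <- which(map$chr == chr)
  if (!length(idx)) stopf("effect locus on unknown chromosome '%s'", chr)
  if (!is.finite(cM) || cM < 0 || cM > max(map$cM[idx])) {
    stopf("effect locus %s:%s cM lies off the map", chr, format(cM))
  }
  idx[which.min(abs(map$cM[idx] - cM))]
}

#' Convenience builders for gene effect tables
#'
#' `genes_null()` makes genes with no eQTL, placed at random positions on
#' the map; `genes_cis()` makes genes whose eQTL coincides with their own
#' physical position (a random marker); `genes_trans()` places the gene on a
#' different chromosome than its eQTL; `hotspot_targets()` makes a set of
#' trans-regulated genes all controlled from one locus, with additive
#' effects drawn from a normal distribution (a negative mean emulates a
#' master regulator whose GK allele downregulates its targets).
#'
#' @param n Number of genes.
#' @param map Genetic map (positions are drawn from its markers).
#' @param prefix Identifier prefix.
#' @param effect Additive effect per GK allele (`genes_cis`/`genes_trans`).
#' @param chr,cM Hotspot locus (`hotspot_targets`).
#' @param effect_mean,effect_sd Normal distribution of hotspot target effects.
#' @param seed Seed for the random placements.
#' @param ... Passed on to [gene_records()] (e.g. `sd`, `b_s`, `b_c`, `gs`).
#' @return A gene-records data frame (see [gene_records()]).
#' @name gene_builders
NULL

# random marker rows for gene placement
random_markers <- function(map, n, seed, exclude_chr = NULL) {
  ok <- seq_len(nrow(map))
  if (!is.null(exclude_chr)) ok <- ok[!(map$chr[ok] %in% exclude_chr)]
  with_seed(seed, sample(ok, n, replace = TRUE))
}

#' @rdname gene_builders
#' @export
genes_null <- function(n, map, prefix = "null", seed = 1L, ...) {
  pos <- random_markers(map, n, seed)
  gene_records(sprintf("%s_%04d", prefix, seq_len(n)),
               gene_chr = map$chr[pos], gene_Mb = map$Mb[pos], ...)
}

#' @rdname gene_builders
#' @export
genes_cis <- function(n, map, effect, prefix = "cis", seed = 2L, ...) {
  pos <- random_markers(map, n, seed)
  gene_records(sprintf("%s_%04d", prefix, seq_len(n)),
               gene_chr = map$chr[pos], gene_Mb = map$Mb[pos],
               eqtl_chr = map$chr[pos], eqtl_cM = map$cM[pos],
               b_g = effect, ...)
}

#' @rdname gene_builders
#' @export
genes_trans <- function(n, map, effect, prefix = "trans", seed = 3L, ...) {
  qtl <- random_markers(map, n, seed)
  gpos <- integer(n)
  for (j in seq_len(n)) {
    gpos[j] <- random_markers(map, 1L, substream_seed(seed, j),
                              exclude_chr = map$chr[qtl[j]])
  }
  gene_records(sprintf("%s_%04d", prefix, seq_len(n)),
               gene_chr = map$chr[gpos], gene_Mb = map$Mb[gpos],
               eqtl_chr = map$chr[qtl], eqtl_cM = map$cM[qtl],
               b_g = effect, ...)
}

#' @rdname gene_builders
#' @export
hotspot_targets <- function(n, map, chr, cM, effect_mean = -0.8,
                            effect_sd = 0.15, prefix = "hot", seed = 4L, ...) {
  gpos <- random_markers(map, n, substream_seed(seed, 1L), exclude_chr = chr)
  eff <- with_seed(substream_seed(seed, 2L),
                   stats::rnorm(n, effect_mean, effect_sd))
  gene_records(sprintf("%s_%04d", prefix, seq_len(n)),
               gene_chr = map$chr[gpos], gene_Mb = map$Mb[gpos],
               eqtl_chr = chr, eqtl_cM = cM, b_g = eff, ...)
}

#' Inject allele-dependent probe artifacts
#'
#' Microarray probes whose target sequence carries a DNA variant between the
#' two strains hybridize less efficiently to transcripts carrying the
#' variant allele.  This multiplies a probe's (linear-scale) intensity by
#' `attenuation` for every GK allele the individual carries at the probe's
#' own locus — i.e. adds `dosage * log2(attenuation)` on the log2 scale —
#' creating a spurious cis-eQTL signal at the gene's own position.
#'
#' @param expr Log2-scale expression matrix (genes x individuals).
#' @param cross The `"f2cross"` the columns correspond to.
#' @param map Genetic map.
#' @param annot Gene annotation (gene, chr, Mb) giving each probe's locus.
#' @param snp_probes Character vector of probe/gene ids carrying variants.
#' @param attenuation Multiplicative intensity attenuation per GK allele,
#'   in (0, 1]; 1 leaves the matrix unchanged.
#' @return The modified expression matrix.
#' @export
inject_probe_artifacts <- function(expr, cross, map, annot, snp_probes,
                                   attenuation) {
  if (!is_number(attenuation) || attenuation <= 0 || attenuation > 1) {
    stopf("attenuation must lie in (0, 1]")
  }
  if (!length(snp_probes) || attenuation == 1) return(expr)
  unknown <- setdiff(snp_probes, rownames(expr))
  if (length(unknown)) {
    stopf("unknown probes in snp_probes: %s", paste(unknown, collapse = ", "))
  }
  mb_per_cM <- attr(map, "mb_per_cM")
  for (p in snp_probes) {
    a <- annot[annot$gene == p, ]
    if (!nrow(a) || is.na(a$chr[1])) stopf("probe '%s' has no annotated position", p)
    idx <- which(map$chr == a$chr[1])
    mi <- idx[which.min(abs(map$Mb[idx] - a$Mb[1]))]
    dose <- cross$geno[, mi] - 1L
    dose[is.na(dose)] <- 1L
    expr[p, ] <- expr[p, ] + as.numeric(dose) * log2(attenuation)
  }
  expr
}

#' Simulate raw array intensities and detection scores
#'
#' Produces unnormalized intensities under the additive background +
#' exponential signal model: for probe j on array i,
#' `raw = N(bg_mean, bg_sd^2) + Exp(mean = signal_scale * 2^expr)`.
#' A pool of background-only draws per array (emulating negative-control
#' beads) yields a detection score for each probe: the fraction of
#' background draws below the observed value, so pure-background probes
#' score approximately Uniform(0, 1).
#'
#' @param expr Log2-scale expression matrix (genes x individuals); use a
#'   zero matrix for a pure background + exponential fixture.
#' @param bg_mean,bg_sd Normal background parameters (`bg_sd > 0`).
#' @param signal_scale Mean of the exponential signal at `expr = 0` (> 0).
#' @param seed Seed.
#' @param n_background Background-only draws per array for detection scores.
#' @return List with `raw` and `detection`, both shaped like `expr`.
#' @export
sim_raw_intensities <- function(expr, bg_mean, bg_sd, signal_scale, seed = 1L,
                                n_background = 2000L) {
  if (!is_number(bg_sd) || bg_sd <= 0) stopf("bg_sd must be positive")
  if (!is_number(signal_scale) || signal_scale <= 0) {
    stopf("signal_scale must be positive")
  }
  with_seed(seed, {
    np <- nrow(expr); ni <- ncol(expr)
    bg <- matrix(stats::rnorm(np * ni, bg_mean, bg_sd), np, ni)
    sig <- matrix(stats::rexp(np * ni, rate = 1 / (signal_scale * 2^expr)), np, ni)
    raw <- bg + sig
    detection <- matrix(NA_real_, np, ni, dimnames = dimnames(expr))
    for (i in seq_len(ni)) {
      ref <- sort(stats::rnorm(n_background, bg_mean, bg_sd))
      detection[, i] <- findInterval(raw[, i], ref) / n_background
    }
    dimnames(raw) <- dimnames(expr)
    list(raw = raw, detection = detection)
  })
}

#' Read / write expression matrices
#'
#' Tab-separated text, probes in rows (first column `gene`), individuals in
#' columns.
#' @param expr Matrix with rownames (probes) and colnames (individuals).
#' @param path File path.
#' @export
write_expression <- function(expr, path) {
  df <- data.frame(gene = rownames(expr), expr, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write_tsv_file(df, path)
}

#' @rdname write_expression
#' @export
read_expression <- function(path) {
  df <- read_tsv_file(path, colClasses = list(gene = "character"))
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}
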