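#' Describe the genetic architecture of a simulated F2 study
#'
#' Collects everything the simulator needs: the cross design (number of F2
#' individuals, fraction from each reciprocal cross direction, sex ratio),
#' a per-gene table of genetic effects, and the master seed.  The per-gene
#' effects parameterize the generative model
#' \deqn{y_i = m + b_c c_i + b_s s_i + b_g g_i + b_d h_i + g_s s_i g_i + g_c c_i g_i + e_i}
#' where \eqn{g_i} is the signed GK-allele dosage (-1, 0, 1) at the gene's
#' eQTL locus, \eqn{h_i} the heterozygote indicator, \eqn{s_i} sex (1 =
#' female), \eqn{c_i} cross direction (1 = BN-grandmother lineage) and
#' \eqn{e_i} iid Gaussian noise.
#'
#' @param n_individuals Number of F2 animals.
#' @param genes Data frame of per-gene effect records, usually built with
#'   [gene_records()] and its helpers ([genes_null()], [genes_cis()],
#'   [genes_trans()], [hotspot_targets()]).
#' @param cross_fraction Fraction of individuals from the first reciprocal
#'   direction (coded `c = 0`).
#' @param sex_fraction Fraction of females (coded `s = 1`).
#' @param missing_rate Optional missing-at-random rate for marker genotypes.
#' @param seed Master seed; all randomness is derived from it.
#'
#' @return A list of class `"sim_architecture"`.
#' @export
sim_architecture <- function(n_individuals, genes = gene_records(character(0)),
                             cross_fraction = 0.5, sex_fraction = 0.5,
                             missing_rate = 0, seed = 1L) {
  if (!is_count(n_individuals)) stopf("n_individuals must be a positive integer")
  for (f in c(cross_fraction, sex_fraction)) {
    if (!is_number(f) || f < 0 || f > 1) stopf("fractions must lie in [0, 1]")
  }
  if (!is_number(missing_rate) || missing_rate < 0 || missing_rate >= 1) {
    stopf("missing_rate must lie in [0, 1)")
  }
  genes <- validate_gene_records(genes)
  structure(
    list(n_individuals = as.integer(n_individuals), genes = genes,
         cross_fraction = cross_fraction, sex_fraction = sex_fraction,
         missing_rate = missing_rate, seed = as.integer(seed)),
    class = "sim_architecture"
  )
}

#' Per-gene effect records for the expression simulator
#'
#' One row per simulated probe/gene.  `eqtl_chr`/`eqtl_cM` give the true
#' eQTL locus (NA for null genes); `gene_chr`/`gene_Mb` the physical
#' location the probe is annotated to (used downstream for cis/trans
#' classification); the remaining columns are the coefficients of the
#' generative model (see [sim_architecture()]).
#'
#' @param gene Character vector of gene/probe identifiers.
#' @param gene_chr,gene_Mb Physical annotation of each gene.
#' @param eqtl_chr,eqtl_cM True eQTL locus (NA = no eQTL).
#' @param b_g Additive effect per GK allele (log2 scale).
#' @param b_d Dominance deviation of the heterozygote.
#' @param gs Sex-by-genotype interaction effect.
#' @param gc Cross-direction-by-genotype interaction effect.
#' @param sd Residual standard deviation (> 0).
#' @param m Baseline (mean) expression.
#' @param b_s,b_c Sex and cross-direction main effects.
#' @return A data frame with one row per gene.
#' @export
gene_records <- function(gene, gene_chr = NA_character_, gene_Mb = NA_real_,
                         eqtl_chr = NA_character_, eqtl_cM = NA_real_,
                         b_g = 0, b_d = 0, gs = 0, gc = 0,
                         sd = 1, m = 8, b_s = 0, b_c = 0) {
  if (!length(gene)) {
    return(data.frame(gene = character(0), gene_chr = character(0),
                      gene_Mb = numeric(0), eqtl_chr = character(0),
                      eqtl_cM = numeric(0), b_g = numeric(0), b_d = numeric(0),
                      gs = numeric(0), gc = numeric(0), sd = numeric(0),
                      m = numeric(0), b_s = numeric(0), b_c = numeric(0),
                      stringsAsFactors = FALSE))
  }
  data.frame(gene = as.character(gene),
             gene_chr = as.character(gene_chr), gene_Mb = as.numeric(gene_Mb),
             eqtl_chr = as.character(eqtl_chr), eqtl_cM = as.numeric(eqtl_cM),
             b_g = b_g, b_d = b_d, gs = gs, gc = gc,
             sd = sd, m = m, b_s = b_s, b_c = b_c,
             stringsAsFactors = FALSE)
}

validate_gene_records <- function(genes) {
  need <- c("gene", "gene_chr", "gene_Mb", "eqtl_chr", "eqtl_cM",
            "b_g", "b_d", "gs", "gc", "sd", "m", "b_s", "b_c")
  if (!is.data.frame(genes) || !all(need %in% names(genes))) {
    stopf("gene records need columns %s", paste(need, collapse = ", "))
  }
  if (anyDuplicated(genes$gene)) stopf("duplicated gene identifiers")
  eff <- as.matrix(genes[, c("b_g", "b_d", "gs", "gc", "m", "b_s", "b_c")])
  if (nrow(genes) && any(!is.finite(eff))) stopf("effects must be finite")
  if (nrow(genes) && any(!is.finite(genes$sd) | genes$sd <= 0)) {
    stopf("residual sd must be positive")
  }
  genes
}

#' Simulate F2 intercross genotypes
#'
#' Each F2 genome is the union of two independent gametes; each gamete is a
#' Markov walk along each chromosome, with recombination probability between
#' adjacent markers given by the Haldane map function (no crossover
#' interference).  Sex and reciprocal-cross-direction labels are assigned
#' deterministically from the architecture's fractions, interleaved so the
#' four sex-by-direction strata are as balanced as possible.
#'
#' @param map A `"genmap"` data frame from [sim_map()] or [read_map()].
#' @param arch A `"sim_architecture"`.
#' @return An object of class `"f2cross"`: a list with `geno` (individuals x
#'   markers integer matrix, 1 = AA homozygous BN, 2 = AB, 3 = BB homozygous
#'   GK, NA = missing), `sex` (1 = female), `cross` (1 = second reciprocal
#'   direction), `id`, and the map used.  GK is the "B" allele throughout.
#' @examples
#' map <- sim_map(c(100, 100), 10)
#' cr <- sim_f2_cross(map, sim_architecture(50, seed = 7))
#' table(cr$geno[, 1])
#' @export
sim_f2_cross <- function(map, arch) {
  validate_map(map)
  stopifnot(inherits(arch, "sim_architecture"))
  n <- arch$n_individuals
  chrs <- unique(map$chr)

  gam1 <- gam2 <- matrix(NA_integer_, n, nrow(map))
  for (ci in seq_along(chrs)) {
    idx <- which(map$chr == chrs[ci])
    pos <- map$cM[idx]
    r <- haldane_r(diff(pos))
    gam1[, idx] <- with_seed(substream_seed(arch$seed, 2L * ci),
                             sim_gamete(n, r))
    gam2[, idx] <- with_seed(substream_seed(arch$seed, 2L * ci + 1L),
                             sim_gamete(n, r))
  }
  geno <- gam1 + gam2 + 1L  # GK dosage 0/1/2 -> codes 1/2/3

  if (arch$missing_rate > 0) {
    geno <- with_seed(substream_seed(arch$seed, 999983L), {
      drop <- matrix(stats::runif(length(geno)) < arch$missing_rate,
                     nrow(geno), ncol(geno))
      geno[drop] <- NA_integer_
      geno
    })
  }
  colnames(geno) <- map$marker

  # deterministic, balanced sex / cross-direction assignment
  n_f <- round(n * arch$sex_fraction)
  sex <- as.integer(seq_len(n) <= n_f)
  cross <- integer(n)
  for (sx in c(0L, 1L)) {
    rows <- which(sex == sx)
    n0 <- round(length(rows) * arch$cross_fraction)
    cross[rows] <- as.integer(seq_along(rows) > n0)
  }

  structure(
    list(geno = geno, sex = sex, cross = cross,
         id = sprintf("F2_%03d", seq_len(n)), map = map),
    gametes = list(gam1, gam2),
    class = "f2cross"
  )
}

# one gamete for n individuals along one chromosome: allele 0 (BN) / 1 (GK),
# switching between adjacent markers with probability r[k]
sim_gamete <- function(n, r) {
  m <- length(r) + 1L
  g <- matrix(0L, n, m)
  g[, 1] <- stats::rbinom(n, 1L, 0.5)
  for (k in seq_along(r)) {
    sw <- stats::rbinom(n, 1L, r[k])
    g[, k + 1L] <- bitwXor(g[, k], sw)
  }
  g
}

#' @export
print.f2cross <- function(x, ...) {
  cat(sprintf("F2 intercross: %d individuals, %d markers on %d chromosomes\n",
              nrow(x$geno), ncol(x$geno), length(unique(x$map$chr))))
  cat(sprintf("  females: %d; reciprocal direction 1: %d; missing genotypes: %.2f%%\n",
              sum(x$sex), sum(x$cross), 100 * mean(is.na(x$geno))))
  invisible(x)
}

#' Read / write F2 genotypes
#'
#' Genotypes are stored as comma-separated text: one row per individual with
#' columns `id`, `sex` (F/M), `cross` (dir0/dir1), then one column per
#' marker with codes AA/AB/BB (GK allele = B) or NA.
#'
#' @param cross An `"f2cross"` object.
#' @param path File path.
#' @param map The genetic map the genotypes refer to (for `read_genotypes`).
#' @return `read_genotypes` returns an `"f2cross"`.
#' @export
write_genotypes <- function(cross, path) {
  codes <- c("AA", "AB", "BB")
  gchar <- matrix(codes[cross$geno], nrow(cross$geno), ncol(cross$geno),
                  dimnames = dimnames(cross$geno))
  df <- data.frame(id = cross$id,
                   sex = ifelse(cross$sex == 1, "F", "M"),
                   cross = ifelse(cross$cross == 1, "dir1", "dir0"),
                   gchar, check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "NA")
  invisible(path)
}

#' @rdname write_genotypes
#' @export
read_genotypes <- function(path, map) {
  validate_map(map)
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        na.strings = "NA")
  markers <- setdiff(names(df), c("id", "sex", "cross"))
  missing_in_map <- setdiff(markers, map$marker)
  if (length(missing_in_map)) {
    stopf("genotype file contains markers absent from the map: %s",
          paste(missing_in_map, collapse = ", "))
  }
  geno <- matrix(NA_integer_, nrow(df), nrow(map),
                 dimnames = list(NULL, map$marker))
  for (mk in markers) {
    geno[, mk] <- match(df[[mk]], c("AA", "AB", "BB"))
  }
  structure(
    list(geno = geno,
         sex = as.integer(df$sex == "F"),
         cross = as.integer(df$cross == "dir1"),
         id = as.character(df$id), map = map),
    class = "f2cross"
  )
}

#' Covariate matrix for a cross
#'
#' Sex (1 = female) and cross direction (1 = second reciprocal direction)
#' as 0/1 columns, the additive covariates of the scan model.
#'
#' @param cross An `"f2cross"`.
#' @return Numeric matrix with columns `sex` and `cross`.
#' @export
cross_covariates <- function(cross) {
  cbind(sex = as.numeric(cross$sex), cross = as.numeric(cross$cross))
}
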