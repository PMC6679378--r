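# Haley-Knott scans, permutation significance, allelic effects.

make_scan_fixture <- function(n = 123, seed = 201, genes = NULL,
                              lengths = rep(100, 2), spacing = 10,
                              step = 5) {
  map <- sim_map(lengths, spacing)
  if (is.null(genes)) genes <- genes_null(2, map, seed = 1)
  arch <- sim_architecture(n, genes, seed = seed)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)
  list(map = map, cross = cr, sim = sim,
       gp = calc_genoprob(cr, step_cM = step, error_rate = 0),
       covar = cross_covariates(cr))
}

test_that("hk_lod equals the two-regression OLS oracle on typed data", {
  set.seed(31)
  n <- 20
  dose <- sample(0:2, n, replace = TRUE)
  probs <- matrix(0, n, 3)
  probs[cbind(1:n, dose + 1)] <- 1  # fully typed: degenerate probabilities
  covar <- cbind(sex = rep(0:1, each = n / 2), cross = rep(c(0, 1), n / 2))
  y <- rnorm(n) + 0.4 * (dose - 1)

  X0 <- cbind(1, covar)
  X1 <- cbind(X0, dose - 1, as.numeric(dose == 1))
  expect_equal(hk_lod(y, probs, covar), oracle_lod(y, X0, X1),
               tolerance = 1e-10)
  # additive-only (1 df) variant
  expect_equal(hk_lod(y, probs, covar, dominance = FALSE),
               oracle_lod(y, X0, cbind(X0, dose - 1)), tolerance = 1e-10)
})

test_that("degenerate designs and perfect fits behave as specified", {
  set.seed(32)
  n <- 30
  y <- rnorm(n)
  # genotype probabilities identical across individuals: collinear -> LOD 0
  probs_const <- matrix(rep(c(0.25, 0.5, 0.25), each = n), n, 3)
  expect_equal(hk_lod(y, probs_const), 0)
  # y exactly equal to the additive score: perfect fit, capped
  dose <- sample(0:2, n, replace = TRUE)
  probs <- matrix(0, n, 3); probs[cbind(1:n, dose + 1)] <- 1
  expect_equal(hk_lod(dose - 1, probs), 300)
  expect_equal(hk_lod(dose - 1, probs, cap = 50), 50)
})

test_that("LOD is invariant to affine transformation of the phenotype", {
  fx <- make_scan_fixture(n = 60)
  y <- fx$sim$expr[1, ]
  l1 <- genome_scan(y, fx$gp, fx$covar)$curve$lod
  l2 <- genome_scan(-2.5 * y + 7, fx$gp, fx$covar)$curve$lod
  expect_equal(l1, l2, tolerance = 1e-9)
})

test_that("interaction LOD respects model nesting and detects interactions", {
  map <- sim_map(rep(100, 2), 10)
  genes <- rbind(
    gene_records("int1", eqtl_chr = "1", eqtl_cM = 50, b_g = 0, gs = 1.2,
                 sd = 0.3),
    genes_cis(8, map, effect = 0.8, seed = 5, prefix = "add"),
    genes_null(8, map, seed = 6)
  )
  fx <- make_scan_fixture(n = 123, genes = genes, seed = 205)

  # nesting: LOD_add <= LOD_int everywhere, LODf >= 0
  for (g in c("int1", "add_0001")) {
    y <- fx$sim$expr[g, ]
    curves <- genome_scan(y, fx$gp, fx$covar, mode = "sex_int")$curve
    expect_true(all(curves$lod_int - curves$lod_add >= -1e-9))
    expect_true(all(curves$lod >= 0))
  }

  # a pure sex-interaction gene: LODf >> LOD_add at the true locus, and the
  # stratified OLS oracle confirms opposite-magnitude slopes per sex
  y <- fx$sim$expr["int1", ]
  truth <- fx$sim$truth[fx$sim$truth$gene == "int1", ]
  at <- which(fx$gp$grid$chr == truth$eqtl_chr &
                fx$gp$grid$cM == truth$eqtl_cM)
  v <- hk_lod_interactive(y, fx$gp$probs[, at, ], fx$covar, "sex")
  expect_gt(v[["lodf"]], v[["lod_add"]] + 3)
  dose <- fx$cross$geno[, truth$eqtl_marker] - 1L
  sl_f <- coef(lm(y[fx$cross$sex == 1] ~ I(dose - 1)[fx$cross$sex == 1]))[2]
  sl_m <- coef(lm(y[fx$cross$sex == 0] ~ I(dose - 1)[fx$cross$sex == 0]))[2]
  expect_gt(abs(sl_f), abs(sl_m) + 0.5)

  # additive-only genes: LODf at the additive peak stays near zero
  lodf_at_peak <- vapply(sprintf("add_%04d", 1:8), function(g) {
    y <- fx$sim$expr[g, ]
    pk <- genome_scan(y, fx$gp, fx$covar)$peak
    at <- which(fx$gp$grid$locus == pk$locus)
    hk_lod_interactive(y, fx$gp$probs[, at, ], fx$covar, "sex")[["lodf"]]
  }, 0)
  expect_lt(median(lodf_at_peak), 0.5)
})

test_that("genome_scan peaks and one-locus grids behave", {
  fx <- make_scan_fixture(n = 60)
  y <- fx$sim$expr[1, ]
  sc <- genome_scan(y, fx$gp, fx$covar)
  expect_true(all(sc$curve$lod >= 0))
  expect_equal(sc$peak$lod, max(sc$curve$lod))

  gp1 <- fx$gp
  gp1$probs <- gp1$probs[, 1, , drop = FALSE]
  gp1$grid <- gp1$grid[1, , drop = FALSE]
  sc1 <- genome_scan(y, gp1, fx$covar)
  expect_equal(nrow(sc1$curve), 1)
  expect_equal(sc1$peak$locus, gp1$grid$locus[1])
})

test_that("permutation p-values follow the add-one estimator", {
  genes <- NULL
  map <- sim_map(rep(100, 2), 10)
  genes <- genes_cis(1, map, effect = 3, seed = 7, sd = 0.3)
  fx <- make_scan_fixture(n = 123, genes = genes, seed = 207)
  y <- fx$sim$expr[1, ]
  pr <- perm_adjusted_p(y, fx$gp, fx$covar, n_perm = 100, seed = 3)
  expect_equal(pr$p_adj, 1 / 101)  # observed beats every permutation

  # constant phenotype: observed max 0, never above any permutation max
  pr0 <- perm_adjusted_p(rep(1, 123), fx$gp, fx$covar, n_perm = 100, seed = 3)
  expect_equal(pr0$p_adj, 1)

  expect_error(perm_adjusted_p(y, fx$gp, fx$covar, n_perm = 5), "n_perm")
  expect_warning(perm_adjusted_p(y, fx$gp, fx$covar, n_perm = 50, seed = 1),
                 "coarse")
})

test_that("BH q-values match the step-up computation", {
  expect_equal(fdr_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(fdr_adjust(0.37), 0.37)
  expect_equal(fdr_adjust(rep(0.2, 5)), rep(0.2, 5))
  p <- c(0.001, 0.01, 0.04, 0.8)
  expect_true(all(diff(fdr_adjust(p)[order(p)]) >= 0))
  expect_error(fdr_adjust(c(0.1, 0)), "0, 1")
  expect_error(fdr_adjust(c(0.1, 1.2)), "0, 1")
})

test_that("allelic effects recover the simulated expression ratio", {
  map <- sim_map(rep(100, 2), 10)
  genes <- rbind(genes_cis(1, map, effect = 0.5, seed = 9, sd = 0.05,
                           prefix = "eff"),
                 genes_null(1, map, seed = 10, sd = 0.05))
  fx <- make_scan_fixture(n = 200, genes = genes, seed = 209)
  truth <- fx$sim$truth[1, ]
  at <- which(fx$gp$grid$chr == truth$eqtl_chr &
                fx$gp$grid$cM == truth$eqtl_cM)
  ae <- allele_effect(fx$sim$expr[1, ], fx$gp$probs[, at, ], fx$covar)
  expect_equal(ae$ER, 1.0, tolerance = 0.05)  # two allele steps of +0.5
  expect_false(ae$flagged)

  ae0 <- allele_effect(fx$sim$expr[2, ], fx$gp$probs[, at, ], fx$covar)
  expect_lt(abs(ae0$ER), 0.05)

  # swapping allele labels (AA <-> BB probabilities) flips the sign
  swapped <- fx$gp$probs[, at, c(3, 2, 1)]
  ae_sw <- allele_effect(fx$sim$expr[1, ], swapped, fx$covar)
  expect_equal(ae_sw$ER, -ae$ER, tolerance = 1e-9)
})

test_that("scan_transcripts handles missing phenotypes per transcript", {
  map <- sim_map(rep(100, 2), 10)
  genes <- genes_cis(2, map, effect = 1.5, seed = 11)
  fx <- make_scan_fixture(n = 80, genes = genes, seed = 211)
  expr <- fx$sim$expr
  expr[1, 1:10] <- NA
  sc <- scan_transcripts(expr, fx$gp, fx$covar, n_perm = 120, seed = 5)
  expect_true(all(is.finite(sc$table$lod)))
  expect_true(all(sc$table$p_adj > 0 & sc$table$p_adj <= 1))
  # both cis genes found at their simulated positions
  expect_equal(sc$table$chr, fx$sim$truth$eqtl_chr)
  expect_lt(max(abs(sc$table$cM - fx$sim$truth$eqtl_cM)), 10)
})

test_that("declared eQTLs include secondary peaks on other chromosomes", {
  map <- sim_map(rep(100, 3), 10)
  # one gene controlled from two chromosomes, plus nulls
  poly <- gene_records("poly1", gene_chr = "3", gene_Mb = 10,
                       eqtl_chr = "1", eqtl_cM = 50, b_g = 1.2, sd = 0.5)
  poly2 <- gene_records("poly1b", gene_chr = "3", gene_Mb = 10,
                        eqtl_chr = "2", eqtl_cM = 50, b_g = 1.2, sd = 0.5)
  genes <- rbind(poly, genes_null(3, map, seed = 13))
  arch <- sim_architecture(123, genes, seed = 213)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)
  # add the second QTL's contribution onto gene poly1 by simulating the
  # second architecture with the same cross and summing the genetic parts
  sim2 <- sim_expression(cr, map, sim_architecture(123, poly2, seed = 213))
  expr <- sim$expr
  expr["poly1", ] <- sim$expr["poly1", ] + (sim2$expr["poly1b", ] - 8)
  gp <- calc_genoprob(cr, step_cM = 5)
  sc <- scan_transcripts(expr, gp, cross_covariates(cr), n_perm = 200,
                         seed = 7)
  recs <- declare_eqtls(sc, fdr = 0.05)
  pr <- recs[recs$gene == "poly1", ]
  expect_gte(nrow(pr), 2)
  expect_setequal(pr$chr[1:2], c("1", "2"))
  expect_equal(polygenic_genes(recs), "poly1")
})
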