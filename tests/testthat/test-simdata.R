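# Synthetic F2 cross and expression generator.

test_that("simulated maps have the requested geometry", {
  map <- sim_map(100, 2.5)
  expect_equal(nrow(map), 41)
  expect_equal(map$cM[1], 0)
  expect_equal(unique(diff(map$cM)), 2.5)
  expect_equal(map$Mb, map$cM * 2)

  map2 <- sim_map(c(50, 50), 10)
  expect_equal(as.vector(table(map2$chr)), c(6, 6))
  expect_equal(nrow(map2), 12)

  expect_error(sim_map(100, 0), "spacing")
  expect_error(sim_map(-10, 2.5), "positive")
})

test_that("genotype frequencies follow Mendelian 1:2:1 segregation", {
  map <- sim_map(1e-6, 1)  # single marker
  cr <- sim_f2_cross(map, sim_architecture(10000, seed = 5))
  counts <- tabulate(cr$geno[, 1], nbins = 3)
  p <- chisq.test(counts, p = c(0.25, 0.5, 0.25))$p.value
  expect_gt(p, 0.001)
})

test_that("markers at (almost) zero distance are perfectly correlated", {
  map <- data.frame(marker = c("m1", "m2"), chr = "1",
                    cM = c(0, 1e-9), Mb = c(0, 2e-9))
  class(map) <- c("genmap", "data.frame")
  cr <- sim_f2_cross(map, sim_architecture(500, seed = 3))
  expect_identical(cr$geno[, 1], unname(cr$geno[, 2]))
})

test_that("recombinant gamete fraction matches the Haldane map function", {
  map <- sim_map(10, 10)  # two markers, 10 cM apart
  cr <- sim_f2_cross(map, sim_architecture(20000, seed = 17))
  gam <- attr(cr, "gametes")
  rec <- c(gam[[1]][, 1] != gam[[1]][, 2], gam[[2]][, 1] != gam[[2]][, 2])
  r_hat <- mean(rec)
  r_true <- haldane_r(10)
  se <- sqrt(r_true * (1 - r_true) / length(rec))
  expect_lt(abs(r_hat - r_true), 3 * se)
})

test_that("simulation is deterministic given the seed", {
  map <- sim_map(c(80, 60), 10)
  arch <- sim_architecture(40, genes_cis(5, map, 1), seed = 99,
                           missing_rate = 0.05)
  a <- sim_f2_cross(map, arch); b <- sim_f2_cross(map, arch)
  expect_identical(a$geno, b$geno)
  ea <- sim_expression(a, map, arch); eb <- sim_expression(b, map, arch)
  expect_identical(ea$expr, eb$expr)
})

test_that("expression generator realizes the regression model exactly", {
  map <- sim_map(c(100, 100), 10)
  # near-zero noise: group means at the true locus step by b_g per allele
  genes <- gene_records("g1", gene_chr = "1", gene_Mb = 100,
                        eqtl_chr = "1", eqtl_cM = 50, b_g = 1, sd = 1e-9)
  arch <- sim_architecture(200, genes, seed = 21)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)
  dose <- cr$geno[, sim$truth$eqtl_marker[1]] - 1L
  mns <- tapply(sim$expr[1, ], dose, mean)
  expect_equal(as.vector(diff(mns)), c(1, 1), tolerance = 1e-6)

  # null gene: no association with any genotype
  genes0 <- genes_null(1, map, seed = 4)
  arch0 <- sim_architecture(2000, genes0, seed = 22)
  cr0 <- sim_f2_cross(map, arch0)
  sim0 <- sim_expression(cr0, map, arch0)
  rs <- abs(cor(sim0$expr[1, ], cr0$geno))
  expect_lt(max(rs), 0.08)

  # off-map effect locus is an error
  bad <- gene_records("g1", eqtl_chr = "7", eqtl_cM = 10)
  expect_error(sim_expression(cr, map, sim_architecture(200, bad, seed = 1)),
               "unknown chromosome")
  bad2 <- gene_records("g1", eqtl_chr = "1", eqtl_cM = 500)
  expect_error(sim_expression(cr, map, sim_architecture(200, bad2, seed = 1)),
               "off the map")
})

test_that("true effects are recovered by OLS at the true locus", {
  map <- sim_map(c(100, 100), 10)
  genes <- gene_records("g1", eqtl_chr = "2", eqtl_cM = 40,
                        b_g = 0.7, b_d = 0.3, gs = 0.5, gc = -0.4,
                        b_s = 0.2, b_c = 0.1, m = 8, sd = 0.001)
  arch <- sim_architecture(400, genes, seed = 31)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)
  dose <- cr$geno[, sim$truth$eqtl_marker[1]] - 1L
  g <- dose - 1; h <- as.numeric(dose == 1)
  s <- cr$sex; cc <- cr$cross
  fit <- lm(sim$expr[1, ] ~ cc + s + g + h + I(s * g) + I(cc * g))
  expect_equal(unname(coef(fit)[-1]), c(0.1, 0.2, 0.7, 0.3, 0.5, -0.4),
               tolerance = 1e-2)
})

test_that("sex-interaction effects appear only in the encoded sex stratum", {
  map <- sim_map(c(100, 100), 10)
  genes <- gene_records("g1", eqtl_chr = "1", eqtl_cM = 50,
                        b_g = 0, gs = 2, sd = 0.05)
  arch <- sim_architecture(300, genes, seed = 41)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)
  dose <- cr$geno[, sim$truth$eqtl_marker[1]] - 1L
  g <- dose - 1
  y <- sim$expr[1, ]
  slope_f <- coef(lm(y[cr$sex == 1] ~ g[cr$sex == 1]))[2]
  slope_m <- coef(lm(y[cr$sex == 0] ~ g[cr$sex == 0]))[2]
  expect_equal(unname(slope_f), 2, tolerance = 0.05)
  expect_equal(unname(slope_m), 0, tolerance = 0.05)
})

test_that("probe artifacts attenuate intensity per GK allele", {
  map <- sim_map(c(100, 100), 10)
  genes <- genes_null(3, map, seed = 6)
  arch <- sim_architecture(100, genes, seed = 51)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)

  expect_identical(inject_probe_artifacts(sim$expr, cr, map, sim$annot,
                                          "null_0001", 1), sim$expr)
  expect_identical(inject_probe_artifacts(sim$expr, cr, map, sim$annot,
                                          character(0), 0.5), sim$expr)
  expect_error(inject_probe_artifacts(sim$expr, cr, map, sim$annot,
                                      "nope", 0.5), "unknown probes")

  mod <- inject_probe_artifacts(sim$expr, cr, map, sim$annot, "null_0001", 0.5)
  delta <- mod["null_0001", ] - sim$expr["null_0001", ]
  a <- sim$annot[sim$annot$gene == "null_0001", ]
  idx <- which(map$chr == a$chr)
  mi <- idx[which.min(abs(map$Mb[idx] - a$Mb))]
  dose <- cr$geno[, mi] - 1L
  expect_equal(unname(delta), -as.numeric(dose), tolerance = 1e-12)
  # a formerly-null probe now shows a genotype effect at its own locus (OLS)
  fit <- summary(lm(mod["null_0001", ] ~ I(dose - 1)))
  expect_lt(fit$coefficients[2, 4], 1e-6)
})

test_that("raw intensities follow the background + exponential model", {
  expect_error(sim_raw_intensities(matrix(0, 2, 2), 100, -1, 50), "bg_sd")
  expect_error(sim_raw_intensities(matrix(0, 2, 2), 100, 10, 0), "signal_scale")

  z <- matrix(0, 500, 4, dimnames = list(paste0("p", 1:500), paste0("i", 1:4)))
  res <- sim_raw_intensities(z, bg_mean = 100, bg_sd = 10,
                             signal_scale = 1e-9, seed = 8)
  expect_equal(mean(res$raw), 100, tolerance = 0.5)
  # detection scores of pure-background probes are ~ Uniform(0, 1)
  ks <- suppressWarnings(ks.test(as.vector(res$detection), "punif"))
  expect_gt(ks$p.value, 0.001)
})

test_that("file round-trips preserve maps, genotypes and expression", {
  td <- withr::local_tempdir()
  map <- sim_map(c(60, 40), 10)
  arch <- sim_architecture(30, genes_null(4, map, seed = 2), seed = 61,
                           missing_rate = 0.1)
  cr <- sim_f2_cross(map, arch)
  sim <- sim_expression(cr, map, arch)

  write_map(map, file.path(td, "map.tsv"))
  map2 <- read_map(file.path(td, "map.tsv"))
  expect_equal(as.data.frame(map2), as.data.frame(map)[names(map2)])

  write_genotypes(cr, file.path(td, "geno.csv"))
  cr2 <- read_genotypes(file.path(td, "geno.csv"), map)
  expect_identical(cr2$geno, cr$geno)
  expect_identical(cr2$sex, cr$sex)
  expect_identical(cr2$cross, cr$cross)

  write_expression(sim$expr, file.path(td, "expr.tsv"))
  e2 <- read_expression(file.path(td, "expr.tsv"))
  expect_equal(e2, sim$expr, tolerance = 1e-12)
})
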