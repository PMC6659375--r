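test_that("genotype LD structure follows the autoregressive parameter", {
  ind <- simulate_genotypes(2000, m = 12, ld_rho = 0, seed = 101)
  off <- abs(cor(ind$geno)[upper.tri(diag(12))])
  expect_lt(mean(off), 0.05)

  ld <- simulate_genotypes(2000, m = 12, ld_rho = 0.9, seed = 102)
  adj_r2 <- diag(cor(ld$geno)[-12, -1])^2
  expect_true(all(adj_r2 > 0.5))
})

test_that("per-site allele frequencies track the target MAF", {
  sim <- simulate_genotypes(2000, m = 40, ld_rho = 0.5, maf_range = c(0.1, 0.4), seed = 5)
  f <- colMeans(sim$geno) / 2
  maf <- pmin(f, 1 - f)
  tol <- 3 * sqrt(sim$variants$maf * (1 - sim$variants$maf) / (2 * 2000))
  expect_true(all(abs(maf - sim$variants$maf) < pmax(tol, 0.02)))
})

test_that("null scenario carries no genetic effect on the trait", {
  rs <- vapply(1:100, function(s) {
    cfg <- sim_config(n_panel = 50, n_mqtl = 50, n_eqtl = 10, n_gwas = 400,
                      n_variants = 8, scenario = "null", seed = 1000 + s)
    seeds <- epimr:::derive_seeds(cfg$seed, 3)
    grid <- epimr:::make_variant_grid(8, cfg$maf_range, seed = seeds[1])
    g <- simulate_genotypes(400, grid = grid, ld_rho = cfg$ld_rho, seed = seeds[2])$geno
    ph <- simulate_traits(g[1:10, , drop = FALSE], g[1:10, , drop = FALSE], g,
                          grid, list(m = 4, e = NA, t = NA), cfg, seed = seeds[3])
    cor(g[, 4], ph$trait)
  }, 0)
  ci <- mean(rs) + c(-2, 2) * sd(rs) / sqrt(length(rs))
  expect_true(ci[1] < 0 && ci[2] > 0)
})

test_that("shared scenario transmits the product of path coefficients to the trait", {
  cfg <- sim_config(n_gwas = 20000, scenario = "shared", causal_r2 = 0.1,
                    beta_mt = 0.1, n_variants = 10, seed = 77)
  grid <- epimr:::make_variant_grid(10, cfg$maf_range, seed = 1)
  g <- simulate_genotypes(20000, grid = grid, ld_rho = 0.3, seed = 2)$geno
  dummy <- g[1:10, , drop = FALSE]
  ph <- simulate_traits(dummy, dummy, g, grid, list(m = 5, e = 5, t = 5), cfg, seed = 3)
  fit <- summary(lm(ph$trait ~ g[, 5]))$coefficients
  b_g <- epimr:::per_allele_effect(0.1, grid$maf[5])
  expect_lt(abs(fit[2, 1] - b_g * 0.1), 2 * fit[2, 2])
  expect_equal(ph$truth$true_mr, 0.1)
})

test_that("a zero methylation-trait coefficient means a zero true MR effect", {
  cfg <- sim_config(n_mqtl = 50, n_eqtl = 10, n_gwas = 50, n_panel = 10,
                    n_variants = 6, beta_mt = 0, seed = 4)
  grid <- epimr:::make_variant_grid(6, cfg$maf_range, seed = 4)
  g <- simulate_genotypes(50, grid = grid, seed = 5)$geno
  d <- g[1:10, , drop = FALSE]
  ph <- simulate_traits(g, d, g, grid, list(m = 3, e = 3, t = 3), cfg)
  expect_identical(ph$truth$true_mr, 0)
})

test_that("per-variant summary statistics match an independent regression oracle", {
  sim <- simulate_genotypes(300, m = 6, ld_rho = 0.5, seed = 21)
  y <- local({ set.seed(22); rnorm(300) + 0.2 * sim$geno[, 3] })
  ss <- compute_summary_stats(sim$geno, y, sim$variants, "y")
  for (j in 1:6) {
    fit <- summary(lm(y ~ sim$geno[, j]))$coefficients
    row <- ss[ss$snp == sim$variants$snp[j], ]
    expect_equal(row$beta, fit[2, 1], tolerance = 1e-10)
    expect_equal(row$beta / row$se, fit[2, 3], tolerance = 1e-8)
    expect_equal(row$p, fit[2, 4], tolerance = 1e-8)
  }
})

test_that("a noiseless phenotype gives the scaling slope and a vanishing p", {
  sim <- simulate_genotypes(100, m = 3, ld_rho = 0, seed = 31)
  y <- sim$geno[, 2]
  ss <- suppressWarnings(compute_summary_stats(sim$geno, y, sim$variants, "y"))
  row <- ss[ss$snp == sim$variants$snp[2], ]
  expect_equal(row$beta, 1, tolerance = 1e-12)
  expect_lte(row$p, 1e-250)
})

test_that("permuted phenotypes reject at close to the nominal rate", {
  sim <- simulate_genotypes(200, m = 20, ld_rho = 0, seed = 41)
  y <- local({ set.seed(42); rnorm(200) })
  ps <- unlist(lapply(1:200, function(i) {
    yp <- local({ set.seed(5000 + i); sample(y) })
    compute_summary_stats(sim$geno, yp, sim$variants, "y")$p
  }))
  expect_gt(mean(ps < 0.05), 0.03)
  expect_lt(mean(ps < 0.05), 0.07)
})

test_that("summary z-statistics are internally consistent with genotype-phenotype correlation", {
  sim <- simulate_genotypes(500, m = 8, ld_rho = 0.6, seed = 51)
  y <- local({ set.seed(52); 0.3 * sim$geno[, 4] + rnorm(500) })
  ss <- compute_summary_stats(sim$geno, y, sim$variants, "y")
  z <- ss$beta / ss$se
  r2_summary <- z^2 / (z^2 + 500 - 2)
  r2_direct <- as.vector(cor(sim$geno[, match(ss$snp, colnames(sim$geno))], y))^2
  expect_equal(r2_summary, r2_direct, tolerance = 1e-10)
})

test_that("monomorphic variants are flagged and excluded", {
  sim <- simulate_genotypes(50, m = 4, ld_rho = 0, seed = 61)
  sim$geno[, 2] <- 0
  y <- local({ set.seed(62); rnorm(50) })
  expect_warning(ss <- compute_summary_stats(sim$geno, y, sim$variants, "y"),
                 "monomorphic")
  expect_equal(nrow(ss), 3)
  expect_false(sim$variants$snp[2] %in% ss$snp)
})

test_that("simulated EWAS tables have both effect signs and FDR below 0.01", {
  tab <- simulate_ewas_table(10, seed = 71)
  expect_equal(nrow(tab), 10)
  expect_true(all(tab$ewas_fdr < 0.01))
  expect_true(any(tab$ewas_beta > 0) && any(tab$ewas_beta < 0))

  fixture <- simulate_ewas_table("cg_asp", ewas_beta = -0.008, ewas_se = 0.002, seed = 72)
  expect_equal(fixture$ewas_beta, -0.008)
  expect_equal(fixture$ewas_se, 0.002)
})

test_that("region simulation is bit-identical under a fixed seed", {
  cfg <- sim_config(n_panel = 60, n_mqtl = 80, n_eqtl = 40, n_gwas = 120,
                    n_variants = 10, seed = 99)
  a <- simulate_region(cfg)
  b <- simulate_region(cfg)
  expect_identical(a$mqtl, b$mqtl)
  expect_identical(a$gwas, b$gwas)
  expect_identical(a$panel$geno, b$panel$geno)
  expect_identical(a$truth, b$truth)
})

test_that("study emission round-trips through the on-disk formats", {
  cfg <- sim_config(n_panel = 60, n_mqtl = 80, n_eqtl = 40, n_gwas = 120,
                    n_variants = 10, seed = 13)
  study <- simulate_study(n_cpgs = 2, n_traits = 2, config = cfg)
  dir <- withr::local_tempdir()
  manifest <- write_study(study, dir)
  back <- load_study(manifest)
  expect_setequal(names(back$mqtl), names(study$mqtl))
  cpg <- names(study$mqtl)[1]
  expect_equal(back$mqtl[[cpg]]$beta, study$mqtl[[cpg]]$beta, tolerance = 1e-12)
  expect_equal(back$outcomes[["trait_1"]]$p, study$outcomes[["trait_1"]]$p,
               tolerance = 1e-12)
  ch <- names(study$panels)[1]
  expect_equal(unname(back$panels[[ch]]$geno), unname(study$panels[[ch]]$geno))
})
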