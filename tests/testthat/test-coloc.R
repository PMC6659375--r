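test_that("the Wakefield log ABF follows its closed form and limits", {
  # z = 0 and V = W: lABF = 0.5 * log(0.5)
  expect_equal(wakefield_abf(0, sqrt(0.04), prior_w = 0.04), 0.5 * log(0.5),
               tolerance = 1e-12)
  z <- seq(0, 8, by = 0.5)
  labf <- wakefield_abf(z * 0.1, 0.1, prior_w = 0.04)
  expect_true(all(diff(labf) > 0))
  expect_lt(abs(wakefield_abf(5 * 0.1, 0.1, prior_w = 1e-12)), 1e-6)
})

test_that("configuration classes enumerate every trait-to-variant-group assignment", {
  expect_equal(length(enumerate_configurations(1)), 2)
  labels2 <- vapply(enumerate_configurations(2), `[[`, "", "label")
  expect_setequal(labels2, c("null", "a", "b", "a.b", "ab"))
  cls <- enumerate_configurations(3)
  labels3 <- vapply(cls, `[[`, "", "label")
  expect_equal(length(labels3), 15)
  expect_equal(anyDuplicated(labels3), 0)
  expect_true(all(c("abc", "ab.c", "ac.b", "bc.a", "a.b.c", "a.b", "ab", "null") %in% labels3))
  # independent count oracle: sum over associated subsets of Bell numbers
  expected_n <- sum(vapply(0:3, function(k) choose(3, k) * bell_number(k), 0))
  expect_equal(length(cls), expected_n)
})

test_that("class evidences match a naive exhaustive-loop oracle on small regions", {
  for (seed in 1:5) {
    m <- 2 + seed  # regions of 3 to 7 variants
    labf <- local({
      set.seed(seed)
      matrix(rnorm(m * 3, 0, 4), m, 3, dimnames = list(paste0("v", 1:m), c("a", "b", "c")))
    })
    for (cl in enumerate_configurations(3)) {
      got <- config_evidence(labf, cl$groups)
      want <- naive_config_evidence(labf, cl$groups)
      if (is.finite(want)) {
        expect_equal(got, want, tolerance = 1e-9)
      } else {
        expect_false(is.finite(got))
      }
    }
  }
})

test_that("single-variant regions give zero evidence to multi-variant classes", {
  labf <- matrix(c(2, 1, 0.5), 1, 3, dimnames = list("v1", c("a", "b", "c")))
  expect_equal(config_evidence(labf, list("a")), 2)
  expect_equal(config_evidence(labf, list(c("a", "b", "c"))), 3.5)
  expect_identical(config_evidence(labf, list("a", "b")), -Inf)
  expect_identical(config_evidence(labf, list(c("a", "b"), "c")), -Inf)
  expect_identical(config_evidence(labf, list()), 0)
})

test_that("posteriors normalize, favour the null on flat data, and respect symmetry", {
  m <- 120
  flat <- matrix(wakefield_abf(rep(0, m * 3), rep(0.05, m * 3)), m, 3,
                 dimnames = list(paste0("v", 1:m), c("a", "b", "c")))
  cp <- moloc_posteriors(flat)
  expect_equal(sum(cp$posterior), 1, tolerance = 1e-10)
  expect_gt(cp$posterior[["null"]], 0.99)

  labf <- local({
    set.seed(42)
    matrix(rnorm(30, 0, 3), 10, 3, dimnames = list(paste0("v", 1:10), c("a", "b", "c")))
  })
  cp1 <- moloc_posteriors(labf)
  expect_equal(sum(cp1$posterior), 1, tolerance = 1e-10)

  # permutation of variant rows changes nothing
  cp_perm <- moloc_posteriors(labf[c(7, 2, 9, 1, 5, 3, 10, 4, 8, 6), ])
  expect_equal(cp_perm$posterior, cp1$posterior, tolerance = 1e-12)

  # relabelling traits a<->b swaps the matching class posteriors exactly
  swapped <- labf[, c(2, 1, 3)]
  colnames(swapped) <- c("a", "b", "c")
  cp_sw <- moloc_posteriors(swapped)
  expect_equal(cp_sw$posterior[["a"]], cp1$posterior[["b"]], tolerance = 1e-12)
  expect_equal(cp_sw$posterior[["ac"]], cp1$posterior[["bc"]], tolerance = 1e-12)
  expect_equal(cp_sw$posterior[["bc.a"]], cp1$posterior[["ac.b"]], tolerance = 1e-12)
  expect_equal(cp_sw$posterior[["abc"]], cp1$posterior[["abc"]], tolerance = 1e-12)
})

test_that("the gene-window scan enforces distance, variant-count and MAF rules", {
  cfg <- sim_config(n_panel = 400, n_mqtl = 500, n_eqtl = 300, n_gwas = 2000,
                    n_variants = 55, maf_range = c(0.1, 0.5),
                    beta_mt = 0.3, causal_r2 = 0.15, seed = 808)
  reg <- simulate_region(cfg)
  cpg <- reg$cpg[1, ]
  genes <- data.frame(
    gene_id = c("NEAR", "FAR"), chrom = cpg$chrom,
    start = c(cpg$pos + 99000, cpg$pos + 101000),
    end = c(cpg$pos + 99000, cpg$pos + 101000) + 400,
    stringsAsFactors = FALSE)
  eqtl <- list(NEAR = reg$eqtl, FAR = reg$eqtl)
  out <- gene_window_scan(cpg, reg$mqtl, eqtl, as.data.frame(reg$gwas), genes, reg$panel)
  expect_equal(out$gene_id, "NEAR")  # 101 kb is outside the window
  expect_equal(out$skip_reason, "")
  expect_gte(out$n_variants, 50)
  expect_equal(sum(unlist(out[grep("^pp_", names(out))])), 1, tolerance = 1e-8)

  # a low-frequency variant is excluded from the common grid
  rare_panel <- reg$panel
  rare_snp <- reg$mqtl$snp[1]
  rare_panel$geno[, rare_snp] <- rep(c(0, 1), c(nrow(rare_panel$geno) - 20, 20)) # MAF 2.5%
  out_rare <- gene_window_scan(cpg, reg$mqtl, eqtl["NEAR"], as.data.frame(reg$gwas),
                               genes[1, ], rare_panel)
  expect_equal(out_rare$n_variants, out$n_variants - 1)

  # below 50 common variants the region is skipped with a reason
  out_small <- gene_window_scan(cpg, reg$mqtl, eqtl["NEAR"], as.data.frame(reg$gwas),
                                genes[1, ], reg$panel, min_variants = 56)
  expect_equal(out_small$skip_reason, "min_variants")
  expect_true(is.na(out_small$ppa_abc))
})

test_that("top-trait selection takes the highest PPA with declared tie-breaks", {
  res <- data.frame(cpg_id = c("cg1", "cg1", "cg2", "cg2", "cg3"),
                    trait_id = c("t1", "t2", "t1", "t2", "t9"),
                    gene_id = "g", ppa_abc = c(0.95, 0.22, 0.5, 0.5, 0.4),
                    mr_p = c(0.5, 1e-9, 1e-3, 1e-8, 0.2),
                    stringsAsFactors = FALSE)
  top <- select_top_trait(res)
  expect_equal(top$trait_id[top$cpg_id == "cg1"], "t1")  # plain argmax
  expect_equal(top$trait_id[top$cpg_id == "cg2"], "t2")  # tie: smaller MR p
  expect_equal(top$trait_id[top$cpg_id == "cg3"], "t9")  # single trait
})

test_that("the regional plot writes an image file", {
  cfg <- sim_config(n_panel = 60, n_mqtl = 80, n_eqtl = 40, n_gwas = 120,
                    n_variants = 10, seed = 3)
  reg <- simulate_region(cfg)
  f <- withr::local_tempfile(fileext = ".png")
  plot_region(reg$mqtl, reg$eqtl, reg$gwas, genes = reg$gene, cpg = reg$cpg[1, ],
              file = f)
  expect_true(file.exists(f) && file.size(f) > 0)
})
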