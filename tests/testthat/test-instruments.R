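cpg_at <- function(pos, chrom = "1", id = "cgX") {
  data.frame(cpg_id = id, chrom = chrom, pos = pos,
             ewas_beta = -0.008, ewas_se = 0.002, ewas_fdr = 0.001,
             stringsAsFactors = FALSE)
}

test_that("cis-mQTL candidates respect the distance and p-value rules strictly", {
  cpg <- cpg_at(2e6)
  mqtl <- regional_dataset(make_sumstats(
    c("in_window", "out_window", "at_threshold"),
    pos = c(2e6 + 999999, 2e6 + 1000001, 2e6 + 10),
    beta = c(0.3, 0.5, 0.3), se = c(0.03, 0.03, 0.03),
    p = c(5e-8, 1e-30, 1.0e-7)), "cgX", "methylation")
  got <- select_cis_mqtl(mqtl, cpg)
  expect_equal(got$snp, "in_window")
  expect_message(
    empty <- select_cis_mqtl(regional_dataset(
      make_sumstats("far", pos = 5e6 + 2e6, beta = 0.3, se = 0.03, p = 1e-20),
      "cgX", "methylation"), cpg),
    "no cis-mQTL")
  expect_equal(nrow(empty), 0)
})

sim_mqtl_region <- function(seed, n = 800, m = 20, ld_rho = 0, causal = NULL,
                            betas = NULL, maf_range = c(0.2, 0.5)) {
  grid <- epimr:::make_variant_grid(m, maf_range, seed = seed)
  panel <- simulate_genotypes(600, grid = grid, ld_rho = ld_rho, seed = seed + 1)
  panel <- epimr:::new_ref_panel(panel$geno, panel$variants[c("snp", "chrom", "pos", "ref", "alt")])
  g <- simulate_genotypes(n, grid = grid, ld_rho = ld_rho, seed = seed + 2)$geno
  y <- local({
    set.seed(seed + 3)
    mu <- rep(0, n)
    for (i in seq_along(causal)) mu <- mu + betas[i] * g[, causal[i]]
    mu + rnorm(n)
  })
  list(grid = grid, panel = panel, g = g, y = y,
       mqtl = compute_summary_stats(g, y, grid, "cgX", "methylation"))
}

test_that("a single causal variant without LD is selected exactly", {
  r <- sim_mqtl_region(200, ld_rho = 0, causal = 7, betas = 0.5)
  ins <- cojo_slct(r$mqtl, r$panel)
  expect_equal(ins$snp, r$grid$snp[7])
  expect_equal(ins$joint_beta, ins$beta, tolerance = 1e-6)
})

test_that("two uncorrelated causal variants are both selected with joint effects near truth", {
  r <- sim_mqtl_region(210, n = 2000, ld_rho = 0, causal = c(5, 15), betas = c(0.4, 0.3))
  ins <- cojo_slct(r$mqtl, r$panel)
  expect_setequal(ins$snp, r$grid$snp[c(5, 15)])
  # oracle: joint regression on the individual-level data
  fit <- summary(lm(r$y ~ r$g[, 5] + r$g[, 15]))$coefficients
  for (k in 1:2) {
    snp <- r$grid$snp[c(5, 15)][k]
    row <- ins[ins$snp == snp, ]
    flip <- if (row$ea == r$grid$alt[c(5, 15)][k]) 1 else -1
    expect_lt(abs(flip * row$joint_beta - fit[k + 1, 1]), 2 * fit[k + 1, 2])
  }
})

test_that("a shadow variant in strong LD with the causal one is not co-selected", {
  r <- sim_mqtl_region(220, n = 1500, m = 8, ld_rho = 0.985, causal = 4, betas = 0.5)
  adj_r2 <- epimr:::panel_cor(r$panel, r$grid$snp)[4, ]^2
  expect_gt(max(adj_r2[-4]), 0.9)  # the shadow regime is present
  ins <- cojo_slct(r$mqtl, r$panel)
  expect_equal(nrow(ins), 1)
})

test_that("instrument selection is invariant to candidate row order", {
  r <- sim_mqtl_region(230, n = 1200, m = 15, ld_rho = 0.5, causal = c(3, 12),
                       betas = c(0.4, 0.35))
  ins1 <- cojo_slct(r$mqtl, r$panel)
  shuffled <- local({ set.seed(1); as.data.frame(r$mqtl)[sample(nrow(r$mqtl)), ] })
  attr(shuffled, "trait_id") <- "cgX"
  ins2 <- cojo_slct(shuffled, r$panel)
  expect_equal(ins1$snp, ins2$snp)
  expect_equal(ins1$joint_beta, ins2$joint_beta)
})

test_that("selected instruments tag the true causal variant across seeds", {
  hits <- vapply(1:50, function(s) {
    cfg <- sim_config(n_panel = 300, n_mqtl = 800, n_eqtl = 10, n_gwas = 10,
                      n_variants = 40, causal_r2 = 0.1, seed = 3000 + s)
    reg <- suppressWarnings(simulate_region(cfg))
    ins <- cojo_slct(select_cis_mqtl(reg$mqtl, reg$cpg[1, ]), reg$panel)
    if (nrow(ins) == 0) return(FALSE)
    r2 <- epimr:::panel_cor(reg$panel, ins$snp, reg$truth$causal_snp$m)^2
    any(r2 >= 0.8)
  }, NA)
  expect_gte(mean(hits), 0.9)
})

test_that("proxy lookup returns identity, respects the r2 threshold, and preserves signs", {
  r <- sim_mqtl_region(240, n = 1000, m = 10, ld_rho = 0.95, causal = 5, betas = 0.5)
  outcome <- as.data.frame(r$mqtl)
  query <- outcome[outcome$snp == r$grid$snp[5], ]

  ident <- find_proxy(query, outcome, r$panel)
  expect_equal(ident$proxy, query$snp)
  expect_equal(ident$r2, 1)

  # remove the query from the outcome: the best LD neighbour stands in
  missing <- outcome[outcome$snp != query$snp, ]
  px <- find_proxy(query, missing, r$panel)
  expect_false(is.null(px))
  expect_gt(px$r2, 0.8)
  rec <- proxy_outcome_record(px, query, missing)
  expect_equal(rec$snp, query$snp)
  h <- harmonize(query, rec)
  expect_true(h$kept)
  expect_equal(sign(h$outcome$beta), sign(query$beta))

  # weak LD: nothing clears the threshold
  weak <- sim_mqtl_region(250, n = 1000, m = 10, ld_rho = 0.3, causal = 5, betas = 0.5)
  wout <- as.data.frame(weak$mqtl)
  wquery <- wout[wout$snp == weak$grid$snp[5], ]
  expect_true(max(epimr:::panel_cor(weak$panel, wquery$snp,
                                    setdiff(wout$snp, wquery$snp))^2) < 0.8)
  expect_message(
    wpx <- find_proxy(wquery, wout[wout$snp != wquery$snp, ], weak$panel),
    "no proxy")
  expect_null(wpx)
})

test_that("MR through a proxy agrees in sign with MR through the variant itself", {
  cfg <- sim_config(n_panel = 500, n_mqtl = 1000, n_eqtl = 10, n_gwas = 4000,
                    n_variants = 12, ld_rho = 0.95, causal_r2 = 0.15,
                    beta_mt = 0.3, seed = 424)
  reg <- simulate_region(cfg)
  ins <- cojo_slct(select_cis_mqtl(reg$mqtl, reg$cpg[1, ]), reg$panel)[1, ]
  gwas <- as.data.frame(reg$gwas)
  direct <- wald_ratio(ins, gwas[gwas$snp == ins$snp, ])
  gwas_missing <- gwas[gwas$snp != ins$snp, ]
  px <- find_proxy(ins, gwas_missing, reg$panel)
  expect_false(is.null(px))
  rec <- proxy_outcome_record(px, ins, gwas_missing)
  h <- harmonize(ins, rec)
  via_proxy <- wald_ratio(h$exposure, h$outcome)
  expect_equal(sign(via_proxy$beta), sign(direct$beta))
})

test_that("harmonization aligns swaps, complements strands and drops ambiguity", {
  e <- make_sumstats("rs1", 100, beta = 0.5, se = 0.05, ea = "A", oa = "G", eaf = 0.3)
  o_swap <- make_sumstats("rs1", 100, beta = 0.2, se = 0.05, ea = "G", oa = "A", eaf = 0.7)
  h <- harmonize(e, o_swap)
  expect_true(h$kept)
  expect_equal(h$outcome$beta, -0.2)
  expect_equal(h$outcome$eaf, 0.3)

  o_strand <- make_sumstats("rs1", 100, beta = 0.2, se = 0.05, ea = "T", oa = "C", eaf = 0.3)
  h2 <- harmonize(e, o_strand)
  expect_true(h2$kept)
  expect_equal(h2$outcome$beta, 0.2)
  expect_equal(h2$outcome$ea, "A")

  pal_e <- make_sumstats("rs2", 100, beta = 0.5, se = 0.05, ea = "A", oa = "T", eaf = 0.5)
  pal_o <- make_sumstats("rs2", 100, beta = 0.2, se = 0.05, ea = "A", oa = "T", eaf = 0.5)
  h3 <- harmonize(pal_e, pal_o)
  expect_false(h3$kept)
  expect_equal(h3$reason, "palindromic_ambiguous")

  pal_clear_e <- make_sumstats("rs3", 100, beta = 0.5, se = 0.05, ea = "A", oa = "T", eaf = 0.2)
  pal_clear_o <- make_sumstats("rs3", 100, beta = 0.2, se = 0.05, ea = "A", oa = "T", eaf = 0.79)
  h4 <- harmonize(pal_clear_e, pal_clear_o)
  expect_true(h4$kept)
  expect_equal(h4$outcome$beta, -0.2)  # frequency discordance marks a strand flip

  o_bad <- make_sumstats("rs1", 100, beta = 0.2, se = 0.05, ea = "A", oa = "C")
  h5 <- harmonize(e, o_bad)
  expect_false(h5$kept)
  expect_equal(h5$reason, "incompatible_alleles")
})

test_that("harmonization is idempotent and MR is invariant to global allele relabelling", {
  e <- make_sumstats("rs1", 100, beta = 0.5, se = 0.05, ea = "A", oa = "G", eaf = 0.3)
  o <- make_sumstats("rs1", 100, beta = 0.2, se = 0.04, ea = "G", oa = "A", eaf = 0.7)
  h1 <- harmonize(e, o)
  h2 <- harmonize(h1$exposure, h1$outcome)
  expect_identical(h2$outcome, h1$outcome)

  base <- wald_ratio(h1$exposure, h1$outcome)
  # relabel the outcome dataset's alleles wholesale: same inference
  h_sw <- harmonize(e, swap_allele_labels(o))
  expect_equal(wald_ratio(h_sw$exposure, h_sw$outcome)$beta, base$beta, tolerance = 1e-12)
  # relabel the exposure dataset too
  h_esw <- harmonize(swap_allele_labels(e), o)
  expect_equal(wald_ratio(h_esw$exposure, h_esw$outcome)$beta, base$beta, tolerance = 1e-12)
})
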