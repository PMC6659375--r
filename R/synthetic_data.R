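#' Simulation settings for one coupled methylation/expression/trait region
#'
#' Defines the population model the simulator draws from: an
#' LD-structured variant grid and three independently sampled cohorts
#' (mQTL, eQTL, GWAS) plus a genotype reference panel, with phenotypes
#' coupled through a configurable causal architecture.
#'
#' Scenarios:
#' \describe{
#'   \item{shared}{one causal variant drives methylation; expression and the
#'     trait are downstream of methylation (`beta_me`, `beta_mt`), so all
#'     three association signals share the variant.}
#'   \item{distinct}{methylation, expression and the trait each have their
#'     own causal variant, chosen with low mutual LD; the true
#'     methylation-to-trait effect is zero.}
#'   \item{null}{methylation is genetic; expression and the trait are pure
#'     noise.}
#'   \item{methylation_only}{methylation drives the trait (`beta_mt`) but
#'     expression is noise.}
#'   \item{trait_causal}{the trait is genetic and methylation is downstream
#'     of the trait with effect `beta_mt` (reverse-causation architecture);
#'     expression is noise.}
#' }
#'
#' All phenotypes are built to unit population variance, so effects are in
#' SD-per-SD units and per-allele effects in SD-per-allele units.
#'
#' @param n_panel,n_mqtl,n_eqtl,n_gwas cohort sizes.
#' @param n_variants variants in the region.
#' @param ld_rho first-order autoregressive LD parameter in [0,1).
#' @param maf_range minor-allele-frequency range, within (0, 0.5].
#' @param scenario causal-sharing scenario, see Details.
#' @param causal_r2 variance of methylation (or of the genetic trait in
#'   `trait_causal`) explained by its causal variant, in (0,1).
#' @param beta_me methylation-to-expression effect (SD/SD).
#' @param beta_mt methylation-to-trait effect (SD/SD); in `trait_causal`
#'   it is the trait-to-methylation effect.
#' @param ewas_beta exposure-to-methylation EWAS effect used for the CpG
#'   annotation emitted with the region.
#' @param ewas_se EWAS standard error.
#' @param seed master seed; every cohort uses a sub-stream derived from it.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_panel = 500, n_mqtl = 1000, n_eqtl = 400, n_gwas = 10000,
                       n_variants = 60, ld_rho = 0.7, maf_range = c(0.05, 0.5),
                       scenario = c("shared", "distinct", "null",
                                    "methylation_only", "trait_causal"),
                       causal_r2 = 0.1, beta_me = 0.6, beta_mt = 0.1,
                       ewas_beta = -0.008, ewas_se = 0.002, seed = 1) {
  scenario <- match.arg(scenario)
  stopifnot(causal_r2 > 0, causal_r2 < 1,
            n_panel >= 10, n_mqtl >= 10, n_eqtl >= 10, n_gwas >= 10,
            ld_rho >= 0, ld_rho < 1,
            length(maf_range) == 2, maf_range[1] > 0, maf_range[2] <= 0.5,
            maf_range[1] <= maf_range[2],
            abs(beta_me) < 1, abs(beta_mt) < 1)
  structure(list(n_panel = n_panel, n_mqtl = n_mqtl, n_eqtl = n_eqtl, n_gwas = n_gwas,
                 n_variants = n_variants, ld_rho = ld_rho, maf_range = maf_range,
                 scenario = scenario, causal_r2 = causal_r2,
                 beta_me = beta_me, beta_mt = beta_mt,
                 ewas_beta = ewas_beta, ewas_se = ewas_se,
                 seed = as.integer(seed)),
            class = "sim_config")
}

# Variant grid for one region: MAFs, positions and (non-palindromic)
# allele pairs, shared by every cohort drawn for the region.
# MAFs vary smoothly along the region (AR(1) latent, like the LD itself):
# variants in strong LD necessarily carry similar allele frequencies, and
# frequency mismatch would otherwise cap the attainable genotype
# correlation well below the target.
make_variant_grid <- function(m, maf_range, chrom = "1", start = 1e6, spacing = 2000,
                              seed = NULL, maf_rho = 0.9) {
  draw <- function() {
    u <- stats::rnorm(m)
    if (m > 1) {
      for (j in 2:m) u[j] <- maf_rho * u[j - 1] + sqrt(1 - maf_rho^2) * u[j]
    }
    maf <- maf_range[1] + (maf_range[2] - maf_range[1]) * stats::pnorm(u)
    pairs <- list(c("A", "G"), c("G", "A"), c("A", "C"), c("C", "A"),
                  c("T", "G"), c("G", "T"), c("T", "C"), c("C", "T"))
    al <- pairs[sample.int(length(pairs), m, replace = TRUE)]
    data.frame(snp = sprintf("rs%s_%04d", chrom, seq_len(m)),
               chrom = as.character(chrom),
               pos = start + (seq_len(m) - 1L) * spacing,
               ref = vapply(al, `[`, "", 1L), alt = vapply(al, `[`, "", 2L),
               maf = maf, stringsAsFactors = FALSE)
  }
  if (is.null(seed)) draw() else with_seed(seed, draw())
}

#' Simulate LD-structured genotype dosages
#'
#' Each individual carries two independent haplotypes; within a haplotype,
#' allele indicators come from thresholding a first-order autoregressive
#' latent Gaussian at the MAF quantile (a Gaussian copula). Thresholding
#' attenuates correlation, so each adjacent-pair latent correlation is
#' calibrated (via the bivariate normal orthant probability) to make the
#' *genotype* correlation equal `ld_rho`; genotype correlation therefore
#' decays approximately as `ld_rho^distance` in grid steps.
#'
#' @param n individuals.
#' @param m variants (ignored when `grid` is supplied).
#' @param ld_rho autoregressive LD parameter in [0,1).
#' @param maf_range MAF range for a freshly drawn grid.
#' @param seed optional seed (local to this call).
#' @param grid optional variant grid from a previous call, to draw a new
#'   cohort on the same variants.
#' @param chrom,start chromosome label and first variant position for a
#'   fresh grid.
#' @return list with `geno` (n x m dosage matrix, columns named by variant
#'   id; the dosage counts the `alt` allele) and `variants` (the grid).
#' @export
simulate_genotypes <- function(n, m = NULL, ld_rho = 0.7, maf_range = c(0.05, 0.5),
                               seed = NULL, grid = NULL, chrom = "1", start = 1e6) {
  run <- function() {
    if (is.null(grid)) {
      stopifnot(!is.null(m))
      grid <- make_variant_grid(m, maf_range, chrom = chrom, start = start)
    }
    m <- nrow(grid)
    thr <- stats::qnorm(grid$maf)
    rho_lat <- attr(grid, "rho_lat")
    if (is.null(rho_lat) || !identical(attr(grid, "ld_rho"), ld_rho)) {
      rho_lat <- if (m > 1) {
        vapply(2:m, function(j) latent_rho_for(ld_rho, thr[j - 1], thr[j]), 0)
      } else numeric(0)
    }
    hap <- function() {
      z <- matrix(stats::rnorm(n * m), n, m)
      for (j in seq_along(rho_lat)) {
        r <- rho_lat[j]
        z[, j + 1] <- r * z[, j] + sqrt(1 - r^2) * z[, j + 1]
      }
      sweep(z, 2, thr, `<`) + 0
    }
    geno <- hap() + hap()
    colnames(geno) <- grid$snp
    list(geno = geno, variants = grid)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Latent correlation required for two thresholded standard normals (at
# thresholds t1, t2) to show phi correlation `target`. Root-found through
# the bivariate normal orthant probability; the attainable phi is capped by
# the frequency mismatch, in which case the cap (minus epsilon) is used.
latent_rho_for <- function(target, t1, t2) {
  if (target <= 0) return(0)
  p1 <- stats::pnorm(t1)
  p2 <- stats::pnorm(t2)
  s1 <- sqrt(p1 * (1 - p1))
  s2 <- sqrt(p2 * (1 - p2))
  phi_of <- function(r) {
    p11 <- mvtnorm::pmvnorm(upper = c(t1, t2), corr = matrix(c(1, r, r, 1), 2))[1]
    (p11 - p1 * p2) / (s1 * s2)
  }
  if (phi_of(0.9999) <= target) return(0.9999)
  stats::uniroot(function(r) phi_of(r) - target, c(0, 0.9999), tol = 1e-6)$root
}

# Precompute and cache the calibrated latent AR parameters on a grid so
# that several cohorts drawn on the same grid share the calibration.
calibrate_grid_ld <- function(grid, ld_rho) {
  thr <- stats::qnorm(grid$maf)
  m <- nrow(grid)
  attr(grid, "rho_lat") <- if (m > 1) {
    vapply(2:m, function(j) latent_rho_for(ld_rho, thr[j - 1], thr[j]), 0)
  } else numeric(0)
  attr(grid, "ld_rho") <- ld_rho
  grid
}

# Per-allele effect giving a target variance contribution for a variant
# with population MAF `maf` (genotype variance 2*maf*(1-maf)).
per_allele_effect <- function(target_var, maf) sqrt(target_var / (2 * maf * (1 - maf)))

#' Simulate coupled phenotypes for the three cohorts
#'
#' Builds methylation (mQTL cohort), expression (eQTL cohort) and complex
#' trait (GWAS cohort) phenotypes under the causal architecture of
#' `config$scenario`, with all phenotypes at unit population variance.
#' Downstream phenotypes inherit the genetic signal only through their
#' upstream phenotype, as in a mediation chain.
#'
#' @param g_mqtl,g_eqtl,g_gwas dosage matrices for the three cohorts, on a
#'   common variant grid.
#' @param grid the shared variant grid (with a `maf` column).
#' @param causal list with elements `m`, `e`, `t`: column indices of the
#'   causal variant for methylation, expression and trait (NA when the
#'   scenario gives a trait no genetic driver of its own).
#' @param config a [sim_config()].
#' @param seed optional seed (local to this call).
#' @return list with phenotype vectors `meth`, `expr`, `trait` and a `truth`
#'   list (causal indices, true methylation-to-trait effect `true_mr`,
#'   scenario).
#' @export
simulate_traits <- function(g_mqtl, g_eqtl, g_gwas, grid, causal, config, seed = NULL) {
  run <- function() {
    cr2 <- config$causal_r2
    b_me <- config$beta_me
    b_mt <- config$beta_mt
    sc <- config$scenario

    meth_on <- function(g) {
      b <- per_allele_effect(cr2, grid$maf[causal$m])
      b * g[, causal$m] + stats::rnorm(nrow(g), sd = sqrt(1 - cr2))
    }
    noise <- function(g) stats::rnorm(nrow(g))

    if (sc == "trait_causal") {
      trait_on <- function(g) {
        b <- per_allele_effect(cr2, grid$maf[causal$t])
        b * g[, causal$t] + stats::rnorm(nrow(g), sd = sqrt(1 - cr2))
      }
      trait <- trait_on(g_gwas)
      meth <- b_mt * trait_on(g_mqtl) + stats::rnorm(nrow(g_mqtl), sd = sqrt(1 - b_mt^2))
      expr <- noise(g_eqtl)
      true_mr <- 0
    } else {
      meth <- meth_on(g_mqtl)
      expr <- switch(sc,
        shared = b_me * meth_on(g_eqtl) + stats::rnorm(nrow(g_eqtl), sd = sqrt(1 - b_me^2)),
        distinct = {
          b <- per_allele_effect(cr2, grid$maf[causal$e])
          b * g_eqtl[, causal$e] + stats::rnorm(nrow(g_eqtl), sd = sqrt(1 - cr2))
        },
        noise(g_eqtl))
      trait <- switch(sc,
        shared = ,
        methylation_only = b_mt * meth_on(g_gwas) + stats::rnorm(nrow(g_gwas), sd = sqrt(1 - b_mt^2)),
        distinct = {
          gv <- b_mt^2 * cr2
          b <- b_mt * per_allele_effect(cr2, grid$maf[causal$t])
          b * g_gwas[, causal$t] + stats::rnorm(nrow(g_gwas), sd = sqrt(1 - gv))
        },
        noise(g_gwas))
      true_mr <- if (sc %in% c("shared", "methylation_only")) b_mt else 0
    }
    list(meth = meth, expr = expr, trait = trait,
         truth = list(causal = causal, true_mr = true_mr, scenario = sc))
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

#' Per-variant summary statistics from individual-level data
#'
#' Runs a univariate least-squares regression of the phenotype on each
#' variant's dosage and emits beta, SE, a two-sided t-test p-value, the
#' effect-allele frequency (the counted ALT allele is the effect allele) and
#' the sample size. Monomorphic variants yield a missing beta and are
#' rejected by [regional_dataset()]; p-values are floored at 1e-300.
#'
#' @param geno dosage matrix with variant ids as column names.
#' @param pheno phenotype vector.
#' @param grid variant grid carrying `snp`, `chrom`, `pos`, `ref`, `alt`.
#' @param trait_id,trait_type dataset labels.
#' @return a [regional_dataset()].
#' @export
compute_summary_stats <- function(geno, pheno, grid, trait_id, trait_type = "complex") {
  stopifnot(length(pheno) == nrow(geno), ncol(geno) == nrow(grid))
  n <- length(pheno)
  gc <- sweep(geno, 2, colMeans(geno))
  yc <- pheno - mean(pheno)
  sxx <- colSums(gc^2)
  sxy <- as.vector(crossprod(gc, yc))
  syy <- sum(yc^2)
  mono <- sxx <= 0
  beta <- ifelse(mono, NA_real_, sxy / sxx)
  # floor at numerical-noise scale: an exact fit must keep se > 0
  rss <- pmax(syy - beta * sxy, syy * .Machine$double.eps)
  se <- ifelse(mono, NA_real_, sqrt(rss / ((n - 2) * sxx)))
  tstat <- beta / se
  p <- pmax(2 * stats::pt(-abs(tstat), df = n - 2), 1e-300)
  if (any(mono)) warning(sprintf("%d monomorphic variant(s) flagged with missing beta", sum(mono)))
  df <- data.frame(snp = grid$snp, chrom = grid$chrom, pos = grid$pos,
                   ea = grid$alt, oa = grid$ref,
                   eaf = colMeans(geno) / 2, beta = beta, se = se, p = p, n = n,
                   stringsAsFactors = FALSE)
  suppressWarnings(regional_dataset(df, trait_id = trait_id, trait_type = trait_type))
}

#' Simulate an EWAS-style CpG annotation table
#'
#' Emulates the shape of a prenatal-exposure EWAS hit list: each CpG carries
#' an exposure-to-methylation effect, its SE, and an FDR below 0.01. Signs
#' alternate around `ewas_beta` so both directions are represented whenever
#' two or more CpGs are requested.
#'
#' @param cpg_ids CpG identifiers (or a single integer count).
#' @param chrom,pos chromosome labels and positions (recycled).
#' @param ewas_beta,ewas_se effect magnitude (the first CpG keeps the sign
#'   of `ewas_beta`) and standard error.
#' @param seed optional seed.
#' @return data.frame with `cpg_id`, `chrom`, `pos`, `ewas_beta`, `ewas_se`,
#'   `ewas_fdr`.
#' @export
simulate_ewas_table <- function(cpg_ids, chrom = "1", pos = 1e6,
                                ewas_beta = -0.008, ewas_se = 0.002, seed = NULL) {
  run <- function() {
    if (is.numeric(cpg_ids) && length(cpg_ids) == 1L) {
      cpg_ids <- sprintf("cg%08d", seq_len(cpg_ids))
    }
    k <- length(cpg_ids)
    signs <- rep_len(c(1, -1), k)
    data.frame(cpg_id = cpg_ids, chrom = rep_len(as.character(chrom), k),
               pos = rep_len(pos, k),
               ewas_beta = ewas_beta * signs, ewas_se = ewas_se,
               ewas_fdr = stats::runif(k, 0, 0.009), stringsAsFactors = FALSE)
  }
  if (is.null(seed)) run() else with_seed(seed, run())
}

# Choose causal variant indices on a grid given the scenario, using panel LD
# so that "distinct" variants have low mutual r-squared (<= r2_max).
choose_causal <- function(grid, panel, scenario, r2_max = 0.3) {
  m <- nrow(grid)
  eligible <- which(grid$maf >= 0.1)
  if (!length(eligible)) eligible <- seq_len(m)
  c_m <- eligible[which.min(abs(eligible - (m + 1) / 2))]
  if (scenario != "distinct") {
    return(list(m = c_m,
                e = if (scenario == "shared") c_m else NA_integer_,
                t = switch(scenario,
                           shared = c_m, methylation_only = c_m,
                           trait_causal = c_m, NA_integer_)))
  }
  r2_m <- as.vector(panel_cor(panel, grid$snp, grid$snp[c_m]))^2
  ok_e <- setdiff(eligible[r2_m[eligible] <= r2_max], c_m)
  c_e <- if (length(ok_e)) ok_e[which.min(r2_m[ok_e])] else setdiff(eligible, c_m)[1]
  r2_e <- as.vector(panel_cor(panel, grid$snp, grid$snp[c_e]))^2
  ok_t <- setdiff(eligible[r2_m[eligible] <= r2_max & r2_e[eligible] <= r2_max], c(c_m, c_e))
  c_t <- if (length(ok_t)) ok_t[which.min(pmax(r2_m[ok_t], r2_e[ok_t]))] else
    setdiff(eligible, c(c_m, c_e))[1]
  list(m = c_m, e = c_e, t = c_t)
}

#' Simulate one complete region: panel, three cohorts, summary statistics
#'
#' Draws a variant grid, a reference panel and three non-overlapping cohorts
#' from the same population model (the two-sample assumption), builds
#' phenotypes under the configured scenario, and regresses each phenotype on
#' every variant to emit the three summary-statistic datasets the pipeline
#' consumes. A CpG annotation row (placed next to the methylation causal
#' variant) and a gene interval are emitted alongside.
#'
#' @param config a [sim_config()].
#' @param chrom chromosome label for the region.
#' @param cpg_id,gene_id,trait_id identifiers for the emitted annotations.
#' @return list of class `sim_region` with elements `mqtl`, `eqtl`, `gwas`
#'   (regional datasets), `panel`, `grid`, `cpg`, `gene`, `truth`, `config`.
#' @export
simulate_region <- function(config = sim_config(), chrom = "1",
                            cpg_id = NULL, gene_id = NULL, trait_id = "trait_1") {
  seeds <- derive_seeds(config$seed, 7)
  grid <- make_variant_grid(config$n_variants, config$maf_range, chrom = chrom,
                            seed = seeds[1])
  grid <- calibrate_grid_ld(grid, config$ld_rho)
  panel <- simulate_genotypes(config$n_panel, grid = grid, ld_rho = config$ld_rho,
                              seed = seeds[2])
  panel <- new_ref_panel(panel$geno, panel$variants[c("snp", "chrom", "pos", "ref", "alt")])
  g_m <- simulate_genotypes(config$n_mqtl, grid = grid, ld_rho = config$ld_rho,
                            seed = seeds[3])$geno
  g_e <- simulate_genotypes(config$n_eqtl, grid = grid, ld_rho = config$ld_rho,
                            seed = seeds[4])$geno
  g_g <- simulate_genotypes(config$n_gwas, grid = grid, ld_rho = config$ld_rho,
                            seed = seeds[5])$geno
  causal <- choose_causal(grid, panel, config$scenario)
  ph <- simulate_traits(g_m, g_e, g_g, grid, causal, config, seed = seeds[6])

  if (is.null(cpg_id)) cpg_id <- sprintf("cg%s_1", chrom)
  if (is.null(gene_id)) gene_id <- sprintf("GENE%s", chrom)
  cpg <- simulate_ewas_table(cpg_id, chrom = chrom, pos = grid$pos[causal$m] + 523,
                             ewas_beta = config$ewas_beta, ewas_se = config$ewas_se,
                             seed = seeds[7])
  gene <- data.frame(gene_id = gene_id, chrom = chrom,
                     start = max(1, grid$pos[causal$m] - 20000),
                     end = grid$pos[causal$m] + 20000, stringsAsFactors = FALSE)
  truth <- ph$truth
  truth$causal_snp <- list(m = grid$snp[causal$m],
                           e = if (is.na(causal$e)) NA_character_ else grid$snp[causal$e],
                           t = if (is.na(causal$t)) NA_character_ else grid$snp[causal$t])
  structure(list(
    mqtl = compute_summary_stats(g_m, ph$meth, grid, trait_id = cpg_id, trait_type = "methylation"),
    eqtl = compute_summary_stats(g_e, ph$expr, grid, trait_id = gene_id, trait_type = "expression"),
    gwas = compute_summary_stats(g_g, ph$trait, grid, trait_id = trait_id, trait_type = "complex"),
    panel = panel, grid = grid, cpg = cpg, gene = gene, truth = truth, config = config
  ), class = "sim_region")
}

#' Simulate a multi-region, multi-trait study for an end-to-end run
#'
#' Builds `n_cpgs` regions (one CpG and one nearby gene each, on separate
#' chromosome labels) and `n_traits` complex traits measured in one shared
#' GWAS cohort per region. Exactly one CpG-trait pair is planted with the
#' `shared` causal architecture (methylation -> expression -> trait, all on
#' one variant); every other region-trait combination is null for the trait
#' and every other region's expression is noise.
#'
#' @param n_cpgs,n_traits grid dimensions.
#' @param planted_cpg,planted_trait indices of the planted pair.
#' @param config baseline [sim_config()]; its `scenario` is overridden per
#'   region (shared for the planted region, null elsewhere).
#' @return list of class `sim_study`: `cpgs`, `genes` (annotation tables),
#'   `mqtl` (per-CpG datasets), `eqtl` (per-gene datasets), `outcomes`
#'   (per-trait genome-wide summary data.frames), `panels` (per-chromosome
#'   reference panels), `truth`, `config`.
#' @export
simulate_study <- function(n_cpgs = 10, n_traits = 6, planted_cpg = 1,
                           planted_trait = 1, config = sim_config()) {
  stopifnot(planted_cpg >= 1, planted_cpg <= n_cpgs,
            planted_trait >= 1, planted_trait <= n_traits)
  seeds <- derive_seeds(config$seed, n_cpgs)
  trait_ids <- sprintf("trait_%d", seq_len(n_traits))
  cpg_rows <- list(); gene_rows <- list()
  mqtl <- list(); eqtl <- list(); panels <- list()
  out_rows <- stats::setNames(vector("list", n_traits), trait_ids)
  truths <- list()

  for (i in seq_len(n_cpgs)) {
    chrom <- as.character(i)
    cfg <- config
    cfg$seed <- seeds[i]
    cfg$scenario <- if (i == planted_cpg) "shared" else "null"
    sub <- derive_seeds(cfg$seed, 8)
    grid <- make_variant_grid(cfg$n_variants, cfg$maf_range, chrom = chrom, seed = sub[1])
    grid <- calibrate_grid_ld(grid, cfg$ld_rho)
    panel <- simulate_genotypes(cfg$n_panel, grid = grid, ld_rho = cfg$ld_rho, seed = sub[2])
    panel <- new_ref_panel(panel$geno, panel$variants[c("snp", "chrom", "pos", "ref", "alt")])
    g_m <- simulate_genotypes(cfg$n_mqtl, grid = grid, ld_rho = cfg$ld_rho, seed = sub[3])$geno
    g_e <- simulate_genotypes(cfg$n_eqtl, grid = grid, ld_rho = cfg$ld_rho, seed = sub[4])$geno
    g_g <- simulate_genotypes(cfg$n_gwas, grid = grid, ld_rho = cfg$ld_rho, seed = sub[5])$geno
    causal <- choose_causal(grid, panel, cfg$scenario)
    ph <- simulate_traits(g_m, g_e, g_g, grid, causal, cfg, seed = sub[6])

    cpg_id <- sprintf("cg%08d", i)
    gene_id <- sprintf("GENE%s", chrom)
    cpg_rows[[i]] <- simulate_ewas_table(cpg_id, chrom = chrom,
                                         pos = grid$pos[causal$m] + 523,
                                         ewas_beta = config$ewas_beta,
                                         ewas_se = config$ewas_se, seed = sub[7])
    gene_rows[[i]] <- data.frame(gene_id = gene_id, chrom = chrom,
                                 start = max(1, grid$pos[causal$m] - 20000),
                                 end = grid$pos[causal$m] + 20000, stringsAsFactors = FALSE)
    mqtl[[cpg_id]] <- compute_summary_stats(g_m, ph$meth, grid, cpg_id, "methylation")
    eqtl[[gene_id]] <- compute_summary_stats(g_e, ph$expr, grid, gene_id, "expression")
    panels[[chrom]] <- panel

    # one GWAS cohort per region, n_traits phenotypes on it
    pheno_seeds <- derive_seeds(sub[8], n_traits)
    for (k in seq_len(n_traits)) {
      y <- if (i == planted_cpg && k == planted_trait) ph$trait else
        with_seed(pheno_seeds[k], stats::rnorm(cfg$n_gwas))
      out_rows[[k]][[i]] <- as.data.frame(
        compute_summary_stats(g_g, y, grid, trait_ids[k], "complex"))
    }
    truths[[cpg_id]] <- ph$truth
  }

  outcomes <- lapply(out_rows, function(lst) do.call(rbind, lst))
  structure(list(
    cpgs = do.call(rbind, cpg_rows), genes = do.call(rbind, gene_rows),
    mqtl = mqtl, eqtl = eqtl, outcomes = outcomes, panels = panels,
    truth = list(planted_cpg = sprintf("cg%08d", planted_cpg),
                 planted_trait = trait_ids[planted_trait],
                 regions = truths),
    config = config
  ), class = "sim_study")
}

#' Write a reference panel as a plain-text VCF
#'
#' Emits a minimal VCFv4.2 with GT-only genotype columns, the format
#' [read_reference_panel()] consumes.
#'
#' @param panel a `ref_panel`.
#' @param path output path (`.vcf`).
#' @export
write_panel_vcf <- function(panel, path) {
  v <- panel$variants
  n <- nrow(panel$geno)
  gt <- matrix(c("0/0", "0/1", "1/1")[panel$geno + 1], nrow(panel$geno), ncol(panel$geno))
  header <- c("##fileformat=VCFv4.2",
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO", "FORMAT",
                      sprintf("S%04d", seq_len(n))), collapse = "\t"))
  body <- paste(v$chrom, v$pos, v$snp, v$ref, v$alt, ".", "PASS", ".", "GT",
                apply(gt, 2, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a simulated study to disk in the package's external formats
#'
#' Emits tab-delimited summary tables (one per CpG, gene and trait), CpG and
#' gene annotation tables, one VCF reference panel per chromosome, a truth
#' YAML documenting the planted architecture, and a `study.yaml` manifest
#' that [load_study()] and [run_pipeline()] accept.
#'
#' @param study a `sim_study`.
#' @param dir output directory (created if needed).
#' @return path of the written `study.yaml`, invisibly.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rel <- function(...) file.path(dir, ...)
  for (d in c("mqtl", "eqtl", "gwas", "panel")) dir.create(rel(d), showWarnings = FALSE)
  for (id in names(study$mqtl)) write_summary_table(study$mqtl[[id]], rel("mqtl", paste0(id, ".tsv")))
  for (id in names(study$eqtl)) write_summary_table(study$eqtl[[id]], rel("eqtl", paste0(id, ".tsv")))
  for (id in names(study$outcomes)) write_summary_table(study$outcomes[[id]], rel("gwas", paste0(id, ".tsv")))
  utils::write.table(study$cpgs, rel("cpgs.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(study$genes, rel("genes.tsv"), sep = "\t", quote = FALSE, row.names = FALSE)
  for (ch in names(study$panels)) write_panel_vcf(study$panels[[ch]], rel("panel", paste0("chr", ch, ".vcf")))
  yaml::write_yaml(list(scenario = study$config$scenario,
                        planted_cpg = study$truth$planted_cpg,
                        planted_trait = study$truth$planted_trait,
                        seed = study$config$seed),
                   rel("truth.yaml"))
  manifest <- list(
    cpg_annotation = "cpgs.tsv", gene_annotation = "genes.tsv",
    mqtl_dir = "mqtl", eqtl_dir = "eqtl", gwas_dir = "gwas", panel_dir = "panel")
  yaml::write_yaml(manifest, rel("study.yaml"))
  invisible(rel("study.yaml"))
}

#' Load a study written by [write_study()]
#'
#' @param path a `study.yaml` manifest path.
#' @return list with the same shape as a `sim_study` (annotations, per-CpG
#'   mQTL datasets, per-gene eQTL datasets, per-trait outcome tables,
#'   per-chromosome panels).
#' @export
load_study <- function(path) {
  dir <- dirname(path)
  man <- yaml::read_yaml(path)
  rel <- function(p) file.path(dir, p)
  read_dir <- function(sub, type) {
    files <- sort(list.files(rel(sub), pattern = "\\.tsv$", full.names = TRUE))
    ids <- sub("\\.tsv$", "", basename(files))
    stats::setNames(lapply(seq_along(files), function(i)
      read_summary_table(files[i], trait_id = ids[i], trait_type = type)), ids)
  }
  panels <- list()
  for (f in sort(list.files(rel(man$panel_dir), pattern = "\\.vcf", full.names = TRUE))) {
    p <- read_reference_panel(f)
    panels[[as.character(p$variants$chrom[1])]] <- p
  }
  list(cpgs = read_cpg_annotation(rel(man$cpg_annotation)),
       genes = read_gene_annotation(rel(man$gene_annotation)),
       mqtl = read_dir(man$mqtl_dir, "methylation"),
       eqtl = read_dir(man$eqtl_dir, "expression"),
       outcomes = lapply(read_dir(man$gwas_dir, "complex"), as.data.frame),
       panels = panels)
}
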