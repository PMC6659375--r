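#' Instrument-explained variance from a summary record
#'
#' The squared genotype-phenotype correlation implied by a regression
#' summary record: with `z = beta/se`, `r2 = z^2 / (z^2 + n - 2)`. For
#' several (independent) instruments the per-variant values are summed.
#'
#' @param beta,se,n effect, standard error, sample size (vectorized).
#' @return explained-variance estimate(s) in [0,1).
#' @export
steiger_r2 <- function(beta, se, n) {
  stopifnot(all(n >= 3), all(se > 0))
  z <- beta / se
  z^2 / (z^2 + n - 2)
}

#' Directionality test between two traits sharing instruments
#'
#' Compares the instrument-explained correlation in the exposure candidate
#' against that in the outcome candidate with a two-sample Fisher-z test
#' (the two r values come from non-overlapping samples in the two-sample
#' setting): `z = (atanh(r_x) - atanh(r_y)) / sqrt(1/(n_x-3) + 1/(n_y-3))`.
#' The causal direction is assigned to the trait with the larger explained
#' variance when the test rejects at `alpha`, and is indeterminate
#' otherwise. Exchanging the inputs negates `z` and flips the label.
#'
#' @param r2_x,r2_y explained variance of the instrument(s) in trait X / Y.
#' @param n_x,n_y sample sizes behind the two estimates.
#' @param alpha decision level.
#' @return list of class `steiger_result`: `r2_exposure`, `r2_outcome`,
#'   `direction` (`"exposure_to_outcome"`, `"outcome_to_exposure"` or
#'   `"indeterminate"`), `z_statistic`, `pvalue`.
#' @export
steiger_direction <- function(r2_x, r2_y, n_x, n_y, alpha = 0.05) {
  stopifnot(r2_x >= 0, r2_x < 1, r2_y >= 0, r2_y < 1, n_x > 3, n_y > 3)
  z <- (atanh(sqrt(r2_x)) - atanh(sqrt(r2_y))) / sqrt(1 / (n_x - 3) + 1 / (n_y - 3))
  p <- 2 * stats::pnorm(-abs(z))
  direction <- if (p < alpha) {
    if (r2_x > r2_y) "exposure_to_outcome" else "outcome_to_exposure"
  } else "indeterminate"
  structure(list(r2_exposure = r2_x, r2_outcome = r2_y, direction = direction,
                 z_statistic = z, pvalue = p),
            class = "steiger_result")
}

#' @export
print.steiger_result <- function(x, ...) {
  cat(sprintf("<steiger_result> r2 %.4g vs %.4g -> %s (z = %.2f, p = %.3g)\n",
              x$r2_exposure, x$r2_outcome, x$direction, x$z_statistic, x$pvalue))
  invisible(x)
}

# Greedy LD pruning: keep the best-p variant, drop everything with panel
# r2 >= r2_max to anything kept, repeat.
ld_prune <- function(records, panel, r2_max = 0.1) {
  records <- records[records$snp %in% panel$variants$snp, , drop = FALSE]
  records <- records[order(records$p, records$snp), , drop = FALSE]
  kept <- integer()
  for (i in seq_len(nrow(records))) {
    if (!length(kept)) {
      kept <- i
      next
    }
    r2 <- as.vector(panel_cor(panel, records$snp[i], records$snp[kept]))^2
    if (all(r2 < r2_max)) kept <- c(kept, i)
  }
  records[kept, , drop = FALSE]
}

#' Reverse MR: complex trait as exposure, methylation as outcome
#'
#' Evaluates whether genetic liability to the complex trait has an effect on
#' DNA methylation, by swapping the roles of the forward analysis:
#' genome-wide-significant trait variants (p < `p_threshold`) are LD-pruned
#' in the panel (pairwise r2 < `prune_r2`), harmonized to the mQTL dataset
#' (through proxies where needed) and combined with IVW/Wald.
#'
#' @param trait_ds trait summary data.frame (exposure side).
#' @param mqtl_ds methylation dataset (outcome side).
#' @param panels `ref_panel` or per-chromosome list.
#' @param p_threshold instrument significance threshold.
#' @param prune_r2 LD-pruning cutoff among instruments.
#' @param trait_id,cpg_id labels for the result.
#' @return single-row `mr_result`, or `NULL` (with a reason message) when no
#'   instrument is harmonizable.
#' @export
reverse_mr <- function(trait_ds, mqtl_ds, panels, p_threshold = 5e-8, prune_r2 = 0.1,
                       trait_id = "trait", cpg_id = attr(mqtl_ds, "trait_id")) {
  ins <- trait_ds[!is.na(trait_ds$p) & trait_ds$p < p_threshold, , drop = FALSE]
  if (nrow(ins) == 0L) {
    message("reverse_mr: no genome-wide-significant trait instrument; skipped")
    return(NULL)
  }
  pruned <- list()
  for (ch in unique(ins$chrom)) {
    panel <- tryCatch(get_panel(panels, ch), error = function(e) NULL)
    if (is.null(panel)) next
    pruned[[ch]] <- ld_prune(ins[ins$chrom == ch, , drop = FALSE], panel, prune_r2)
  }
  ins <- do.call(rbind, pruned)
  if (is.null(ins) || nrow(ins) == 0L) {
    message("reverse_mr: no instrument present in the reference panel; skipped")
    return(NULL)
  }
  exp_rows <- list(); out_rows <- list()
  for (i in seq_len(nrow(ins))) {
    q <- ins[i, , drop = FALSE]
    panel <- get_panel(panels, q$chrom)
    out_rec <- mqtl_ds[mqtl_ds$snp == q$snp, , drop = FALSE]
    if (nrow(out_rec) == 0L) {
      px <- find_proxy(q, as.data.frame(mqtl_ds), panel)
      if (is.null(px)) next
      out_rec <- proxy_outcome_record(px, q, as.data.frame(mqtl_ds))
      if (is.null(out_rec)) next
    }
    h <- harmonize(q, out_rec[1, , drop = FALSE])
    if (!h$kept) next
    exp_rows[[length(exp_rows) + 1L]] <- as.data.frame(h$exposure)
    out_rows[[length(out_rows) + 1L]] <- as.data.frame(h$outcome)
  }
  if (!length(exp_rows)) {
    message("reverse_mr: no harmonizable instrument; skipped")
    return(NULL)
  }
  res <- ivw(do.call(rbind, exp_rows), do.call(rbind, out_rows),
             cpg_id = cpg_id, trait_id = trait_id)
  res$method <- paste0("reverse_", res$method)
  res
}

#' Chain the EWAS exposure effect with the MR effect
#'
#' Orients the implied effect of the upstream exposure on the complex trait
#' through the CpG: the sign of `ewas_beta * mr_beta` determines whether the
#' exposure putatively raises or lowers the trait. The report carries both
#' component signs; a zero on either side yields `"none"`. The wording is
#' produced mechanically from the sign product — no phenotype knowledge is
#' embedded.
#'
#' @param cpg CpG annotation row (uses `ewas_beta`).
#' @param mr single-row `mr_result` (uses `beta`).
#' @return data.frame of class `chain_report`: `cpg_id`, `trait_id`,
#'   `ewas_beta`, `mr_beta`, `ewas_sign`, `mr_sign`,
#'   `implied_exposure_effect` (`"raises"`, `"lowers"` or `"none"`).
#' @export
orient_chain <- function(cpg, mr) {
  prod_sign <- sign(cpg$ewas_beta) * sign(mr$beta)
  implied <- if (prod_sign > 0) "raises" else if (prod_sign < 0) "lowers" else "none"
  structure(data.frame(cpg_id = cpg$cpg_id, trait_id = mr$trait_id,
                       ewas_beta = cpg$ewas_beta, mr_beta = mr$beta,
                       ewas_sign = sign(cpg$ewas_beta), mr_sign = sign(mr$beta),
                       implied_exposure_effect = implied, stringsAsFactors = FALSE),
            class = c("chain_report", "data.frame"))
}

#' Compare MR estimates from two independent samples
#'
#' Side-by-side report for the same CpG-trait pair estimated in two samples,
#' timepoints or strata: sign concordance and a two-sample heterogeneity
#' test `z = (b1 - b2) / sqrt(se1^2 + se2^2)` with a two-sided p-value.
#'
#' @param result_a,result_b single-row `mr_result`s (or any records with
#'   `beta` and `se`).
#' @param label_a,label_b sample labels for the report.
#' @return single-row data.frame: both estimates, `sign_concordant`,
#'   `heterogeneity_z`, `heterogeneity_p`.
#' @export
compare_estimates <- function(result_a, result_b, label_a = "sample_a", label_b = "sample_b") {
  z <- (result_a$beta - result_b$beta) / sqrt(result_a$se^2 + result_b$se^2)
  data.frame(label_a = label_a, beta_a = result_a$beta, se_a = result_a$se,
             label_b = label_b, beta_b = result_b$beta, se_b = result_b$se,
             sign_concordant = sign(result_a$beta) == sign(result_b$beta),
             heterogeneity_z = z,
             heterogeneity_p = 2 * stats::pnorm(-abs(z)),
             stringsAsFactors = FALSE)
}
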