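new_mr_result <- function(cpg_id, trait_id, beta, se, p, method, n_instruments, snps) {
  structure(data.frame(cpg_id = cpg_id, trait_id = trait_id, method = method,
                       n_instruments = n_instruments, beta = beta, se = se, p = p,
                       stringsAsFactors = FALSE),
            instruments = snps, class = c("mr_result", "data.frame"))
}

#' Wald ratio causal estimate from a single instrument
#'
#' The causal effect of the exposure on the outcome is the ratio of the
#' variant-outcome association to the variant-exposure association,
#' `beta = Gamma / gamma`, with first-order (delta-method) standard error
#' `se = se_outcome / |gamma|` — exposure-side uncertainty is ignored, which
#' is anti-conservative for weak instruments — and a two-sided normal
#' p-value.
#'
#' @param exposure,outcome harmonized single-row records (`beta`, `se`).
#' @param cpg_id,trait_id labels carried into the result.
#' @return single-row `mr_result` data.frame.
#' @export
wald_ratio <- function(exposure, outcome, cpg_id = NA_character_, trait_id = NA_character_) {
  if (is.na(exposure$beta) || exposure$beta == 0) {
    stop_epimr("Wald ratio undefined: variant-exposure association is zero",
               "epimr_undefined_ratio")
  }
  beta <- outcome$beta / exposure$beta
  se <- outcome$se / abs(exposure$beta)
  p <- min(2 * stats::pnorm(-abs(beta / se)), 1)
  new_mr_result(cpg_id, trait_id, beta, se, max(p, 1e-300), "wald", 1L, exposure$snp)
}

#' Inverse-variance-weighted causal estimate from multiple instruments
#'
#' Fixed-effect IVW: each instrument's Wald ratio is weighted by
#' `w_j = gamma_j^2 / se_outcome_j^2`, giving
#' `beta = sum(w_j * ratio_j) / sum(w_j)` and `se = 1 / sqrt(sum(w_j))`.
#' With a single instrument this reduces exactly to [wald_ratio()].
#'
#' @param exposure,outcome harmonized records, one row per instrument, in
#'   matching order.
#' @param cpg_id,trait_id labels carried into the result.
#' @return single-row `mr_result` data.frame (`method` is `"wald"` for one
#'   instrument, `"ivw"` otherwise).
#' @export
ivw <- function(exposure, outcome, cpg_id = NA_character_, trait_id = NA_character_) {
  exposure <- as.data.frame(exposure)
  outcome <- as.data.frame(outcome)
  if (nrow(exposure) == 0L) stop_epimr("ivw: no instruments", "epimr_empty_input")
  stopifnot(nrow(exposure) == nrow(outcome))
  if (any(exposure$beta == 0)) {
    stop_epimr("ivw: a variant-exposure association is zero", "epimr_undefined_ratio")
  }
  if (nrow(exposure) == 1L) return(wald_ratio(exposure, outcome, cpg_id, trait_id))
  w <- exposure$beta^2 / outcome$se^2
  ratio <- outcome$beta / exposure$beta
  beta <- sum(w * ratio) / sum(w)
  se <- 1 / sqrt(sum(w))
  p <- min(2 * stats::pnorm(-abs(beta / se)), 1)
  new_mr_result(cpg_id, trait_id, beta, se, max(p, 1e-300), "ivw",
                nrow(exposure), exposure$snp)
}

#' Bonferroni significance threshold for a phenome scan
#'
#' `alpha` divided by the number of CpG-trait combinations analysed.
#'
#' @param n_cpgs,n_traits grid dimensions.
#' @param alpha family-wise error rate.
#' @export
bonferroni_threshold <- function(n_cpgs, n_traits, alpha = 0.05) {
  stopifnot(n_cpgs >= 1, n_traits >= 1, alpha > 0, alpha < 1)
  alpha / (n_cpgs * n_traits)
}

#' Asymptotic power of a two-sample MR Wald test
#'
#' For standardized traits, the Wald z-statistic is asymptotically normal
#' with mean `beta_xy * sqrt(n * r2_gx)`, so the two-sided power at level
#' `alpha` is `pnorm(-z_a + ncp) + pnorm(-z_a - ncp)` with
#' `z_a = qnorm(1 - alpha/2)`.
#'
#' @param n_outcome outcome-sample size.
#' @param r2_gx variance of the exposure explained by the instrument(s).
#' @param beta_xy causal effect (SD outcome per SD exposure).
#' @param alpha test level.
#' @export
mr_power <- function(n_outcome, r2_gx, beta_xy, alpha = 0.05) {
  stopifnot(r2_gx > 0, r2_gx < 1, n_outcome >= 10)
  za <- stats::qnorm(1 - alpha / 2)
  ncp <- abs(beta_xy) * sqrt(n_outcome * r2_gx)
  stats::pnorm(-za + ncp) + stats::pnorm(-za - ncp)
}

# Harmonized exposure/outcome instrument pairs for one CpG-trait combination.
# Falls back to an LD proxy when the instrument is absent from the outcome.
collect_pairs <- function(instruments, outcome, panel, r2_threshold = 0.8) {
  exp_rows <- list(); out_rows <- list()
  for (i in seq_len(nrow(instruments))) {
    q <- as.data.frame(instruments)[i, , drop = FALSE]
    out_rec <- outcome[outcome$snp == q$snp & outcome$chrom == q$chrom, , drop = FALSE]
    if (nrow(out_rec) == 0L) {
      px <- find_proxy(q, outcome[outcome$chrom == q$chrom, , drop = FALSE], panel,
                       r2_threshold = r2_threshold)
      if (is.null(px)) next
      out_rec <- proxy_outcome_record(px, q, outcome)
      if (is.null(out_rec)) next
    }
    h <- harmonize(q, out_rec[1, , drop = FALSE])
    if (!h$kept) next
    exp_rows[[length(exp_rows) + 1L]] <- h$exposure
    out_rows[[length(out_rows) + 1L]] <- h$outcome
  }
  if (!length(exp_rows)) return(NULL)
  list(exposure = do.call(rbind, exp_rows), outcome = do.call(rbind, out_rows))
}

#' Phenome-wide two-sample MR scan
#'
#' Runs MR for every CpG-trait combination: instruments are looked up in the
#' outcome dataset (through an LD proxy when absent), harmonized, and
#' combined with the Wald ratio (one instrument) or IVW (several). Results
#' are flagged against the Bonferroni threshold for the scanned grid;
#' per-pair failures never abort the scan and carry machine-readable skip
#' reasons.
#'
#' @param instrument_sets named list (by CpG id) of [cojo_slct()] outputs.
#' @param outcomes named list (by trait id) of outcome summary data.frames.
#' @param panels a `ref_panel` or named per-chromosome list of panels.
#' @param alpha family-wise error rate for the Bonferroni threshold.
#' @param proxy_r2 minimum proxy r-squared.
#' @return data.frame (`cpg_id`, `trait_id`, `method`, `n_instruments`,
#'   `beta`, `se`, `p`, `significant`, `reason`) with the threshold in the
#'   `threshold` attribute.
#' @export
run_phenome_scan <- function(instrument_sets, outcomes, panels, alpha = 0.05,
                             proxy_r2 = 0.8) {
  threshold <- bonferroni_threshold(length(instrument_sets), length(outcomes), alpha)
  rows <- list()
  for (cpg_id in names(instrument_sets)) {
    ins <- instrument_sets[[cpg_id]]
    for (trait_id in names(outcomes)) {
      row <- data.frame(cpg_id = cpg_id, trait_id = trait_id, method = NA_character_,
                        n_instruments = 0L, beta = NA_real_, se = NA_real_, p = NA_real_,
                        significant = FALSE, reason = "", stringsAsFactors = FALSE)
      if (is.null(ins) || nrow(ins) == 0L) {
        row$reason <- "no_instrument"
        rows[[length(rows) + 1L]] <- row
        next
      }
      panel <- get_panel(panels, ins$chrom[1])
      pairs <- collect_pairs(ins, outcomes[[trait_id]], panel, r2_threshold = proxy_r2)
      if (is.null(pairs)) {
        row$reason <- "no_instrument"
        rows[[length(rows) + 1L]] <- row
        next
      }
      res <- tryCatch(ivw(pairs$exposure, pairs$outcome, cpg_id, trait_id),
                      error = function(e) NULL)
      if (is.null(res)) {
        row$reason <- "estimation_failed"
        rows[[length(rows) + 1L]] <- row
        next
      }
      row[c("method", "n_instruments", "beta", "se", "p")] <-
        res[c("method", "n_instruments", "beta", "se", "p")]
      row$significant <- res$p < threshold
      rows[[length(rows) + 1L]] <- row
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  structure(out, threshold = threshold, alpha = alpha,
            n_cpgs = length(instrument_sets), n_traits = length(outcomes))
}
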