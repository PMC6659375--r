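#' Candidate cis-mQTLs for a CpG
#'
#' Retains mQTL records with p-value strictly below `p_threshold` and
#' position strictly within `cis_window` base pairs of the CpG, on the CpG's
#' chromosome. Trans variants are never returned: only proximal (cis)
#' variants are acceptable instruments, since trans-mQTL are more prone to
#' horizontal pleiotropy.
#'
#' @param mqtl a methylation [regional_dataset()].
#' @param cpg one row of a CpG annotation table (`cpg_id`, `chrom`, `pos`).
#' @param p_threshold marginal p-value threshold (strict `<`).
#' @param cis_window maximum CpG-variant distance in bp (strict `<`).
#' @return the qualifying subset of `mqtl` (possibly zero rows, which marks
#'   the CpG as uninstrumentable).
#' @export
select_cis_mqtl <- function(mqtl, cpg, p_threshold = 1e-7, cis_window = 1e6) {
  keep <- mqtl$chrom == as.character(cpg$chrom) &
    abs(mqtl$pos - cpg$pos) < cis_window &
    mqtl$p < p_threshold
  out <- mqtl[keep, , drop = FALSE]
  if (nrow(out) == 0L) {
    message(sprintf("CpG %s: no cis-mQTL below p=%g within %g bp; skipped",
                    cpg$cpg_id, p_threshold, cis_window))
  }
  out
}

# Align summary records to the panel's ALT-dosage coding: after alignment the
# effect allele is the panel ALT allele. Returns the records with beta/eaf
# flipped where needed and a logical of rows that could not be reconciled.
align_to_panel <- function(records, panel) {
  idx <- match(records$snp, panel$variants$snp)
  ref <- panel$variants$ref[idx]
  alt <- panel$variants$alt[idx]
  same <- records$ea == alt & records$oa == ref
  swap <- records$ea == ref & records$oa == alt
  csame <- complement_alleles(records$ea) == alt & complement_alleles(records$oa) == ref
  cswap <- complement_alleles(records$ea) == ref & complement_alleles(records$oa) == alt
  flip <- !same & !csame & (swap | cswap)
  bad <- is.na(idx) | !(same | swap | csame | cswap)
  records$beta[flip] <- -records$beta[flip]
  records$eaf[flip] <- 1 - records$eaf[flip]
  records$ea <- alt
  records$oa <- ref
  list(records = records, bad = bad)
}

# Joint multivariate least-squares approximation from marginal summary
# statistics: X'X rebuilt from panel LD correlations and 2f(1-f) genotype
# variances, phenotypic variance taken as 1 (standardized traits).
fit_joint_model <- function(beta, R, D, n) {
  k <- length(beta)
  B <- outer(sqrt(D), sqrt(D)) * R
  Binv <- tryCatch(solve(B), error = function(e) NULL)
  if (is.null(Binv) || any(!is.finite(Binv))) return(NULL)
  xty <- D * beta
  b <- as.vector(Binv %*% xty)
  s2 <- max(1 - sum(b * xty), 1e-10) * n / max(n - k - 1, 1)
  se <- sqrt(diag(Binv) * s2 / n)
  z <- b / se
  list(beta = b, se = se, p = 2 * stats::pnorm(-abs(z)))
}

#' Stepwise approximate conditional-and-joint instrument selection
#'
#' Selects conditionally independent cis-mQTLs for one CpG from marginal
#' summary statistics plus a genotype reference panel, in the manner of
#' summary-statistic stepwise conditional analysis: seed the model with the
#' smallest marginal p-value, then repeatedly fit the joint model of the
#' selected set plus each remaining candidate (LD correlations and
#' allele-frequency-scaled genotype variances from the panel, phenotypic
#' variance 1) and add the candidate with the smallest joint p-value while
#' it is below `p_threshold` and its squared panel correlation with every
#' selected variant is below `collinearity_r2`. Candidates that make the LD
#' submatrix singular are dropped with a warning. The final joint effects
#' and p-values of all selected variants are reported.
#'
#' Selection is invariant to the input row order: ties are broken by
#' p-value, then variant id.
#'
#' @param candidates candidate records, normally from [select_cis_mqtl()].
#' @param panel a `ref_panel` covering the candidates.
#' @param p_threshold joint p-value threshold (strict `<`).
#' @param collinearity_r2 maximum squared correlation tolerated between
#'   selected instruments.
#' @param cpg_id CpG identifier stored on the result.
#' @return data.frame of class `instrument_set` with marginal (`beta`, `se`,
#'   `p`) and joint (`joint_beta`, `joint_se`, `joint_p`) statistics, effect
#'   alleles aligned to the panel ALT allele. Zero rows when nothing is
#'   selectable.
#' @export
cojo_slct <- function(candidates, panel, p_threshold = 1e-7, collinearity_r2 = 0.9,
                      cpg_id = attr(candidates, "trait_id")) {
  empty <- structure(
    data.frame(cpg_id = character(), snp = character(), chrom = character(),
               pos = numeric(), ea = character(), oa = character(), eaf = numeric(),
               beta = numeric(), se = numeric(), p = numeric(),
               joint_beta = numeric(), joint_se = numeric(), joint_p = numeric(),
               stringsAsFactors = FALSE),
    class = c("instrument_set", "data.frame"), cpg_id = cpg_id)
  if (is.null(candidates) || nrow(candidates) == 0L) return(empty)
  cand <- as.data.frame(candidates)
  cand <- cand[cand$p < p_threshold & cand$snp %in% panel$variants$snp, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  al <- align_to_panel(cand, panel)
  if (any(al$bad)) {
    warning(sprintf("cojo_slct: %d candidate(s) with alleles irreconcilable with the panel dropped",
                    sum(al$bad)))
  }
  cand <- al$records[!al$bad, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  cand <- cand[order(cand$p, cand$snp), , drop = FALSE]
  rownames(cand) <- NULL

  f <- panel_alt_freq(panel)[cand$snp]
  poly <- f > 0 & f < 1
  cand <- cand[poly, , drop = FALSE]
  if (nrow(cand) == 0L) return(empty)
  f <- f[cand$snp]
  D <- 2 * f * (1 - f)
  R <- panel_cor(panel, cand$snp)
  n <- stats::median(cand$n)

  selected <- 1L  # smallest marginal p seeds the model
  dropped <- integer()
  repeat {
    remaining <- setdiff(seq_len(nrow(cand)), c(selected, dropped))
    if (!length(remaining)) break
    best <- NULL
    for (r in remaining) {
      if (max(R[r, selected]^2) >= collinearity_r2) next
      fit <- fit_joint_model(cand$beta[c(selected, r)], R[c(selected, r), c(selected, r)],
                             D[c(selected, r)], n)
      if (is.null(fit)) {
        warning(sprintf("cojo_slct: dropping %s (singular LD submatrix)", cand$snp[r]))
        dropped <- c(dropped, r)
        next
      }
      p_r <- fit$p[length(fit$p)]
      if (is.null(best) || p_r < best$p ||
          (p_r == best$p && cand$snp[r] < cand$snp[best$r])) {
        best <- list(r = r, p = p_r)
      }
    }
    if (is.null(best) || !(best$p < p_threshold)) break
    selected <- c(selected, best$r)
  }

  fit <- fit_joint_model(cand$beta[selected], R[selected, selected, drop = FALSE],
                         D[selected], n)
  out <- cand[selected, c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p"),
              drop = FALSE]
  out <- cbind(cpg_id = cpg_id, out,
               joint_beta = fit$beta, joint_se = fit$se, joint_p = fit$p)
  out <- out[order(out$pos), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("instrument_set", "data.frame"), cpg_id = cpg_id)
}

#' @export
print.instrument_set <- function(x, ...) {
  cat(sprintf("<instrument_set> CpG %s: %d conditionally independent cis-mQTL(s)\n",
              attr(x, "cpg_id"), nrow(x)))
  print(as.data.frame(x))
  invisible(x)
}

#' Find an LD proxy for an instrument absent from an outcome dataset
#'
#' When the query variant is present in the outcome dataset an identity
#' proxy (r2 = 1) is returned. Otherwise, among outcome variants present in
#' the panel within `window` bp of the query, the variant with the highest
#' squared dosage correlation to the query is returned provided it exceeds
#' `r2_threshold`; the allele correspondence follows the sign of the dosage
#' correlation, so harmonized effect signs are invariant to whether the
#' variant itself or its proxy is used.
#'
#' @param query one exposure record (list or single-row data.frame with
#'   `snp`, `chrom`, `pos`, `ea`, `oa`).
#' @param outcome outcome summary data.frame.
#' @param panel a `ref_panel` containing the query.
#' @param r2_threshold minimum panel r-squared (strict `>`).
#' @param window search window in bp either side of the query.
#' @return list of class `proxy_result` (`query`, `proxy`, `r2`,
#'   `query_ea_allele`: the proxy allele corresponding to the query's
#'   effect allele), or `NULL` when no proxy clears the threshold.
#' @export
find_proxy <- function(query, outcome, panel, r2_threshold = 0.8, window = 5e5) {
  if (query$snp %in% outcome$snp) {
    return(structure(list(query = query$snp, proxy = query$snp, r2 = 1,
                          query_ea_allele = query$ea, query_oa_allele = query$oa),
                     class = "proxy_result"))
  }
  if (!query$snp %in% panel$variants$snp) return(NULL)
  pv <- panel$variants
  cand <- outcome[outcome$snp %in% pv$snp & outcome$chrom == query$chrom &
                    abs(outcome$pos - query$pos) <= window &
                    outcome$snp != query$snp, , drop = FALSE]
  if (nrow(cand) == 0L) return(NULL)
  r <- as.vector(panel_cor(panel, query$snp, cand$snp))
  r2 <- r^2
  best <- which.max(r2)
  if (!(r2[best] > r2_threshold)) {
    message(sprintf("no proxy above r2=%g for %s; pair skipped", r2_threshold, query$snp))
    return(NULL)
  }
  # orient: does the query's effect allele count with the panel ALT dosage?
  qrow <- pv[pv$snp == query$snp, ]
  dir_q <- if (query$ea == qrow$alt || complement_alleles(query$ea) == qrow$alt) 1 else
    if (query$ea == qrow$ref || complement_alleles(query$ea) == qrow$ref) -1 else NA
  if (is.na(dir_q)) return(NULL)
  prow <- pv[pv$snp == cand$snp[best], ]
  eff_r <- r[best] * dir_q
  structure(list(query = query$snp, proxy = cand$snp[best], r2 = r2[best],
                 query_ea_allele = if (eff_r > 0) prow$alt else prow$ref,
                 query_oa_allele = if (eff_r > 0) prow$ref else prow$alt),
            class = "proxy_result")
}

#' Rewrite an outcome record through a proxy onto the query variant
#'
#' Takes the outcome dataset's record at the proxy variant and re-expresses
#' it as a record for the query variant: the effect is aligned to the proxy
#' allele that tags the query's effect allele, then relabelled with the
#' query's id and alleles, ready for [harmonize()].
#'
#' @param proxy a `proxy_result` from [find_proxy()].
#' @param query the exposure record the proxy stands in for.
#' @param outcome outcome summary data.frame containing the proxy variant.
#' @return a single-row outcome record on the query's variant key, or `NULL`
#'   if the outcome record's alleles do not match the panel's at the proxy.
#' @export
proxy_outcome_record <- function(proxy, query, outcome) {
  rec <- outcome[outcome$snp == proxy$proxy, , drop = FALSE]
  if (nrow(rec) != 1L) return(NULL)
  same <- rec$ea == proxy$query_ea_allele & rec$oa == proxy$query_oa_allele
  swap <- rec$ea == proxy$query_oa_allele & rec$oa == proxy$query_ea_allele
  if (!same && !swap) {
    csame <- complement_alleles(rec$ea) == proxy$query_ea_allele &
      complement_alleles(rec$oa) == proxy$query_oa_allele
    cswap <- complement_alleles(rec$ea) == proxy$query_oa_allele &
      complement_alleles(rec$oa) == proxy$query_ea_allele
    if (cswap) swap <- TRUE else if (!csame) return(NULL)
  }
  if (swap) {
    rec$beta <- -rec$beta
    rec$eaf <- 1 - rec$eaf
  }
  rec$snp <- query$snp
  rec$chrom <- query$chrom
  rec$pos <- query$pos
  rec$ea <- query$ea
  rec$oa <- query$oa
  rec
}

#' Harmonize an exposure/outcome record pair onto the exposure's alleles
#'
#' Aligns the outcome record's effect allele to the exposure's: a swapped
#' allele pair negates the outcome beta and reflects its frequency; an
#' opposite-strand pair is complemented first. Palindromic (A/T or C/G)
#' variants are dropped when either frequency is missing or lies in the
#' ambiguity window [0.42, 0.58]; otherwise they are oriented by frequency
#' concordance. Irreconcilable allele pairs are dropped with a reason.
#'
#' @param exposure,outcome single-row records sharing a variant id.
#' @param eaf_window palindrome frequency-ambiguity window.
#' @return list with `kept` (logical), `reason` (`""`,
#'   `"palindromic_ambiguous"` or `"incompatible_alleles"`), and the aligned
#'   `exposure` and `outcome` records when kept.
#' @export
harmonize <- function(exposure, outcome, eaf_window = c(0.42, 0.58)) {
  stopifnot(exposure$snp == outcome$snp)
  drop <- function(reason) list(kept = FALSE, reason = reason,
                                exposure = exposure, outcome = outcome)
  flip <- function(rec) {
    rec$beta <- -rec$beta
    rec$eaf <- 1 - rec$eaf
    tmp <- rec$ea; rec$ea <- rec$oa; rec$oa <- tmp
    rec
  }
  ea_e <- exposure$ea; oa_e <- exposure$oa
  ea_o <- outcome$ea; oa_o <- outcome$oa

  if (is_palindromic(ea_e, oa_e)) {
    if (!setequal(c(ea_o, oa_o), c(ea_e, oa_e))) return(drop("incompatible_alleles"))
    ambiguous <- function(f) is.na(f) || (f >= eaf_window[1] && f <= eaf_window[2])
    if (ambiguous(exposure$eaf) || ambiguous(outcome$eaf)) return(drop("palindromic_ambiguous"))
    if (ea_o != ea_e) outcome <- flip(outcome)
    # a residual frequency discordance marks a strand flip on one side
    if ((exposure$eaf - 0.5) * (outcome$eaf - 0.5) < 0) {
      outcome$beta <- -outcome$beta
      outcome$eaf <- 1 - outcome$eaf
    }
    return(list(kept = TRUE, reason = "", exposure = exposure, outcome = outcome))
  }

  if (ea_o == ea_e && oa_o == oa_e) {
    # already aligned
  } else if (ea_o == oa_e && oa_o == ea_e) {
    outcome <- flip(outcome)
  } else {
    ea_c <- complement_alleles(ea_o); oa_c <- complement_alleles(oa_o)
    if (ea_c == ea_e && oa_c == oa_e) {
      outcome$ea <- ea_c; outcome$oa <- oa_c
    } else if (ea_c == oa_e && oa_c == ea_e) {
      outcome$ea <- ea_c; outcome$oa <- oa_c
      outcome <- flip(outcome)
    } else {
      return(drop("incompatible_alleles"))
    }
  }
  list(kept = TRUE, reason = "", exposure = exposure, outcome = outcome)
}
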