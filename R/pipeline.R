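#' Run the full epigenetic MR pipeline on a study
#'
#' Executes the analysis stages in order: outcome-eligibility filtering (if
#' trait metadata is supplied), cis-mQTL instrument selection per CpG
#' (candidate filtering plus stepwise conditional selection), the
#' phenome-wide MR scan with Bonferroni flagging, three-trait
#' colocalization over the gene window for every significant CpG-trait pair,
#' per-CpG top-trait selection among colocalizing pairs, and orientation
#' (sign chaining with the EWAS effect, the pairwise Steiger chain over
#' methylation/expression/trait, and reverse MR). Gating is strict: only
#' MR-significant pairs reach colocalization and only pairs with
#' `ppa_abc >= ppa_threshold` reach orientation. Per-pair failures are
#' recorded as skip reasons and never abort the run.
#'
#' @param study a `sim_study`, the list returned by [load_study()], or a
#'   path to a `study.yaml` manifest.
#' @param out_dir optional directory; when given, every stage table, the
#'   final report and a run manifest are written as tab-delimited text /
#'   YAML. Reruns on identical inputs produce byte-identical files.
#' @param alpha family-wise error rate of the scan.
#' @param p_threshold cis-mQTL selection threshold.
#' @param cis_window cis window in bp.
#' @param collinearity_r2 instrument collinearity cutoff.
#' @param ppa_threshold colocalization evidence threshold on `ppa_abc`.
#' @param coloc_window CpG-to-gene scan window in bp.
#' @param maf_min,min_variants region filter for colocalization.
#' @param priors,prior_w colocalization priors.
#' @param steiger_alpha decision level of the directionality test.
#' @return list of class `epimr_report`: `eligibility`, `instruments`
#'   (table), `mr` (scan table with threshold attribute), `coloc`,
#'   `selected`, `final` (oriented report), `manifest`.
#' @export
run_pipeline <- function(study, out_dir = NULL, alpha = 0.05, p_threshold = 1e-7,
                         cis_window = 1e6, collinearity_r2 = 0.9, ppa_threshold = 0.8,
                         coloc_window = 1e5, maf_min = 0.05, min_variants = 50,
                         priors = c(1e-4, 1e-6, 1e-7), prior_w = 0.04,
                         steiger_alpha = 0.05) {
  if (is.character(study)) study <- load_study(study)

  # stage 0: outcome eligibility
  outcomes <- study$outcomes
  eligibility <- NULL
  if (!is.null(study$trait_meta)) {
    eligibility <- filter_trait_eligibility(study$trait_meta)
    outcomes <- outcomes[intersect(names(outcomes), eligibility$trait_id[eligibility$eligible])]
  }

  # stage 1: instruments per CpG
  instrument_sets <- list()
  for (i in seq_len(nrow(study$cpgs))) {
    cpg <- study$cpgs[i, ]
    mqtl <- study$mqtl[[cpg$cpg_id]]
    if (is.null(mqtl)) next
    cand <- suppressMessages(select_cis_mqtl(mqtl, cpg, p_threshold, cis_window))
    panel <- get_panel(study$panels, cpg$chrom)
    instrument_sets[[cpg$cpg_id]] <- cojo_slct(cand, panel, p_threshold,
                                               collinearity_r2, cpg_id = cpg$cpg_id)
  }
  instruments_tbl <- do.call(rbind, lapply(instrument_sets, as.data.frame))
  rownames(instruments_tbl) <- NULL

  # stage 2: phenome scan + Bonferroni flags
  mr_tbl <- run_phenome_scan(instrument_sets, outcomes, study$panels, alpha = alpha)
  threshold <- attr(mr_tbl, "threshold")

  # stage 3: colocalization, significant pairs only
  sig <- mr_tbl[mr_tbl$significant & !is.na(mr_tbl$p), , drop = FALSE]
  coloc_rows <- list()
  for (i in seq_len(nrow(sig))) {
    cpg <- study$cpgs[study$cpgs$cpg_id == sig$cpg_id[i], ]
    res <- gene_window_scan(cpg, study$mqtl[[cpg$cpg_id]], study$eqtl,
                            outcomes[[sig$trait_id[i]]], study$genes,
                            get_panel(study$panels, cpg$chrom),
                            window = coloc_window, maf_min = maf_min,
                            min_variants = min_variants, priors = priors,
                            prior_w = prior_w, trait_id = sig$trait_id[i])
    if (!is.null(res)) {
      res$mr_p <- sig$p[i]
      coloc_rows[[length(coloc_rows) + 1L]] <- res
    }
  }
  coloc_tbl <- if (length(coloc_rows)) do.call(rbind, coloc_rows) else NULL

  # stage 4: PPA gating and top-trait selection per CpG
  selected <- NULL
  if (!is.null(coloc_tbl)) {
    # a pair colocalizes if any gene in the window clears the threshold;
    # carry the best gene per pair forward
    pair <- coloc_tbl[!is.na(coloc_tbl$ppa_abc), , drop = FALSE]
    if (nrow(pair)) {
      pair <- pair[order(-pair$ppa_abc), , drop = FALSE]
      pair <- pair[!duplicated(pair[c("cpg_id", "trait_id")]), , drop = FALSE]
      pair <- pair[pair$ppa_abc >= ppa_threshold, , drop = FALSE]
      if (nrow(pair)) selected <- select_top_trait(pair)
    }
  }

  # stage 5: orientation of the surviving pairs
  final_rows <- list()
  for (i in seq_len(NROW(selected))) {
    sel <- selected[i, ]
    cpg <- study$cpgs[study$cpgs$cpg_id == sel$cpg_id, ]
    mrrow <- mr_tbl[mr_tbl$cpg_id == sel$cpg_id & mr_tbl$trait_id == sel$trait_id, ]
    chain <- orient_chain(cpg, mrrow)
    ins <- instrument_sets[[sel$cpg_id]]
    mqtl <- study$mqtl[[sel$cpg_id]]
    eq <- study$eqtl[[sel$gene_id]]
    gw <- outcomes[[sel$trait_id]]
    steiger <- steiger_chain(ins, mqtl, eq, gw, alpha = steiger_alpha)
    rev <- tryCatch(
      suppressMessages(reverse_mr(gw, mqtl, study$panels, trait_id = sel$trait_id)),
      error = function(e) NULL)
    final_rows[[length(final_rows) + 1L]] <- cbind(
      chain,
      gene_id = sel$gene_id, ppa_abc = sel$ppa_abc, mr_p = mrrow$p,
      dir_meth_expr = steiger$meth_expr, dir_expr_trait = steiger$expr_trait,
      dir_meth_trait = steiger$meth_trait,
      reverse_mr_p = if (is.null(rev)) NA_real_ else rev$p,
      stringsAsFactors = FALSE)
  }
  final <- if (length(final_rows)) do.call(rbind, final_rows) else
    data.frame(cpg_id = character(), trait_id = character(), ewas_beta = numeric(),
               mr_beta = numeric(), ewas_sign = numeric(), mr_sign = numeric(),
               implied_exposure_effect = character(), gene_id = character(),
               ppa_abc = numeric(), mr_p = numeric(), dir_meth_expr = character(),
               dir_expr_trait = character(), dir_meth_trait = character(),
               reverse_mr_p = numeric(), stringsAsFactors = FALSE)
  rownames(final) <- NULL

  manifest <- list(alpha = alpha, bonferroni_threshold = threshold,
                   n_cpgs = length(instrument_sets), n_traits = length(outcomes),
                   p_threshold = p_threshold, cis_window = cis_window,
                   collinearity_r2 = collinearity_r2, ppa_threshold = ppa_threshold,
                   coloc_window = coloc_window, maf_min = maf_min,
                   min_variants = min_variants,
                   priors = as.numeric(priors), prior_w = prior_w,
                   steiger_alpha = steiger_alpha,
                   seed = study$config$seed %||% NA,
                   package_version = as.character(utils::packageVersion("epimr")))

  report <- structure(list(eligibility = eligibility, instruments = instruments_tbl,
                           mr = mr_tbl, coloc = coloc_tbl, selected = selected,
                           final = final, manifest = manifest),
                      class = "epimr_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

# Pairwise Steiger chain across methylation, expression and trait at the
# CpG's instruments. Explained variances are summed over instruments.
steiger_chain <- function(instruments, mqtl, eqtl, gwas, alpha = 0.05) {
  na <- list(meth_expr = "indeterminate", expr_trait = "indeterminate",
             meth_trait = "indeterminate")
  snps <- intersect(intersect(instruments$snp, eqtl$snp), gwas$snp)
  if (!length(snps)) return(na)
  r2_of <- function(ds) {
    idx <- match(snps, ds$snp)
    list(r2 = sum(steiger_r2(ds$beta[idx], ds$se[idx], ds$n[idx])),
         n = stats::median(ds$n[idx]))
  }
  m <- r2_of(mqtl); e <- r2_of(eqtl); g <- r2_of(gwas)
  dir_label <- function(s) s$direction
  list(
    meth_expr = dir_label(steiger_direction(m$r2, e$r2, m$n, e$n, alpha)),
    expr_trait = dir_label(steiger_direction(e$r2, g$r2, e$n, g$n, alpha)),
    meth_trait = dir_label(steiger_direction(m$r2, g$r2, m$n, g$n, alpha)))
}

#' Write a pipeline report to disk
#'
#' Emits each stage table as tab-delimited text plus a YAML run manifest and
#' a short human-readable summary. Output is deterministic: identical
#' reports produce byte-identical files.
#'
#' @param report an `epimr_report` from [run_pipeline()].
#' @param dir output directory (created if needed).
#' @export
write_report <- function(report, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wt <- function(x, f) {
    if (is.null(x)) return(invisible(NULL))
    utils::write.table(format(as.data.frame(x), digits = 15, trim = TRUE),
                       file.path(dir, f), sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wt(report$eligibility, "eligibility.tsv")
  wt(report$instruments, "instruments.tsv")
  wt(report$mr, "mr_scan.tsv")
  wt(report$coloc, "coloc.tsv")
  wt(report$selected, "selected.tsv")
  wt(report$final, "final_report.tsv")
  yaml::write_yaml(report$manifest, file.path(dir, "manifest.yaml"))
  n_sig <- sum(report$mr$significant, na.rm = TRUE)
  lines <- c(
    sprintf("Scanned %d CpG(s) x %d trait(s); Bonferroni threshold %.4g.",
            report$manifest$n_cpgs, report$manifest$n_traits,
            report$manifest$bonferroni_threshold),
    sprintf("%d CpG-trait pair(s) survived multiple testing.", n_sig),
    sprintf("%d pair(s) colocalized at PPA >= %.2f and were oriented.",
            NROW(report$final), report$manifest$ppa_threshold))
  if (NROW(report$final)) {
    lines <- c(lines, "", apply(report$final, 1, function(r) {
      sprintf("%s -> %s (gene %s): the upstream exposure putatively %s the trait (EWAS %s, MR %s).",
              r[["cpg_id"]], r[["trait_id"]], r[["gene_id"]],
              r[["implied_exposure_effect"]],
              r[["ewas_beta"]], r[["mr_beta"]])
    }))
  }
  writeLines(lines, file.path(dir, "summary.txt"))
  invisible(dir)
}

#' @export
print.epimr_report <- function(x, ...) {
  cat(sprintf("<epimr_report> %d CpG(s) x %d trait(s); threshold %.3g; %d significant; %d oriented\n",
              x$manifest$n_cpgs, x$manifest$n_traits, x$manifest$bonferroni_threshold,
              sum(x$mr$significant, na.rm = TRUE), NROW(x$final)))
  if (NROW(x$final)) print(x$final[c("cpg_id", "trait_id", "gene_id", "ppa_abc",
                                     "implied_exposure_effect")])
  invisible(x)
}
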