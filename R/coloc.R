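#' Wakefield log approximate Bayes factor
#'
#' Per-variant evidence for association from a beta/SE pair under a normal
#' prior with variance `prior_w` on the true effect: with `z = beta/se`,
#' `V = se^2` and shrinkage `r = prior_w / (V + prior_w)`, the log ABF is
#' `0.5 * (log(1 - r) + z^2 * r)`. As `prior_w` tends to 0 the ABF tends to
#' 1 (log 0) for any z.
#'
#' @param beta,se effect estimates and standard errors (vectorized).
#' @param prior_w prior variance of the true effect; 0.04 (SD 0.2) is the
#'   conventional choice for standardized continuous traits.
#' @return vector of log ABFs.
#' @export
wakefield_abf <- function(beta, se, prior_w = 0.04) {
  stopifnot(all(se > 0), prior_w > 0)
  z <- beta / se
  r <- prior_w / (se^2 + prior_w)
  0.5 * (log1p(-r) + z^2 * r)
}

# All set partitions of the elements of x (list of lists of groups).
set_partitions <- function(x) {
  if (length(x) == 0L) return(list(list()))
  first <- x[1]
  rest <- set_partitions(x[-1])
  out <- list()
  for (p in rest) {
    # join first with each existing group
    for (i in seq_along(p)) {
      q <- p
      q[[i]] <- c(first, q[[i]])
      out[[length(out) + 1L]] <- q
    }
    out[[length(out) + 1L]] <- c(list(first), p)
  }
  out
}

config_label <- function(groups) {
  if (!length(groups)) return("null")
  gs <- vapply(groups, function(g) paste(sort(g), collapse = ""), "")
  gs <- gs[order(-nchar(gs), gs)]
  paste(gs, collapse = ".")
}

#' Enumerate causal-sharing configuration classes
#'
#' Each class assigns every trait either to "unassociated" or to a causal
#' -variant group; associated traits in one group share a causal variant and
#' distinct groups have distinct variants. For one, two and three traits
#' this yields 2, 5 and 15 classes respectively (for three traits:
#' null, a, b, c, ab, ac, bc, a.b, a.c, b.c, abc, ab.c, ac.b, bc.a, a.b.c).
#'
#' @param n_traits number of traits (1 to 3 supported).
#' @param trait_names letters used in the labels.
#' @return list of classes; each has `label` and `groups` (list of character
#'   vectors of trait names).
#' @export
enumerate_configurations <- function(n_traits, trait_names = letters[seq_len(n_traits)]) {
  if (!n_traits %in% 1:3) {
    stop_epimr("only 1 to 3 traits supported", "epimr_config_error")
  }
  out <- list()
  idx <- seq_len(n_traits)
  for (assoc_size in 0:n_traits) {
    for (sub in utils::combn(idx, assoc_size, simplify = FALSE)) {
      for (p in set_partitions(trait_names[sub])) {
        out[[length(out) + 1L]] <- list(label = config_label(p), groups = p)
      }
    }
  }
  out
}

#' Log marginal evidence of one configuration class
#'
#' Sums, over all assignments of distinct causal variants to the class's
#' groups, the product of group ABFs (a group's per-variant ABF is the
#' product of its member traits' ABFs at that variant). Evaluated in log
#' space with max-shift summation; classes requiring more distinct variants
#' than the region holds get `-Inf`. The null class has evidence 1 (log 0).
#'
#' @param labf matrix of per-variant log ABFs, one column per trait, column
#'   names matching the trait names used in `groups`.
#' @param groups list of character vectors (one per group), as in the
#'   classes from [enumerate_configurations()].
#' @return log evidence (scalar).
#' @export
config_evidence <- function(labf, groups) {
  k <- length(groups)
  if (k == 0L) return(0)
  # more groups than variants: no admissible assignment of distinct variants
  if (nrow(labf) < k) return(-Inf)
  l <- lapply(groups, function(g) rowSums(labf[, g, drop = FALSE]))
  S <- vapply(l, logsumexp, 0)
  if (k == 1L) return(S[1])
  if (k == 2L) {
    d12 <- logsumexp(l[[1]] + l[[2]])
    tot <- S[1] + S[2]
    if (d12 >= tot) return(-Inf)
    return(tot + log1p(-exp(d12 - tot)))
  }
  # three singleton groups: inclusion-exclusion over coincident assignments
  M <- S[1] + S[2] + S[3]
  d12 <- logsumexp(l[[1]] + l[[2]])
  d13 <- logsumexp(l[[1]] + l[[3]])
  d23 <- logsumexp(l[[2]] + l[[3]])
  t123 <- logsumexp(l[[1]] + l[[2]] + l[[3]])
  val <- 1 - exp(d12 + S[3] - M) - exp(d13 + S[2] - M) - exp(d23 + S[1] - M) +
    2 * exp(t123 - M)
  if (!is.finite(M) || val <= 0) return(-Inf)
  M + log(val)
}

#' Posterior probabilities over three-trait colocalization configurations
#'
#' Combines per-variant log ABFs for (up to) three traits over a shared
#' variant grid into posterior probabilities for every configuration class.
#' Each class's weight is its prior — the product over causal-variant groups
#' of the per-variant prior for that group size (`p1` per single-trait
#' variant, `p2` per two-trait shared variant, `p3` for the three-trait
#' shared variant) — times its marginal evidence; weights are normalized
#' over all classes (the null class has weight 1). `ppa_abc` is the
#' posterior of the single class in which one variant is causal for all
#' three traits; partial-sharing classes such as `ab.c` are reported but do
#' not count toward it. No multiple-testing correction is applied to
#' posteriors.
#'
#' @param labf matrix of log ABFs (variants x traits), rownames = variant
#'   ids, colnames = trait letters (default `a` = methylation,
#'   `b` = expression, `c` = complex trait).
#' @param priors per-variant priors `c(p1, p2, p3)` for group sizes 1-3.
#' @return object of class `coloc_posterior`: list with `posterior` (named
#'   vector summing to 1), `ppa_abc`, `best_shared_variant` (argmax of the
#'   summed three-trait ABF), `n_variants`.
#' @export
moloc_posteriors <- function(labf, priors = c(1e-4, 1e-6, 1e-7)) {
  labf <- as.matrix(labf)
  stopifnot(all(is.finite(labf)))
  n_traits <- ncol(labf)
  if (is.null(colnames(labf))) colnames(labf) <- letters[seq_len(n_traits)]
  classes <- enumerate_configurations(n_traits, colnames(labf))
  lw <- vapply(classes, function(cl) {
    lp <- sum(log(priors[vapply(cl$groups, length, 0L)]))
    lp + config_evidence(labf, cl$groups)
  }, 0)
  labels <- vapply(classes, `[[`, "", "label")
  post <- exp(lw - logsumexp(lw))
  post[!is.finite(post)] <- 0
  names(post) <- labels
  all_label <- paste(sort(colnames(labf)), collapse = "")
  shared <- rowSums(labf)
  best <- if (!is.null(rownames(labf))) rownames(labf)[which.max(shared)] else
    which.max(shared)
  structure(list(posterior = post,
                 ppa_abc = unname(post[all_label]) %||% NA_real_,
                 best_shared_variant = best,
                 n_variants = nrow(labf)),
            class = "coloc_posterior")
}

#' @export
print.coloc_posterior <- function(x, ...) {
  cat(sprintf("<coloc_posterior> %d variants; PPA(all traits share one variant) = %.3f; best shared variant %s\n",
              x$n_variants, x$ppa_abc, x$best_shared_variant))
  print(round(sort(x$posterior, decreasing = TRUE), 4))
  invisible(x)
}

#' Scan genes around a CpG for three-trait colocalization
#'
#' For every gene whose annotated interval lies within `window` bp of the
#' CpG position, intersects the variant grids of the methylation, expression
#' and trait datasets with the panel, drops variants with panel minor allele
#' frequency below `maf_min`, and runs [moloc_posteriors()] only when at
#' least `min_variants` variants remain. Skipped genes carry a reason
#' instead of posteriors. Allele orientation does not need harmonizing here
#' because ABFs depend on squared z-scores only.
#'
#' @param cpg one CpG annotation row.
#' @param mqtl methylation dataset for the CpG.
#' @param eqtl named list of expression datasets (by gene id).
#' @param gwas outcome summary data.frame for one trait.
#' @param genes gene annotation data.frame.
#' @param panel `ref_panel` for the CpG's chromosome.
#' @param window CpG-to-gene distance limit in bp (to the nearest interval
#'   edge; 0 when the CpG lies inside the gene).
#' @param maf_min panel minor-allele-frequency floor (kept when `>=`).
#' @param min_variants minimum size of the common variant grid.
#' @param priors,prior_w passed to [moloc_posteriors()] / [wakefield_abf()].
#' @param trait_id label recorded in the output.
#' @return data.frame with one row per gene in the window: `cpg_id`,
#'   `gene_id`, `trait_id`, `n_variants`, `ppa_abc`, `best_shared_variant`,
#'   `skip_reason`, and one `pp_<class>` column per configuration class.
#' @export
gene_window_scan <- function(cpg, mqtl, eqtl, gwas, genes, panel, window = 1e5,
                             maf_min = 0.05, min_variants = 50,
                             priors = c(1e-4, 1e-6, 1e-7), prior_w = 0.04,
                             trait_id = "trait") {
  genes <- genes[genes$chrom == as.character(cpg$chrom), , drop = FALSE]
  dist <- pmax(genes$start - cpg$pos, cpg$pos - genes$end, 0)
  genes <- genes[dist <= window, , drop = FALSE]
  class_labels <- vapply(enumerate_configurations(3), `[[`, "", "label")
  rows <- list()
  for (g in seq_len(nrow(genes))) {
    gene_id <- genes$gene_id[g]
    row <- data.frame(cpg_id = cpg$cpg_id, gene_id = gene_id, trait_id = trait_id,
                      n_variants = 0L, ppa_abc = NA_real_,
                      best_shared_variant = NA_character_, skip_reason = "",
                      stringsAsFactors = FALSE)
    for (lb in class_labels) row[[paste0("pp_", lb)]] <- NA_real_
    eq <- eqtl[[gene_id]]
    if (is.null(eq)) {
      row$skip_reason <- "no_eqtl_data"
      rows[[length(rows) + 1L]] <- row
      next
    }
    maf <- panel_maf(panel)
    common <- Reduce(intersect, list(mqtl$snp, eq$snp, gwas$snp, names(maf)[maf >= maf_min]))
    row$n_variants <- length(common)
    if (length(common) < min_variants) {
      row$skip_reason <- "min_variants"
      rows[[length(rows) + 1L]] <- row
      next
    }
    labf <- cbind(
      a = wakefield_abf(mqtl$beta[match(common, mqtl$snp)], mqtl$se[match(common, mqtl$snp)], prior_w),
      b = wakefield_abf(eq$beta[match(common, eq$snp)], eq$se[match(common, eq$snp)], prior_w),
      c = wakefield_abf(gwas$beta[match(common, gwas$snp)], gwas$se[match(common, gwas$snp)], prior_w))
    rownames(labf) <- common
    cp <- moloc_posteriors(labf, priors = priors)
    row$ppa_abc <- cp$ppa_abc
    row$best_shared_variant <- cp$best_shared_variant
    row[paste0("pp_", names(cp$posterior))] <- as.list(cp$posterior)
    rows[[length(rows) + 1L]] <- row
  }
  out <- if (length(rows)) do.call(rbind, rows) else NULL
  if (!is.null(out)) rownames(out) <- NULL
  out
}

#' Keep the best-colocalizing trait per CpG
#'
#' When a CpG is associated with several (typically correlated) traits, only
#' the trait with the highest posterior probability of three-trait
#' colocalization is taken forward. Ties are broken by the smaller MR
#' p-value, then by trait id.
#'
#' @param results data.frame with at least `cpg_id`, `trait_id`, `ppa_abc`,
#'   and optionally `mr_p`.
#' @return one row per CpG.
#' @export
select_top_trait <- function(results) {
  if (!"mr_p" %in% names(results)) results$mr_p <- NA_real_
  picked <- lapply(split(results, results$cpg_id), function(d) {
    d <- d[order(-d$ppa_abc, d$mr_p, d$trait_id), , drop = FALSE]
    d[1, , drop = FALSE]
  })
  out <- do.call(rbind, picked)
  rownames(out) <- NULL
  out
}

#' Stacked regional association plot for three traits
#'
#' Draws the overlapping distributions of -log10 p-values for the
#' methylation, expression and complex-trait datasets over one region, with
#' gene intervals annotated under the x-axis and a cross marking the CpG.
#'
#' @param mqtl,eqtl,gwas regional datasets on a common region.
#' @param genes optional gene annotation data.frame.
#' @param cpg optional CpG annotation row.
#' @param file optional output path; when it ends in `.png` a PNG device is
#'   opened for the plot.
#' @export
plot_region <- function(mqtl, eqtl, gwas, genes = NULL, cpg = NULL, file = NULL) {
  if (!is.null(file)) {
    grDevices::png(file, width = 900, height = 600)
    on.exit(grDevices::dev.off(), add = TRUE)
  }
  mlp <- function(d) -log10(pmax(d$p, 1e-300))
  xlim <- range(mqtl$pos, eqtl$pos, gwas$pos) / 1e6
  ylim <- c(0, max(mlp(mqtl), mlp(eqtl), mlp(gwas)) * 1.15)
  graphics::par(mar = c(5, 4, 2, 1))
  graphics::plot(gwas$pos / 1e6, mlp(gwas), pch = 16, col = "grey40",
                 xlim = xlim, ylim = ylim,
                 xlab = sprintf("position on chromosome %s (Mb)", mqtl$chrom[1]),
                 ylab = expression(-log[10](italic(P))))
  graphics::points(eqtl$pos / 1e6, mlp(eqtl), pch = 16, col = "steelblue")
  graphics::points(mqtl$pos / 1e6, mlp(mqtl), pch = 16, col = "firebrick")
  if (!is.null(genes)) {
    y0 <- -0.06 * ylim[2]
    for (g in seq_len(nrow(genes))) {
      graphics::segments(genes$start[g] / 1e6, y0, genes$end[g] / 1e6, y0,
                         lwd = 4, col = "darkgreen", xpd = TRUE)
      graphics::text((genes$start[g] + genes$end[g]) / 2e6, y0, genes$gene_id[g],
                     pos = 1, cex = 0.7, xpd = TRUE)
    }
  }
  if (!is.null(cpg)) {
    graphics::points(cpg$pos / 1e6, 0, pch = 4, col = "red", cex = 1.6, lwd = 2)
  }
  graphics::legend("topright", c("complex trait", "expression", "methylation"),
                   col = c("grey40", "steelblue", "firebrick"), pch = 16, bty = "n")
  invisible(NULL)
}
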