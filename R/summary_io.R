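#' Construct a regional summary-statistic dataset
#'
#' A regional dataset holds per-variant association records for one trait:
#' variant identity (id, chromosome, position, effect and other allele),
#' effect-allele frequency, effect estimate, its standard error, a two-sided
#' p-value and the sample size. Rows violating basic record invariants
#' (non-positive SE, p outside (0,1], frequency outside [0,1], identical or
#' non-ACGT alleles, missing beta) are dropped with a warning; the number of
#' rejected rows is kept in the `n_rejected` attribute.
#'
#' @param df data.frame with columns `snp`, `chrom`, `pos`, `ea`, `oa`,
#'   `eaf`, `beta`, `se`, `p`, `n`.
#' @param trait_id identifier of the measured trait (CpG, gene or phenotype).
#' @param trait_type one of `"methylation"`, `"expression"`, `"complex"`.
#' @return data.frame of class `regional_dataset`, ordered by position, with
#'   attributes `trait_id`, `trait_type`, `n_rejected`.
#' @export
regional_dataset <- function(df, trait_id, trait_type = c("complex", "methylation", "expression")) {
  trait_type <- match.arg(trait_type)
  required <- c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_epimr(paste("missing mandatory column(s):", paste(missing_cols, collapse = ", ")),
               "epimr_config_error")
  }
  df <- df[required]
  df$snp <- as.character(df$snp)
  df$chrom <- as.character(df$chrom)
  df$ea <- toupper(as.character(df$ea))
  df$oa <- toupper(as.character(df$oa))
  for (col in c("pos", "eaf", "beta", "se", "p", "n")) df[[col]] <- as.numeric(df[[col]])

  ok <- !is.na(df$beta) &
    !is.na(df$se) & df$se > 0 &
    !is.na(df$p) & df$p > 0 & df$p <= 1 &
    (is.na(df$eaf) | (df$eaf >= 0 & df$eaf <= 1)) &
    !is.na(df$pos) & df$pos >= 1 &
    df$ea %in% c("A", "C", "G", "T") & df$oa %in% c("A", "C", "G", "T") &
    df$ea != df$oa
  ok[is.na(ok)] <- FALSE
  n_rejected <- sum(!ok)
  if (n_rejected > 0) {
    warning(sprintf("regional_dataset('%s'): rejected %d invalid row(s)", trait_id, n_rejected))
  }
  df <- df[ok, , drop = FALSE]
  if (nrow(df) == 0L) {
    stop_epimr(sprintf("no valid rows for trait '%s'", trait_id), "epimr_empty_input")
  }
  if (anyDuplicated(df$snp)) {
    dup <- duplicated(df$snp)
    warning(sprintf("regional_dataset('%s'): dropped %d duplicated variant id(s)", trait_id, sum(dup)))
    df <- df[!dup, , drop = FALSE]
  }
  df <- df[order(df$chrom, df$pos, df$snp), , drop = FALSE]
  rownames(df) <- NULL
  structure(df,
            trait_id = trait_id, trait_type = trait_type, n_rejected = n_rejected,
            class = c("regional_dataset", "data.frame"))
}

#' @export
print.regional_dataset <- function(x, ...) {
  cat(sprintf("<regional_dataset> trait '%s' (%s): %d variants on chrom %s; %d rejected at read\n",
              attr(x, "trait_id"), attr(x, "trait_type"), nrow(x),
              paste(unique(x$chrom), collapse = ","), attr(x, "n_rejected")))
  print(utils::head(as.data.frame(x), 6))
  invisible(x)
}

#' Default header set for tab-delimited GWAS/QTL summary statistics
#'
#' Maps internal field names to the column headers expected in input files.
#' Override any entry through the `column_map` argument of
#' [read_summary_table()] to accommodate other dialects.
#' @export
default_column_map <- function() {
  c(snp = "SNP", chrom = "CHR", pos = "BP", ea = "EA", oa = "OA",
    eaf = "EAF", beta = "BETA", se = "SE", p = "P", n = "N")
}

#' Read a tab-delimited summary-statistics table
#'
#' @param path file path; tab-delimited with a header row.
#' @param trait_id,trait_type passed to [regional_dataset()].
#' @param column_map named character vector overriding entries of
#'   [default_column_map()], e.g. `c(p = "pval")`.
#' @return a [regional_dataset()]. Invalid rows are rejected (counted, not
#'   fatal); a missing mapped column is a configuration error and zero valid
#'   rows is an empty-input error.
#' @export
read_summary_table <- function(path, trait_id, trait_type = "complex", column_map = NULL) {
  cmap <- default_column_map()
  if (!is.null(column_map)) cmap[names(column_map)] <- column_map
  raw <- utils::read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                           check.names = FALSE)
  missing_cols <- setdiff(unname(cmap), names(raw))
  if (length(missing_cols)) {
    stop_epimr(paste0("column(s) not found in ", path, ": ",
                      paste(missing_cols, collapse = ", ")), "epimr_config_error")
  }
  df <- stats::setNames(raw[unname(cmap)], names(cmap))
  regional_dataset(df, trait_id = trait_id, trait_type = trait_type)
}

#' Write a summary-statistics table in the package's tab-delimited format
#'
#' Inverse of [read_summary_table()] under the default column map; numeric
#' fields round-trip to full double precision.
#' @param x a `regional_dataset` (or compatible data.frame).
#' @param path output file path.
#' @export
write_summary_table <- function(x, path) {
  out <- as.data.frame(x)[c("snp", "chrom", "pos", "ea", "oa", "eaf", "beta", "se", "p", "n")]
  names(out) <- unname(default_column_map())
  utils::write.table(format(out, digits = 17, trim = TRUE, scientific = NA),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a genotype reference panel from a VCF file
#'
#' Loads biallelic SNPs from a VCF (plain or bgzipped) into a dosage matrix
#' (individuals x variants, counting ALT alleles 0/1/2). Indels,
#' multi-allelic records and non-ACGT alleles are skipped.
#'
#' @param path VCF file.
#' @param chrom,start,end optional region restriction (1-based, inclusive).
#' @return object of class `ref_panel`: list with `geno` (dosage matrix,
#'   columns named by variant id) and `variants` (data.frame `snp`, `chrom`,
#'   `pos`, `ref`, `alt`).
#' @export
read_reference_panel <- function(path, chrom = NULL, start = NULL, end = NULL) {
  if (!file.exists(path)) stop_epimr(paste("cannot read VCF:", path), "epimr_io_error")
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  keep <- nchar(fix$REF) == 1L & nchar(fix$ALT) == 1L &
    fix$REF %in% c("A", "C", "G", "T") & fix$ALT %in% c("A", "C", "G", "T") &
    !grepl(",", fix$ALT, fixed = TRUE)
  pos <- as.numeric(fix$POS)
  if (!is.null(chrom)) keep <- keep & fix$CHROM == as.character(chrom)
  if (!is.null(start)) keep <- keep & pos >= start
  if (!is.null(end)) keep <- keep & pos <= end
  keep[is.na(keep)] <- FALSE
  if (!any(keep)) stop_epimr("no biallelic SNPs in the requested region", "epimr_empty_region")
  gt <- vcfR::extract.gt(v, element = "GT")[keep, , drop = FALSE]
  dos <- apply(gt, c(1, 2), function(g) {
    if (is.na(g)) return(NA_real_)
    sum(as.integer(strsplit(g, "[/|]")[[1]]) > 0)
  })
  ids <- fix$ID[keep]
  no_id <- is.na(ids) | ids == "."
  ids[no_id] <- paste0(fix$CHROM[keep][no_id], ":", fix$POS[keep][no_id])
  geno <- t(dos)
  colnames(geno) <- ids
  new_ref_panel(geno, data.frame(snp = ids, chrom = fix$CHROM[keep], pos = pos[keep],
                                 ref = fix$REF[keep], alt = fix$ALT[keep],
                                 stringsAsFactors = FALSE))
}

new_ref_panel <- function(geno, variants) {
  stopifnot(ncol(geno) == nrow(variants))
  rownames(variants) <- NULL
  structure(list(geno = geno, variants = variants), class = "ref_panel")
}

#' @export
print.ref_panel <- function(x, ...) {
  cat(sprintf("<ref_panel> %d individuals x %d biallelic SNPs (chrom %s)\n",
              nrow(x$geno), ncol(x$geno), paste(unique(x$variants$chrom), collapse = ",")))
  invisible(x)
}

#' Minor allele frequencies of a reference panel
#' @param panel a `ref_panel`.
#' @return named vector of per-variant minor allele frequencies from dosages.
#' @export
panel_maf <- function(panel) {
  f <- colMeans(panel$geno, na.rm = TRUE) / 2
  stats::setNames(pmin(f, 1 - f), panel$variants$snp)
}

# ALT-allele frequency (not folded).
panel_alt_freq <- function(panel) {
  stats::setNames(colMeans(panel$geno, na.rm = TRUE) / 2, panel$variants$snp)
}

#' Dosage correlation between panel variants
#' @param panel a `ref_panel`.
#' @param snps,snps2 variant ids; `snps2` defaults to `snps`.
#' @return correlation matrix of ALT-dosages.
#' @export
panel_cor <- function(panel, snps, snps2 = snps) {
  stats::cor(panel$geno[, snps, drop = FALSE], panel$geno[, snps2, drop = FALSE])
}

# Resolve a per-chromosome panel from either one ref_panel or a named list.
get_panel <- function(panels, chrom) {
  if (inherits(panels, "ref_panel")) return(panels)
  p <- panels[[as.character(chrom)]]
  if (is.null(p)) stop_epimr(paste("no reference panel for chromosome", chrom), "epimr_config_error")
  p
}

#' Read a CpG annotation table
#'
#' Tab-delimited table with columns `cpg_id`, `chrom`, `pos`, `ewas_beta`,
#' `ewas_se`, `ewas_fdr`: the exposure-associated CpG list (with its EWAS
#' effect estimates) that seeds the pipeline.
#' @param path file path.
#' @export
read_cpg_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("cpg_id", "chrom", "pos", "ewas_beta", "ewas_se", "ewas_fdr")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_epimr(paste("CpG annotation lacks column(s):", paste(missing_cols, collapse = ", ")),
               "epimr_config_error")
  }
  df$chrom <- as.character(df$chrom)
  ok <- !is.na(df$ewas_se) & df$ewas_se > 0 &
    !is.na(df$ewas_fdr) & df$ewas_fdr >= 0 & df$ewas_fdr <= 1
  if (any(!ok)) warning(sprintf("dropped %d invalid CpG annotation row(s)", sum(!ok)))
  df[ok, required]
}

#' Read a gene annotation table
#'
#' Tab-delimited with columns `gene_id`, `chrom`, `start`, `end` (1-based,
#' inclusive interval of the gene body).
#' @param path file path.
#' @export
read_gene_annotation <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  required <- c("gene_id", "chrom", "start", "end")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop_epimr(paste("gene annotation lacks column(s):", paste(missing_cols, collapse = ", ")),
               "epimr_config_error")
  }
  df$chrom <- as.character(df$chrom)
  df[required]
}

#' GWAS inclusion filter for outcome datasets
#'
#' A complex-trait study is eligible when all four criteria hold: sample size
#' strictly greater than 1000, effects reported for more than 100 000
#' variants, a European or mixed ancestry population, and reported beta, SE
#' and effect alleles.
#'
#' @param meta data.frame (or single-row list) with columns `trait_id`,
#'   `sample_n`, `n_variants_reported`, `population`, `has_beta_se_ea`.
#' @return data.frame with columns `trait_id`, `eligible`, `reason` (empty
#'   string when eligible; otherwise the first failing criterion among
#'   "sample size", "variant count", "population", "missing effect columns").
#' @export
filter_trait_eligibility <- function(meta) {
  meta <- as.data.frame(meta, stringsAsFactors = FALSE)
  reason <- character(nrow(meta))
  fail <- function(cond, why) ifelse(reason == "" & cond, why, reason)
  reason <- fail(!(meta$sample_n > 1000), "sample size")
  reason <- fail(!(meta$n_variants_reported > 100000), "variant count")
  reason <- fail(!(meta$population %in% c("European", "mixed")), "population")
  reason <- fail(!meta$has_beta_se_ea, "missing effect columns")
  data.frame(trait_id = meta$trait_id, eligible = reason == "", reason = reason,
             stringsAsFactors = FALSE)
}
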