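# Independent oracles and small fixture builders shared across tests.

# Naive exhaustive-loop evidence for a configuration class: sums the product
# of group ABFs over every assignment of distinct variants to groups.
# Deliberately written as plain loops, independent of config_evidence().
naive_config_evidence <- function(labf, groups) {
  k <- length(groups)
  if (k == 0L) return(0)
  m <- nrow(labf)
  l <- lapply(groups, function(g) rowSums(labf[, g, drop = FALSE]))
  total <- 0
  if (k == 1L) {
    for (v in seq_len(m)) total <- total + exp(l[[1]][v])
  } else if (k == 2L) {
    for (v in seq_len(m)) for (w in seq_len(m)) {
      if (v != w) total <- total + exp(l[[1]][v] + l[[2]][w])
    }
  } else {
    for (v in seq_len(m)) for (w in seq_len(m)) for (x in seq_len(m)) {
      if (v != w && v != x && w != x) {
        total <- total + exp(l[[1]][v] + l[[2]][w] + l[[3]][x])
      }
    }
  }
  unname(log(total))
}

# Global allele-label swap of a summary dataset: relabels every record's
# effect/other allele and adjusts beta and eaf accordingly. A dataset and
# its swap describe identical associations.
swap_allele_labels <- function(df) {
  tmp <- df$ea
  df$ea <- df$oa
  df$oa <- tmp
  df$beta <- -df$beta
  df$eaf <- 1 - df$eaf
  df
}

# Minimal well-formed summary data.frame builder.
make_sumstats <- function(snp, pos, beta, se, p = NULL, ea = "G", oa = "A",
                          eaf = 0.3, n = 1000, chrom = "1") {
  k <- length(snp)
  if (is.null(p)) p <- pmin(2 * pnorm(-abs(beta / se)), 1)
  data.frame(snp = snp, chrom = rep_len(chrom, k), pos = pos,
             ea = rep_len(ea, k), oa = rep_len(oa, k), eaf = rep_len(eaf, k),
             beta = beta, se = se, p = p, n = rep_len(n, k),
             stringsAsFactors = FALSE)
}

# Bell numbers via the recurrence B(n+1) = sum C(n,k) B(k); used as an
# independent count oracle for configuration enumeration.
bell_number <- function(n) {
  b <- c(1)
  for (i in seq_len(n)) {
    b <- c(b, sum(choose(i - 1, 0:(i - 1)) * b))
  }
  b[n + 1]
}
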