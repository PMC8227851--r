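# shared fixtures, built in code

# a small two-SNP panel with an explicit frequency so simulation works
toy_panel <- function(kinds = c("additive", "additive"), freqs = c(0.3, 0.5)) {
  rsids <- paste0("rsT", seq_along(kinds))
  panel(
    "toy",
    tibble::tibble(variable = rsids, kind = kinds, rsids = as.list(rsids)),
    tibble::tibble(
      gene = "GENE", rsid = rsids,
      ref_allele = "A", var_allele = "G", var_freq = freqs
    )
  )
}

# cohort built from explicit genotype counts at a single biallelic SNP
# (ref A / var G), with optional PIE-scores
counts_cohort <- function(n_AA, n_AG, n_GG, pie = NULL, rsid = "rsT1") {
  calls <- c(rep("AA", n_AA), rep("AG", n_AG), rep("GG", n_GG))
  gt <- tibble::as_tibble(setNames(
    list(sprintf("S%03d", seq_along(calls)), calls),
    c("sample_id", rsid)
  ))
  ph <- if (!is.null(pie)) {
    tibble::tibble(sample_id = gt$sample_id, pie_score = pie)
  }
  cohort(gt, ph)
}

# brute-force exact HWE oracle: directly enumerates every heterozygote
# configuration compatible with the observed allele counts, with
# probabilities computed from first principles via choose()
hwe_oracle <- function(hom_ref, het, hom_var) {
  n <- hom_ref + het + hom_var
  n_a <- 2 * hom_ref + het # ref-allele count
  n_b <- 2 * hom_var + het
  rare <- min(n_a, n_b)
  if (rare == 0) return(1)
  hets <- seq(rare %% 2, rare, by = 2)
  probs <- vapply(hets, function(h) {
    hr <- (n_a - h) / 2
    hv <- (n_b - h) / 2
    if (hr < 0 || hv < 0) return(0)
    # P(h) proportional to n! / (hr! h! hv!) * 2^h ; normalised below
    exp(lchoose(n, hr) + lchoose(n - hr, h) + h * log(2))
  }, numeric(1))
  probs <- probs / sum(probs)
  p_obs <- probs[hets == het]
  sum(probs[probs <= p_obs + 1e-12])
}
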