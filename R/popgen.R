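#' Variant-allele frequency in a cohort
#'
#' Fraction of non-missing alleles at `rsid` equal to the declared variant
#' allele: (variant-allele count) / (2 x non-missing samples).
#'
#' @param x An `ec_cohort`.
#' @param rsid Variant identifier (column of the genotype table).
#' @param panel Optional `ec_panel` supplying the allele definitions; defaults
#'   to the packaged [variant_table()].
#' @return Frequency in `[0, 1]`.
#' @export
allele_frequency <- function(x, rsid, panel = NULL) {
  stopifnot(inherits(x, "ec_cohort"))
  if (!rsid %in% names(x$genotypes)) abort(paste0("no calls for ", rsid))
  def <- variant_def(rsid, panel)
  calls <- x$genotypes[[rsid]]
  calls <- calls[!is.na(calls)]
  if (length(calls) == 0) abort(paste0("no non-missing calls for ", rsid))
  alleles <- c(def$ref_allele, def$var_allele)
  n_var <- vapply(calls, function(call) {
    sum(split_call(call, alleles) == def$var_allele)
  }, integer(1))
  sum(n_var) / (2 * length(calls))
}

variant_def <- function(rsid, panel = NULL) {
  tab <- if (is.null(panel)) variant_table() else panel$variants
  row <- tab[tab$rsid == rsid, ]
  if (nrow(row) == 0) abort(paste0("unknown variant: ", rsid))
  row[1, ]
}

#' Exact test of Hardy-Weinberg equilibrium
#'
#' Exact test on the heterozygote count conditional on the observed allele
#' counts (Wigginton-style): the p-value is the total probability of all
#' heterozygote configurations no more probable than the observed one.
#'
#' @param hom_ref,het,hom_var Genotype counts; `hom_ref` may also be a
#'   length-3 vector `(hom_ref, het, hom_var)`.
#' @return p-value in `(0, 1]`.
#' @examples
#' hwe_test(25, 50, 25)  # perfect HWE proportions -> p = 1
#' hwe_test(50, 0, 50)   # maximal heterozygote deficit -> tiny p
#' @export
hwe_test <- function(hom_ref, het = NULL, hom_var = NULL) {
  if (is.null(het) && length(hom_ref) == 3) {
    counts <- hom_ref
  } else {
    counts <- c(hom_ref, het, hom_var)
  }
  if (length(counts) != 3 || any(is.na(counts)) || any(counts < 0)) {
    abort("hwe_test needs three non-negative genotype counts")
  }
  counts <- as.integer(counts)
  n <- sum(counts)
  if (n == 0) abort("no genotypes observed")
  obs_het <- counts[2]
  rare <- 2L * min(counts[1], counts[3]) + obs_het # minor-allele count
  if (rare == 0) return(1) # monomorphic: nothing to test

  # P(het = h | n, rare) over all h with the parity of `rare`
  hets <- seq(rare %% 2L, min(rare, 2L * n - rare), by = 2L)
  logp <- vapply(hets, function(h) {
    hom_r <- (rare - h) / 2
    hom_c <- n - h - hom_r
    lgamma(n + 1) - lgamma(hom_r + 1) - lgamma(h + 1) - lgamma(hom_c + 1) +
      h * log(2) +
      lgamma(rare + 1) + lgamma(2 * n - rare + 1) - lgamma(2 * n + 1)
  }, numeric(1))
  p <- exp(logp - max(logp))
  p <- p / sum(p)
  p_obs <- p[hets == obs_het]
  min(1, sum(p[p <= p_obs + 1e-12]))
}

#' Pairwise linkage disequilibrium r-squared
#'
#' Squared Pearson correlation of variant-allele dosages (composite LD).
#' Phased haplotypes are not required; this differs from haplotype-based
#' (EM) r-squared when genotypes are far from HWE.
#'
#' @param x An `ec_cohort`.
#' @param rsid_a,rsid_b Variant identifiers.
#' @param panel Optional `ec_panel` with allele definitions.
#' @return r-squared in `[0, 1]`.
#' @export
ld_r2 <- function(x, rsid_a, rsid_b, panel = NULL) {
  stopifnot(inherits(x, "ec_cohort"))
  dose <- function(rsid) {
    def <- variant_def(rsid, panel)
    alleles <- c(def$ref_allele, def$var_allele)
    calls <- x$genotypes[[rsid]]
    out <- rep(NA_real_, length(calls))
    ok <- !is.na(calls)
    out[ok] <- vapply(calls[ok], function(call) {
      sum(split_call(call, alleles) == def$var_allele)
    }, integer(1))
    out
  }
  a <- dose(rsid_a)
  b <- dose(rsid_b)
  ok <- !is.na(a) & !is.na(b)
  if (sum(ok) < 2) abort("need at least two samples typed at both variants")
  if (sd(a[ok]) == 0 || sd(b[ok]) == 0) {
    abort("LD r-squared undefined for a fixed variant")
  }
  cor(a[ok], b[ok])^2
}
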