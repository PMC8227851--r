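#' Encode a cohort's genotypes as a numeric design matrix
#'
#' Applies each panel variable's coding scheme to the raw calls:
#'
#' * `additive` — number of minor alleles (0/1/2), minor alleles determined
#'   from allele frequencies in the supplied cohort (ties at 0.5 broken by the
#'   lexicographically smaller allele, so encodings are reproducible).
#' * `dominant` — 1 if homozygous for the variant allele, else 0 (for
#'   rs12913832: AA and AG are 0, GG is 1).
#' * `carrier` — 1 if carrying at least one minor allele.
#' * `combined` — sum of minor-allele counts over the constituent variants,
#'   capped at 2.
#'
#' Samples with any missing panel call are dropped by default (prediction
#' modelling uses complete profiles); `missing = "impute"` substitutes the
#' cohort mean of the coded values instead.
#'
#' @param x An `ec_cohort`.
#' @param panel An `ec_panel`.
#' @param missing `"drop"` (default) or `"impute"`.
#' @return A tibble (`sample_id` + one integer column per panel variable,
#'   doubles under imputation) with attributes `minor_allele_map` (named
#'   character vector rsid -> minor allele) and `panel_name`.
#' @examples
#' cht <- simulate_cohort(sim_config(n_samples = 20, seed = 1))
#' encode_cohort(cht, panel_ec11())
#' @export
encode_cohort <- function(x, panel, missing = c("drop", "impute")) {
  stopifnot(inherits(x, "ec_cohort"), inherits(panel, "ec_panel"))
  missing <- match.arg(missing)
  gt <- x$genotypes
  need <- unique(unlist(panel$variables$rsids))
  absent <- setdiff(need, names(gt))
  if (length(absent) > 0) {
    abort(paste0("cohort lacks panel variants: ", paste(absent, collapse = ", ")))
  }
  minor_map <- minor_allele_map(x, panel)

  count_minor <- function(rsid) {
    v <- panel$variants[panel$variants$rsid == rsid, ]
    alleles <- c(v$ref_allele, v$var_allele)
    calls <- gt[[rsid]]
    out <- rep(NA_integer_, length(calls))
    ok <- !is.na(calls)
    out[ok] <- vapply(calls[ok], function(call) {
      sum(split_call(call, alleles) == minor_map[[rsid]])
    }, integer(1))
    out
  }

  cols <- list(sample_id = gt$sample_id)
  for (i in seq_len(nrow(panel$variables))) {
    var <- panel$variables$variable[i]
    kind <- panel$variables$kind[i]
    rsids <- panel$variables$rsids[[i]]
    coded <- switch(kind,
      additive = count_minor(rsids),
      carrier = {
        cnt <- count_minor(rsids)
        ifelse(is.na(cnt), NA_integer_, as.integer(cnt >= 1L))
      },
      dominant = {
        v <- panel$variants[panel$variants$rsid == rsids, ]
        hom_var <- make_call(v$var_allele, v$var_allele)
        calls <- gt[[rsids]]
        ifelse(is.na(calls), NA_integer_, as.integer(calls == hom_var))
      },
      combined = {
        counts <- lapply(rsids, count_minor)
        tot <- Reduce(`+`, counts)
        pmin(tot, 2L)
      },
      abort(paste0("unknown coding kind: ", kind))
    )
    cols[[var]] <- coded
  }
  coded <- as_tibble(cols)

  vars <- panel$variables$variable
  if (missing == "drop") {
    keep <- complete.cases(coded[vars])
    coded <- coded[keep, ]
  } else {
    for (v in vars) {
      col <- coded[[v]]
      if (all(is.na(col))) abort(paste0("variable ", v, " is entirely missing"))
      col[is.na(col)] <- mean(col, na.rm = TRUE)
      coded[[v]] <- col
    }
  }
  attr(coded, "minor_allele_map") <- minor_map
  attr(coded, "panel_name") <- panel$name
  attr(coded, "variable_kinds") <- setNames(panel$variables$kind, vars)
  coded
}

# minor allele per variant from allele frequencies in this cohort
minor_allele_map <- function(x, panel) {
  map <- character(0)
  for (i in seq_len(nrow(panel$variants))) {
    v <- panel$variants[i, ]
    if (!v$rsid %in% names(x$genotypes)) next
    q <- allele_frequency(x, v$rsid, panel)
    map[[v$rsid]] <- if (q < 0.5) {
      v$var_allele
    } else if (q > 0.5) {
      v$ref_allele
    } else {
      min(v$ref_allele, v$var_allele) # tie: lexicographic
    }
  }
  map
}
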