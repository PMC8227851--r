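#' Assemble a cohort from genotype and phenotype tables
#'
#' A cohort bundles raw genotype calls (one column per rsid, unordered
#' allele-pair strings such as `"AG"`, `NA` for missing) with quantitative
#' PIE-score phenotypes.  Calls are canonicalised so `"GA"` and `"AG"` are the
#' same genotype.
#'
#' @param genotypes Data frame with `sample_id` plus one character column per
#'   rsid.
#' @param phenotypes Data frame with `sample_id` and `pie_score` in `[-1, 1]`.
#'   May be `NULL` for genotype-only cohorts.
#' @return An `ec_cohort` object (list of two tibbles, `genotypes` and
#'   `phenotypes`).
#' @export
cohort <- function(genotypes, phenotypes = NULL) {
  genotypes <- as_tibble(genotypes)
  if (!"sample_id" %in% names(genotypes)) abort("genotypes need a sample_id column")
  genotypes$sample_id <- as.character(genotypes$sample_id)
  if (anyDuplicated(genotypes$sample_id)) abort("duplicate sample ids in genotypes")
  rsids <- setdiff(names(genotypes), "sample_id")
  genotypes[rsids] <- lapply(genotypes[rsids], canonicalise_calls)
  if (!is.null(phenotypes)) {
    phenotypes <- as_tibble(phenotypes)
    if (!all(c("sample_id", "pie_score") %in% names(phenotypes))) {
      abort("phenotypes need sample_id and pie_score columns")
    }
    phenotypes$sample_id <- as.character(phenotypes$sample_id)
    if (anyDuplicated(phenotypes$sample_id)) abort("duplicate sample ids in phenotypes")
    bad <- !is.na(phenotypes$pie_score) &
      (phenotypes$pie_score < -1 | phenotypes$pie_score > 1)
    if (any(bad)) {
      abort(paste0(
        "PIE-scores outside [-1, 1] for: ",
        paste(phenotypes$sample_id[bad], collapse = ", ")
      ))
    }
    only_g <- setdiff(genotypes$sample_id, phenotypes$sample_id)
    only_p <- setdiff(phenotypes$sample_id, genotypes$sample_id)
    if (length(only_g) || length(only_p)) {
      abort(paste0(
        "samples present in only one table: ",
        paste(head(c(only_g, only_p), 5), collapse = ", ")
      ))
    }
    phenotypes <- phenotypes[match(genotypes$sample_id, phenotypes$sample_id), ]
  }
  structure(list(genotypes = genotypes, phenotypes = phenotypes),
    class = "ec_cohort"
  )
}

# sort the two allele strings within each call so "GA" == "AG";
# missing calls ("./.", ".", "", NA) become NA
canonicalise_calls <- function(x, alleles = NULL) {
  x <- as.character(x)
  x[x %in% c("./.", ".", "")] <- NA_character_
  ok <- !is.na(x)
  if (!any(ok)) return(x)
  if (is.null(alleles)) {
    # without declared alleles, only single-character alleles can be split
    two <- ok & nchar(x) == 2
    x[two] <- vapply(
      strsplit(x[two], ""),
      function(a) paste(sort(a), collapse = ""), character(1)
    )
    return(x)
  }
  x[ok] <- vapply(x[ok], function(call) {
    pair <- split_call(call, alleles)
    paste(sort(pair), collapse = "")
  }, character(1))
  x
}

# parse a concatenated allele-pair string against the declared alleles,
# e.g. "TCT-" with alleles c("TCT", "-") -> c("TCT", "-")
split_call <- function(call, alleles) {
  for (a in alleles) {
    for (b in alleles) {
      if (paste0(a, b) == call) return(c(a, b))
    }
  }
  abort(paste0(
    "genotype call '", call, "' does not match declared alleles {",
    paste(alleles, collapse = ", "), "}"
  ))
}

# genotype call for an (unordered) allele pair
make_call <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "")
}

#' @export
print.ec_cohort <- function(x, ...) {
  n_rs <- ncol(x$genotypes) - 1L
  cat("<ec_cohort> ", nrow(x$genotypes), " samples, ", n_rs, " variants, ",
    if (is.null(x$phenotypes)) "no phenotypes" else "PIE phenotypes",
    "\n",
    sep = ""
  )
  invisible(x)
}

#' Number of samples in a cohort
#' @param x An `ec_cohort`.
#' @return Integer sample count.
#' @export
n_samples <- function(x) {
  stopifnot(inherits(x, "ec_cohort"))
  nrow(x$genotypes)
}

#' Read and write cohorts as TSV
#'
#' Genotype TSV: header `sample_id` plus one column per rsid; calls are the
#' two allele strings concatenated (e.g. `"AG"`, `"TCT-"`), missing `"./."`.
#' Phenotype TSV: columns `sample_id`, `pie_score`.  Writing then reading a
#' cohort is the identity.
#'
#' @param genotype_path,phenotype_path File paths.  `phenotype_path` may be
#'   `NULL` for a genotype-only cohort.
#' @param panel Optional `ec_panel`; when supplied, calls for its variants are
#'   validated against the declared alleles.
#' @return `read_cohort()` an `ec_cohort`; `write_cohort()` the cohort,
#'   invisibly.
#' @export
read_cohort <- function(genotype_path, phenotype_path = NULL, panel = NULL) {
  gt <- readr::read_tsv(genotype_path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  ph <- NULL
  if (!is.null(phenotype_path)) {
    ph <- readr::read_tsv(phenotype_path,
      col_types = readr::cols(
        sample_id = readr::col_character(),
        pie_score = readr::col_double()
      ),
      progress = FALSE
    )
  }
  out <- cohort(gt, ph)
  if (!is.null(panel)) validate_calls(out, panel)
  out
}

#' @rdname read_cohort
#' @param x An `ec_cohort`.
#' @export
write_cohort <- function(x, genotype_path, phenotype_path = NULL) {
  stopifnot(inherits(x, "ec_cohort"))
  gt <- x$genotypes
  rsids <- setdiff(names(gt), "sample_id")
  gt[rsids] <- lapply(gt[rsids], function(col) ifelse(is.na(col), "./.", col))
  readr::write_tsv(gt, genotype_path, progress = FALSE)
  if (!is.null(phenotype_path) && !is.null(x$phenotypes)) {
    readr::write_tsv(x$phenotypes, phenotype_path, progress = FALSE)
  }
  invisible(x)
}

# check every non-missing call against the panel's declared alleles
validate_calls <- function(x, panel) {
  for (i in seq_len(nrow(panel$variants))) {
    v <- panel$variants[i, ]
    if (!v$rsid %in% names(x$genotypes)) next
    alleles <- c(v$ref_allele, v$var_allele)
    calls <- x$genotypes[[v$rsid]]
    for (call in unique(calls[!is.na(calls)])) split_call(call, alleles)
  }
  invisible(x)
}

#' Read genotype calls from a VCF
#'
#' Reads the GT field of a VCF 4.x file (via the vcfR package), matching rows
#' to panel variants by the ID column (rsid) and decoding 0/1 allele indices
#' through the REF and ALT columns.  Only the panel's rsids are kept.
#'
#' @param vcf_path Path to an uncompressed or bgzipped VCF.
#' @param panel An `ec_panel` whose rsids are looked up.
#' @param phenotypes Optional phenotype data frame (`sample_id`, `pie_score`).
#' @return An `ec_cohort`.
#' @export
read_cohort_vcf <- function(vcf_path, panel, phenotypes = NULL) {
  if (!requireNamespace("vcfR", quietly = TRUE)) {
    abort("the vcfR package is required to read VCF files")
  }
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(vcf), stringsAsFactors = FALSE)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  keep <- which(fix$ID %in% panel$variants$rsid)
  if (length(keep) == 0) abort("no panel rsids found in VCF ID column")
  samples <- colnames(gt)
  cols <- list(sample_id = samples)
  for (i in keep) {
    alleles <- c(fix$REF[i], fix$ALT[i])
    calls <- vapply(gt[i, ], function(g) {
      if (is.na(g)) return(NA_character_)
      idx <- as.integer(strsplit(g, "[/|]")[[1]]) + 1L
      if (any(is.na(idx)) || any(idx > length(alleles))) {
        abort(paste0("unparseable GT '", g, "' at ", fix$ID[i]))
      }
      make_call(alleles[idx[1]], alleles[idx[2]])
    }, character(1))
    cols[[fix$ID[i]]] <- unname(calls)
  }
  out <- cohort(as_tibble(cols), phenotypes)
  validate_calls(out, panel)
  out
}
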