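#' Packaged variant table
#'
#' Loads the packaged table of 44 pigmentary variants (gene, rsid, reference
#' and variant allele, variant-allele frequency in the 757-individual
#' discovery set and, where typed, the 523-individual Norwegian model set).
#' Frequencies published as "<0.01" are stored as 0.005.
#'
#' @return A tibble with columns `gene`, `rsid`, `ref_allele`, `var_allele`,
#'   `freq_discovery`, `freq_model`, `ec11`, `irisplex`.
#' @export
variant_table <- function() {
  path <- system.file("extdata", "variant_table.json", package = "ec11")
  raw <- jsonlite::fromJSON(path)$variants
  as_tibble(raw)
}

#' Construct a custom panel
#'
#' Defines a named SNP set: an ordered list of coded variables (each a
#' coding scheme over one or more variants) plus the variant definitions
#' they resolve to.
#'
#' @param name Panel name.
#' @param variables Tibble with columns `variable` (unique names), `kind`
#'   (`"additive"`, `"dominant"`, `"carrier"` or `"combined"`) and `rsids`
#'   (list-column of constituent rsids; singletons except for combined).
#' @param variants Tibble with columns `gene`, `rsid`, `ref_allele`,
#'   `var_allele`, `var_freq` covering every constituent rsid.
#' @return An `ec_panel`.
#' @export
panel <- function(name, variables, variants) {
  variables <- as_tibble(variables)
  variants <- as_tibble(variants)
  bad <- setdiff(variables$kind, c("additive", "dominant", "carrier", "combined"))
  if (length(bad) > 0) {
    abort(paste0("unknown coding kind(s): ", paste(bad, collapse = ", ")))
  }
  single <- variables$kind != "combined" & lengths(variables$rsids) != 1
  if (any(single)) abort("non-combined variables must have exactly one rsid")
  new_panel(name, variables, variants)
}

new_panel <- function(name, variables, variants) {
  stopifnot(is_tibble(variables), is_tibble(variants))
  all_rsids <- unlist(variables$rsids)
  missing <- setdiff(all_rsids, variants$rsid)
  if (length(missing) > 0) {
    abort(paste0("panel rsids not in variant table: ", paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(variables$variable)) abort("variable names must be unique")
  if (any(variants$ref_allele == variants$var_allele)) abort("ref and variant allele must differ")
  if (any(variants$var_freq < 0 | variants$var_freq > 1, na.rm = TRUE)) {
    abort("variant frequencies must lie in [0, 1]")
  }
  structure(
    list(name = name, variables = variables, variants = variants),
    class = "ec_panel"
  )
}

#' @export
print.ec_panel <- function(x, ...) {
  cat("<ec_panel> ", x$name, ": ", nrow(x$variables), " variables over ",
    nrow(x$variants), " variants\n",
    sep = ""
  )
  print(x$variables, n = Inf)
  invisible(x)
}

panel_variants <- function(rsids, freq = c("discovery", "model")) {
  freq <- match.arg(freq)
  tab <- variant_table()
  col <- if (freq == "discovery") "freq_discovery" else "freq_model"
  out <- tab[match(rsids, tab$rsid), c("gene", "rsid", "ref_allele", "var_allele", col)]
  names(out)[5] <- "var_freq"
  out
}

#' Built-in SNP panels
#'
#' Constructors for the three SNP sets used in eye-colour prediction plus the
#' 44-variant discovery ranking panel:
#'
#' * `panel_ec11()` — the 11-variable EC11 panel: rs12913832 coded dominant
#'   (AA/AG = 0, GG = 1), the two rare OCA2 variants rs121918166 and
#'   rs74653330 carrier-coded (0/1), and eight additive (0/1/2 minor-allele
#'   count) SNPs.  Its genotype space has \eqn{2^3 \cdot 3^8 = 52{,}488}
#'   combinations.
#' * `panel_irisplex6()` — the six IrisPlex SNPs, all additive
#'   (\eqn{3^6 = 729} combinations).
#' * `panel_rs12913832()` — rs12913832 alone, dominant-coded.
#' * `panel_discovery44()` — the ranking panel: all 44 discovery variants,
#'   with rs12913832 dominant, rs121918166 + rs74653330 combined into one
#'   capped minor-allele-count variable, and the rest additive.
#'
#' @param freq Which published frequency column to attach to the variant
#'   definitions: `"discovery"` (757 Europeans) or `"model"` (523 Norwegians).
#' @return An `ec_panel` object: `name`, a `variables` tibble
#'   (`variable`, `kind`, `rsids` list-column), and a `variants` tibble.
#' @examples
#' panel_ec11()
#' prod(variable_levels(panel_ec11()))  # 52488
#' @export
panel_ec11 <- function(freq = c("model", "discovery")) {
  freq <- match.arg(freq)
  additive <- c(
    "rs16891982", "rs1800407", "rs1408799", "rs4904927",
    "rs12896399", "rs1126809", "rs10131374", "rs1800401"
  )
  variables <- dplyr::bind_rows(
    tibble(variable = "rs12913832", kind = "dominant", rsids = list("rs12913832")),
    tibble(variable = "rs121918166", kind = "carrier", rsids = list("rs121918166")),
    tibble(variable = "rs74653330", kind = "carrier", rsids = list("rs74653330")),
    tibble(variable = additive, kind = "additive", rsids = as.list(additive))
  )
  new_panel("EC11", variables, panel_variants(unlist(variables$rsids), freq))
}

#' @rdname panel_ec11
#' @export
panel_irisplex6 <- function(freq = c("model", "discovery")) {
  freq <- match.arg(freq)
  rsids <- c(
    "rs12913832", "rs16891982", "rs1800407",
    "rs12896399", "rs1393350", "rs12203592"
  )
  variables <- tibble(variable = rsids, kind = "additive", rsids = as.list(rsids))
  new_panel("IrisPlex6", variables, panel_variants(rsids, freq))
}

#' @rdname panel_ec11
#' @export
panel_rs12913832 <- function(freq = c("model", "discovery")) {
  freq <- match.arg(freq)
  variables <- tibble(
    variable = "rs12913832", kind = "dominant", rsids = list("rs12913832")
  )
  new_panel("rs12913832", variables, panel_variants("rs12913832", freq))
}

#' @rdname panel_ec11
#' @export
panel_discovery44 <- function(freq = c("discovery", "model")) {
  freq <- match.arg(freq)
  tab <- variant_table()
  combined <- c("rs121918166", "rs74653330")
  additive <- setdiff(tab$rsid, c("rs12913832", combined))
  variables <- dplyr::bind_rows(
    tibble(variable = "rs12913832", kind = "dominant", rsids = list("rs12913832")),
    tibble(
      variable = "rs121918166+rs74653330", kind = "combined",
      rsids = list(combined)
    ),
    tibble(variable = additive, kind = "additive", rsids = as.list(additive))
  )
  new_panel("discovery44", variables, panel_variants(tab$rsid, freq))
}

#' Coded levels per panel variable
#'
#' Number of distinct coded values each panel variable can take: 3 for
#' additive and combined codings, 2 for dominant and carrier codings.
#'
#' @param panel An `ec_panel`.
#' @return Named integer vector of level counts.
#' @export
variable_levels <- function(panel) {
  stopifnot(inherits(panel, "ec_panel"))
  setNames(
    ifelse(panel$variables$kind %in% c("additive", "combined"), 3L, 2L),
    panel$variables$variable
  )
}

#' Look up a panel by name
#'
#' @param name One of `"ec11"`, `"irisplex6"`, `"rs12913832"`,
#'   `"discovery44"`, case-insensitive.
#' @param freq Frequency column passed to the constructor.
#' @return An `ec_panel`.
#' @export
get_panel <- function(name, freq = NULL) {
  key <- tolower(name)
  ctor <- switch(key,
    ec11 = panel_ec11,
    irisplex6 = ,
    irisplex = panel_irisplex6,
    rs12913832 = panel_rs12913832,
    discovery44 = panel_discovery44,
    abort(paste0("unknown panel: ", name))
  )
  if (is.null(freq)) ctor() else ctor(freq)
}
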