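# run code with a temporary RNG state so simulation never disturbs the
# caller's random stream
with_local_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed %% .Machine$integer.max))
  force(code)
}

# deterministic per-task substream seeds below 2^31
derive_seed <- function(seed, index) {
  as.integer((as.double(seed) * 48271 + index * 16807) %% 2147483647)
}

#' Genotype-to-phenotype effect model for simulation
#'
#' Defines the generative map from coded genotypes to the transformed
#' PIE-score: `y = intercept + sum(beta_j g_j) + sum(gamma_j g_dom g_j) + e`,
#' with `e ~ N(0, noise_sd^2)` and `g_dom` the dominant rs12913832 variable.
#' The PIE-score is `inverse_transform(y)`, so all real `y` map into
#' `(-1, 1)` without clamping.
#'
#' @param intercept Intercept on the transformed scale.
#' @param main_effects Named numeric vector: panel variable -> coefficient.
#' @param interaction_effects Named numeric vector: partner variable ->
#'   coefficient of `g_rs12913832 x g_partner`.
#' @param noise_sd Residual standard deviation on the transformed scale
#'   (must be > 0 unless `allow_zero`).
#' @param rs12913832_variable Name of the dominant rs12913832 variable.
#' @return An `ec_effect_model` list.
#' @export
effect_model <- function(intercept = 0, main_effects = numeric(0),
                         interaction_effects = numeric(0), noise_sd = 1,
                         rs12913832_variable = "rs12913832") {
  if (noise_sd < 0) abort("noise_sd must be non-negative")
  structure(
    list(
      intercept = intercept,
      main_effects = main_effects,
      interaction_effects = interaction_effects,
      noise_sd = noise_sd,
      rs12913832_variable = rs12913832_variable
    ),
    class = "ec_effect_model"
  )
}

#' Simulation configuration
#'
#' Bundles everything needed to generate a cohort reproducibly: identical
#' configurations yield identical cohorts.
#'
#' @param n_samples Number of samples.
#' @param panel Generating `ec_panel` (its `var_freq` column drives the
#'   genotype frequencies).
#' @param effects An [effect_model()]; `NULL` for genotype-only simulation.
#' @param seed Integer seed.
#' @param tag_blocks Optional list of `list(source =, target =, r2 =)`
#'   entries; the target variant's alleles copy the source's with probability
#'   `sqrt(r2)`, emulating a tag-SNP haploblock.  Default: variants
#'   independent.
#' @return An `ec_sim_config` list.
#' @export
sim_config <- function(n_samples, panel = panel_ec11("model"), effects = NULL,
                       seed = 1L, tag_blocks = NULL) {
  if (n_samples < 0) abort("n_samples must be non-negative")
  if (is.null(effects)) effects <- default_effects(panel)
  structure(
    list(
      n_samples = as.integer(n_samples), panel = panel,
      effects = effects, seed = as.integer(seed), tag_blocks = tag_blocks
    ),
    class = "ec_sim_config"
  )
}

#' Simulate Hardy-Weinberg genotypes
#'
#' Each variant is drawn i.i.d. across samples with genotype probabilities
#' `(1-q)^2, 2q(1-q), q^2` at its panel variant-allele frequency `q`;
#' variants are mutually independent unless `tag_blocks` links them.
#'
#' @param panel An `ec_panel` with `var_freq` populated.
#' @param n Number of samples.
#' @param seed Integer seed.
#' @param tag_blocks See [sim_config()].
#' @return An `ec_cohort` without phenotypes.
#' @export
simulate_genotypes <- function(panel, n, seed = 1L, tag_blocks = NULL) {
  stopifnot(inherits(panel, "ec_panel"))
  if (any(is.na(panel$variants$var_freq))) {
    abort("panel has variants without a var_freq; cannot simulate")
  }
  n <- as.integer(n)
  with_local_seed(seed, {
    alleles <- list() # per rsid: n x 2 matrix of 0/1 variant-allele indicators
    for (i in seq_len(nrow(panel$variants))) {
      v <- panel$variants[i, ]
      q <- v$var_freq
      alleles[[v$rsid]] <- matrix(rbinom(2L * n, 1L, q), ncol = 2)
    }
    for (tb in tag_blocks %||% list()) {
      src <- alleles[[tb$source]]
      q <- panel$variants$var_freq[panel$variants$rsid == tb$target]
      copy <- matrix(runif(2L * n) < sqrt(tb$r2), ncol = 2)
      fresh <- matrix(rbinom(2L * n, 1L, q), ncol = 2)
      alleles[[tb$target]] <- ifelse(copy, src, fresh)
    }
    cols <- list(sample_id = sprintf("S%04d", seq_len(n)))
    for (i in seq_len(nrow(panel$variants))) {
      v <- panel$variants[i, ]
      al <- alleles[[v$rsid]]
      a1 <- ifelse(al[, 1] == 1L, v$var_allele, v$ref_allele)
      a2 <- ifelse(al[, 2] == 1L, v$var_allele, v$ref_allele)
      cols[[v$rsid]] <- if (n > 0) make_call(a1, a2) else character(0)
    }
    cohort(as_tibble(cols))
  })
}

#' Simulate PIE phenotypes from coded genotypes
#'
#' @param coded A coded matrix from [encode_cohort()].
#' @param effects An [effect_model()].
#' @param seed Integer seed.
#' @return A tibble `sample_id`, `pie_score` (plus the transformed `y`).
#' @export
simulate_phenotypes <- function(coded, effects, seed = 1L) {
  stopifnot(inherits(effects, "ec_effect_model"))
  vars <- setdiff(names(coded), "sample_id")
  named <- c(names(effects$main_effects), names(effects$interaction_effects))
  unknown <- setdiff(named, vars)
  if (length(unknown) > 0) {
    abort(paste0("effect variables not in coded matrix: ", paste(unknown, collapse = ", ")))
  }
  n <- nrow(coded)
  y <- rep(effects$intercept, n)
  for (v in names(effects$main_effects)) {
    y <- y + effects$main_effects[[v]] * coded[[v]]
  }
  if (length(effects$interaction_effects) > 0) {
    gdom <- coded[[effects$rs12913832_variable]]
    if (is.null(gdom)) abort("rs12913832 variable missing from coded matrix")
    for (v in names(effects$interaction_effects)) {
      y <- y + effects$interaction_effects[[v]] * gdom * coded[[v]]
    }
  }
  y <- y + with_local_seed(seed, rnorm(n, 0, effects$noise_sd))
  tibble(sample_id = coded$sample_id, pie_score = inverse_transform(y), y = y)
}

#' Simulate a complete cohort
#'
#' Draws Hardy-Weinberg genotypes at the panel frequencies, encodes them with
#' the generating panel, and draws phenotypes from the effect model.  The
#' genotype and phenotype streams use seeds derived from the config seed, so
#' the cohort is a deterministic function of its configuration.
#'
#' @param config An [sim_config()].
#' @return An `ec_cohort` with genotypes and PIE phenotypes.
#' @examples
#' cht <- simulate_cohort(paper_like_config(n = 100, seed = 7))
#' table(categorise_pie(cht$phenotypes$pie_score, "two_category"))
#' @export
simulate_cohort <- function(config) {
  stopifnot(inherits(config, "ec_sim_config"))
  geno <- simulate_genotypes(
    config$panel, config$n_samples,
    seed = derive_seed(config$seed, 1L), tag_blocks = config$tag_blocks
  )
  if (config$n_samples == 0) {
    return(cohort(geno$genotypes, tibble(sample_id = character(0), pie_score = numeric(0))))
  }
  coded <- encode_cohort(geno, config$panel)
  ph <- simulate_phenotypes(coded, config$effects, seed = derive_seed(config$seed, 2L))
  cohort(geno$genotypes, ph[c("sample_id", "pie_score")])
}

#' Paper-like simulation configurations
#'
#' `paper_like_config()` returns a configuration emulating the coarse
#' structure of the study cohorts: genotypes in HWE at the published allele
#' frequencies, and PIE-scores dominated by rs12913832 (strong dominant
#' effect on the transformed scale), with small synthetic modifier effects,
#' a blue-promoting effect of the rare OCA2 variants confined to rs12913832
#' A-allele carriers (main effect cancelled by a negative interaction in GG
#' homozygotes), and Gaussian noise.  `set = "discovery"` simulates all 44
#' ranking variants at discovery frequencies; `set = "model"` simulates the
#' 13 variants typed in the Norwegian model cohort at model frequencies.
#'
#' The effect values are packaged synthetic constants, calibrated only so
#' that coarse marginals resemble the published ones (roughly 60-70% blue in
#' the two-category system and LOOCV two-category accuracy near 0.9); they
#' are not estimates of any real genotype-phenotype map.
#'
#' @param n Number of samples (757 and 523 are the study sizes).
#' @param seed Integer seed.
#' @param set `"discovery"` or `"model"`.
#' @return An `ec_sim_config`.
#' @export
paper_like_config <- function(n = 757, seed = 1L, set = c("discovery", "model")) {
  set <- match.arg(set)
  if (set == "discovery") {
    panel <- panel_discovery44("discovery")
    effects <- effect_model(
      intercept = -1.5,
      main_effects = c(
        "rs12913832" = 6.0,
        "rs121918166+rs74653330" = 4.0,
        "rs16891982" = -0.6,
        "rs1800407" = -0.5,
        "rs1408799" = 0.3,
        "rs4904927" = -0.3,
        "rs12896399" = 0.3,
        "rs1126809" = -0.3,
        "rs7120151" = 0.3,
        "rs10131374" = -0.3,
        "rs1800401" = -0.4
      ),
      interaction_effects = c("rs121918166+rs74653330" = -4.0),
      noise_sd = 2.0
    )
  } else {
    panel <- panel_model13()
    effects <- effect_model(
      intercept = -1.5,
      main_effects = c(
        "rs12913832" = 6.0,
        "rs121918166" = 4.0,
        "rs74653330" = 4.0,
        "rs16891982" = -0.6,
        "rs1800407" = -0.5,
        "rs1408799" = 0.3,
        "rs4904927" = -0.3,
        "rs12896399" = 0.3,
        "rs1126809" = -0.3,
        "rs10131374" = -0.3,
        "rs1800401" = -0.4
      ),
      interaction_effects = c("rs121918166" = -4.0, "rs74653330" = -4.0),
      noise_sd = 2.0
    )
  }
  sim_config(n_samples = n, panel = panel, effects = effects, seed = seed)
}

#' @rdname paper_like_config
#' @export
panel_model13 <- function() {
  ec <- panel_ec11("model")
  extra <- c("rs12203592", "rs1393350")
  variables <- dplyr::bind_rows(
    ec$variables,
    tibble(variable = extra, kind = "additive", rsids = as.list(extra))
  )
  new_panel(
    "model13", variables,
    panel_variants(unlist(variables$rsids), "model")
  )
}

default_effects <- function(panel) {
  i <- match("rs12913832", panel$variables$variable)
  if (is.na(i)) {
    return(effect_model(intercept = 0, noise_sd = 2.0))
  }
  if (panel$variables$kind[i] == "additive") {
    # minor allele is A at the published frequencies, so GG codes 0:
    # intercept 4.5 (blue) minus 3 per A allele reaches -1.5 for AA
    effect_model(intercept = 4.5, main_effects = c("rs12913832" = -3.0), noise_sd = 2.0)
  } else {
    effect_model(intercept = -1.5, main_effects = c("rs12913832" = 6.0), noise_sd = 2.0)
  }
}
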