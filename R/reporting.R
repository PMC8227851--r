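#' Reporting call policy
#'
#' `"pmax"` reports the most probable category with no threshold; a numeric
#' threshold `t` in (0, 1) reports the most probable category only when its
#' probability reaches `t`, otherwise the prediction is inconclusive.  Exact
#' ties at the maximum are always inconclusive.
#'
#' @param threshold `"pmax"` or a number in (0, 1); 0.5 and 0.7 are the
#'   conventional forensic thresholds.
#' @return An `ec_call_policy`.
#' @export
call_policy <- function(threshold = "pmax") {
  if (!(identical(threshold, "pmax") ||
    (is.numeric(threshold) && threshold > 0 && threshold < 1))) {
    abort("threshold must be \"pmax\" or a number in (0, 1)")
  }
  structure(list(threshold = threshold, tie_rule = "inconclusive"),
    class = "ec_call_policy"
  )
}

#' Call a category from predicted probabilities
#'
#' @param p A probability vector (named by category) or a matrix/data frame
#'   with one row per prediction and one named column per category; each row
#'   must sum to 1.
#' @param policy An [call_policy()] (or `"pmax"` / a number).
#' @return Factor of calls with levels `c(categories, "inconclusive")`.
#' @examples
#' call_category(c(blue = 0.6, intermediate = 0.3, brown = 0.1), 0.7)
#' @export
call_category <- function(p, policy = call_policy("pmax")) {
  if (!inherits(policy, "ec_call_policy")) policy <- call_policy(policy)
  P <- if (is.null(dim(p))) matrix(p, nrow = 1, dimnames = list(NULL, names(p))) else as.matrix(p)
  if (is.null(colnames(P))) abort("probabilities must be named by category")
  if (any(abs(rowSums(P) - 1) > 1e-6) || any(P < -1e-9)) {
    abort("each probability vector must be non-negative and sum to 1")
  }
  cats <- colnames(P)
  pmax_val <- apply(P, 1, max)
  n_at_max <- rowSums(abs(P - pmax_val) < .Machine$double.eps * 4)
  winner <- cats[max.col(P, ties.method = "first")]
  inconclusive <- n_at_max > 1
  if (is.numeric(policy$threshold)) {
    inconclusive <- inconclusive | pmax_val < policy$threshold
  }
  out <- ifelse(inconclusive, "inconclusive", winner)
  factor(out, levels = c(cats, "inconclusive"))
}

#' Threshold-based outcome report for a LOOCV result
#'
#' Applies a call policy to the per-sample predicted probabilities and
#' tabulates outcomes: percent correct / incorrect / inconclusive over all
#' samples (summing to 100), a confusion table with an inconclusive column,
#' and one-vs-rest sensitivity and specificity per category computed over
#' the conclusive calls (`NA` when a category has no conclusive calls to
#' judge).
#'
#' @param loocv An `ec_loocv` from a categorical system.
#' @param policy An [call_policy()] (or `"pmax"` / a number).
#' @return An `ec_report`: list with `outcome` (tibble: correct/incorrect/
#'   inconclusive counts and percentages), `per_class` (tibble: category,
#'   sensitivity, specificity), `confusion` (truth x call counts), `policy`.
#' @export
report <- function(loocv, policy = call_policy("pmax")) {
  stopifnot(inherits(loocv, "ec_loocv"))
  if (loocv$system == "quantitative") {
    abort("outcome reports apply to categorical systems")
  }
  if (!inherits(policy, "ec_call_policy")) policy <- call_policy(policy)
  pred <- loocv$predictions
  if (nrow(pred) == 0) abort("empty LOOCV result")
  cats <- levels(pred$truth)
  P <- as.matrix(pred[paste0("p_", cats)])
  colnames(P) <- cats
  calls <- call_category(P, policy)
  truth <- pred$truth

  n <- length(truth)
  n_inc <- sum(calls == "inconclusive")
  n_cor <- sum(calls != "inconclusive" & as.character(calls) == as.character(truth))
  n_wrong <- n - n_inc - n_cor
  outcome <- tibble(
    outcome = c("correct", "incorrect", "inconclusive"),
    count = c(n_cor, n_wrong, n_inc),
    percent = 100 * c(n_cor, n_wrong, n_inc) / n
  )
  confusion <- as.data.frame.matrix(table(truth = truth, call = calls))

  conclusive <- calls != "inconclusive"
  per_class <- purrr::map_dfr(cats, function(k) {
    is_k_truth <- truth == k & conclusive
    is_k_call <- as.character(calls) == k & conclusive
    tp <- sum(is_k_truth & is_k_call)
    fn <- sum(is_k_truth & !is_k_call)
    fp <- sum(!is_k_truth & conclusive & is_k_call)
    tn <- sum(!is_k_truth & conclusive & !is_k_call)
    tibble(
      category = k,
      sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
      specificity = if (tn + fp > 0) tn / (tn + fp) else NA_real_
    )
  })
  structure(
    list(
      outcome = outcome, per_class = per_class, confusion = confusion,
      policy = policy, system = loocv$system, panel_name = loocv$panel_name,
      n = n
    ),
    class = "ec_report"
  )
}

#' @export
print.ec_report <- function(x, ...) {
  thr <- if (identical(x$policy$threshold, "pmax")) "pmax" else paste0("p >= ", x$policy$threshold)
  cat("<ec_report> ", x$system, ", panel ", x$panel_name, ", policy ", thr,
    ", n = ", x$n, "\n",
    sep = ""
  )
  print(x$outcome)
  print(x$per_class)
  invisible(x)
}

#' Enumerate the coded genotype space of a panel
#'
#' All combinations of coded values over the panel variables (3 levels for
#' additive/combined, 2 for dominant/carrier).  The EC11 coding (1 dominant,
#' 2 carrier, 8 additive) gives `2^3 * 3^8 = 52,488` combinations; six
#' additive IrisPlex SNPs give `3^6 = 729`.  When a fitted categorical model
#' is supplied, each combination's predicted probabilities and most-probable
#' category are added, along with per-category counts, fractions, and the
#' maximum probability any combination attains for each category.
#'
#' @param panel An `ec_panel`.
#' @param model Optional categorical `ec_fit` on the same panel.
#' @param cap Refuse to enumerate more than this many combinations.
#' @return An `ec_genotype_space`: list with `combinations` (tibble),
#'   `n_combinations`, and (with a model) `category_summary`.
#' @examples
#' enumerate_genotype_space(panel_irisplex6())$n_combinations  # 729
#' @export
enumerate_genotype_space <- function(panel, model = NULL, cap = 1e7) {
  levels <- variable_levels(panel)
  n_comb <- prod(levels)
  if (n_comb > cap) {
    abort(paste0("genotype space has ", n_comb, " combinations (cap ", cap, ")"))
  }
  grid <- expand.grid(
    lapply(levels, function(k) seq.int(0L, k - 1L)),
    KEEP.OUT.ATTRS = FALSE
  )
  names(grid) <- names(levels)
  grid <- as_tibble(grid)
  out <- list(
    panel_name = panel$name, n_combinations = as.integer(n_comb),
    combinations = grid
  )
  if (!is.null(model)) {
    stopifnot(inherits(model, "ec_fit"))
    if (model$system == "quantitative") {
      abort("genotype-space prediction needs a categorical model")
    }
    pr <- predict(model, grid)
    cats <- model$categories
    P <- as.matrix(pr[paste0("p_", cats)])
    colnames(P) <- cats
    grid <- dplyr::bind_cols(grid, as_tibble(pr[paste0("p_", cats)]))
    grid$call_pmax <- call_category(P, call_policy("pmax"))
    summary <- tibble(
      category = cats,
      n_pmax = vapply(cats, function(k) sum(grid$call_pmax == k), numeric(1)),
      fraction_pmax = vapply(cats, function(k) mean(grid$call_pmax == k), numeric(1)),
      max_probability = vapply(cats, function(k) max(P[, k]), numeric(1))
    )
    out$combinations <- grid
    out$category_summary <- summary
  }
  structure(out, class = "ec_genotype_space")
}

#' @export
print.ec_genotype_space <- function(x, ...) {
  cat("<ec_genotype_space> panel ", x$panel_name, ": ", x$n_combinations,
    " coded genotype combinations\n",
    sep = ""
  )
  if (!is.null(x$category_summary)) print(x$category_summary)
  invisible(x)
}

#' Two-category likelihood ratios for genotypes
#'
#' The weight of evidence for brown versus blue eye colour given a genotype:
#' `LR = P(genotype | brown) / P(genotype | blue)` with the conditional
#' probabilities estimated as relative genotype frequencies among brown-eyed
#' (H1) and blue-eyed (H2) individuals in the cohort.  With
#' `smoothing = TRUE`, 0.5 is added to each genotype count (and the matching
#' total adjustment to each denominator); without smoothing a genotype
#' unobserved among blue-eyed individuals is an error.
#'
#' @param x An `ec_cohort` with phenotypes.
#' @param rsid Variant whose genotypes are evaluated.
#' @param genotype Optional specific call (e.g. `"GG"`); default all calls
#'   observed at the variant.
#' @param smoothing Add-0.5 smoothing flag.
#' @return Tibble: `genotype`, `lr`, `n_brown`, `n_blue`, `freq_brown`,
#'   `freq_blue`.
#' @examples
#' cht <- simulate_cohort(paper_like_config(n = 400, seed = 11, set = "model"))
#' likelihood_ratio(cht, "rs12913832")
#' @export
likelihood_ratio <- function(x, rsid, genotype = NULL, smoothing = FALSE) {
  stopifnot(inherits(x, "ec_cohort"))
  if (is.null(x$phenotypes)) abort("likelihood ratios need phenotypes")
  if (!rsid %in% names(x$genotypes)) abort(paste0("no calls for ", rsid))
  lab <- categorise_pie(x$phenotypes$pie_score, "two_category")
  calls <- x$genotypes[[rsid]]
  ok <- !is.na(calls)
  calls <- calls[ok]
  lab <- lab[ok]
  if (!any(lab == "brown") || !any(lab == "blue")) {
    abort("both eye-colour categories must be represented")
  }
  gts <- if (is.null(genotype)) sort(unique(calls)) else genotype
  n_brown <- sum(lab == "brown")
  n_blue <- sum(lab == "blue")
  n_gt <- length(unique(calls))
  purrr::map_dfr(gts, function(g) {
    cb <- sum(calls == g & lab == "brown")
    cl <- sum(calls == g & lab == "blue")
    if (smoothing) {
      fb <- (cb + 0.5) / (n_brown + 0.5 * n_gt)
      fl <- (cl + 0.5) / (n_blue + 0.5 * n_gt)
    } else {
      if (cl == 0) {
        abort(paste0(
          "genotype ", g, " unobserved among blue-eyed individuals; ",
          "use smoothing = TRUE"
        ))
      }
      fb <- cb / n_brown
      fl <- cl / n_blue
    }
    tibble(
      genotype = g, lr = fb / fl, n_brown = cb, n_blue = cl,
      freq_brown = fb, freq_blue = fl
    )
  })
}
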