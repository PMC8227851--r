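#' Repeated 2/3 - 1/3 resampling splits
#'
#' Draws `n_reps` random partitions of the cohort into a training set of
#' `round(2n/3)` samples and a test set of the remainder.  A draw whose
#' training set leaves any coded panel variable fixed (a single observed
#' value) is discarded and redrawn; the number of redraws is recorded.
#' Samples are sorted by id before drawing, so the splits depend only on the
#' seed, not on input row order.
#'
#' @param x An `ec_cohort`.
#' @param panel An `ec_panel` (its coded variables define "fixed").
#' @param n_reps Number of splits.
#' @param seed Integer master seed; each replicate uses a derived substream.
#' @param max_redraws Redraw cap per replicate before failing.
#' @return List of splits, each `list(train_ids, test_ids, redraw_count)`.
#' @export
make_splits <- function(x, panel, n_reps = 100, seed = 1L, max_redraws = 10000) {
  stopifnot(inherits(x, "ec_cohort"))
  coded <- encode_cohort(x, panel)
  coded <- coded[order(coded$sample_id), ]
  n <- nrow(coded)
  if (n < 6) abort("need at least 6 complete samples to split")
  vars <- setdiff(names(coded), "sample_id")
  globally_fixed <- vars[vapply(coded[vars], function(v) length(unique(v)) == 1L, logical(1))]
  if (length(globally_fixed) > 0) {
    abort(paste0(
      "coded variable(s) fixed in the whole cohort: ",
      paste(globally_fixed, collapse = ", ")
    ))
  }
  n_train <- round(2 * n / 3)
  mat <- as.matrix(coded[vars])
  purrr::map(seq_len(n_reps), function(rep) {
    with_local_seed(derive_seed(seed, rep), {
      redraws <- 0L
      repeat {
        idx <- sample.int(n, n_train)
        fixed <- vars[apply(mat[idx, , drop = FALSE], 2, function(v) {
          all(v == v[1])
        })]
        if (length(fixed) == 0) break
        redraws <- redraws + 1L
        if (redraws > max_redraws) {
          abort(paste0(
            "redraw cap exceeded; near-fixed variable(s): ",
            paste(fixed, collapse = ", ")
          ))
        }
      }
      list(
        train_ids = coded$sample_id[sort(idx)],
        test_ids = coded$sample_id[sort(setdiff(seq_len(n), idx))],
        redraw_count = redraws
      )
    })
  })
}

# design matrix for LASSO fits: main-effect columns, optionally plus
# rs12913832-by-everything pairwise interaction columns (main effects always
# retained: hierarchy holds by construction)
lasso_design <- function(coded, interactions = FALSE,
                         rs12913832_variable = "rs12913832") {
  vars <- setdiff(names(coded), "sample_id")
  X <- as.matrix(coded[vars])
  terms <- lapply(vars, function(v) v) # constituent variables per column
  names(terms) <- vars
  if (interactions) {
    if (!rs12913832_variable %in% vars) {
      abort(paste0(rs12913832_variable, " not present; cannot build interactions"))
    }
    gdom <- X[, rs12913832_variable]
    for (v in setdiff(vars, rs12913832_variable)) {
      cn <- paste0(rs12913832_variable, ":", v)
      X <- cbind(X, gdom * X[, v])
      colnames(X)[ncol(X)] <- cn
      terms[[cn]] <- c(rs12913832_variable, v)
    }
  }
  list(X = X, terms = terms)
}

#' L1-penalised regression with the one-standard-error rule
#'
#' Fits a LASSO path (glmnet: 100 log-spaced penalties, lambda.min.ratio
#' 1e-4, predictors standardised to unit SD) and selects the most regularised
#' model whose 10-fold cross-validated error is within one standard error of
#' the minimum.  With `interactions = TRUE` the design adds products of every
#' variable with the rs12913832 variable, keeping all main effects.
#'
#' @param coded Coded matrix (tibble from [encode_cohort()], or any data
#'   frame of numeric predictors plus `sample_id`).
#' @param response Numeric (gaussian) or two-level factor/0-1 (binomial).
#' @param family `"gaussian"` or `"binomial"`.
#' @param interactions Add rs12913832 pairwise interactions?
#' @param seed Seed controlling the CV fold assignment.
#' @param lambda Optional fixed penalty value(s) overriding CV selection
#'   (`lambda = 0` gives the unpenalised fit).
#' @param rs12913832_variable Interaction anchor variable.
#' @return An `ec_lasso` list: `coefficients` (original scale, incl.
#'   intercept), `std_coefficients` (slope x predictor SD), `lambda`,
#'   `family`, `terms`.
#' @export
fit_lasso <- function(coded, response, family = c("gaussian", "binomial"),
                      interactions = FALSE, seed = 1L, lambda = NULL,
                      rs12913832_variable = "rs12913832") {
  family <- match.arg(family)
  des <- lasso_design(coded, interactions, rs12913832_variable)
  X <- des$X
  if (nrow(X) < 10) abort("need at least 10 training samples")
  if (is.factor(response) || is.character(response)) {
    response <- as.integer(factor(response)) - 1L
  }
  if (family == "binomial" && length(unique(response)) < 2) {
    abort("binomial response has a single class in the training set")
  }
  sds <- apply(X, 2, sd)
  fixed_main <- colnames(X)[sds == 0 &
    lengths(des$terms[colnames(X)]) == 1]
  if (length(fixed_main) > 0) {
    # fixed main-effect columns make the fit ill-defined; fixed interaction
    # columns are harmless (coefficient and standardised importance are 0)
    abort(paste0(
      "fixed design column(s): ", paste(fixed_main, collapse = ", ")
    ))
  }
  if (!is.null(lambda)) {
    fit <- glmnet::glmnet(X, response,
      family = family, lambda = lambda,
      standardize = TRUE, thresh = 1e-12, maxit = 1e6
    )
    chosen <- min(lambda)
    co <- as.numeric(coef(fit, s = chosen))
  } else {
    foldid <- with_local_seed(
      derive_seed(seed, 7919L),
      sample(rep_len(1:10, nrow(X)))
    )
    cv <- glmnet::cv.glmnet(X, response,
      family = family, foldid = foldid,
      nlambda = 100, lambda.min.ratio = 1e-4, standardize = TRUE,
      thresh = 1e-6
    )
    chosen <- cv$lambda.1se
    co <- as.numeric(coef(cv, s = "lambda.1se"))
  }
  names(co) <- c("(Intercept)", colnames(X))
  std <- co[-1] * sds
  structure(
    list(
      coefficients = co, std_coefficients = std, lambda = chosen,
      family = family, terms = des$terms
    ),
    class = "ec_lasso"
  )
}

#' CART tree fit with primary-split variable importance
#'
#' Fits an rpart tree (cp 0.01, minsplit 20, maxdepth 30) with variance
#' splits for continuous responses and Gini splits for categorical ones.
#' Competitor and surrogate splits are disabled, so a variable's importance
#' is exactly the impurity decrease summed over its primary splits.  A
#' constant response yields a root-only tree with all-zero importances.
#'
#' @param coded Coded matrix (tibble with `sample_id`).
#' @param response Numeric, or factor for classification.
#' @param response_kind `"continuous"`, `"binary"` or `"three_class"`.
#' @return An `ec_tree` list: `fit` (rpart object), `importance` (named
#'   vector over all coded variables, zeros included).
#' @export
fit_tree <- function(coded, response,
                     response_kind = c("continuous", "binary", "three_class")) {
  response_kind <- match.arg(response_kind)
  vars <- setdiff(names(coded), "sample_id")
  df <- as.data.frame(coded[vars])
  df$.response <- if (response_kind == "continuous") {
    as.numeric(response)
  } else {
    factor(response)
  }
  method <- if (response_kind == "continuous") "anova" else "class"
  fit <- rpart::rpart(
    .response ~ ., df,
    method = method,
    control = rpart::rpart.control(
      cp = 0.01, minsplit = 20, maxdepth = 30,
      maxcompete = 0, maxsurrogate = 0, xval = 0
    )
  )
  imp <- setNames(numeric(length(vars)), vars)
  # with surrogates and competitors disabled, rpart's variable.importance is
  # exactly the impurity decrease summed over each variable's primary splits
  vi <- fit$variable.importance
  if (!is.null(vi)) imp[names(vi)] <- vi
  structure(list(fit = fit, importance = imp), class = "ec_tree")
}

#' Raw variable importance from a fitted model
#'
#' LASSO fits: the absolute standardised coefficient; each interaction term's
#' absolute coefficient is attributed to both partner variables (set
#' `attribute_to_partner_only = TRUE` to credit only the non-rs12913832
#' partner).  Tree fits: primary-split impurity decrease.
#'
#' @param fit An `ec_lasso` or `ec_tree`.
#' @param variables Variable names over which to report (zeros filled in).
#' @param attribute_to_partner_only Interaction attribution switch.
#' @param rs12913832_variable Interaction anchor variable.
#' @return Named numeric vector of non-negative raw importances.
#' @export
variable_importance <- function(fit, variables = NULL,
                                attribute_to_partner_only = FALSE,
                                rs12913832_variable = "rs12913832") {
  if (inherits(fit, "ec_tree")) {
    imp <- fit$importance
  } else if (inherits(fit, "ec_lasso")) {
    imp <- numeric(0)
    for (term in names(fit$std_coefficients)) {
      members <- fit$terms[[term]]
      if (attribute_to_partner_only && length(members) > 1) {
        members <- setdiff(members, rs12913832_variable)
      }
      for (v in members) {
        imp[v] <- (if (v %in% names(imp)) imp[[v]] else 0) +
          abs(fit$std_coefficients[[term]])
      }
    }
  } else {
    abort("unsupported fit type")
  }
  if (!is.null(variables)) {
    full <- setNames(numeric(length(variables)), variables)
    common <- intersect(names(imp), variables)
    full[common] <- imp[common]
    imp <- full
  }
  imp
}

#' The seven ranking model specifications
#'
#' Quantitative (transformed PIE) and two-category responses are each
#' analysed with a main-effects LASSO, a LASSO with rs12913832 pairwise
#' interactions, and a CART tree; the three-category response with a
#' classification tree only.
#'
#' @return Tibble with columns `model`, `system`, `family`.
#' @export
ranking_model_specs <- function() {
  tibble(
    model = c(
      "quant_lasso_main", "quant_lasso_int", "quant_tree",
      "twocat_lasso_main", "twocat_lasso_int", "twocat_tree",
      "threecat_tree"
    ),
    system = c(rep("quantitative", 3), rep("two_category", 3), "three_category"),
    family = c(
      "lasso_main", "lasso_interactions", "tree",
      "lasso_main", "lasso_interactions", "tree", "tree"
    )
  )
}

#' Resampled multi-model variable-importance ranking
#'
#' The variable-selection procedure: the cohort is repeatedly split 2/3-1/3;
#' on each training set the seven models of [ranking_model_specs()] are
#' fitted; each model's raw variable importances are standardised to sum to
#' one; importances are averaged over all (replicate x model) cells; and
#' variables are ranked by descending mean importance.  Test-set prediction
#' errors are recorded per replicate and model but play no role in ranking.
#'
#' A replicate in which any model fails (e.g. a single-class two-category
#' training set) is dropped with a recorded reason; the run errors if more
#' than 10% of replicates are dropped.
#'
#' @param x An `ec_cohort` with phenotypes.
#' @param panel Ranking `ec_panel` (default the 44-variant discovery panel).
#' @param n_reps Number of resampling replicates.
#' @param seed Integer master seed.
#' @param attribute_to_partner_only Passed to [variable_importance()].
#' @return An `ec_importance` tibble (`rank`, `gene`, `variable`,
#'   `mean_importance`) with attributes `per_model` (cell-level importances),
#'   `per_model_mean`, `test_errors`, `n_reps`, `dropped`.
#' @export
rank_variants <- function(x, panel = panel_discovery44(), n_reps = 100,
                          seed = 1L, attribute_to_partner_only = FALSE) {
  stopifnot(inherits(x, "ec_cohort"))
  if (is.null(x$phenotypes)) abort("ranking needs PIE phenotypes")
  coded <- encode_cohort(x, panel)
  coded <- coded[order(coded$sample_id), ]
  vars <- setdiff(names(coded), "sample_id")
  ph <- x$phenotypes[match(coded$sample_id, x$phenotypes$sample_id), ]
  resp <- list(
    quantitative = transform_pie(ph$pie_score),
    two_category = as.integer(categorise_pie(ph$pie_score, "two_category") == "blue"),
    three_category = categorise_pie(ph$pie_score, "three_category")
  )
  splits <- make_splits(x, panel, n_reps = n_reps, seed = seed)
  specs <- ranking_model_specs()

  cells <- list()
  errors <- list()
  dropped <- list()
  for (rep in seq_len(n_reps)) {
    sp <- splits[[rep]]
    tr <- match(sp$train_ids, coded$sample_id)
    te <- match(sp$test_ids, coded$sample_id)
    rep_cells <- list()
    rep_errors <- list()
    ok <- TRUE
    for (j in seq_len(nrow(specs))) {
      spec <- specs[j, ]
      y_tr <- if (spec$system == "three_category") {
        resp[[spec$system]][tr]
      } else {
        resp[[spec$system]][tr]
      }
      res <- tryCatch(
        fit_ranking_model(
          coded[tr, ], y_tr, spec,
          seed = derive_seed(seed, rep * 101L + j)
        ),
        error = function(e) e
      )
      if (inherits(res, "error")) {
        dropped[[length(dropped) + 1]] <- tibble(
          replicate = rep, model = spec$model, reason = conditionMessage(res)
        )
        ok <- FALSE
        break
      }
      raw <- variable_importance(res, vars,
        attribute_to_partner_only = attribute_to_partner_only
      )
      total <- sum(raw)
      std <- if (total > 0) raw / total else raw
      rep_cells[[spec$model]] <- tibble(
        replicate = rep, model = spec$model, variable = vars,
        importance = unname(std)
      )
      rep_errors[[spec$model]] <- tibble(
        replicate = rep, model = spec$model,
        test_error = ranking_test_error(res, spec, coded[te, ], resp, te)
      )
    }
    if (ok) {
      cells <- c(cells, rep_cells)
      errors <- c(errors, rep_errors)
    }
  }
  dropped <- dplyr::bind_rows(dropped)
  n_ok <- length(cells) / nrow(specs)
  if (n_ok < 0.9 * n_reps) {
    abort(paste0(
      "more than 10% of replicates failed (", n_reps - n_ok, " of ", n_reps, ")"
    ))
  }
  per_model <- dplyr::bind_rows(cells)
  means <- per_model |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(mean_importance = mean(.data$importance), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$mean_importance))
  gene_of <- variable_genes(panel)
  out <- tibble(
    rank = seq_len(nrow(means)),
    gene = unname(gene_of[means$variable]),
    variable = means$variable,
    mean_importance = means$mean_importance
  )
  per_model_mean <- per_model |>
    dplyr::group_by(.data$model, .data$variable) |>
    dplyr::summarise(mean_importance = mean(.data$importance), .groups = "drop")
  structure(out,
    per_model = per_model, per_model_mean = per_model_mean,
    test_errors = dplyr::bind_rows(errors), n_reps = n_ok, dropped = dropped,
    class = c("ec_importance", class(out))
  )
}

fit_ranking_model <- function(coded_tr, y_tr, spec, seed) {
  if (spec$family == "tree") {
    kind <- switch(spec$system,
      quantitative = "continuous",
      two_category = "binary",
      three_category = "three_class"
    )
    fit_tree(coded_tr, y_tr, kind)
  } else {
    fit_lasso(
      coded_tr, y_tr,
      family = if (spec$system == "quantitative") "gaussian" else "binomial",
      interactions = spec$family == "lasso_interactions", seed = seed
    )
  }
}

# out-of-sample error of one ranking model on its test third: MSE for the
# quantitative system, mean negative log-likelihood for categorical ones
ranking_test_error <- function(fit, spec, coded_te, resp, te) {
  y_te <- resp[[spec$system]][te]
  if (inherits(fit, "ec_lasso")) {
    interactions <- spec$family == "lasso_interactions"
    X <- lasso_design(coded_te, interactions)$X
    eta <- drop(cbind(1, X[, names(fit$coefficients)[-1], drop = FALSE]) %*%
      fit$coefficients)
    if (spec$system == "quantitative") {
      mean((eta - y_te)^2)
    } else {
      p <- clip_prob(plogis(eta))
      -mean(ifelse(y_te == 1, log(p), log(1 - p)))
    }
  } else {
    df <- as.data.frame(coded_te[setdiff(names(coded_te), "sample_id")])
    if (spec$system == "quantitative") {
      mean((predict(fit$fit, df) - y_te)^2)
    } else {
      pr <- predict(fit$fit, df, type = "prob")
      truth <- as.character(y_te)
      idx <- cbind(seq_len(nrow(pr)), match(truth, colnames(pr)))
      -mean(log(clip_prob(pr[idx])))
    }
  }
}

variable_genes <- function(panel) {
  g <- vapply(seq_len(nrow(panel$variables)), function(i) {
    rsids <- panel$variables$rsids[[i]]
    genes <- unique(panel$variants$gene[panel$variants$rsid %in% rsids])
    paste(genes, collapse = "+")
  }, character(1))
  setNames(g, panel$variables$variable)
}

#' Select top-ranked variables by mean-importance cutoff
#'
#' @param table An `ec_importance` table (or any tibble with `variable` and
#'   `mean_importance`).
#' @param cutoff Minimum mean importance (default 0.003, i.e. 0.3%).
#' @return Character vector of selected variables in rank order.
#' @examples
#' # the published importance profile selects 11 variables at 0.3%
#' @export
select_top <- function(table, cutoff = 0.003) {
  tab <- dplyr::arrange(as_tibble(table), dplyr::desc(.data$mean_importance))
  tab$variable[tab$mean_importance >= cutoff]
}
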