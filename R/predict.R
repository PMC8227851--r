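clip_prob <- function(p, eps = 1e-12) {
  pmin(pmax(p, eps), 1 - eps)
}

#' Fit an eye-colour prediction model under one reporting system
#'
#' Builds the panel's main-effects design and fits:
#'
#' * `quantitative` — least squares on the transformed PIE-score
#'   `y = logit(0.5 + 0.499 r)`;
#' * `two_category` — binomial logistic regression (blue = 1, brown = 0);
#' * `three_category` — multinomial logistic regression over
#'   blue/intermediate/brown.
#'
#' The logistic fits use Newton/IRLS with a tiny L2 ridge (default 1e-6) on
#' the slope coefficients so the estimates stay finite under perfect
#' separation, which small panels readily produce; set `ridge = 0` for the
#' unpenalised maximum-likelihood fit.
#'
#' @param x An `ec_cohort` with phenotypes, or a coded matrix when `response`
#'   is supplied directly.
#' @param panel An `ec_panel`.
#' @param system `"quantitative"`, `"two_category"` or `"three_category"`.
#' @param ridge L2 penalty on slopes of the logistic fits.
#' @return An `ec_fit` with `coefficients` (matrix for multinomial),
#'   `system`, `variables`, `categories`.
#' @export
fit_system_model <- function(x, panel,
                             system = c("quantitative", "two_category", "three_category"),
                             ridge = 1e-6) {
  system <- match.arg(system)
  stopifnot(inherits(x, "ec_cohort"))
  coded <- encode_cohort(x, panel)
  ph <- x$phenotypes[match(coded$sample_id, x$phenotypes$sample_id), ]
  fit_system_model_coded(coded, ph$pie_score, panel, system, ridge)
}

fit_system_model_coded <- function(coded, pie, panel, system, ridge = 1e-6) {
  vars <- panel$variables$variable
  X <- cbind(`(Intercept)` = 1, as.matrix(coded[vars]))
  fit <- switch(system,
    quantitative = {
      y <- transform_pie(pie)
      co <- lm.fit(X, y)$coefficients
      co[is.na(co)] <- 0 # rank-deficient designs: drop aliased columns
      list(coefficients = co, categories = NULL)
    },
    two_category = {
      lab <- categorise_pie(pie, "two_category")
      if (length(unique(lab)) < 2) abort("single-category training data")
      y <- as.integer(lab == "blue")
      list(
        coefficients = logistic_ridge(X, y, ridge),
        categories = c("blue", "brown")
      )
    },
    three_category = {
      lab <- categorise_pie(pie, "three_category")
      present <- levels(lab)[table(lab) > 0]
      if (length(present) < 2) abort("single-category training data")
      B <- multinom_ridge(X, lab, ridge)
      list(coefficients = B, categories = levels(lab))
    }
  )
  structure(
    c(fit, list(
      system = system, variables = vars, panel_name = panel$name,
      ridge = ridge
    )),
    class = "ec_fit"
  )
}

# binomial logistic regression by Newton's method with an L2 penalty on the
# slopes (never the intercept); converges on gradient max-norm <= 1e-8
logistic_ridge <- function(X, y, ridge, tol = 1e-8, max_iter = 200) {
  p <- ncol(X)
  pen <- diag(c(0, rep(ridge, p - 1)), p)
  beta <- numeric(p)
  for (iter in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- plogis(eta)
    grad <- drop(crossprod(X, y - mu)) - drop(pen %*% beta)
    if (max(abs(grad)) <= tol) break
    W <- mu * (1 - mu)
    H <- crossprod(X, X * W) + pen
    step <- solve(H, grad)
    # halve the step while the penalised log-likelihood worsens
    ll <- function(b) {
      e <- drop(X %*% b)
      sum(y * e - log1p(exp(e))) - 0.5 * sum(diag(pen) * b^2)
    }
    ll0 <- ll(beta)
    fac <- 1
    while (ll(beta + fac * step) < ll0 && fac > 1e-8) fac <- fac / 2
    beta <- beta + fac * step
  }
  if (iter == max_iter && max(abs(grad)) > tol * 100) {
    warn("logistic fit did not fully converge")
  }
  setNames(beta, colnames(X))
}

# multinomial logistic regression by full Newton with an L2 penalty on
# slopes.  The baseline is the last category present in the training data
# (its coefficient column is 0); categories absent from the training data
# are pinned at a large negative intercept so their probability stays ~0.
# Returns the full p x K coefficient matrix.
multinom_ridge <- function(X, lab, ridge, tol = 1e-8, max_iter = 200) {
  cats <- levels(lab)
  K <- length(cats)
  p <- ncol(X)
  Y <- matrix(0, nrow(X), K)
  Y[cbind(seq_along(lab), as.integer(lab))] <- 1
  present <- colSums(Y) > 0
  bk <- max(which(present)) # baseline
  par_cats <- setdiff(seq_len(K), bk)
  nb <- length(par_cats) * p
  pen_diag <- rep(c(0, rep(ridge, p - 1)), length(par_cats))
  beta <- numeric(nb)
  fixed <- rep(FALSE, nb)
  for (j in seq_along(par_cats)) {
    if (!present[par_cats[j]]) {
      beta[(j - 1) * p + 1] <- -30
      fixed[(j - 1) * p + seq_len(p)] <- TRUE
    }
  }
  eta_of <- function(b) {
    E <- matrix(0, nrow(X), K)
    for (j in seq_along(par_cats)) {
      E[, par_cats[j]] <- X %*% b[(j - 1) * p + seq_len(p)]
    }
    E
  }
  pll <- function(b) {
    E <- eta_of(b)
    M <- apply(E, 1, max)
    sum(rowSums(Y * E) - M - log(rowSums(exp(E - M)))) -
      0.5 * sum(pen_diag * b^2)
  }
  free <- which(!fixed)
  grad <- numeric(nb)
  for (iter in seq_len(max_iter)) {
    E <- eta_of(beta)
    M <- apply(E, 1, max)
    ex <- exp(E - M)
    P <- ex / rowSums(ex)
    for (j in seq_along(par_cats)) {
      grad[(j - 1) * p + seq_len(p)] <- crossprod(X, Y[, par_cats[j]] - P[, par_cats[j]])
    }
    grad <- grad - pen_diag * beta
    if (max(abs(grad[free])) <= tol) break
    H <- matrix(0, nb, nb)
    for (j in seq_along(par_cats)) {
      for (m in seq_along(par_cats)) {
        pj <- P[, par_cats[j]]
        pm <- P[, par_cats[m]]
        W <- if (j == m) pj * (1 - pj) else -pj * pm
        H[(j - 1) * p + seq_len(p), (m - 1) * p + seq_len(p)] <-
          crossprod(X, X * W)
      }
    }
    H <- H + diag(pen_diag, nb) + diag(1e-10, nb)
    step <- numeric(nb)
    step[free] <- solve(H[free, free, drop = FALSE], grad[free])
    ll0 <- pll(beta)
    fac <- 1
    while (pll(beta + fac * step) < ll0 && fac > 1e-8) fac <- fac / 2
    beta <- beta + fac * step
  }
  if (iter == max_iter && max(abs(grad[free])) > tol * 100) {
    warn("multinomial fit did not fully converge")
  }
  B <- matrix(0, nrow = p, ncol = K, dimnames = list(colnames(X), cats))
  for (j in seq_along(par_cats)) {
    B[, par_cats[j]] <- beta[(j - 1) * p + seq_len(p)]
  }
  B
}

#' Predict from a fitted system model
#'
#' @param object An `ec_fit`.
#' @param newdata An `ec_cohort` or a coded matrix with the fit's variables.
#' @param panel Panel used to encode `newdata` when it is a cohort.
#' @param ... Unused.
#' @return A tibble: quantitative fits give `y_pred` (transformed scale) and
#'   `pie_pred`; categorical fits give one probability column per category
#'   (`p_blue`, ..., summing to 1) plus the `pmax` category call.
#' @export
predict.ec_fit <- function(object, newdata, panel = NULL, ...) {
  coded <- if (inherits(newdata, "ec_cohort")) {
    if (is.null(panel)) abort("supply the panel to encode a cohort")
    encode_cohort(newdata, panel)
  } else {
    newdata
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(coded[object$variables]))
  ids <- if ("sample_id" %in% names(coded)) coded$sample_id else as.character(seq_len(nrow(X)))
  if (object$system == "quantitative") {
    y <- drop(X %*% object$coefficients)
    return(tibble(
      sample_id = ids,
      y_pred = y, pie_pred = inverse_transform(y)
    ))
  }
  P <- if (object$system == "two_category") {
    pb <- plogis(drop(X %*% object$coefficients))
    cbind(blue = pb, brown = 1 - pb)
  } else {
    E <- X %*% object$coefficients # full matrix incl. zero baseline column
    M <- apply(E, 1, max)
    ex <- exp(E - M)
    ex / rowSums(ex)
  }
  out <- tibble(sample_id = ids)
  for (k in colnames(P)) out[[paste0("p_", k)]] <- unname(P[, k])
  out$call_pmax <- call_category(P, call_policy("pmax"))
  out
}

#' Leave-one-out cross-validated prediction
#'
#' For each sample the system model is refitted on all other samples and used
#' to predict the held-out one; the per-sample out-of-sample predictions are
#' scored with [prediction_error()].  Genotype coding (the minor-allele map)
#' comes from the full cohort, matching how the models are coded in practice;
#' only model fitting is cross-validated.
#'
#' @inheritParams fit_system_model
#' @return An `ec_loocv`: `predictions` tibble (truth + predictions per
#'   sample), scalar `error`, `system`, `panel_name`, `n`.
#' @examples
#' cht <- simulate_cohort(paper_like_config(n = 60, seed = 3, set = "model"))
#' res <- loocv_predict(cht, panel_rs12913832(), "two_category")
#' glance(res)
#' @export
loocv_predict <- function(x, panel,
                          system = c("quantitative", "two_category", "three_category"),
                          ridge = 1e-6) {
  system <- match.arg(system)
  stopifnot(inherits(x, "ec_cohort"))
  coded <- encode_cohort(x, panel)
  n <- nrow(coded)
  if (n < 10) abort("LOOCV needs at least 10 complete samples")
  ph <- x$phenotypes[match(coded$sample_id, x$phenotypes$sample_id), ]
  rows <- vector("list", n)
  for (i in seq_len(n)) {
    fit <- tryCatch(
      fit_system_model_coded(coded[-i, ], ph$pie_score[-i], panel, system, ridge),
      error = function(e) {
        abort(paste0(
          "LOOCV refit failed leaving out ", coded$sample_id[i], ": ",
          conditionMessage(e)
        ))
      }
    )
    rows[[i]] <- predict(fit, coded[i, ])
  }
  pred <- dplyr::bind_rows(rows)
  pred <- dplyr::bind_cols(
    tibble(
      pie_obs = ph$pie_score,
      y_obs = transform_pie(ph$pie_score)
    ),
    pred
  )
  if (system != "quantitative") {
    pred$truth <- categorise_pie(ph$pie_score, system)
  }
  pred <- dplyr::relocate(pred, "sample_id")
  out <- structure(
    list(
      predictions = pred, system = system, panel_name = panel$name,
      n = n, ridge = ridge
    ),
    class = "ec_loocv"
  )
  out$error <- prediction_error(out)
  out
}

#' Out-of-sample prediction error of a LOOCV result
#'
#' Quantitative system: mean squared error on the transformed scale.
#' Two-category system: mean negative log-probability of the observed
#' category (`-log p` for blue truths, `-log(1-p)` for brown).
#' Three-category system: mean Kullback-Leibler divergence from the one-hot
#' observed distribution, i.e. mean `-log` of the probability assigned to
#' the observed category.  Probabilities are clipped to
#' `[1e-12, 1 - 1e-12]` before taking logs; the number of clipped values is
#' attached as attribute `n_clipped`.
#'
#' @param result An `ec_loocv`.
#' @return Scalar error with attribute `n_clipped`.
#' @export
prediction_error <- function(result) {
  stopifnot(inherits(result, "ec_loocv"))
  pred <- result$predictions
  if (result$system == "quantitative") {
    err <- mean((pred$y_pred - pred$y_obs)^2)
    attr(err, "n_clipped") <- 0L
    return(err)
  }
  pcols <- paste0("p_", levels(pred$truth))
  P <- as.matrix(pred[pcols])
  p_true <- P[cbind(seq_len(nrow(P)), as.integer(pred$truth))]
  n_clipped <- sum(p_true < 1e-12 | p_true > 1 - 1e-12)
  err <- mean(-log(clip_prob(p_true)))
  attr(err, "n_clipped") <- n_clipped
  err
}

#' @export
print.ec_loocv <- function(x, ...) {
  cat(
    "<ec_loocv> ", x$system, " system, panel ", x$panel_name, ", n = ", x$n,
    "\n  out-of-sample error: ", format(as.numeric(x$error), digits = 4), "\n",
    sep = ""
  )
  invisible(x)
}

#' @export
print.ec_fit <- function(x, ...) {
  cat("<ec_fit> ", x$system, " model, panel ", x$panel_name, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}
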