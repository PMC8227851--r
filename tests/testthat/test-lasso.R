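# small deterministic design for closed-form comparisons
ols_instance <- function(n = 20, p = 3, seed = 42) {
  withr::local_seed(seed)
  X <- matrix(round(rnorm(n * p), 2), n, p,
    dimnames = list(NULL, paste0("v", 1:p))
  )
  beta <- c(1.5, -2, 0.5)
  y <- drop(X %*% beta) + rnorm(n, 0, 0.3)
  coded <- tibble::as_tibble(X)
  coded$sample_id <- sprintf("s%02d", 1:n)
  list(coded = coded, y = y, X = X)
}

test_that("the unpenalised fit matches closed-form least squares", {
  inst <- ols_instance()
  fit <- fit_lasso(inst$coded, inst$y, family = "gaussian", lambda = 0)
  Xd <- cbind(1, inst$X)
  beta_ols <- drop(solve(crossprod(Xd), crossprod(Xd, inst$y)))
  expect_equal(unname(fit$coefficients), unname(beta_ols), tolerance = 1e-6)
})

test_that("a pure-noise response yields the intercept-only model at the 1-SE penalty", {
  withr::local_seed(7)
  n <- 200
  coded <- tibble::as_tibble(matrix(rnorm(n * 5), n, 5,
    dimnames = list(NULL, paste0("v", 1:5))
  ))
  coded$sample_id <- sprintf("s%03d", 1:n)
  y <- rnorm(n)
  fit <- fit_lasso(coded, y, family = "gaussian", seed = 3)
  expect_true(all(fit$coefficients[-1] == 0))
})

test_that("the 1-SE penalty choice matches an exhaustive per-fold grid evaluation", {
  inst <- ols_instance(n = 60, seed = 10)
  seed <- 17
  fit <- fit_lasso(inst$coded, inst$y, family = "gaussian", seed = seed)

  # independent oracle: refit glmnet fold by fold over the same grid and
  # apply the one-standard-error rule by hand
  foldid <- ec11:::with_local_seed(
    ec11:::derive_seed(seed, 7919L),
    sample(rep_len(1:10, nrow(inst$X)))
  )
  path <- glmnet::glmnet(inst$X, inst$y,
    nlambda = 100, lambda.min.ratio = 1e-4, standardize = TRUE
  )
  lam <- path$lambda
  fold_mse <- sapply(1:10, function(k) {
    f <- glmnet::glmnet(inst$X[foldid != k, ], inst$y[foldid != k],
      lambda = lam, standardize = TRUE
    )
    pred <- predict(f, inst$X[foldid == k, , drop = FALSE])
    colMeans((pred - inst$y[foldid == k])^2)
  })
  # cv.glmnet averages over observations' errors grouped by fold
  nk <- table(foldid)
  cvm <- drop(fold_mse %*% (nk / sum(nk)))
  cvsd <- sqrt(
    rowSums(sweep(fold_mse, 1, cvm)^2 %*% diag(as.numeric(nk) / sum(nk))) / 9
  )
  best <- which.min(cvm)
  lambda_1se <- max(lam[cvm <= cvm[best] + cvsd[best]])
  expect_equal(fit$lambda, lambda_1se, tolerance = 0.02)
})

test_that("a single dominant predictor is the only selected coefficient", {
  p <- panel(
    "dom",
    tibble::tibble(
      variable = c("rs12913832", "rsT2", "rsT3"),
      kind = c("dominant", "additive", "additive"),
      rsids = list("rs12913832", "rsT2", "rsT3")
    ),
    tibble::tibble(
      gene = c("HERC2", "G2", "G3"),
      rsid = c("rs12913832", "rsT2", "rsT3"),
      ref_allele = "A", var_allele = "G", var_freq = c(0.74, 0.3, 0.4)
    )
  )
  cht <- simulate_genotypes(p, 300, seed = 2)
  coded <- encode_cohort(cht, p)
  ph <- simulate_phenotypes(
    coded, effect_model(-3, c("rs12913832" = 6), noise_sd = 0.2), seed = 4
  )
  fit <- fit_lasso(coded, ph$y, family = "gaussian", seed = 1)
  expect_gt(abs(fit$coefficients[["rs12913832"]]), 1)
  expect_equal(unname(fit$coefficients[c("rsT2", "rsT3")]), c(0, 0))
})

test_that("binomial fits refuse single-class training data", {
  inst <- ols_instance()
  expect_error(
    fit_lasso(inst$coded, rep(1, 20), family = "binomial"),
    "single class"
  )
})

test_that("LASSO importances are absolute standardised coefficients with
           interaction terms credited to both partners", {
  fake <- structure(
    list(
      std_coefficients = c(
        rs12913832 = 2.0, mod = -0.5, other = 0,
        "rs12913832:mod" = 0.5
      ),
      terms = list(
        rs12913832 = "rs12913832", mod = "mod", other = "other",
        "rs12913832:mod" = c("rs12913832", "mod")
      )
    ),
    class = "ec_lasso"
  )
  imp <- variable_importance(fake)
  expect_equal(imp[["rs12913832"]], 2.5)
  expect_equal(imp[["mod"]], 1.0)
  expect_equal(imp[["other"]], 0)
  solo <- variable_importance(fake, attribute_to_partner_only = TRUE)
  expect_equal(solo[["rs12913832"]], 2.0)
  expect_equal(solo[["mod"]], 1.0)
})
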