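# helper: cohort over one dominant-coded SNP with category counts chosen
# exactly (blue truth = PIE 1, brown truth = PIE -1)
two_group_cohort <- function(n_blue_g1, n_brown_g1, n_blue_g0, n_brown_g0) {
  calls <- c(
    rep("GG", n_blue_g1 + n_brown_g1),
    rep("AG", n_blue_g0 + n_brown_g0)
  )
  pie <- c(
    rep(1, n_blue_g1), rep(-1, n_brown_g1),
    rep(1, n_blue_g0), rep(-1, n_brown_g0)
  )
  ids <- sprintf("s%03d", seq_along(calls))
  cohort(
    tibble::tibble(sample_id = ids, rs12913832 = calls),
    tibble::tibble(sample_id = ids, pie_score = pie)
  )
}

test_that("the two-category logistic fit reproduces the saturated closed form", {
  cht <- two_group_cohort(90, 10, 10, 90)
  fit <- fit_system_model(cht, panel_rs12913832(), "two_category")
  pred <- predict(fit, tibble::tibble(rs12913832 = c(1L, 0L)))
  expect_equal(pred$p_blue, c(0.9, 0.1), tolerance = 0.01)
})

test_that("noise-free quantitative data recovers the generating coefficients", {
  p <- toy_panel(freqs = c(0.4, 0.6))
  geno <- simulate_genotypes(p, 120, seed = 3)
  coded <- encode_cohort(geno, p)
  eff <- effect_model(0.7, c(rsT1 = 1.2, rsT2 = -0.8), noise_sd = 0)
  ph <- simulate_phenotypes(coded, eff, seed = 1)
  cht <- cohort(geno$genotypes, ph[c("sample_id", "pie_score")])
  fit <- fit_system_model(cht, p, "quantitative")
  expect_equal(
    unname(fit$coefficients),
    c(0.7, 1.2, -0.8),
    tolerance = 1e-6
  )
})

test_that("an intercept-only multinomial fit returns the category frequencies", {
  lab <- factor(
    rep(c("blue", "intermediate", "brown"), c(50, 20, 30)),
    levels = c("blue", "intermediate", "brown")
  )
  X <- matrix(1, length(lab), 1, dimnames = list(NULL, "(Intercept)"))
  B <- ec11:::multinom_ridge(X, lab, ridge = 0)
  p <- exp(B[1, ])
  p <- p / sum(p)
  expect_equal(unname(p), c(0.5, 0.2, 0.3), tolerance = 1e-7)
})

test_that("ridge-stabilised logistic and multinomial fits agree with reference
           optimisers away from separation", {
  skip_if_not_installed("nnet")
  cht <- simulate_cohort(paper_like_config(n = 300, seed = 19, set = "model"))
  pan <- panel_rs12913832()
  coded <- encode_cohort(cht, pan)
  pie <- cht$phenotypes$pie_score[match(coded$sample_id, cht$phenotypes$sample_id)]

  d <- data.frame(
    g = coded$rs12913832,
    two = as.integer(categorise_pie(pie, "two_category") == "blue"),
    three = categorise_pie(pie, "three_category")
  )

  fit2 <- fit_system_model(cht, pan, "two_category", ridge = 0)
  ref2 <- glm(two ~ g, data = d, family = binomial())
  expect_equal(unname(fit2$coefficients), unname(coef(ref2)), tolerance = 1e-5)

  fit3 <- fit_system_model(cht, pan, "three_category", ridge = 0)
  ref3 <- nnet::multinom(three ~ g, data = d, trace = FALSE, reltol = 1e-12)
  p_ours <- as.matrix(
    predict(fit3, tibble::tibble(rs12913832 = c(0L, 1L)))[paste0("p_", levels(d$three))]
  )
  p_ref <- predict(ref3, newdata = data.frame(g = c(0L, 1L)), type = "probs")
  expect_equal(unname(p_ours), unname(p_ref[, levels(d$three)]), tolerance = 1e-4)
})

test_that("multinomial predicted probabilities always sum to one", {
  cht <- simulate_cohort(paper_like_config(n = 200, seed = 23, set = "model"))
  fit <- fit_system_model(cht, panel_ec11(), "three_category")
  space <- enumerate_genotype_space(panel_ec11(), model = fit)
  P <- as.matrix(space$combinations[paste0("p_", fit$categories)])
  expect_lt(max(abs(rowSums(P) - 1)), 1e-9)
  expect_true(all(P >= 0))
})

test_that("LOOCV equals a naive per-fold refit for all three systems", {
  cht <- simulate_cohort(paper_like_config(n = 30, seed = 77, set = "model"))
  pan <- panel_irisplex6()
  coded <- encode_cohort(cht, pan)
  pie <- cht$phenotypes$pie_score[match(coded$sample_id, cht$phenotypes$sample_id)]
  for (sys in c("quantitative", "two_category", "three_category")) {
    res <- loocv_predict(cht, pan, sys)
    naive <- purrr::map_dfr(seq_len(nrow(coded)), function(i) {
      f <- ec11:::fit_system_model_coded(coded[-i, ], pie[-i], pan, sys)
      predict(f, coded[i, ])
    })
    keep <- intersect(names(naive), names(res$predictions))
    expect_equal(res$predictions[keep], naive[keep], info = sys)
  }
})

test_that("a constant-response cohort predicts the common value with zero error", {
  gt <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:12),
    rsT1 = rep(c("AA", "AG", "GG"), 4)
  )
  ph <- tibble::tibble(sample_id = gt$sample_id, pie_score = 0.42)
  cht <- cohort(gt, ph)
  res <- loocv_predict(cht, toy_panel(kinds = "additive", freqs = 0.25), "quantitative")
  expect_equal(res$predictions$pie_pred, rep(0.42, 12), tolerance = 1e-9)
  expect_equal(as.numeric(res$error), 0, tolerance = 1e-12)
})

test_that("prediction-error identities hold", {
  mk_loocv <- function(pred, system) {
    structure(
      list(predictions = pred, system = system, panel_name = "x", n = nrow(pred)),
      class = "ec_loocv"
    )
  }
  # uniform three-class prediction: mean KL is ln 3
  pred3 <- tibble::tibble(
    truth = factor(c("blue", "intermediate", "brown"),
      levels = c("blue", "intermediate", "brown")
    ),
    p_blue = 1 / 3, p_intermediate = 1 / 3, p_brown = 1 / 3
  )
  expect_equal(as.numeric(prediction_error(mk_loocv(pred3, "three_category"))), log(3))
  # two-class p = 0.5 everywhere: log-loss is ln 2
  pred2 <- tibble::tibble(
    truth = factor(c("blue", "brown"), levels = c("blue", "brown")),
    p_blue = 0.5, p_brown = 0.5
  )
  expect_equal(as.numeric(prediction_error(mk_loocv(pred2, "two_category"))), log(2))
  # perfect prediction: zero error
  perfect <- tibble::tibble(
    truth = factor(c("blue", "brown"), levels = c("blue", "brown")),
    p_blue = c(1, 0), p_brown = c(0, 1)
  )
  expect_equal(
    as.numeric(prediction_error(mk_loocv(perfect, "two_category"))), 0,
    tolerance = 1e-10
  )
})

test_that("in-sample log-loss never worsens when a panel is extended (ridge 0)", {
  cht <- simulate_cohort(paper_like_config(n = 250, seed = 41, set = "model"))
  in_sample_logloss <- function(pan) {
    fit <- fit_system_model(cht, pan, "two_category", ridge = 0)
    coded <- encode_cohort(cht, pan)
    pie <- cht$phenotypes$pie_score[match(coded$sample_id, cht$phenotypes$sample_id)]
    pred <- predict(fit, coded)
    truth <- categorise_pie(pie, "two_category")
    p <- ifelse(truth == "blue", pred$p_blue, pred$p_brown)
    mean(-log(pmax(p, 1e-12)))
  }
  # rs12913832 (dominant) is nested inside EC11
  expect_lte(
    in_sample_logloss(panel_ec11()),
    in_sample_logloss(panel_rs12913832()) + 1e-8
  )
})

test_that("out-of-sample errors order EC11 <= IrisPlex <= rs12913832 on
           modifier-rich cohorts", {
  ok <- purrr::map_lgl(1:3, function(s) {
    cht <- simulate_cohort(paper_like_config(n = 400, seed = 300 + s, set = "model"))
    errs <- purrr::map_dbl(
      list(panel_ec11(), panel_irisplex6(), panel_rs12913832()),
      function(p) as.numeric(loocv_predict(cht, p, "two_category")$error)
    )
    errs[1] <= errs[2] + 0.02 && errs[2] <= errs[3] + 0.02
  })
  expect_gte(sum(ok), 2)
})
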