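test_that("category calls follow the threshold and tie rules", {
  p3 <- c(blue = 0.6, intermediate = 0.3, brown = 0.1)
  expect_equal(as.character(call_category(p3, "pmax")), "blue")
  expect_equal(as.character(call_category(p3, 0.7)), "inconclusive")
  expect_equal(as.character(call_category(p3, 0.5)), "blue")
  tie <- c(blue = 0.5, brown = 0.5)
  expect_equal(as.character(call_category(tie, "pmax")), "inconclusive")
  expect_error(call_policy(1.5), "in \\(0, 1\\)")
  expect_error(call_category(c(blue = 0.9, brown = 0.3)), "sum to 1")
})

mk_loocv2 <- function(p_blue, truth) {
  pred <- tibble::tibble(
    sample_id = sprintf("s%02d", seq_along(p_blue)),
    truth = factor(truth, levels = c("blue", "brown")),
    p_blue = p_blue, p_brown = 1 - p_blue
  )
  structure(
    list(
      predictions = pred, system = "two_category", panel_name = "toy",
      n = nrow(pred)
    ),
    class = "ec_loocv"
  )
}

test_that("a hand-counted confusion example gives sensitivity and specificity 0.8", {
  # 5 blue truths (one predicted brown), 5 brown truths (one predicted blue)
  res <- mk_loocv2(
    p_blue = c(0.9, 0.9, 0.9, 0.9, 0.2, 0.1, 0.1, 0.1, 0.1, 0.8),
    truth = c(rep("blue", 5), rep("brown", 5))
  )
  rep <- report(res, "pmax")
  expect_equal(rep$per_class$sensitivity[rep$per_class$category == "blue"], 0.8)
  expect_equal(rep$per_class$specificity[rep$per_class$category == "blue"], 0.8)
  expect_equal(rep$outcome$percent, c(80, 20, 0))
  expect_equal(sum(rep$outcome$percent), 100)
})

test_that("an unreachable threshold reports everything inconclusive with NA rates", {
  res <- mk_loocv2(p_blue = rep(0.6, 10), truth = rep(c("blue", "brown"), 5))
  rep <- report(res, 0.99)
  expect_equal(rep$outcome$percent, c(0, 0, 100))
  expect_true(all(is.na(rep$per_class$sensitivity)))
})

test_that("outcome percentages always sum to 100 and inconclusive counts are
           monotone in the threshold", {
  cht <- simulate_cohort(paper_like_config(n = 120, seed = 55, set = "model"))
  res <- loocv_predict(cht, panel_ec11(), "three_category")
  n_inc <- purrr::map_dbl(list("pmax", 0.5, 0.7), function(thr) {
    rep <- report(res, thr)
    expect_equal(sum(rep$outcome$percent), 100)
    expect_equal(sum(rep$outcome$count), rep$n)
    rep$outcome$count[rep$outcome$outcome == "inconclusive"]
  })
  expect_true(all(diff(n_inc) >= 0))
})

test_that("genotype-space sizes equal the product of coded level counts", {
  expect_equal(enumerate_genotype_space(panel_irisplex6())$n_combinations, 729)
  expect_equal(enumerate_genotype_space(panel_ec11())$n_combinations, 52488)
  single <- toy_panel(kinds = "additive", freqs = 0.3)
  expect_equal(enumerate_genotype_space(single)$n_combinations, 3)
  # property: random coding mixtures
  withr::local_seed(8)
  tab <- variant_table()
  for (i in 1:5) {
    k <- sample(2:6, 1)
    rows <- sample(which(nchar(tab$ref_allele) == 1 & nchar(tab$var_allele) == 1), k)
    kinds <- sample(c("additive", "dominant", "carrier"), k, replace = TRUE)
    pan <- panel(
      "rand",
      tibble::tibble(variable = tab$rsid[rows], kind = kinds, rsids = as.list(tab$rsid[rows])),
      dplyr::transmute(tab[rows, ], gene, rsid, ref_allele, var_allele,
        var_freq = freq_discovery
      )
    )
    expect_equal(
      enumerate_genotype_space(pan)$n_combinations,
      prod(ifelse(kinds == "additive", 3, 2))
    )
  }
  expect_error(enumerate_genotype_space(panel_ec11(), cap = 100), "cap")
})

test_that("genotype-space predictions summarise category reachability", {
  cht <- simulate_cohort(paper_like_config(n = 300, seed = 61, set = "model"))
  fit <- fit_system_model(cht, panel_rs12913832(), "three_category")
  space <- enumerate_genotype_space(panel_rs12913832(), model = fit)
  expect_equal(nrow(space$combinations), 2)
  expect_equal(sum(space$category_summary$n_pmax), 2)
  expect_true(all(space$category_summary$max_probability <= 1))
})

test_that("likelihood ratios are conditional genotype-frequency ratios", {
  # brown-eyed: 1 GG of 20; blue-eyed: 10 GG of 20 -> LR(GG) = 0.05 / 0.5
  gt <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:40),
    rs12913832 = c(rep("GG", 1), rep("AG", 19), rep("GG", 10), rep("AA", 10))
  )
  ph <- tibble::tibble(
    sample_id = gt$sample_id,
    pie_score = c(rep(-1, 20), rep(1, 20))
  )
  cht <- cohort(gt, ph)
  lr <- likelihood_ratio(cht, "rs12913832", "GG")
  expect_equal(lr$lr, 0.1)
  # independent oracle: straight contingency arithmetic
  truth <- categorise_pie(ph$pie_score, "two_category")
  oracle <- (sum(gt$rs12913832 == "GG" & truth == "brown") / sum(truth == "brown")) /
    (sum(gt$rs12913832 == "GG" & truth == "blue") / sum(truth == "blue"))
  expect_equal(lr$lr, oracle)
  # AG is absent among the blue-eyed: unsmoothed LR is undefined
  expect_error(likelihood_ratio(cht, "rs12913832", "AG"), "smoothing")
  sm <- likelihood_ratio(cht, "rs12913832", "AG", smoothing = TRUE)
  expect_gt(sm$lr, 1) # still strong brown evidence
  # equal conditional frequencies give LR = 1
  gt3 <- tibble::tibble(
    sample_id = c("a", "b", "c", "d"),
    rs12913832 = c("GG", "GG", "AG", "AG")
  )
  ph3 <- tibble::tibble(sample_id = gt3$sample_id, pie_score = c(-1, 1, -1, 1))
  expect_equal(likelihood_ratio(cohort(gt3, ph3), "rs12913832", "GG")$lr, 1)
})
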