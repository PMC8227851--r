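test_that("built-in panels have the expected shape and genotype-space sizes", {
  ec <- panel_ec11()
  expect_equal(nrow(ec$variables), 11)
  expect_equal(sort(table(ec$variables$kind), decreasing = TRUE)[["additive"]], 8)
  expect_equal(prod(variable_levels(ec)), 52488) # 2^3 * 3^8
  expect_equal(prod(variable_levels(panel_irisplex6())), 729) # 3^6
  expect_equal(prod(variable_levels(panel_rs12913832())), 2)
  expect_equal(nrow(panel_discovery44()$variants), 44)
  expect_equal(nrow(panel_discovery44()$variables), 43) # two variants combined
  expect_error(get_panel("nosuchpanel"), "unknown panel")
})

test_that("coding schemes follow their definitions", {
  # dominant rs12913832: AA and AG are 0, GG is 1
  p <- panel(
    "dom",
    tibble::tibble(variable = "rs12913832", kind = "dominant", rsids = list("rs12913832")),
    tibble::tibble(
      gene = "HERC2", rsid = "rs12913832",
      ref_allele = "A", var_allele = "G", var_freq = 0.74
    )
  )
  cht <- counts_cohort(2, 3, 5, rsid = "rs12913832")
  coded <- encode_cohort(cht, p)
  expect_equal(coded$rs12913832, c(rep(0L, 5), rep(1L, 5)))

  # additive: homozygous minor codes 2
  cht2 <- counts_cohort(6, 3, 1) # G is minor here (freq 0.25)
  coded2 <- encode_cohort(cht2, toy_panel(kinds = "additive", freqs = 0.25))
  expect_equal(coded2$rsT1, c(rep(0L, 6), rep(1L, 3), 2L))
  expect_equal(attr(coded2, "minor_allele_map")[["rsT1"]], "G")

  # carrier: any minor allele codes 1
  coded3 <- encode_cohort(cht2, toy_panel(kinds = "carrier", freqs = 0.25))
  expect_equal(coded3$rsT1, c(rep(0L, 6), rep(1L, 4)))
})

test_that("combined coding sums constituent minor-allele counts, capped at 2", {
  p <- panel(
    "comb",
    tibble::tibble(
      variable = "rs121918166+rs74653330", kind = "combined",
      rsids = list(c("rs121918166", "rs74653330"))
    ),
    tibble::tibble(
      gene = "OCA2", rsid = c("rs121918166", "rs74653330"),
      ref_allele = "C", var_allele = "T", var_freq = 0.005
    )
  )
  gt <- tibble::tibble(
    sample_id = c("a", "b", "c", "d", "e", "f", "g", "h"),
    rs121918166 = c("CT", "CC", "TT", "TT", rep("CC", 4)),
    rs74653330 = c("CC", "CC", "CT", "TT", rep("CC", 4))
  )
  coded <- encode_cohort(cohort(gt), p)
  # T is minor in this cohort; counts are 1+0, 0+0, 2+1 and 2+2 (capped)
  expect_equal(
    coded$`rs121918166+rs74653330`,
    c(1L, 0L, 2L, 2L, 0L, 0L, 0L, 0L)
  )
})

test_that("encoding is invariant to sample order and within-call allele order", {
  p <- toy_panel()
  gt <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    rsT1 = c("AG", "GA", "GG"),
    rsT2 = c("AA", "AG", "GA")
  )
  c1 <- encode_cohort(cohort(gt), p)
  c2 <- encode_cohort(cohort(gt[c(3, 1, 2), ]), p)
  expect_equal(
    dplyr::arrange(c1, sample_id)$rsT1,
    dplyr::arrange(tibble::as_tibble(c2), sample_id)$rsT1
  )
  expect_equal(c1$rsT2[2], c1$rsT2[3]) # "AG" == "GA"
})

test_that("minor-allele ties at 0.5 break lexicographically", {
  cht <- counts_cohort(1, 2, 1) # allele freq exactly 0.5
  coded <- encode_cohort(cht, toy_panel(kinds = "additive", freqs = 0.5))
  expect_equal(attr(coded, "minor_allele_map")[["rsT1"]], "A")
})

test_that("missing panel calls drop samples by default and can be imputed", {
  p <- toy_panel(kinds = "additive", freqs = 0.25)
  gt <- tibble::tibble(
    sample_id = c("s1", "s2", "s3", "s4"),
    rsT1 = c("AG", "./.", "GG", "AA")
  )
  dropped <- encode_cohort(cohort(gt), p)
  expect_equal(dropped$sample_id, c("s1", "s3", "s4"))
  imputed <- encode_cohort(cohort(gt), p, missing = "impute")
  expect_equal(nrow(imputed), 4)
  expect_equal(imputed$rsT1[2], mean(c(1, 2, 0)))
})

test_that("calls with undeclared alleles are an error, not a silent fix", {
  p <- toy_panel(kinds = "additive", freqs = 0.25)
  gt <- tibble::tibble(sample_id = "s1", rsT1 = "AT")
  expect_error(encode_cohort(cohort(gt), p), "does not match declared alleles")
})

test_that("indel alleles code like SNP alleles through full allele strings", {
  p <- panel(
    "indel",
    tibble::tibble(variable = "rs10530949", kind = "additive", rsids = list("rs10530949")),
    tibble::tibble(
      gene = "IRF4", rsid = "rs10530949",
      ref_allele = "TCT", var_allele = "-", var_freq = 0.43
    )
  )
  gt <- tibble::tibble(
    sample_id = c("s1", "s2", "s3"),
    rs10530949 = c("TCTTCT", "TCT-", "--")
  )
  coded <- encode_cohort(cohort(gt), p)
  # deletion-allele freq is exactly 0.5 here; the tie picks "-" lexicographically
  expect_equal(coded$rs10530949, c(0L, 1L, 2L))
})
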