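sel_table <- function() matrix(c(143, 37, 1917, 741), 2, 2, byrow = TRUE)

test_that("expected counts conserve margins and match printed values", {
  E <- expected_counts(sel_table())
  expect_equal(round(E[1, 1], 2), 130.66)
  expect_equal(rowSums(E), rowSums(sel_table()))
  expect_equal(colSums(E), colSums(sel_table()))

  expect_equal(expected_counts(matrix(10, 2, 2)), matrix(10, 2, 2))

  E2 <- expected_counts(matrix(c(61, 1975, 46, 2342), 2, 2, byrow = TRUE))
  expect_equal(round(E2[1, 1], 2), 49.24)
  expect_error(expected_counts(matrix(0, 2, 2)), "zero total")
})

test_that("uncorrected Pearson chi-square matches published statistics", {
  r <- chisq_2x2(sel_table())
  expect_equal(round(r$statistic, 2), 4.54)
  expect_equal(round(r$p_value, 4), 0.0331)
  expect_equal(r$df, 1L)

  expect_equal(chisq_2x2(matrix(c(20, 10, 40, 20), 2, byrow = TRUE))$statistic, 0)
  expect_equal(round(chisq_2x2(matrix(c(28, 318, 10, 375), 2, byrow = TRUE))$statistic, 1),
               11.2)
})

test_that("a continuity correction would NOT reproduce the published value", {
  corrected <- suppressWarnings(stats::chisq.test(sel_table(), correct = TRUE))
  expect_equal(round(unname(corrected$statistic), 2), 4.18)
  expect_false(round(unname(corrected$statistic), 2) == 4.54)
})

test_that("the statistic is invariant to row/column swaps and transposition", {
  x <- sel_table()
  s0 <- chisq_2x2(x)$statistic
  expect_equal(chisq_2x2(x[2:1, ])$statistic, s0)
  expect_equal(chisq_2x2(x[, 2:1])$statistic, s0)
  expect_equal(chisq_2x2(t(x))$statistic, s0)
})

test_that("zero expected cells are refused with advice", {
  expect_error(chisq_2x2(matrix(c(0, 0, 5, 5), 2, byrow = TRUE)), "exact")
})

test_that("association_scan applies the strict >min_genes filter", {
  labels <- setNames(rep(c("A", "O"), each = 50), sprintf("g%03d", 1:100))
  cats <- data.frame(
    gene_id = c(sprintf("g%03d", 1:4),    # 4 members: excluded
                sprintf("g%03d", 10:14),  # 5 members: still excluded (>5)
                sprintf("g%03d", 20:25)), # 6 members: included
    category = rep(c("tiny", "five", "six"), c(4, 5, 6)))
  out <- association_scan(labels, cats, focal = "A")
  expect_identical(out$category, "six")
})

test_that("association_scan recovers a planted enrichment", {
  set.seed(97)
  labels <- setNames(sample(c("A", "L", "other"), 2000, replace = TRUE,
                            prob = c(0.45, 0.2, 0.35)),
                     sprintf("g%04d", 1:2000))
  cats <- plant_enrichment(labels, n_categories = 40,
                           enriched = list(list(category = "cat0007",
                                                hypothesis = "A",
                                                odds_ratio = 3)),
                           seed = 103)
  out <- association_scan(labels, cats, focal = "A")
  expect_equal(out$category[1], "cat0007")
  expect_lt(out$p_value[1], 0.001)
})

test_that("a scan row rebuilt from printed category counts reproduces X^2", {
  # focal supporters: 777 genes, 12 with the category; others: 3647, 20 with
  labels <- setNames(rep(c("L", "O"), c(777, 3647)), sprintf("g%04d", 1:4424))
  members <- c(sprintf("g%04d", 1:12), sprintf("g%04d", 778:797))
  cats <- data.frame(gene_id = members, category = "scaffold")
  out <- association_scan(labels, cats, focal = "L")
  expect_equal(round(out$statistic, 1), 8.8)
  expect_equal(out[, c("focal_with", "focal_without", "other_with",
                       "other_without")],
               data.frame(focal_with = 12L, focal_without = 765L,
                          other_with = 20L, other_without = 3627L))
})

test_that("two-hypotheses mode conditions on the two focal supporters", {
  labels <- setNames(rep(c("A", "L", "other"), c(60, 30, 40)),
                     sprintf("g%03d", 1:130))
  cats <- data.frame(gene_id = sprintf("g%03d", c(1:20, 61:65)),
                     category = "c1")
  out <- association_scan(labels, cats, focal = "A", alternative = "L",
                          mode = "two_hypotheses")
  # 90 genes in the conditioned universe: 20+5 with category
  expect_equal(out$focal_with + out$other_with, 25L)
  expect_equal(out$focal_with + out$focal_without +
                 out$other_with + out$other_without, 90L)
})
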