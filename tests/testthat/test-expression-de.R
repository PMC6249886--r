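make_table <- function(cv, gf, gene_ids = NULL, organ = "liver") {
  # cv, gf: matrices genes x replicates
  if (is.null(gene_ids)) gene_ids <- sprintf("g%d", seq_len(nrow(cv)))
  values <- cbind(cv, gf)
  rownames(values) <- gene_ids
  colnames(values) <- c(paste0(organ, "_CV_", seq_len(ncol(cv))),
                        paste0(organ, "_GF_", seq_len(ncol(gf))))
  design <- data.frame(
    sample_id = colnames(values), organ = organ,
    enterotype = rep(c("CV", "GF"), c(ncol(cv), ncol(gf))),
    replicate = c(seq_len(ncol(cv)), seq_len(ncol(gf))))
  expression_table(values, design)
}

test_that("expression calls use strict FPKM > 1 on either enterotype mean", {
  tab <- make_table(rbind(c(0.5, 0.5, 0.5), c(1, 1, 1), c(0, 0, 0)),
                    rbind(c(2, 2, 2), c(0, 0, 0), c(0, 0, 0)))
  calls <- call_expressed(tab, "liver")
  expect_identical(calls$expressed, c(TRUE, FALSE, FALSE))
  expect_equal(calls$mean_fpkm_gf[1], 2)
  expect_error(call_expressed(tab, "colon"), "organ not present")
})

test_that("benjamini_hochberg matches the step-up definition", {
  expect_equal(benjamini_hochberg(0.5), 0.5)
  expect_equal(benjamini_hochberg(c(0.001, 0.9)), c(0.002, 0.9))
  expect_equal(benjamini_hochberg(c(0.01, 0.02, 0.03, 0.04)),
               rep(0.04, 4))
  expect_error(benjamini_hochberg(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(benjamini_hochberg(numeric()), "empty")
})

test_that("BH q-values equal brute force and p.adjust on random inputs", {
  set.seed(5)
  n_instances <- 0L
  for (seed in 1:5) {
    set.seed(seed)
    for (i in 1:200) {
      p <- runif(sample(1:40, 1))^sample(1:3, 1)
      q <- benjamini_hochberg(p)
      expect_equal(q, oracle_bh(p))
      expect_equal(q, stats::p.adjust(p, "BH"))
      # monotone in sorted order, q >= p, q <= 1
      expect_true(all(diff(q[order(p)]) >= -1e-15))
      expect_true(all(q >= p - 1e-15) && all(q <= 1))
      n_instances <- n_instances + 1L
    }
  }
  expect_gte(n_instances, 1000L)
})

test_that("fallback test computes the stated fold change and degenerate p", {
  tab <- make_table(rbind(c(1, 1, 1), c(2, 2, 2), c(3, 3, 3)),
                    rbind(c(8, 8.1, 7.9), c(2, 2, 2), c(4, 4, 4)))
  d <- fallback_de_test(tab, "liver")
  expect_lt(abs(d$log2_fold_change[1] - 3), 0.05)
  # identical groups: zero variance, equal means -> p = 1, log2FC = 0
  expect_equal(d$p_value[2], 1)
  expect_equal(d$log2_fold_change[2], 0)
  # zero variance, different means -> smallest representable positive p
  expect_equal(d$p_value[3], .Machine$double.xmin)
  one_rep <- make_table(matrix(c(1, 2), ncol = 1),
                        matrix(c(3, 4), ncol = 1))
  expect_error(fallback_de_test(one_rep, "liver"), ">= 2 replicates")
})

test_that("differential calls require expression and strict q < alpha", {
  diff <- data.frame(
    gene_id = c("a", "b", "c", "d"), organ = "liver",
    mean_fpkm_cv = c(2, 2, 0.1, 2), mean_fpkm_gf = c(9, 3, 0.2, 0.5),
    log2_fold_change = c(1.5, 0.5, -2, -1.7),
    p_value = c(0.001, 0.05, 0.001, 0.002),
    q_value = c(0.04, 0.06, 0.01, 0.03))
  expressed <- c(TRUE, TRUE, FALSE, TRUE)
  calls <- call_differential(diff, expressed)
  expect_identical(calls$differentially_regulated,
                   c(TRUE, FALSE, FALSE, TRUE))
  expect_identical(calls$direction, c("up_in_gf", "none", "none",
                                      "down_in_gf"))
  # invariants: DR implies expressed and q < 0.05
  expect_true(all(!calls$differentially_regulated |
                    (calls$expressed & calls$q_value < 0.05)))
})

test_that("null data yields calibrated type-I error near 0.05", {
  tab <- generate_null_expression(n_genes = 5000, seed = 2024)
  d <- fallback_de_test(tab, "null")
  rate <- mean(d$p_value < 0.05, na.rm = TRUE)
  expect_gte(rate, 0.03)
  expect_lte(rate, 0.07)
})

test_that("planted effects of |log2FC| >= 2 are recovered with high
           sensitivity and precision", {
  set.seed(99)
  n <- 400; n_true <- 60
  delta <- c(sample(c(-2.5, 2, 3), n_true, replace = TRUE), rep(0, n - n_true))
  baseline <- rlnorm(n, 1, 1) + 1.01  # keep everything expressed
  cv <- sapply(1:3, function(i) baseline * 2^rnorm(n, 0, 0.2))
  gf <- sapply(1:3, function(i) baseline * 2^(delta + rnorm(n, 0, 0.2)))
  tab <- make_table(cv, gf)
  d <- fallback_de_test(tab, "liver")
  calls <- call_differential(d, call_expressed(tab, "liver"))
  dr <- calls$differentially_regulated
  sens <- sum(dr[1:n_true]) / n_true
  prec <- sum(dr[1:n_true]) / sum(dr)
  expect_gte(sens, 0.90)
  expect_gte(prec, 0.90)
  # recovered directions match the planted signs
  expect_true(all(calls$direction[1:n_true][dr[1:n_true]] ==
                    ifelse(delta[1:n_true][dr[1:n_true]] > 0,
                           "up_in_gf", "down_in_gf")))
})
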