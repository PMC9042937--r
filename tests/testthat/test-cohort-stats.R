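test_that("normality gate passes Gaussians at its nominal rate and rejects two-point data", {
  set.seed(31)
  pass <- vapply(1:1000, function(i) normality_gate(rnorm(500))$normal, TRUE)
  expect_gt(mean(pass), 0.93)
  expect_lt(mean(pass), 0.97)
  two_pt <- vapply(1:200, function(i)
    normality_gate(sample(c(0, 1), 50, replace = TRUE))$normal, TRUE)
  expect_lt(mean(two_pt), 0.01)
  g <- normality_gate(rep(4, 10))
  expect_false(g$normal)
  expect_true(g$degenerate)
  expect_error(normality_gate(c(1, 2)), "n >= 3")
})

test_that("two-group comparison dispatches on normality and reports Student df", {
  set.seed(32)
  a <- rnorm(12, 0, 1); b <- rnorm(12, 1, 1)
  stopifnot(normality_gate(a)$normal, normality_gate(b)$normal)
  res <- compare_groups(a, b)
  expect_equal(res$method, "student_t")
  expect_equal(res$df, 22)
  expect_equal(res$p_value,
               stats::t.test(a, b, var.equal = TRUE)$p.value, tolerance = 1e-12)
  # identical samples: t = 0, p = 1
  same <- compare_groups(a, a)
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)
  # clearly non-normal samples take the rank branch and report U
  x <- rexp(30)^3; y <- rexp(30)^3
  stopifnot(!normality_gate(x)$normal)
  resw <- compare_groups(x, y)
  expect_equal(resw$method, "mann_whitney")
  expect_equal(resw$statistic,
               unname(suppressWarnings(stats::wilcox.test(x, y, exact = FALSE)$statistic)))
  expect_error(compare_groups(1, c(1, 2)), "n >= 2")
})

test_that("t-branch power matches the closed-form oracle", {
  set.seed(33)
  reps <- 800
  hits <- 0; used <- 0
  for (i in seq_len(reps)) {
    a <- rnorm(12); b <- rnorm(12, 1)
    res <- compare_groups(a, b)
    if (res$method == "student_t") {
      used <- used + 1
      if (res$p_value < 0.05) hits <- hits + 1
    }
  }
  oracle <- stats::power.t.test(n = 12, delta = 1, sd = 1,
                                sig.level = 0.05)$power
  expect_lt(abs(hits / used - oracle), 0.05)
})

test_that("Friedman statistic follows the rank-sum formula", {
  # saturated ordering: ten blocks, four conditions, identical strict order
  blocks <- matrix(rep(c(1, 2, 3, 4), each = 10), 10, 4)
  res <- friedman_statistic(blocks)
  expect_identical(res$statistic, 30)
  expect_equal(res$df, 3)
  # all-equal matrix: midranks make the statistic exactly zero
  expect_equal(friedman_statistic(matrix(5, 6, 3))$statistic, 0)
  # random matrices against the definition oracle and stats::friedman.test
  set.seed(34)
  for (rep in 1:10) {
    m <- matrix(rnorm(18), 6, 3)
    res <- friedman_statistic(m)
    expect_equal(res$statistic, friedman_oracle(m), tolerance = 1e-12)
    expect_equal(res$statistic,
                 unname(stats::friedman.test(m)$statistic), tolerance = 1e-12)
    expect_equal(res$p_value,
                 stats::pchisq(res$statistic, 2, lower.tail = FALSE))
  }
  # tied data still agrees with the explicit midrank oracle
  mt <- matrix(c(1, 1, 2, 2, 3, 3, 1, 2, 2), 3, 3)
  expect_equal(friedman_statistic(mt)$statistic, friedman_oracle(mt))
  expect_error(friedman_statistic(matrix(1, 1, 3)), "at least 2")
})

test_that("identical strict orderings maximize the Friedman statistic (closed form)", {
  for (n in 2:12) for (k in 3:5) {
    blocks <- matrix(rep(seq_len(k), each = n), n, k)
    expected <- 12 / (n * k * (k + 1)) * n^2 * sum(seq_len(k)^2) - 3 * n * (k + 1)
    expect_equal(friedman_statistic(blocks)$statistic, expected)
    expect_equal(expected, n * (k - 1))    # the known saturation value
  }
})

test_that("BKY two-stage step-up controls and adapts as defined", {
  expect_equal(sum(bky_two_stage(rep(1, 10))$rejected), 0)
  expect_equal(sum(bky_two_stage(rep(1e-6, 10))$rejected), 10)
  p <- c(0.001, 0.002, 0.2, 0.8, 0.9)
  out <- bky_two_stage(p, q = 0.05)
  expect_equal(attr(out, "m0"), 3)
  expect_equal(attr(out, "stage2_level"), (0.05 / 1.05) * 5 / 3)
  expect_true(all(out$rejected[1:2]))
  expect_error(bky_two_stage(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_error(bky_two_stage(0.5, q = 1.2), "in \\(0, 1\\)")
  # monotone decisions: rejected p-values never exceed accepted ones
  set.seed(35)
  for (rep in 1:20) {
    p <- runif(40)^2
    out <- bky_two_stage(p)
    if (any(out$rejected) && any(!out$rejected))
      expect_lt(max(p[out$rejected]), min(p[!out$rejected]) + 1e-15)
  }
})

test_that("one-way ANOVA reports the printed df layout and matches the SS oracle", {
  set.seed(36)
  groups <- lapply(1:4, function(i) rnorm(12, mean = i * 0.5))
  names(groups) <- paste0("Q", 1:4)
  res <- anova_bonferroni(groups)
  expect_equal(res$df, c(3, 44))
  expect_equal(res$statistic, anova_f_oracle(groups), tolerance = 1e-10)
  expect_equal(nrow(res$post_hoc), 6)
  # identical groups: F = 0, no post-hoc rejections
  same <- anova_bonferroni(lapply(1:3, function(i) c(1, 2, 3, 4)))
  expect_equal(same$statistic, 0)
  expect_false(any(same$post_hoc$significant))
  expect_error(anova_bonferroni(list(rnorm(5))), ">= 2 groups")
})

test_that("tidy and glance summarise test objects as tibbles", {
  set.seed(37)
  res <- anova_bonferroni(lapply(1:3, function(i) rnorm(8, i)))
  td <- tidy(res)
  expect_s3_class(td, "tbl_df")
  expect_equal(nrow(td), 3)
  gl <- glance(res)
  expect_equal(nrow(gl), 1)
  expect_equal(gl$df1, 2)
  simple <- compare_groups(rnorm(10), rnorm(10))
  expect_equal(nrow(tidy(simple)), 1)
})

test_that("the full cohort grid runs both branches and flags missing hemispheres", {
  means <- list(young = c(Q1 = -36, Q2 = -30, Q3 = -24, Q4 = -18),
                old = c(Q1 = -40, Q2 = -34, Q3 = -28, Q4 = -22))
  sds <- lapply(means, function(m) stats::setNames(rep(1, 4), names(m)))
  tab <- gen_cohort(cohort_truth(c(young = 6, old = 6), 2, means, sds, seed = 38),
                    measure = "quartile_cutoff_db")
  res <- run_cohort_analysis(tab)
  expect_true(all(c("scope", "comparison", "method", "p_value") %in% names(res)))
  omni <- res[res$comparison == "omnibus", ]
  expect_equal(nrow(omni), 2)
  expect_true(all(omni$significant))
  # strong separation: every within-group contiguous post hoc significant
  ph <- res[grepl("_posthoc", res$method), ]
  contiguous <- grepl("Q1 vs Q2|Q2 vs Q3|Q3 vs Q4|Q2 vs Q1|Q3 vs Q2|Q4 vs Q3",
                      ph$comparison)
  expect_true(all(ph$significant[contiguous]))
  # between-age rows, one per level, all significant at these effect sizes
  btw <- res[grepl("between", res$scope), ]
  expect_equal(nrow(btw), 4)
  expect_true(all(btw$significant))
  expect_error(run_cohort_analysis(tab[tab$hemisphere == "left", ]),
               "both hemispheres")
})
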