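new_hv_test <- function(method, statistic, df, p_value, post_hoc = NULL,
                        alpha = 0.05, note = NULL) {
  structure(list(method = method, statistic = statistic, df = df,
                 p_value = p_value, post_hoc = post_hoc, alpha = alpha,
                 note = note),
            class = "hv_test")
}

#' @export
print.hv_test <- function(x, ...) {
  dfs <- if (length(x$df)) paste(x$df, collapse = ", ") else "-"
  cat(sprintf("<hv_test> %s: statistic = %.4g, df = %s, p = %.4g\n",
              x$method, x$statistic, dfs, x$p_value))
  if (!is.null(x$post_hoc)) { cat("post hoc:\n"); print(x$post_hoc) }
  invisible(x)
}

#' Shapiro-Wilk normality gate
#'
#' Tests a sample for normality; the result decides whether downstream
#' comparisons use the parametric (t / ANOVA) or rank-based (Mann-Whitney /
#' Friedman) branch. A constant sample cannot be tested and is returned as a
#' defined degenerate result: `normal = FALSE`, `W = NA` (documented
#' fail-soft, routed to the rank branch).
#'
#' @param x Numeric sample, `n >= 3`.
#' @param alpha Gate level, default 0.05.
#' @return A list: `normal` (logical decision), `W`, `p_value`, `degenerate`.
#' @export
normality_gate <- function(x, alpha = 0.05) {
  x <- x[!is.na(x)]
  abort_if(length(x) < 3, "normality gate needs n >= 3.")
  if (diff(range(x)) == 0)
    return(list(normal = FALSE, W = NA_real_, p_value = NA_real_, degenerate = TRUE))
  s <- stats::shapiro.test(x)
  list(normal = s$p.value > alpha, W = unname(s$statistic),
       p_value = s$p.value, degenerate = FALSE)
}

#' Two-group comparison with automatic parametric/rank dispatch
#'
#' Compares two samples of independent hippocampi. Each sample passes
#' through the Shapiro-Wilk gate; if both look normal the unpaired Student's
#' t test (pooled variance, `df = n_a + n_b - 2`) is used, otherwise the
#' Mann-Whitney U test (midranks; exact enumeration for small tie-free
#' samples, normal approximation with continuity correction otherwise).
#' Two-tailed throughout.
#'
#' @param a,b Numeric samples, each `n >= 2` (gate needs `n >= 3`).
#' @param paired Paired comparison (default FALSE; the cohort design treats
#'   hippocampi as independent).
#' @param alpha Significance and gate level.
#' @return An `hv_test` with `method` `"student_t"` or `"mann_whitney"`;
#'   Mann-Whitney `statistic` is U for the first sample.
#' @export
compare_groups <- function(a, b, paired = FALSE, alpha = 0.05) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  abort_if(length(a) < 2 || length(b) < 2, "both samples need n >= 2.")
  normal <- length(a) >= 3 && length(b) >= 3 &&
    normality_gate(a, alpha)$normal && normality_gate(b, alpha)$normal
  if (normal) {
    tt <- stats::t.test(a, b, paired = paired, var.equal = TRUE,
                        alternative = "two.sided")
    new_hv_test("student_t", unname(tt$statistic), unname(tt$parameter),
                tt$p.value, alpha = alpha)
  } else {
    exact <- max(length(a), length(b)) <= 8 && !any(duplicated(c(a, b)))
    wt <- suppressWarnings(stats::wilcox.test(a, b, paired = paired,
                                              exact = exact, correct = TRUE,
                                              alternative = "two.sided"))
    new_hv_test("mann_whitney", unname(wt$statistic), numeric(0), wt$p.value,
                alpha = alpha)
  }
}

#' Friedman rank statistic for blocked data
#'
#' Within-block (per-hippocampus) midranks across k conditions give column
#' rank sums `R_j`; the statistic is
#' `12 / (n k (k+1)) * sum(R_j^2) - 3 n (k+1)` on `k - 1` degrees of
#' freedom, with the p-value from the chi-square approximation. When every
#' block orders the conditions identically and strictly, the statistic
#' attains its maximum `n (k - 1) * 12/(k(k+1)) * ...` — e.g. 30 for ten
#' blocks of four conditions.
#'
#' @param blocks Numeric matrix, `n` blocks (rows) by `k` conditions
#'   (columns), `n >= 2`, `k >= 2`.
#' @param alpha Significance level recorded in the result.
#' @return An `hv_test` with method `"friedman"`.
#' @export
friedman_statistic <- function(blocks, alpha = 0.05) {
  abort_if(!is.matrix(blocks) || !is.numeric(blocks), "`blocks` must be a numeric matrix.")
  abort_if(any(!is.finite(blocks)), "`blocks` contains non-finite values.")
  n <- nrow(blocks); k <- ncol(blocks)
  abort_if(n < 2 || k < 2, "need at least 2 blocks and 2 conditions.")
  ranks <- t(apply(blocks, 1, rank))           # midranks within each block
  r_sum <- colSums(ranks)
  stat <- 12 / (n * k * (k + 1)) * sum(r_sum^2) - 3 * n * (k + 1)
  df <- k - 1
  new_hv_test("friedman", stat, df, stats::pchisq(stat, df, lower.tail = FALSE),
              alpha = alpha)
}

# linear step-up (Benjamini-Hochberg) rejections at level q: returns logical
bh_reject <- function(p, q) {
  m <- length(p)
  o <- order(p)
  thresh <- seq_len(m) * q / m
  k <- suppressWarnings(max(which(p[o] <= thresh)))
  rej <- logical(m)
  if (is.finite(k) && k >= 1) rej[o[seq_len(k)]] <- TRUE
  rej
}

#' Benjamini-Krieger-Yekutieli two-stage step-up procedure
#'
#' Adaptive FDR control: stage one runs the linear step-up at
#' `q' = q / (1 + q)` and uses its rejection count `r1` to estimate the
#' number of true nulls `m0 = m - r1`; if `r1 = 0` nothing is rejected, if
#' `r1 = m` everything is; otherwise stage two reruns the step-up at level
#' `q' * m / m0`.
#'
#' @param p_values Numeric vector of raw p-values in `[0, 1]`.
#' @param q Target false-discovery rate in (0, 1), default 0.05.
#' @return A tibble `p_value, rejected` (input order) with attributes `m0`
#'   (estimated true nulls) and `stage2_level`.
#' @export
bky_two_stage <- function(p_values, q = 0.05) {
  abort_if(!is.numeric(p_values) || any(is.na(p_values)) ||
             any(p_values < 0 | p_values > 1), "p-values must lie in [0, 1].")
  abort_if(!(is.numeric(q) && length(q) == 1 && q > 0 && q < 1),
           "`q` must be in (0, 1).")
  m <- length(p_values)
  q1 <- q / (1 + q)
  r1 <- sum(bh_reject(p_values, q1))
  if (r1 == 0) {
    rej <- logical(m); m0 <- m; q2 <- q1
  } else if (r1 == m) {
    rej <- rep(TRUE, m); m0 <- 0L; q2 <- NA_real_
  } else {
    m0 <- m - r1
    q2 <- q1 * m / m0
    rej <- bh_reject(p_values, q2)
  }
  out <- tibble::tibble(p_value = p_values, rejected = rej)
  attr(out, "m0") <- m0
  attr(out, "stage2_level") <- q2
  out
}

#' One-way ANOVA with Bonferroni pairwise post hoc
#'
#' Treats the supplied groups as independent samples (the printed cohort
#' design: each quartile/range value from each hippocampus enters as its own
#' observation), reports the F statistic on `(k - 1, N - k)` degrees of
#' freedom, and runs all pairwise pooled-SD t comparisons with Bonferroni
#' adjustment.
#'
#' @param samples Named list of numeric vectors (>= 2 groups, each `n >= 2`).
#' @param alpha Significance level for the post-hoc flags.
#' @return An `hv_test` with method `"anova"`; `post_hoc` is a tibble
#'   `comparison, adjusted_p, significant`.
#' @export
anova_bonferroni <- function(samples, alpha = 0.05) {
  abort_if(!is.list(samples) || length(samples) < 2, "need >= 2 groups.")
  abort_if(any(vapply(samples, length, 1L) < 2), "each group needs n >= 2.")
  if (is.null(names(samples))) names(samples) <- paste0("g", seq_along(samples))
  values <- unlist(samples, use.names = FALSE)
  grp <- factor(rep(names(samples), lengths(samples)), levels = names(samples))
  fit <- stats::aov(values ~ grp)
  an <- stats::anova(fit)
  ph <- stats::pairwise.t.test(values, grp, p.adjust.method = "bonferroni",
                               pool.sd = TRUE)
  pm <- ph$p.value
  comps <- which(!is.na(pm), arr.ind = TRUE)
  post <- tibble::tibble(
    comparison = paste(colnames(pm)[comps[, 2]], "vs", rownames(pm)[comps[, 1]]),
    adjusted_p = pm[comps]) |>
    dplyr::mutate(significant = .data$adjusted_p < alpha)
  new_hv_test("anova", an$`F value`[1], c(an$Df[1], an$Df[2]),
              an$`Pr(>F)`[1], post_hoc = post, alpha = alpha)
}

#' Friedman omnibus with BKY-adjusted pairwise post hoc
#'
#' Rank-branch counterpart of [anova_bonferroni()] for blocked data: the
#' Friedman omnibus across conditions, then all pairwise paired Wilcoxon
#' signed-rank comparisons whose raw p-values are passed through the
#' two-stage [bky_two_stage()] step-up.
#'
#' @param blocks `n x k` numeric matrix with named columns.
#' @param alpha Omnibus level and post-hoc FDR level `q`.
#' @return An `hv_test` with method `"friedman"`; `post_hoc` has
#'   `comparison, p_value, significant` (significance = BKY rejection).
#' @export
friedman_bky <- function(blocks, alpha = 0.05) {
  omni <- friedman_statistic(blocks, alpha = alpha)
  k <- ncol(blocks)
  if (is.null(colnames(blocks))) colnames(blocks) <- paste0("c", seq_len(k))
  pairs <- utils::combn(k, 2)
  raw <- apply(pairs, 2, function(ij) {
    suppressWarnings(stats::wilcox.test(blocks[, ij[1]], blocks[, ij[2]],
                                        paired = TRUE, exact = FALSE,
                                        correct = TRUE)$p.value)
  })
  dec <- bky_two_stage(raw, q = alpha)
  omni$post_hoc <- tibble::tibble(
    comparison = paste(colnames(blocks)[pairs[1, ]], "vs", colnames(blocks)[pairs[2, ]]),
    p_value = raw, significant = dec$rejected)
  omni
}

#' Run the full cohort comparison grid
#'
#' Executes the cohort workflow on a tidy table of per-hippocampus values:
#' within each group, values are compared across levels (quartiles or VVF
#' ranges) — one-way ANOVA with Bonferroni post hoc when every level sample
#' passes the Shapiro-Wilk gate, otherwise the Friedman test with
#' Benjamini-Krieger-Yekutieli post hoc on per-hippocampus blocks; between
#' groups, each level is compared with [compare_groups()] (Student's t or
#' Mann-Whitney by the same gate). All tests are two-tailed at `alpha`.
#'
#' @param table Tibble with columns
#'   `mouse_id, group, hemisphere, measure, level, value` (as produced by
#'   [gen_cohort()] or the pipeline); exactly two groups.
#' @param alpha Significance level, default 0.05.
#' @return A tidy tibble, one row per omnibus test or post-hoc/between-group
#'   comparison: `scope, comparison, method, statistic, df1, df2, p_value,
#'   adjusted_p, significant`.
#' @export
run_cohort_analysis <- function(table, alpha = 0.05) {
  need <- c("mouse_id", "group", "hemisphere", "measure", "level", "value")
  abort_if(!all(need %in% names(table)),
           paste("table needs columns:", paste(need, collapse = ", ")))
  groups <- unique(table$group)
  abort_if(length(groups) != 2, "expected exactly two groups.")
  levels_ <- unique(table$level)
  abort_if(length(levels_) < 2, "need at least two levels.")
  n_hemi <- table |> dplyr::distinct(.data$group, .data$mouse_id, .data$hemisphere) |>
    dplyr::count(.data$group, .data$mouse_id)
  abort_if(any(n_hemi$n < 2), "each mouse must contribute both hemispheres.")

  rows <- list()
  for (g in groups) {
    sub <- dplyr::filter(table, .data$group == g)
    by_level <- split(sub$value, factor(sub$level, levels = levels_))
    all_normal <- all(vapply(by_level, function(v) normality_gate(v, alpha)$normal, TRUE))
    if (all_normal) {
      res <- anova_bonferroni(by_level, alpha = alpha)
    } else {
      wide <- sub |>
        dplyr::select("mouse_id", "hemisphere", "level", "value") |>
        tidyr::pivot_wider(names_from = "level", values_from = "value")
      blocks <- as.matrix(wide[, levels_, drop = FALSE])
      abort_if(any(is.na(blocks)), "incomplete blocks for the Friedman branch.")
      res <- friedman_bky(blocks, alpha = alpha)
    }
    rows[[length(rows) + 1]] <- tibble::tibble(
      scope = paste0("within_", g), comparison = "omnibus", method = res$method,
      statistic = res$statistic, df1 = res$df[1],
      df2 = ifelse(length(res$df) > 1, res$df[2], NA_real_),
      p_value = res$p_value, adjusted_p = NA_real_,
      significant = res$p_value < alpha)
    ph <- res$post_hoc
    padj <- if ("adjusted_p" %in% names(ph)) ph$adjusted_p else ph$p_value
    rows[[length(rows) + 1]] <- tibble::tibble(
      scope = paste0("within_", g), comparison = ph$comparison,
      method = paste0(res$method, "_posthoc"), statistic = NA_real_,
      df1 = NA_real_, df2 = NA_real_, p_value = NA_real_,
      adjusted_p = padj, significant = ph$significant)
  }
  for (lv in levels_) {
    a <- table$value[table$group == groups[1] & table$level == lv]
    b <- table$value[table$group == groups[2] & table$level == lv]
    res <- compare_groups(a, b, alpha = alpha)
    rows[[length(rows) + 1]] <- tibble::tibble(
      scope = paste0("between_", groups[1], "_", groups[2]), comparison = lv,
      method = res$method, statistic = res$statistic,
      df1 = ifelse(length(res$df) >= 1, res$df[1], NA_real_), df2 = NA_real_,
      p_value = res$p_value, adjusted_p = NA_real_,
      significant = res$p_value < alpha)
  }
  purrr::list_rbind(rows)
}
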