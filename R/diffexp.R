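#' Pooled-variance two-sample t-test
#'
#' Classical equal-variance two-sample t with df = nA + nB - 2 and a
#' two-sided p-value. Degenerate conventions for zero pooled variance:
#' p = 1 when the group means are equal, p = 0 when they differ (the
#' groups are then perfectly separated point masses).
#'
#' @param x,y Numeric vectors, at least 2 values each.
#' @return One-row tibble: `statistic` (t, sign of `mean(x) - mean(y)`),
#'   `df`, `p_value`.
#' @export
pooled_t_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) {
    stop("need at least 2 values per group", call. = FALSE)
  }
  nx <- length(x); ny <- length(y)
  df <- nx + ny - 2
  delta <- mean(x) - mean(y)
  sp2 <- ((nx - 1) * stats::var(x) + (ny - 1) * stats::var(y)) / df
  if (sp2 == 0) {
    return(tibble::tibble(statistic = if (delta == 0) 0 else sign(delta) * Inf,
                          df = df, p_value = if (delta == 0) 1 else 0))
  }
  t_stat <- delta / sqrt(sp2 * (1 / nx + 1 / ny))
  tibble::tibble(statistic = t_stat, df = df,
                 p_value = 2 * stats::pt(-abs(t_stat), df = df))
}

#' Exact Wilcoxon rank-sum test by full enumeration
#'
#' Computes the rank-sum W of the first group (midranks for ties) and its
#' exact two-sided p-value by enumerating all `choose(nA + nB, nA)`
#' assignments of the observed pooled values to groups. Because ties are
#' handled by midranks on the observed pooled sample, the null
#' distribution is conditional on the observed values, so the test is
#' exact even with ties. The two-sided p doubles the smaller tail:
#' `min(1, 2 * min(P(W <= w), P(W >= w)))`.
#'
#' For tie-free 3 vs 3 data the most extreme assignment has probability
#' 2/20, so the smallest attainable two-sided p is exactly 0.1 — at or
#' below the floor used to call differential expression, which is why raw
#' (unadjusted) p-values are the natural choice with this test at n = 3
#' (see [call_de()]).
#'
#' @param x,y Numeric vectors, 3 to 8 values each (enumeration bound).
#' @return One-row tibble: `statistic` (rank-sum of `x`), `p_value`
#'   (exact two-sided).
#' @export
#' @examples
#' wilcoxon_exact(c(1, 2, 3), c(4, 5, 6)) # p = 0.1
wilcoxon_exact <- function(x, y) {
  nx <- length(x); ny <- length(y)
  if (nx < 3L || ny < 3L || nx > 8L || ny > 8L) {
    stop("exact enumeration supports 3-8 values per group; ",
         "use a normal-approximation test for larger groups", call. = FALSE)
  }
  pooled <- c(x, y)
  ranks <- rank(pooled) # midranks for ties
  w_obs <- sum(ranks[seq_len(nx)])
  assignments <- utils::combn(nx + ny, nx)
  w_all <- colSums(matrix(ranks[assignments], nrow = nx))
  eps <- 1e-9
  p_le <- mean(w_all <= w_obs + eps)
  p_ge <- mean(w_all >= w_obs - eps)
  tibble::tibble(statistic = w_obs,
                 p_value = min(1, 2 * min(p_le, p_ge)))
}

#' Per-gene two-group differential expression
#'
#' Applies [pooled_t_test()] or [wilcoxon_exact()] to every gene,
#' comparing the miRNA-overexpression condition against the control.
#' The log2 fold change is the difference of group means (expression is
#' assumed log2-scale), and direction follows its sign: `"down"` means
#' lower in the overexpression condition.
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param conditions Tibble (`sample`, `condition`).
#' @param test `"wrs"` (exact rank-sum, default) or `"t"` (pooled t).
#' @param treatment,control Condition labels; `log2fc = mean(treatment) -
#'   mean(control)`.
#' @return Tibble: `gene`, `test`, `statistic`, `p_raw`, `log2fc`,
#'   `direction` (`"up"`/`"down"`; ties in means give `"up"` with
#'   `log2fc = 0`).
#' @export
run_diffexp <- function(expr, conditions, test = c("wrs", "t"),
                        treatment = "mir142", control = "null") {
  test <- match.arg(test)
  s_trt <- conditions$sample[conditions$condition == treatment]
  s_ctl <- conditions$sample[conditions$condition == control]
  if (length(s_trt) < 2L || length(s_ctl) < 2L) {
    stop("need at least 2 samples in each condition", call. = FALSE)
  }
  trt <- as.matrix(expr[s_trt])
  ctl <- as.matrix(expr[s_ctl])
  fun <- if (test == "wrs") wilcoxon_exact else pooled_t_test
  res <- purrr::map_dfr(seq_len(nrow(expr)), function(i) {
    fun(trt[i, ], ctl[i, ])[c("statistic", "p_value")]
  })
  tibble::tibble(
    gene = expr$gene,
    test = test,
    statistic = res$statistic,
    p_raw = res$p_value,
    log2fc = rowMeans(trt) - rowMeans(ctl)
  ) |>
    dplyr::mutate(direction = ifelse(.data$log2fc < 0, "down", "up"))
}

#' Call differentially expressed genes
#'
#' Adjusts the raw p-values (Benjamini-Hochberg FDR by default) and flags
#' genes at `p_adj <= alpha`. With the exact 3 vs 3 rank-sum test every
#' p-value sits at or above the enumeration floor of 0.1, so BH
#' adjustment at alpha = 0.1 can only call genes if essentially all tests
#' are at the floor; `adjust = "none"` makes the raw-p convention
#' explicit for that design.
#'
#' @param de Tibble from [run_diffexp()].
#' @param alpha Significance threshold on the adjusted p-value
#'   (default 0.1).
#' @param adjust `"BH"` or `"none"`.
#' @return `de` with `p_adj` and logical `significant` columns; the
#'   numbers of up- and downregulated calls are stored in the
#'   `n_up`/`n_down` attributes.
#' @export
call_de <- function(de, alpha = 0.1, adjust = c("BH", "none")) {
  adjust <- match.arg(adjust)
  out <- de |>
    dplyr::mutate(
      p_adj = if (adjust == "none") .data$p_raw else
        adjust_pvalues(.data$p_raw, method = "BH"),
      significant = .data$p_adj <= alpha
    )
  attr(out, "n_up") <- sum(out$significant & out$direction == "up")
  attr(out, "n_down") <- sum(out$significant & out$direction == "down")
  out
}
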