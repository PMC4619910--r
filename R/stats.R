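#' Pearson chi-square test of independence
#'
#' Computes the Pearson statistic sum((O - E)^2 / E) on a labeled integer
#' contingency table, with expected counts from the row/column margins,
#' no continuity correction, df = (rows - 1) * (cols - 1) and an
#' upper-tail chi-square p-value. (For df = 2 the p-value has the closed
#' form exp(-chi2 / 2).)
#'
#' @param table Integer matrix (>= 2x2), ideally with dimnames; or a
#'   data frame whose first column holds row labels.
#' @return A `coex_chisq` object with elements `table`, `statistic`,
#'   `df`, `p_value`, `expected`; see [tidy.coex_chisq()] /
#'   [glance.coex_chisq()].
#' @export
#' @examples
#' chisq_independence(matrix(c(15, 3, 0, 14, 15, 13), nrow = 3))
chisq_independence <- function(table) {
  if (is.data.frame(table)) {
    labels <- as.character(table[[1]])
    table <- as.matrix(table[-1])
    rownames(table) <- labels
  }
  if (!is.matrix(table) || nrow(table) < 2L || ncol(table) < 2L) {
    stop("need a matrix with at least 2 rows and 2 columns", call. = FALSE)
  }
  if (any(table < 0) || any(table != round(table))) {
    stop("table must contain nonnegative integer counts", call. = FALSE)
  }
  rs <- rowSums(table); cs <- colSums(table)
  if (any(rs == 0) || any(cs == 0)) {
    stop("zero row or column margin: statistic undefined", call. = FALSE)
  }
  expected <- outer(rs, cs) / sum(table)
  stat <- sum((table - expected)^2 / expected)
  df <- (nrow(table) - 1L) * (ncol(table) - 1L)
  structure(
    list(table = table, statistic = stat, df = df,
         p_value = stats::pchisq(stat, df = df, lower.tail = FALSE),
         expected = expected),
    class = "coex_chisq"
  )
}

#' @export
print.coex_chisq <- function(x, ...) {
  cat("Pearson chi-square test of independence\n")
  cat(sprintf("  X-squared = %.4f, df = %d, p-value = %.4g\n",
              x$statistic, x$df, x$p_value))
  invisible(x)
}

#' @rdname chisq_independence
#' @param x A `coex_chisq` object.
#' @param ... Unused.
#' @method tidy coex_chisq
#' @export
tidy.coex_chisq <- function(x, ...) {
  tibble::tibble(statistic = x$statistic, df = x$df, p_value = x$p_value,
                 method = "Pearson chi-square (no continuity correction)")
}

#' @rdname chisq_independence
#' @method glance coex_chisq
#' @export
glance.coex_chisq <- function(x, ...) tidy(x)[c("statistic", "df", "p_value")]

#' Fisher z-transform of a correlation coefficient
#'
#' The variance-stabilising transform `0.5 * log((1 + rho) / (1 - rho))`
#' (artanh), used in power and sample-size calculations for detecting a
#' correlation.
#'
#' @param rho Correlation value(s), strictly inside (-1, 1).
#' @return Transformed value(s).
#' @export
#' @examples
#' fisher_z(0.9998) # ~4.605
fisher_z <- function(rho) {
  if (any(abs(rho) >= 1)) stop("|rho| must be < 1", call. = FALSE)
  0.5 * log((1 + rho) / (1 - rho))
}

#' Sample size to detect a correlation
#'
#' The classical Fisher-z sample-size formula for testing rho = 0 against
#' a target correlation: `n = ((z_alpha + z_beta) / fisher_z(rho))^2 + 3`.
#' At rho = 0.9998, alpha = 0.01 (one-sided) and power 0.8 the formula
#' value is ~3.47: rounding to the nearest integer admits the three
#' replicates per condition of the study design, while ceiling would ask
#' for four. Both conventions are exposed because published sample-size
#' calculators differ; neither is asserted as canonical.
#'
#' @param rho Target correlation, in (0, 1).
#' @param alpha Significance level.
#' @param power Desired power (1 - beta).
#' @param sided `"one"` or `"two"`: whether `alpha` is split across tails.
#' @param rounding `"ceiling"` (conservative) or `"round"` (nearest).
#' @return One-row tibble: `rho`, `alpha`, `power`, `sided`, `z_alpha`,
#'   `z_beta`, `c_rho` (the Fisher z of rho), `n_raw` (unrounded formula
#'   value), `rounding`, `n`.
#' @export
#' @examples
#' sample_size_correlation(0.9998, alpha = 0.01, power = 0.8,
#'                         sided = "one", rounding = "round")
sample_size_correlation <- function(rho, alpha = 0.01, power = 0.8,
                                    sided = c("one", "two"),
                                    rounding = c("ceiling", "round")) {
  sided <- match.arg(sided)
  rounding <- match.arg(rounding)
  if (rho <= 0 || rho >= 1) stop("rho must lie in (0, 1)", call. = FALSE)
  if (alpha <= 0 || alpha >= 1 || power <= 0 || power >= 1) {
    stop("alpha and power must lie in (0, 1)", call. = FALSE)
  }
  z_alpha <- stats::qnorm(1 - if (sided == "one") alpha else alpha / 2)
  z_beta <- stats::qnorm(power)
  c_rho <- fisher_z(rho)
  n_raw <- ((z_alpha + z_beta) / c_rho)^2 + 3
  tibble::tibble(
    rho = rho, alpha = alpha, power = power, sided = sided,
    z_alpha = z_alpha, z_beta = z_beta, c_rho = c_rho, n_raw = n_raw,
    rounding = rounding,
    n = if (rounding == "ceiling") ceiling(n_raw) else round(n_raw)
  )
}

ref_table <- function(file) {
  path <- system.file("extdata", file, package = "coexmir", mustWork = TRUE)
  tibble::as_tibble(utils::read.delim(path, check.names = FALSE))
}

#' Reference count tables from the miR-142 overexpression study
#'
#' Published gene counts from a microarray study of miR-142
#' overexpression in neuronal cells (3 miR-null vs 3 miR-142 replicates),
#' shipped as plain-text fixtures. They let the contingency-table and
#' network-arithmetic statistics be reproduced without the underlying
#' expression data:
#'
#' * `de_seed_counts`: differentially expressed genes (BH-adjusted
#'   p <= 0.1) cross-tabulated by seed-mapping class (exact/inexact,
#'   per arm) and direction (down/up). 63 of the 85 DE genes carry a
#'   seed site.
#' * `network_seed_counts`: seed-mapped node counts per coexpression
#'   network (miR-null, miR-142) and genome-wide, by class.
#' * `network_sizes`: node and edge counts of the two condition networks.
#'
#' @return Named list of three tibbles.
#' @export
#' @examples
#' mir142_reference_counts()$network_sizes
mir142_reference_counts <- function() {
  list(
    de_seed_counts = ref_table("mir142_de_seed_counts.tsv"),
    network_seed_counts = ref_table("mir142_network_seed_counts.tsv"),
    network_sizes = ref_table("mir142_network_sizes.tsv")
  )
}

#' Arm-by-outcome contingency tables from the reference counts
#'
#' Collapses the reference tables to the two 3x2 tables whose Pearson
#' chi-square statistics summarise the study:
#'
#' * `de_by_arm()`: rows 5p / 3p / both (exact + inexact mapping summed
#'   per arm), columns down / up — does either arm's targeting prefer a
#'   regulation direction among DE genes?
#' * `network_mapping_by_arm()`: rows 5p / 3p / both, columns exact /
#'   inexact, node counts summed over both condition networks — is match
#'   quality independent of arm among network nodes?
#'
#' @return Integer matrix with dimnames, ready for
#'   [chisq_independence()].
#' @export
de_by_arm <- function() {
  counts <- mir142_reference_counts()$de_seed_counts
  collapse_by_arm(counts, c("down", "up"))
}

#' @rdname de_by_arm
#' @export
network_mapping_by_arm <- function() {
  counts <- mir142_reference_counts()$network_seed_counts
  wide <- counts |>
    dplyr::mutate(n = .data$mir_null + .data$mir_142) |>
    dplyr::select("arm", "quality", "n") |>
    tidyr::pivot_wider(names_from = "quality", values_from = "n")
  m <- as.matrix(wide[c("exact", "inexact")])
  rownames(m) <- wide$arm
  m
}

collapse_by_arm <- function(counts, value_cols) {
  collapsed <- counts |>
    dplyr::group_by(.data$arm) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(value_cols), sum),
                     .groups = "drop") |>
    dplyr::arrange(match(.data$arm, c("5p", "3p", "both")))
  m <- as.matrix(collapsed[value_cols])
  rownames(m) <- collapsed$arm
  m
}
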