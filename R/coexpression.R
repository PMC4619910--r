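#' Two-sided p-value for a Pearson correlation
#'
#' Uses the exact null distribution of r for bivariate normal data:
#' t = r * sqrt((n - 2) / (1 - r^2)) referred to a t distribution with
#' n - 2 degrees of freedom. With three samples per condition df = 1, so
#' the smallest attainable two-sided p at r = 0.9998 is about 0.0127 —
#' the reason genome-wide adjusted-p edge selection is essentially
#' impossible at n = 3 (see the `r-threshold` mode of [build_network()]).
#' `|r| = 1` returns p = 0 by convention.
#'
#' @param r Correlation coefficient(s) in \[-1, 1\].
#' @param n Number of samples (>= 3).
#' @return Two-sided p-value(s), same length as `r`.
#' @export
cor_pvalue <- function(r, n) {
  if (any(n < 3)) stop("need at least 3 samples for a correlation p-value",
                       call. = FALSE)
  if (any(abs(r) > 1 + 1e-12, na.rm = TRUE)) stop("|r| must be <= 1", call. = FALSE)
  r <- pmin(1, pmax(-1, r))
  p <- rep(0, length(r))
  ok <- abs(r) < 1
  t_stat <- r[ok] * sqrt((n - 2) / (1 - r[ok]^2))
  p[ok] <- 2 * stats::pt(-abs(t_stat), df = n - 2)
  p
}

#' All-pairs Pearson correlation within one condition
#'
#' Computes the Pearson correlation for every unordered gene pair using
#' only the samples of one condition, together with its two-sided p-value
#' ([cor_pvalue()]). Genes with zero variance within the condition have no
#' defined correlation and are dropped with a warning; the number dropped
#' is recorded in the `dropped_genes` attribute.
#'
#' @param expr Expression tibble: first column `gene`, one column per
#'   sample (log2-scale values).
#' @param conditions Tibble (`sample`, `condition`) mapping samples to
#'   condition labels.
#' @param condition Condition label to use.
#' @return Tibble (`gene_a`, `gene_b`, `r`, `p_raw`) with
#'   `gene_a < gene_b` lexicographically; `choose(G, 2)` rows over the G
#'   retained genes.
#' @export
pearson_pairs <- function(expr, conditions, condition) {
  samples <- conditions$sample[conditions$condition == condition]
  if (length(samples) < 3L) {
    stop("condition '", condition, "' has fewer than 3 samples", call. = FALSE)
  }
  missing <- setdiff(samples, names(expr))
  if (length(missing) > 0L) {
    stop("samples absent from expression matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  mat <- as.matrix(expr[samples])
  rownames(mat) <- expr$gene
  vars <- apply(mat, 1, stats::var)
  dropped <- rownames(mat)[vars == 0]
  if (length(dropped) > 0L) {
    warning(length(dropped), " zero-variance gene(s) dropped in condition '",
            condition, "'", call. = FALSE)
    mat <- mat[vars > 0, , drop = FALSE]
  }
  g <- nrow(mat)
  ord <- order(rownames(mat))
  mat <- mat[ord, , drop = FALSE]
  if (g < 2L) {
    out <- tibble::tibble(gene_a = character(), gene_b = character(),
                          r = double(), p_raw = double())
  } else {
    cm <- stats::cor(t(mat))
    ut <- upper.tri(cm)
    idx <- which(ut, arr.ind = TRUE)
    out <- tibble::tibble(
      gene_a = rownames(mat)[idx[, "row"]],
      gene_b = rownames(mat)[idx[, "col"]],
      r = cm[ut],
      p_raw = cor_pvalue(cm[ut], n = length(samples))
    ) |>
      dplyr::arrange(.data$gene_a, .data$gene_b)
  }
  attr(out, "dropped_genes") <- dropped
  attr(out, "n_samples") <- length(samples)
  out
}

#' Adjust p-values for multiple testing
#'
#' Validated front end to [stats::p.adjust()] for the four procedures used
#' here: Bonferroni, Holm (step-down), Hochberg (step-up) and
#' Benjamini-Hochberg FDR (step-up). All outputs are capped at 1 and are
#' never smaller than the raw p-values.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @param method One of `"BH"`, `"holm"`, `"hochberg"`, `"bonferroni"`.
#' @return Adjusted p-values, same length and order as `p`.
#' @export
adjust_pvalues <- function(p, method = c("BH", "holm", "hochberg", "bonferroni")) {
  method <- match.arg(method)
  if (any(p < 0 | p > 1, na.rm = TRUE)) {
    stop("p-values must lie in [0, 1]", call. = FALSE)
  }
  stats::p.adjust(p, method = method)
}

#' Build a condition-specific coexpression network
#'
#' Turns an all-pairs correlation table into an undirected simple graph:
#' nodes are genes, edges are retained gene pairs carrying `r`, `p_raw`
#' and `p_adj`. Only positive correlations are ever retained, modelling
#' coexpression as a positive effect. Two retention modes:
#'
#' * `"r-threshold"` (default): keep pairs with `r >= r_min`. The default
#'   `r_min = 0.9998` is the minimum retained correlation observed in the
#'   miR-142 overexpression study this package models; at three samples
#'   per group it is also the correlation at which a Fisher-z power
#'   calculation at alpha = 0.01 / power 0.8 admits n = 3
#'   ([sample_size_correlation()]).
#' * `"adjusted-p"`: keep pairs with `p_adj <= alpha` after adjusting
#'   `p_raw` with `method`.
#'
#' Nodes are the genes incident to at least one retained edge, so every
#' node has degree >= 1.
#'
#' @param pairs Tibble from [pearson_pairs()].
#' @param mode `"r-threshold"` or `"adjusted-p"`.
#' @param r_min Minimum retained correlation for `r-threshold` mode,
#'   in (0, 1].
#' @param alpha Significance level for `adjusted-p` mode, in (0, 1).
#' @param method Adjustment method for `adjusted-p` mode
#'   (see [adjust_pvalues()]).
#' @param condition Condition label stored on the network.
#' @return A `coex_network` object: list with `condition`, `mode`,
#'   `edges` (tibble `gene_a`, `gene_b`, `r`, `p_raw`, `p_adj`), `nodes`
#'   (sorted character vector) and `r_min_retained` (minimum r among
#'   retained edges; `NA` if none).
#' @export
build_network <- function(pairs, mode = c("r-threshold", "adjusted-p"),
                          r_min = 0.9998, alpha = 0.01, method = "bonferroni",
                          condition = NA_character_) {
  mode <- match.arg(mode)
  stopifnot(all(c("gene_a", "gene_b", "r", "p_raw") %in% names(pairs)))
  if (mode == "r-threshold") {
    if (!is.numeric(r_min) || r_min <= 0 || r_min > 1) {
      stop("`r_min` must lie in (0, 1]", call. = FALSE)
    }
  } else {
    if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1) {
      stop("`alpha` must lie in (0, 1)", call. = FALSE)
    }
  }
  edges <- pairs |>
    dplyr::mutate(p_adj = adjust_pvalues(.data$p_raw, method = method)) |>
    dplyr::arrange(.data$p_raw, .data$gene_a, .data$gene_b)
  edges <- if (mode == "r-threshold") {
    dplyr::filter(edges, .data$r >= r_min)
  } else {
    dplyr::filter(edges, .data$p_adj <= alpha)
  }
  edges <- edges |>
    dplyr::filter(.data$r > 0) |>
    dplyr::arrange(.data$gene_a, .data$gene_b)
  structure(
    list(
      condition = condition,
      mode = mode,
      params = if (mode == "r-threshold") list(r_min = r_min) else
        list(alpha = alpha, method = method),
      edges = edges,
      nodes = sort(unique(c(edges$gene_a, edges$gene_b))),
      r_min_retained = if (nrow(edges) > 0) min(edges$r) else NA_real_
    ),
    class = "coex_network"
  )
}

#' @export
print.coex_network <- function(x, ...) {
  cat("<coex_network>", if (!is.na(x$condition)) paste0("condition: ", x$condition),
      "\n  mode:", x$mode, "\n  nodes:", length(x$nodes),
      " edges:", nrow(x$edges),
      "\n  min retained r:", format(x$r_min_retained, digits = 6), "\n")
  invisible(x)
}

#' Edge density of a simple undirected graph
#'
#' @param n_nodes,n_edges Node and edge counts.
#' @return `n_edges / choose(n_nodes, 2)`; 0 (with nothing to normalise)
#'   when fewer than two nodes.
#' @export
#' @examples
#' edge_density(57, 217) # 0.136 to 3 decimals
edge_density <- function(n_nodes, n_edges) {
  possible <- n_nodes * (n_nodes - 1) / 2
  ifelse(possible > 0, n_edges / possible, 0)
}

#' Node/edge/density summary of a network
#'
#' @param network A `coex_network`.
#' @return One-row tibble: `condition`, `n_nodes`, `n_edges`, `density`,
#'   `density_defined` (FALSE for networks with < 2 nodes, where density
#'   is reported as 0), `r_min_retained`.
#' @export
network_stats <- function(network) {
  stopifnot(inherits(network, "coex_network"))
  n <- length(network$nodes)
  e <- nrow(network$edges)
  tibble::tibble(
    condition = network$condition,
    n_nodes = n,
    n_edges = e,
    density = edge_density(n, e),
    density_defined = n >= 2,
    r_min_retained = network$r_min_retained
  )
}

edge_keys <- function(net) {
  if (nrow(net$edges) == 0L) return(character())
  paste(pmin(net$edges$gene_a, net$edges$gene_b),
        pmax(net$edges$gene_a, net$edges$gene_b), sep = "\r")
}

jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0L) return(NA_real_)
  length(intersect(a, b)) / u
}

#' Compare two condition networks
#'
#' Reports shared nodes and edges and the corresponding Jaccard indices;
#' symmetric in its arguments. For the miR-142 study design the two
#' condition networks are expected to be fully disjoint.
#'
#' @param net_a,net_b `coex_network` objects over a common gene universe.
#' @return One-row tibble: `shared_nodes`, `shared_edges`, `node_jaccard`,
#'   `edge_jaccard` (Jaccard is `NA` when both networks are empty).
#' @export
compare_networks <- function(net_a, net_b) {
  stopifnot(inherits(net_a, "coex_network"), inherits(net_b, "coex_network"))
  ka <- edge_keys(net_a); kb <- edge_keys(net_b)
  tibble::tibble(
    shared_nodes = length(intersect(net_a$nodes, net_b$nodes)),
    shared_edges = length(intersect(ka, kb)),
    node_jaccard = jaccard(net_a$nodes, net_b$nodes),
    edge_jaccard = jaccard(ka, kb)
  )
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a coexpression network into its edge list
#'
#' @param x A `coex_network`.
#' @param ... Unused.
#' @return The edge tibble (`gene_a`, `gene_b`, `r`, `p_raw`, `p_adj`).
#' @method tidy coex_network
#' @export
tidy.coex_network <- function(x, ...) x$edges

#' One-row network summary
#'
#' @param x A `coex_network`.
#' @param ... Unused.
#' @return See [network_stats()].
#' @method glance coex_network
#' @export
glance.coex_network <- function(x, ...) network_stats(x)
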