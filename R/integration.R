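COLOR_KEYS <- c(
  "exact-5p" = "dark-red", "inexact-5p" = "pink",
  "exact-3p" = "dark-green", "inexact-3p" = "light-green",
  "inexact-both" = "blue", "none" = "plain",
  "exact-both" = "dark-red+dark-green"
)
SHAPE_KEYS <- c(down = "down-arrow", up = "up-arrow", ns = "ellipse")

#' Annotate network nodes with seed class and DE status
#'
#' Joins the per-gene seed classification and the differential-expression
#' calls onto the union of the two condition networks' node sets, and
#' attaches the Cytoscape-style visual encoding: node colour keyed by
#' seed class (dark-red = exact 5p, pink = inexact 5p, dark-green =
#' exact 3p, light-green = inexact 3p, blue = inexact both, plain =
#' none) and node shape keyed by DE direction (down-arrow / up-arrow /
#' ellipse for not significant).
#'
#' @param networks Named list of `coex_network` objects (typically
#'   `list(null = ..., mir142 = ...)`).
#' @param classes Tibble (`gene`, `seed_class`) from [classify_genes()].
#'   Genes missing from it default to class `"none"`.
#' @param de_calls Tibble from [call_de()]. Genes missing from it, or
#'   present but not significant, get `de_status = "ns"`.
#' @return Tibble with one row per gene in either network: `gene`,
#'   `seed_class`, `de_status`, `log2fc`, one logical `in_<name>` column
#'   per network, `color_key`, `shape_key`.
#' @export
annotate_networks <- function(networks, classes, de_calls = NULL) {
  stopifnot(is.list(networks), length(networks) >= 1L,
            !is.null(names(networks)))
  if (anyDuplicated(classes$gene)) {
    stop("duplicate gene records in `classes`", call. = FALSE)
  }
  genes <- sort(unique(unlist(lapply(networks, function(n) n$nodes))))
  out <- tibble::tibble(gene = genes) |>
    dplyr::left_join(
      dplyr::mutate(classes, seed_class = as.character(.data$seed_class)),
      by = "gene") |>
    dplyr::mutate(seed_class = dplyr::coalesce(.data$seed_class, "none"))
  if (!is.null(de_calls)) {
    if (anyDuplicated(de_calls$gene)) {
      stop("duplicate gene records in `de_calls`", call. = FALSE)
    }
    de_min <- de_calls |>
      dplyr::transmute(.data$gene, .data$log2fc,
                       de_status = ifelse(.data$significant,
                                          .data$direction, "ns"))
    out <- dplyr::left_join(out, de_min, by = "gene")
  } else {
    out$de_status <- NA_character_
    out$log2fc <- NA_real_
  }
  out <- dplyr::mutate(out, de_status = dplyr::coalesce(.data$de_status, "ns"))
  for (nm in names(networks)) {
    out[[paste0("in_", nm)]] <- out$gene %in% networks[[nm]]$nodes
  }
  dplyr::mutate(out,
                color_key = unname(COLOR_KEYS[.data$seed_class]),
                shape_key = unname(SHAPE_KEYS[.data$de_status]))
}

#' Select triad genes: in-network, seed-mapped and downregulated
#'
#' The study's highlight criterion: genes simultaneously (1) present in
#' the overexpression-condition coexpression network, (2) carrying any
#' seed site, and (3) called downregulated. In the original data this
#' conjunction singles out TEAD2, PLEKHA6 and (under the rank-sum test)
#' POGLUT1.
#'
#' @param annotated Tibble from [annotate_networks()].
#' @param condition Network name whose membership is required
#'   (default `"mir142"`).
#' @return Character vector of gene ids, sorted.
#' @export
select_triad <- function(annotated, condition = "mir142") {
  col <- paste0("in_", condition)
  if (!col %in% names(annotated)) {
    stop("no network membership column for condition '", condition, "'",
         call. = FALSE)
  }
  sort(annotated$gene[annotated[[col]] &
                        annotated$seed_class != "none" &
                        annotated$de_status == "down"])
}

#' Seed-mapping counts per network
#'
#' Cross-tabulates annotated nodes by seed class and network membership:
#' one row per mapped class (exact/inexact x 5p/3p/both), one count
#' column per network, plus a summary row set giving each network's
#' mapped-node fraction.
#'
#' @param annotated Tibble from [annotate_networks()].
#' @return List with `counts` (tibble `seed_class` x per-network counts)
#'   and `fractions` (tibble `network`, `n_nodes`, `n_mapped`,
#'   `fraction_mapped`).
#' @export
summarize_mapping <- function(annotated) {
  nets <- sub("^in_", "", grep("^in_", names(annotated), value = TRUE))
  counts <- tibble::tibble(
    seed_class = factor(setdiff(SEED_CLASSES, "none"),
                        levels = setdiff(SEED_CLASSES, "none")))
  fractions <- purrr::map_dfr(nets, function(nm) {
    members <- annotated[annotated[[paste0("in_", nm)]], ]
    tibble::tibble(network = nm, n_nodes = nrow(members),
                   n_mapped = sum(members$seed_class != "none"),
                   fraction_mapped = ifelse(nrow(members) > 0,
                                            sum(members$seed_class != "none") /
                                              nrow(members), NA_real_))
  })
  for (nm in nets) {
    members <- annotated[annotated[[paste0("in_", nm)]], ]
    counts[[nm]] <- vapply(as.character(counts$seed_class), function(cl) {
      sum(members$seed_class == cl)
    }, integer(1), USE.NAMES = FALSE)
  }
  list(counts = counts, fractions = fractions)
}

#' Export a network as a Cytoscape SIF file
#'
#' One `geneA coexp geneB` line per edge (tab-separated); isolated nodes
#' cannot occur because every network node has degree >= 1.
#'
#' @param network A `coex_network`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_sif <- function(network, path) {
  stopifnot(inherits(network, "coex_network"))
  lines <- sprintf("%s\tcoexp\t%s", network$edges$gene_a, network$edges$gene_b)
  writeLines(lines, path)
  invisible(path)
}

#' Export node attributes for Cytoscape
#'
#' Tab-separated table of the visual encoding produced by
#' [annotate_networks()].
#'
#' @param annotated Tibble from [annotate_networks()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_node_attributes <- function(annotated, path) {
  cols <- c("gene", "seed_class", "color_key", "de_status", "shape_key",
            "log2fc")
  utils::write.table(annotated[intersect(cols, names(annotated))], path,
                     sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

as_igraph <- function(network, annotated = NULL) {
  g <- igraph::graph_from_data_frame(
    network$edges[c("gene_a", "gene_b", "r", "p_adj")],
    directed = FALSE,
    vertices = data.frame(name = network$nodes)
  )
  if (!is.null(annotated)) {
    idx <- match(igraph::V(g)$name, annotated$gene)
    for (col in c("seed_class", "color_key", "de_status", "shape_key")) {
      if (col %in% names(annotated)) {
        g <- igraph::set_vertex_attr(g, col, value = annotated[[col]][idx])
      }
    }
  }
  g
}

#' Export a network as GraphML
#'
#' Richer Cytoscape-compatible export carrying the edge correlation and
#' the node visual attributes.
#'
#' @param network A `coex_network`.
#' @param path Output file.
#' @param annotated Optional tibble from [annotate_networks()].
#' @return `path`, invisibly.
#' @export
write_graphml <- function(network, path, annotated = NULL) {
  igraph::write_graph(as_igraph(network, annotated), path, format = "graphml")
  invisible(path)
}
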