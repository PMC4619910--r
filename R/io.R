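#' Read a gene expression matrix from TSV
#'
#' Expects a header row of sample ids, a first column of unique gene ids
#' and an all-numeric body with no missing values; violations are
#' rejected with the offending genes/cells named.
#'
#' @param path TSV file, first column `gene`.
#' @return Tibble: `gene` + one numeric column per sample.
#' @export
read_expression_tsv <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE,
                          colClasses = "character")
  if (ncol(df) < 2L) stop("expression TSV needs gene + sample columns",
                          call. = FALSE)
  names(df)[1] <- "gene"
  dup <- unique(df$gene[duplicated(df$gene)])
  if (length(dup) > 0L) {
    stop("duplicated gene id(s): ", paste(utils::head(dup, 5), collapse = ", "),
         call. = FALSE)
  }
  body <- df[-1]
  num <- suppressWarnings(lapply(body, as.numeric))
  bad <- vapply(num, anyNA, logical(1))
  if (any(bad)) {
    col <- names(body)[which(bad)[1]]
    row <- which(is.na(num[[which(bad)[1]]]))[1]
    stop("non-numeric or missing value at gene '", df$gene[row],
         "', sample '", col, "' (no missing-value support)", call. = FALSE)
  }
  dplyr::bind_cols(tibble::tibble(gene = df$gene), tibble::as_tibble(num))
}

#' Write an expression matrix to TSV
#'
#' @param expr Expression tibble (`gene` + sample columns).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_expression_tsv <- function(expr, path) {
  utils::write.table(expr, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write the sample-condition sidecar (YAML)
#'
#' The sidecar maps each sample id to its condition label
#' (`null` / `mir142` in the default design).
#'
#' @param path YAML file: a mapping `sample: condition`.
#' @return Tibble (`sample`, `condition`).
#' @export
read_conditions <- function(path) {
  m <- yaml::read_yaml(path)
  tibble::tibble(sample = names(m),
                 condition = vapply(m, as.character, character(1),
                                    USE.NAMES = FALSE))
}

#' @rdname read_conditions
#' @param conditions Tibble (`sample`, `condition`).
#' @export
write_conditions <- function(conditions, path) {
  yaml::write_yaml(as.list(stats::setNames(conditions$condition,
                                           conditions$sample)), path)
  invisible(path)
}

parse_fasta_id <- function(header) {
  token <- sub("\\s.*$", "", header)
  parts <- strsplit(token, "|", fixed = TRUE)[[1]]
  if (length(parts) >= 2L) c(gene = parts[1], transcript = parts[2])
  else c(gene = token, transcript = token)
}

#' Read 3' UTR sequences from FASTA
#'
#' Headers of the form `>geneID|transcriptID` are split into the two
#' ids; otherwise the whole first token serves as both. Sequences are
#' uppercased and U is normalised to T; empty records or non-nucleotide
#' characters (other than N) are rejected.
#'
#' @param path FASTA file (DNA or RNA alphabet).
#' @return Tibble (`gene`, `transcript`, `sequence`).
#' @export
read_utr_fasta <- function(path) {
  set_ <- Biostrings::readBStringSet(path)
  if (length(set_) == 0L) stop("no FASTA records in ", path, call. = FALSE)
  seqs <- normalize_utr(as.character(set_))
  if (any(nchar(seqs) == 0L)) stop("empty FASTA record", call. = FALSE)
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad)) {
    stop("illegal characters in record '", names(set_)[which(bad)[1]], "'",
         call. = FALSE)
  }
  ids <- t(unname(vapply(names(set_), parse_fasta_id, character(2))))
  tibble::tibble(gene = ids[, 1], transcript = ids[, 2],
                 sequence = unname(seqs))
}

#' Write UTR records to FASTA
#'
#' @param utrs Tibble (`gene`, `transcript`, `sequence`).
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_utr_fasta <- function(utrs, path) {
  set_ <- Biostrings::DNAStringSet(utrs$sequence)
  names(set_) <- paste(utrs$gene, utrs$transcript, sep = "|")
  Biostrings::writeXStringSet(set_, path, width = 70L)
  invisible(path)
}

#' Serialise / restore a ground-truth manifest (JSON)
#'
#' Round-trips the `truth` lists produced by [simulate_expression()] and
#' [simulate_utrs()] losslessly.
#'
#' @param truth A ground-truth list of tibbles.
#' @param path JSON file.
#' @return `path` invisibly (write) or the restored list (read).
#' @export
write_ground_truth <- function(truth, path) {
  jsonlite::write_json(truth, path, dataframe = "columns", digits = NA,
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(raw, function(el) {
    if (is.list(el) && !is.null(names(el)) && length(el) > 0 &&
        all(lengths(el) == lengths(el)[1]) && is.atomic(el[[1]])) {
      tibble::as_tibble(el)
    } else el
  })
}

#' Run the full synthetic-study pipeline
#'
#' Generates (or loads) the inputs and executes every stage in order:
#' expression + UTR simulation, seed scanning and gene classification,
#' differential expression, one coexpression network per condition,
#' node annotation, triad selection, mapping summary and the Cytoscape
#' exports. All artifacts are written to `out_dir` together with a
#' manifest recording the effective parameters and an md5 checksum per
#' file, so identical configs produce identical bundles.
#'
#' @param config A [sim_config()]; or a list with pre-loaded `expression`,
#'   `conditions` and `utrs` elements to run on real data.
#' @param out_dir Output directory (created if needed).
#' @param mode,r_min,alpha Network retention parameters
#'   (see [build_network()]).
#' @param de_test,de_alpha,de_adjust Differential-expression parameters
#'   (see [run_diffexp()], [call_de()]).
#' @return Invisibly, a list with every intermediate result
#'   (`expression`, `conditions`, `utrs`, `truth`, `hits`, `classes`,
#'   `de`, `networks`, `annotated`, `triad`, `mapping`, `stats`,
#'   `manifest`).
#' @export
run_pipeline <- function(config, out_dir,
                         mode = "r-threshold", r_min = 0.9998, alpha = 0.01,
                         de_test = "wrs", de_alpha = 0.1, de_adjust = "none") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (inherits(config, "sim_config")) {
    sim <- simulate_expression(config)
    utr_sim <- simulate_utrs(config)
    data <- list(expression = sim$expression, conditions = sim$conditions,
                 utrs = utr_sim$utrs,
                 truth = c(sim$truth, utr_sim$truth["sites"],
                           utr_sim$truth["classes"]))
    seeds <- seed_table(config$seed_5p, config$seed_3p)
  } else {
    stopifnot(all(c("expression", "conditions", "utrs") %in% names(config)))
    data <- config
    seeds <- seed_table()
  }

  hits <- scan_utrs(data$utrs, seeds)
  classes <- classify_genes(hits, genes = data$expression$gene)
  de <- run_diffexp(data$expression, data$conditions, test = de_test) |>
    call_de(alpha = de_alpha, adjust = de_adjust)
  networks <- lapply(stats::setNames(nm = unique(data$conditions$condition)),
                     function(cond) {
                       pearson_pairs(data$expression, data$conditions, cond) |>
                         build_network(mode = mode, r_min = r_min,
                                       alpha = alpha, condition = cond)
                     })
  annotated <- annotate_networks(networks, classes, de)
  triad <- select_triad(annotated,
                        condition = intersect(c("mir142", names(networks)),
                                              names(networks))[1])
  mapping <- summarize_mapping(annotated)
  net_stats <- purrr::map_dfr(networks, network_stats)
  overlap <- if (length(networks) == 2L) {
    compare_networks(networks[[1]], networks[[2]])
  } else NULL

  files <- c(expression = "expression.tsv", conditions = "conditions.yaml",
             utrs = "utrs.fasta", hits = "seed_hits.tsv",
             classes = "gene_classes.tsv", de = "diffexp.tsv",
             annotated = "node_attributes.tsv", triad = "triad_genes.tsv",
             stats = "network_stats.json")
  paths <- file.path(out_dir, files)
  names(paths) <- names(files)
  write_expression_tsv(data$expression, paths["expression"])
  write_conditions(data$conditions, paths["conditions"])
  write_utr_fasta(data$utrs, paths["utrs"])
  utils::write.table(hits, paths["hits"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(classes, paths["classes"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(de, paths["de"], sep = "\t", quote = FALSE,
                     row.names = FALSE)
  write_node_attributes(annotated, paths["annotated"])
  writeLines(c("gene", triad), paths["triad"])
  jsonlite::write_json(list(networks = net_stats, overlap = overlap),
                       paths["stats"], dataframe = "rows", auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  for (nm in names(networks)) {
    sif <- file.path(out_dir, paste0("network_", nm, ".sif"))
    gml <- file.path(out_dir, paste0("network_", nm, ".graphml"))
    write_sif(networks[[nm]], sif)
    write_graphml(networks[[nm]], gml, annotated)
    paths[paste0("sif_", nm)] <- sif
    paths[paste0("graphml_", nm)] <- gml
  }
  if (!is.null(data$truth)) {
    paths["truth"] <- file.path(out_dir, "ground_truth.json")
    write_ground_truth(data$truth, paths[["truth"]])
  }
  manifest <- tibble::tibble(
    artifact = names(paths), file = basename(unname(paths)),
    md5 = unname(tools::md5sum(unname(paths)))
  )
  utils::write.table(manifest, file.path(out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(expression = data$expression, conditions = data$conditions,
                 utrs = data$utrs, truth = data$truth, hits = hits,
                 classes = classes, de = de, networks = networks,
                 annotated = annotated, triad = triad, mapping = mapping,
                 stats = list(networks = net_stats, overlap = overlap),
                 manifest = manifest))
}
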