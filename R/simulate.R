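#' Configuration for the synthetic study generator
#'
#' Describes a synthetic two-condition microarray experiment shaped like
#' the miR-142 overexpression design: `n_per_group` replicates per
#' condition (`"null"` control vs `"mir142"` overexpression), planted
#' near-perfect coexpression cliques specific to one condition, planted
#' differentially expressed genes, and 3' UTR sequences carrying planted
#' seed sites over a site-free background.
#'
#' Cliques are simulated with a latent-profile model: each clique has one
#' shared random profile over the samples of its condition, and every
#' member gene observes that profile plus independent noise of sd
#' `clique_noise_sd`; in the other condition the same genes are plain
#' background. As `clique_noise_sd -> 0`, within-clique correlations in
#' the planted condition approach 1.
#'
#' Defaults emulate the study this package models: 3 replicates per
#' condition; planted clique node totals matching the observed network
#' sizes (57 control, 52 overexpression); 85 DE genes shifted by 2 log2
#' units; and, when `planted_sites = NULL`, seed-site classes drawn with
#' the genome-wide class frequencies of the reference counts
#' ([mir142_reference_counts()]).
#'
#' @param n_genes Number of genes (default 2000).
#' @param n_per_group Replicates per condition (>= 3; default 3, the
#'   study design).
#' @param cliques_null,cliques_mir142 Planted cliques per condition:
#'   either an integer vector of clique sizes (genes assigned
#'   automatically) or a list of character vectors of explicit gene ids.
#'   A gene may not sit in two cliques of the same condition.
#' @param n_de_genes Number of planted DE genes (disjoint from clique
#'   genes; alternating up/down direction).
#' @param de_shift Mean shift between conditions for DE genes, log2
#'   units (default 2, i.e. 4-fold).
#' @param clique_noise_sd Within-clique noise sd, log2 units; must be
#'   smaller than `background_sd` (default 1e-4).
#' @param background_sd Background noise sd, log2 units (default 0.5, a
#'   typical residual spread of RMA-normalised arrays).
#' @param baseline Mean log2 expression level (default 7).
#' @param profile_sd Sd of the latent clique profiles around `baseline`
#'   (default 1).
#' @param utr_length_range Length-2 integer vector, min/max UTR length
#'   in bases (default c(200, 800)).
#' @param planted_sites `NULL` for the default genome-frequency planting,
#'   `"none"` for site-free UTRs, or a tibble with columns `gene`, `arm`
#'   (`"5p"`/`"3p"`), `quality` (`"exact"`/`"inexact"`), `count`.
#' @param seed_5p,seed_3p Seed sequences handed to [seed_table()].
#' @param rng_seed Integer seed; all outputs are bit-reproducible given
#'   the config.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_genes = 2000,
                       n_per_group = 3,
                       cliques_null = c(25, 20, 12),
                       cliques_mir142 = c(22, 18, 12),
                       n_de_genes = 85,
                       de_shift = 2,
                       clique_noise_sd = 1e-4,
                       background_sd = 0.5,
                       baseline = 7,
                       profile_sd = 1,
                       utr_length_range = c(200L, 800L),
                       planted_sites = NULL,
                       seed_5p = mir142_seeds()[["5p"]],
                       seed_3p = mir142_seeds()[["3p"]],
                       rng_seed = 1L) {
  cfg <- list(n_genes = as.integer(n_genes), n_per_group = as.integer(n_per_group),
              cliques_null = cliques_null, cliques_mir142 = cliques_mir142,
              n_de_genes = as.integer(n_de_genes), de_shift = de_shift,
              clique_noise_sd = clique_noise_sd, background_sd = background_sd,
              baseline = baseline, profile_sd = profile_sd,
              utr_length_range = as.integer(utr_length_range),
              planted_sites = planted_sites,
              seed_5p = seed_5p, seed_3p = seed_3p,
              rng_seed = as.integer(rng_seed))
  class(cfg) <- "sim_config"
  validate_sim_config(cfg)
}

gene_ids <- function(n) sprintf("g%04d", seq_len(n))

resolve_cliques <- function(spec, ids, offset) {
  if (is.list(spec)) {
    return(list(members = lapply(spec, as.character), offset = offset))
  }
  sizes <- as.integer(spec)
  members <- vector("list", length(sizes))
  for (i in seq_along(sizes)) {
    members[[i]] <- ids[offset + seq_len(sizes[i])]
    offset <- offset + sizes[i]
  }
  list(members = members, offset = offset)
}

validate_sim_config <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (cfg$n_genes < 1L) stop("n_genes must be positive", call. = FALSE)
  if (cfg$n_per_group < 3L) stop("n_per_group must be >= 3", call. = FALSE)
  if (cfg$n_de_genes < 0L) stop("n_de_genes must be >= 0", call. = FALSE)
  if (cfg$clique_noise_sd < 0 || cfg$background_sd <= 0 ||
      cfg$clique_noise_sd >= cfg$background_sd) {
    stop("need 0 <= clique_noise_sd < background_sd", call. = FALSE)
  }
  if (length(cfg$utr_length_range) != 2L ||
      cfg$utr_length_range[1] < 20L ||
      cfg$utr_length_range[1] > cfg$utr_length_range[2]) {
    stop("utr_length_range must be c(min, max) with min >= 20", call. = FALSE)
  }
  ids <- gene_ids(cfg$n_genes)
  rn <- resolve_cliques(cfg$cliques_null, ids, 0L)
  rm_ <- resolve_cliques(cfg$cliques_mir142, ids, rn$offset)
  for (cond in list(null = rn$members, mir142 = rm_$members)) {
    all_members <- unlist(cond)
    if (anyNA(all_members)) {
      stop("clique sizes exceed n_genes", call. = FALSE)
    }
    if (anyDuplicated(all_members)) {
      stop("a gene is assigned to two cliques of the same condition",
           call. = FALSE)
    }
    if (!all(all_members %in% ids)) {
      stop("planted clique genes exceed or fall outside the gene set",
           call. = FALSE)
    }
  }
  n_planted <- length(unlist(rn$members)) + length(unlist(rm_$members))
  if (is.numeric(cfg$cliques_null) && is.numeric(cfg$cliques_mir142) &&
      n_planted + cfg$n_de_genes > cfg$n_genes) {
    stop("clique and DE gene counts exceed n_genes", call. = FALSE)
  }
  if (is.data.frame(cfg$planted_sites)) {
    stopifnot(all(c("gene", "arm", "quality", "count") %in%
                    names(cfg$planted_sites)))
    if (!all(cfg$planted_sites$gene %in% ids)) {
      stop("planted_sites references unknown genes", call. = FALSE)
    }
  }
  cfg
}

#' Simulate a two-condition expression matrix with planted structure
#'
#' Draws i.i.d. background for all genes, overlays the latent-profile
#' cliques of each condition, and shifts the planted DE genes by
#' `de_shift` in the `mir142` condition (alternating up/down). See
#' [sim_config()] for the model.
#'
#' @param config A [sim_config()].
#' @return List with `expression` (tibble: `gene` + sample columns),
#'   `conditions` (tibble `sample`, `condition`) and `truth`, a list of
#'   tibbles (`cliques`: gene/condition/clique; `de`: gene/direction)
#'   plus the `rng_seed`.
#' @export
simulate_expression <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed)
  ids <- gene_ids(config$n_genes)
  n <- config$n_per_group
  conditions <- tibble::tibble(
    sample = c(sprintf("null_%d", seq_len(n)), sprintf("mir142_%d", seq_len(n))),
    condition = rep(c("null", "mir142"), each = n)
  )
  mat <- matrix(stats::rnorm(config$n_genes * 2 * n, mean = config$baseline,
                             sd = config$background_sd),
                nrow = config$n_genes,
                dimnames = list(ids, conditions$sample))

  rn <- resolve_cliques(config$cliques_null, ids, 0L)
  rm_ <- resolve_cliques(config$cliques_mir142, ids, rn$offset)
  cliques <- list(null = rn$members, mir142 = rm_$members)
  clique_truth <- purrr::imap_dfr(cliques, function(members, cond) {
    purrr::imap_dfr(members, function(genes, i) {
      tibble::tibble(gene = genes, condition = cond,
                     clique = paste0(cond, "_c", i))
    })
  })
  if (nrow(clique_truth) == 0L) {
    clique_truth <- tibble::tibble(gene = character(), condition = character(),
                                   clique = character())
  }
  for (cond in names(cliques)) {
    cols <- conditions$sample[conditions$condition == cond]
    for (genes in cliques[[cond]]) {
      profile <- stats::rnorm(length(cols), mean = config$baseline,
                              sd = config$profile_sd)
      noise <- matrix(stats::rnorm(length(genes) * length(cols), sd =
                                     config$clique_noise_sd),
                      nrow = length(genes))
      mat[genes, cols] <- matrix(profile, nrow = length(genes),
                                 ncol = length(cols), byrow = TRUE) + noise
    }
  }

  de_truth <- tibble::tibble(gene = character(), direction = character())
  if (config$n_de_genes > 0L) {
    taken <- unique(clique_truth$gene)
    free <- setdiff(ids, taken)
    if (length(free) < config$n_de_genes) {
      stop("not enough unplanted genes for n_de_genes", call. = FALSE)
    }
    de_genes <- free[seq_len(config$n_de_genes)]
    direction <- rep(c("up", "down"), length.out = config$n_de_genes)
    cols <- conditions$sample[conditions$condition == "mir142"]
    shift <- ifelse(direction == "up", config$de_shift, -config$de_shift)
    mat[de_genes, cols] <- mat[de_genes, cols] + shift
    de_truth <- tibble::tibble(gene = de_genes, direction = direction)
  }

  list(
    expression = dplyr::bind_cols(tibble::tibble(gene = ids),
                                  tibble::as_tibble(mat)),
    conditions = conditions,
    truth = list(cliques = clique_truth, de = de_truth,
                 rng_seed = config$rng_seed)
  )
}

DNA_BASES <- c("A", "C", "G", "T")

random_dna <- function(n) {
  paste(sample(DNA_BASES, n, replace = TRUE), collapse = "")
}

# Resample every site-matching window until the sequence is site-free,
# leaving the (possibly empty) protected planted ranges untouched.
scrub_sites <- function(chars, sites, protected = integer(0), max_iter = 200L) {
  k <- nchar(sites[1])
  for (iter in seq_len(max_iter)) {
    s <- paste(chars, collapse = "")
    L <- length(chars)
    pos <- seq_len(L - k + 1L)
    win <- substring(s, pos, pos + k - 1L)
    bad <- pos[win %in% sites]
    bad <- bad[!(bad %in% protected)] # planted starts stay
    if (length(bad) == 0L) return(chars)
    for (p in bad) {
      span <- p:(p + k - 1L)
      editable <- setdiff(span, protected_bases(protected, k))
      if (length(editable) == 0L) {
        stop("cannot scrub a spurious site inside planted ranges", call. = FALSE)
      }
      chars[editable] <- sample(DNA_BASES, length(editable), replace = TRUE)
    }
  }
  stop("rejection sampling failed to produce a site-free sequence", call. = FALSE)
}

protected_bases <- function(starts, k) {
  if (length(starts) == 0L) return(integer(0))
  unique(unlist(lapply(starts, function(p) p:(p + k - 1L))))
}

default_site_classes <- function(genes) {
  counts <- mir142_reference_counts()$network_seed_counts
  genome <- stats::setNames(counts$genome,
                            paste(counts$quality, counts$arm, sep = "-"))
  genome_total <- 25000 # approximate protein-coding transcriptome size
  classes <- c(names(genome), "none")
  prob <- c(genome, none = genome_total - sum(genome)) / genome_total
  stats::setNames(sample(classes, length(genes), replace = TRUE, prob = prob),
                  genes)
}

sites_for_class <- function(class) {
  switch(class,
    "exact-5p" = tibble::tibble(arm = "5p", quality = "exact", count = 1L),
    "exact-3p" = tibble::tibble(arm = "3p", quality = "exact", count = 1L),
    "exact-both" = tibble::tibble(arm = c("5p", "3p"), quality = "exact",
                                  count = 1L),
    "inexact-5p" = tibble::tibble(arm = "5p", quality = "inexact", count = 1L),
    "inexact-3p" = tibble::tibble(arm = "3p", quality = "inexact", count = 1L),
    "inexact-both" = tibble::tibble(arm = c("5p", "3p"), quality = "inexact",
                                    count = 1L),
    tibble::tibble(arm = character(), quality = character(), count = integer())
  )
}

#' Simulate 3' UTR sequences with planted seed sites
#'
#' Generates one UTR per gene: a uniform-random DNA background,
#' rejection-sampled so that it contains no exact or one-base-mutant site
#' of either arm, with the requested sites inserted at recorded
#' (non-overlapping, >= 7 bases apart) positions. Every scanner hit on
#' the output is therefore a planted site, and the returned manifest is
#' exact ground truth for [scan_utrs()]/[classify_genes()].
#'
#' @param config A [sim_config()]; `planted_sites` selects the planting
#'   (see there). The generator reseeds at `rng_seed + 1` so expression
#'   and sequence simulation are independently reproducible.
#' @return List with `utrs` (tibble `gene`, `transcript`, `sequence`)
#'   and `truth`: tibbles `sites` (gene, transcript, arm, quality, label,
#'   position, site) and `classes` (gene, seed_class per the manifest),
#'   plus `rng_seed`.
#' @export
simulate_utrs <- function(config) {
  config <- validate_sim_config(config)
  set.seed(config$rng_seed + 1L)
  ids <- gene_ids(config$n_genes)
  seeds <- seed_table(config$seed_5p, config$seed_3p)
  all_sites <- unique(seeds$site)
  k <- nchar(all_sites[1])

  plan <- if (is.data.frame(config$planted_sites)) {
    tibble::as_tibble(config$planted_sites)
  } else if (identical(config$planted_sites, "none")) {
    tibble::tibble(gene = character(), arm = character(),
                   quality = character(), count = integer())
  } else {
    classes <- default_site_classes(ids)
    purrr::imap_dfr(classes, function(cl, g) {
      dplyr::mutate(sites_for_class(cl), gene = g)
    })
  }

  utr_len <- sample(seq(config$utr_length_range[1], config$utr_length_range[2]),
                    config$n_genes, replace = TRUE)
  names(utr_len) <- ids

  records <- vector("list", config$n_genes)
  manifests <- vector("list", config$n_genes)
  for (gi in seq_len(config$n_genes)) {
    g <- ids[gi]
    L <- utr_len[[g]]
    gene_plan <- plan[plan$gene == g, , drop = FALSE]
    gene_plan <- gene_plan[rep(seq_len(nrow(gene_plan)), gene_plan$count), ]
    n_sites <- nrow(gene_plan)
    if (n_sites * 2L * k > L) {
      stop("UTR of gene ", g, " too short for ", n_sites, " planted sites",
           call. = FALSE)
    }
    chars <- strsplit(random_dna(L), "")[[1]]

    positions <- integer(0)
    site_rows <- NULL
    if (n_sites > 0L) {
      # keep planted sites >= k bases apart so any spurious window
      # spanning one still contains scrubbable background bases
      while (TRUE) {
        cand <- sort(sample(seq_len(L - k + 1L), n_sites))
        if (n_sites == 1L || min(diff(cand)) >= 2L * k) break
      }
      positions <- cand
      site_rows <- purrr::pmap_dfr(
        list(gene_plan$arm, gene_plan$quality, positions),
        function(arm, quality, pos) {
          pool <- seeds[seeds$arm == arm & seeds$quality == quality, ]
          pick <- pool[sample(nrow(pool), 1L), ]
          tibble::tibble(gene = g, transcript = paste0(g, ".t1"),
                         arm = arm, quality = quality, label = pick$label,
                         position = as.integer(pos), site = pick$site)
        })
      for (i in seq_len(nrow(site_rows))) {
        span <- site_rows$position[i]:(site_rows$position[i] + k - 1L)
        chars[span] <- strsplit(site_rows$site[i], "")[[1]]
      }
    }
    chars <- scrub_sites(chars, all_sites, protected = positions)
    records[[gi]] <- paste(chars, collapse = "")
    manifests[[gi]] <- site_rows
  }

  sites <- dplyr::bind_rows(manifests)
  if (nrow(sites) == 0L) {
    sites <- tibble::tibble(gene = character(), transcript = character(),
                            arm = character(), quality = character(),
                            label = character(), position = integer(),
                            site = character())
  }
  list(
    utrs = tibble::tibble(gene = ids, transcript = paste0(ids, ".t1"),
                          sequence = unlist(records)),
    truth = list(sites = sites,
                 classes = classify_genes(sites, genes = ids),
                 rng_seed = config$rng_seed)
  )
}
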