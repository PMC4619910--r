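#' Default miR-142 seed sequences
#'
#' The 7-nt seed regions of the two mature arms of miR-142, written 5'->3'
#' as RNA. Both arms are loaded into the RISC complex and can repress
#' targets independently, so the scanner always considers both.
#'
#' @return Named character vector with elements `5p` and `3p`.
#' @export
#' @examples
#' mir142_seeds()
mir142_seeds <- function() {
  c(`5p` = "AUAAAGU", `3p` = "GUAGUGU")
}

RNA_BASES <- c("A", "U", "G", "C")

assert_rna <- function(x, what = "seed") {
  if (length(x) != 1L || is.na(x) || nchar(x) < 1L) {
    stop(what, " must be a single non-empty RNA string", call. = FALSE)
  }
  bad <- setdiff(unique(strsplit(x, "")[[1]]), RNA_BASES)
  if (length(bad) > 0L) {
    stop(what, " contains non-RNA characters: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  invisible(x)
}

#' All one-base mutants of a seed sequence
#'
#' Enumerates every sequence differing from `seed` at exactly one position:
#' 3 variants per position, `3 * nchar(seed)` in total (21 for a 7-mer).
#' Labels follow the position-index/variant-letter scheme, e.g. `"2b"` is
#' the second alternative base at position 2; at each position the three
#' alternatives are taken in A, U, G, C order with the original base
#' skipped. The exact seed itself is never included.
#'
#' @param seed A single RNA string (alphabet A/U/G/C).
#' @return A tibble with columns `label` and `seed`, one row per mutant.
#' @export
#' @examples
#' mutant_seeds("AUAAAGU")
mutant_seeds <- function(seed) {
  assert_rna(seed)
  bases <- strsplit(seed, "")[[1]]
  purrr::map_dfr(seq_along(bases), function(pos) {
    alts <- setdiff(RNA_BASES, bases[pos])
    tibble::tibble(
      label = paste0(pos, letters[seq_along(alts)]),
      seed = vapply(alts, function(b) {
        mutated <- bases
        mutated[pos] <- b
        paste(mutated, collapse = "")
      }, character(1), USE.NAMES = FALSE)
    )
  })
}

#' Reverse-complement a seed into its UTR target site
#'
#' A miRNA binds its target by Watson-Crick pairing of the seed against the
#' mRNA, so the predicted site is the reverse complement of the seed,
#' rendered in the DNA alphabet and read 5'->3' on the UTR sense strand.
#'
#' @param seed Character vector of RNA seed sequences.
#' @return Character vector of DNA site sequences of the same length.
#' @export
#' @examples
#' seed_to_site("AUAAAGU") # "ACTTTAT"
seed_to_site <- function(seed) {
  vapply(seed, function(s) {
    assert_rna(s)
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(chartr("U", "T", s))))
  }, character(1), USE.NAMES = FALSE)
}

#' Build the full exact + one-base-mutant seed table for both arms
#'
#' @param seed_5p,seed_3p 7-nt RNA seeds for the 5p and 3p arms. Defaults
#'   are the miR-142 arms ([mir142_seeds()]).
#' @return A tibble with one row per seed variant (2 x 22 rows for 7-mers):
#'   columns `arm` (`"5p"`/`"3p"`), `quality` (`"exact"`/`"inexact"`),
#'   `label` (`""` for exact, else e.g. `"3b"`), `seed` (RNA) and `site`
#'   (DNA reverse complement searched on the UTR).
#' @export
#' @examples
#' seed_table()
seed_table <- function(seed_5p = mir142_seeds()[["5p"]],
                       seed_3p = mir142_seeds()[["3p"]]) {
  one_arm <- function(arm, seed) {
    dplyr::bind_rows(
      tibble::tibble(arm = arm, quality = "exact", label = "", seed = seed),
      dplyr::mutate(mutant_seeds(seed), arm = arm, quality = "inexact")
    )
  }
  dplyr::bind_rows(one_arm("5p", seed_5p), one_arm("3p", seed_3p)) |>
    dplyr::mutate(site = seed_to_site(.data$seed)) |>
    dplyr::select("arm", "quality", "label", "seed", "site")
}

normalize_utr <- function(x) chartr("u", "T", chartr("U", "T", toupper(x)))

#' Scan 3' UTR sequences for seed sites
#'
#' Slides a 7-base window over each UTR (sense strand only; mRNA is
#' single-stranded) and reports every window equal to the reverse
#' complement of any exact or one-base-mutant seed of either arm.
#' Overlapping occurrences are each reported; positions are 1-based
#' inclusive starts. A window equal to an arm's exact site is reported as
#' exact only, never additionally as an inexact hit of that arm.
#' Sequences shorter than the window yield no hits; windows containing
#' ambiguous bases (e.g. N) never match.
#'
#' @param utrs A tibble with columns `gene`, `transcript`, `sequence`
#'   (as returned by [read_utr_fasta()] or [simulate_utrs()]), or a named
#'   character vector of sequences (names used as both gene and transcript).
#' @param seeds Seed table from [seed_table()].
#' @return A tibble of hits: `gene`, `transcript`, `arm`, `quality`,
#'   `label`, `position`, `site`, ordered by gene, transcript, position.
#' @export
#' @examples
#' scan_utrs(c(g1 = "ACTTTAT"))
scan_utrs <- function(utrs, seeds = seed_table()) {
  if (is.character(utrs)) {
    if (is.null(names(utrs))) stop("character `utrs` must be named", call. = FALSE)
    utrs <- tibble::tibble(gene = names(utrs), transcript = names(utrs),
                           sequence = unname(utrs))
  }
  stopifnot(all(c("gene", "transcript", "sequence") %in% names(utrs)))
  k <- nchar(seeds$site[1])
  if (any(nchar(seeds$site) != k)) stop("all seeds must share one length", call. = FALSE)

  windows <- purrr::pmap_dfr(
    utrs[c("gene", "transcript", "sequence")],
    function(gene, transcript, sequence) {
      s <- normalize_utr(sequence)
      L <- nchar(s)
      if (L < k) return(tibble::tibble())
      pos <- seq_len(L - k + 1L)
      tibble::tibble(gene = gene, transcript = transcript, position = pos,
                     site = substring(s, pos, pos + k - 1L))
    }
  )
  if (nrow(windows) == 0L) {
    return(tibble::tibble(gene = character(), transcript = character(),
                          arm = character(), quality = character(),
                          label = character(), position = integer(),
                          site = character()))
  }
  dplyr::inner_join(windows, seeds[c("arm", "quality", "label", "site")],
                    by = "site", relationship = "many-to-many") |>
    dplyr::select("gene", "transcript", "arm", "quality", "label",
                  "position", "site") |>
    dplyr::arrange(.data$gene, .data$transcript, .data$position, .data$arm)
}

SEED_CLASSES <- c("exact-5p", "exact-3p", "exact-both",
                  "inexact-5p", "inexact-3p", "inexact-both", "none")

#' Collapse seed hits to one class per gene
#'
#' A gene is seed-mapped if any of its transcripts' UTRs carries a hit.
#' Classes are mutually exclusive with exact-over-inexact precedence: a
#' gene with any exact hit is classed by which arms have exact hits
#' (`exact-5p`, `exact-3p` or `exact-both`, ignoring its inexact hits);
#' otherwise by which arms have inexact hits; genes with no hits are
#' `none`.
#'
#' @param hits Hit tibble from [scan_utrs()].
#' @param genes Optional character vector: the gene universe to classify.
#'   Defaults to the genes present in `hits`. Genes absent from `hits`
#'   are classed `none`.
#' @param transcript_map Optional tibble (`transcript`, `gene`) used to
#'   validate that every hit references a known transcript.
#' @return Tibble (`gene`, `seed_class`) with `seed_class` a factor over
#'   the seven classes; one row per gene, every gene in exactly one class.
#' @export
classify_genes <- function(hits, genes = NULL, transcript_map = NULL) {
  if (!is.null(transcript_map)) {
    unknown <- setdiff(unique(hits$transcript), transcript_map$transcript)
    if (length(unknown) > 0L) {
      stop("hits reference unknown transcripts: ",
           paste(utils::head(unknown, 5), collapse = ", "), call. = FALSE)
    }
  }
  if (is.null(genes)) genes <- unique(hits$gene)

  class_of <- function(arms) {
    if (length(arms) == 0L) return(NA_character_)
    if (all(c("5p", "3p") %in% arms)) "both" else arms[1]
  }
  per_gene <- hits |>
    dplyr::group_by(.data$gene) |>
    dplyr::summarise(
      exact_arms = class_of(sort(unique(.data$arm[.data$quality == "exact"]),
                                 decreasing = TRUE)),
      inexact_arms = class_of(sort(unique(.data$arm[.data$quality == "inexact"]),
                                   decreasing = TRUE)),
      .groups = "drop"
    ) |>
    dplyr::mutate(seed_class = dplyr::case_when(
      !is.na(.data$exact_arms) ~ paste0("exact-", .data$exact_arms),
      !is.na(.data$inexact_arms) ~ paste0("inexact-", .data$inexact_arms),
      TRUE ~ "none"
    ))

  tibble::tibble(gene = genes) |>
    dplyr::left_join(per_gene[c("gene", "seed_class")], by = "gene") |>
    dplyr::mutate(seed_class = factor(
      dplyr::coalesce(.data$seed_class, "none"), levels = SEED_CLASSES))
}
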