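# Copy-number genotyping from germline allele calls: per-gene zygosity via
# the unique-allele-count rule (more than two unique alleles => duplicated),
# and population summaries over covered participants.
#
# Known blind spots, by construction of the method: duplications composed of
# completely identical alleles are never called, and deletions are never
# emitted (a single unique allele may equally be homozygosity).

.zygosity_state <- function(n_unique) {
  ifelse(n_unique == 0L, "no_coverage",
         ifelse(n_unique == 1L, "homozygous",
                ifelse(n_unique == 2L, "heterozygous", "duplicated")))
}

#' Genotype one participant-gene from its allele calls
#'
#' @param calls Calls for a single participant and gene (post abundance
#'   filtering).
#' @param identity `"full"` counts distinct full-length sequences (V-region
#'   plus regulatory variants distinguish alleles); `"v_region"` restricts
#'   to distinct canonical allele names for sensitivity analysis.
#' @return One-row tibble: `n_unique`, `state`, list-column `alleles`
#'   (canonical allele names).
#' @export
genotype_gene <- function(calls, identity = c("full", "v_region")) {
  identity <- match.arg(identity)
  if (nrow(calls) == 0L) {
    return(tibble(n_unique = 0L, state = "no_coverage",
                  alleles = list(character())))
  }
  names_ <- .canonical_name(
    ifelse(calls$is_novel, calls$novel_name, calls$allele_key))
  n_unique <- if (identity == "full") {
    dplyr::n_distinct(calls$sequence)
  } else {
    dplyr::n_distinct(names_)
  }
  tibble(n_unique = as.integer(n_unique),
         state = .zygosity_state(n_unique),
         alleles = list(sort(unique(names_))))
}

#' Genotype every participant-gene combination
#'
#' Applies the unique-allele-count rule per participant per gene. When a
#' `genes` panel is given, combinations without calls are emitted as
#' `no_coverage` (first-class, but excluded from population denominators).
#'
#' @param calls Calls tibble from [genotype_germline()].
#' @param genes Optional gene panel to force coverage rows for.
#' @param participants Optional participant set (defaults to those in
#'   `calls`).
#' @inheritParams genotype_gene
#' @return Tibble: `participant`, `gene`, `n_unique`, `state`, `alleles`.
#' @export
genotype_genes <- function(calls, genes = NULL, participants = NULL,
                           identity = c("full", "v_region")) {
  identity <- match.arg(identity)
  participants <- participants %||% sort(unique(calls$participant))
  genes <- genes %||% sort(unique(calls$gene))
  grid <- expand.grid(participant = participants, gene = genes,
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    sub <- calls[calls$participant == grid$participant[i] &
                   calls$gene == grid$gene[i], , drop = FALSE]
    dplyr::bind_cols(tibble(participant = grid$participant[i],
                            gene = grid$gene[i]),
                     genotype_gene(sub, identity))
  })
  bind_rows(rows) |> arrange(.data$participant, .data$gene)
}

#' Summarise zygosity and duplication per gene across a population
#'
#' Proportions are computed over covered participants only (the per-gene
#' denominator excludes `no_coverage`); genes with zero covered participants
#' are omitted with a warning. Deletions are never reported.
#'
#' @param zygosities Output of [genotype_genes()].
#' @return Tibble: `gene`, `n_covered`, `prop_homozygous`,
#'   `prop_heterozygous`, `prop_duplicated` (the three proportions sum
#'   to 1).
#' @export
summarize_population <- function(zygosities) {
  covered <- zygosities |> filter(.data$state != "no_coverage")
  empty <- setdiff(unique(zygosities$gene), unique(covered$gene))
  if (length(empty)) {
    warning("gene(s) with zero covered participants omitted: ",
            paste(empty, collapse = ", "))
  }
  covered |>
    group_by(.data$gene) |>
    summarise(
      n_covered = dplyr::n(),
      prop_homozygous = mean(.data$state == "homozygous"),
      prop_heterozygous = mean(.data$state == "heterozygous"),
      prop_duplicated = mean(.data$state == "duplicated"),
      .groups = "drop"
    )
}
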