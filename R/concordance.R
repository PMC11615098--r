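# Concordance reporting: compare germline and transcriptome-derived allele
# calls per participant per gene (Jaccard on canonicalised allele-name
# sets), tally allele categories by database source, and export the
# heatmap-ready matrices with a digest manifest.

#' Compare germline and expressed allele calls per participant-gene cell
#'
#' Allele names are canonicalised (base allele plus sorted SNV tokens)
#' before comparison, so a germline `X*01_C288T` matches an expressed
#' inference of the same variant. The score is Jaccard
#' (`|intersection| / |union|`), symmetric in its arguments; status is
#' `concordant` (score 1), `partial` (0 < score < 1), `discordant`
#' (score 0), or `missing_one_side` when exactly one set is empty.
#'
#' @param germline Tibble: `participant`, `gene`, list-column `alleles`.
#' @param expressed Tibble of the same shape.
#' @return Tibble: `participant`, `gene`, `germline_alleles`,
#'   `expressed_alleles` (list-columns), `status`, `score` (`NA` when a
#'   side is missing).
#' @export
compare_calls <- function(germline, expressed) {
  key <- function(df) paste(df$participant, df$gene, sep = "\r")
  cells <- unique(rbind(
    data.frame(participant = germline$participant, gene = germline$gene),
    data.frame(participant = expressed$participant, gene = expressed$gene)
  ))
  cells <- cells[order(cells$participant, cells$gene), , drop = FALSE]
  gk <- key(germline)
  ek <- key(expressed)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    ck <- paste(cells$participant[i], cells$gene[i], sep = "\r")
    gs <- if (ck %in% gk)
      .canonical_name(unlist(germline$alleles[gk == ck])) else character()
    es <- if (ck %in% ek)
      .canonical_name(unlist(expressed$alleles[ek == ck])) else character()
    gs <- sort(unique(gs))
    es <- sort(unique(es))
    if (length(gs) == 0L || length(es) == 0L) {
      status <- "missing_one_side"
      score <- NA_real_
    } else {
      score <- length(intersect(gs, es)) / length(union(gs, es))
      status <- if (score == 1) "concordant" else
        if (score == 0) "discordant" else "partial"
    }
    tibble(participant = cells$participant[i], gene = cells$gene[i],
           germline_alleles = list(gs), expressed_alleles = list(es),
           status = status, score = score)
  })
  bind_rows(rows)
}

#' Pivot concordance cells into a gene-by-participant score matrix
#'
#' @param cells Output of [compare_calls()].
#' @param missing Sentinel for cells lacking data on one side (default
#'   `NA`).
#' @return A data frame with genes as rows and participants as columns.
#' @export
concordance_matrix <- function(cells, missing = NA_real_) {
  cells$score[cells$status == "missing_one_side"] <- missing
  wide <- cells |>
    select("participant", "gene", "score") |>
    tidyr::pivot_wider(names_from = "participant", values_from = "score")
  as.data.frame(wide)
}

#' Tally called alleles by database category
#'
#' Each distinct called allele is assigned one category by source-tag
#' precedence `known-reference` (IMGT) > `prior-study` > `inferred-db`
#' (IgPDb/OGRDB) > `novel`; categories are exhaustive and mutually
#' exclusive, and the counts sum to the number of distinct alleles.
#'
#' @param allele_names Character vector of called allele names (novel names
#'   in canonical form).
#' @param db An `ighv_refdb` whose records carry `source` tags.
#' @return Tibble: `category`, `n`, `fraction`.
#' @export
tally_categories <- function(allele_names, db) {
  alleles <- sort(unique(.canonical_name(allele_names)))
  src <- setNames(db$alleles$source, db$alleles$allele_key)
  category <- vapply(alleles, function(a) {
    s <- unname(src[a])
    if (is.na(s)) return("novel")
    switch(s,
           "IMGT" = "known-reference",
           "prior-study" = "prior-study",
           "IgPDb/OGRDB" = "inferred-db",
           "novel")
  }, character(1))
  levels_ <- c("known-reference", "prior-study", "inferred-db", "novel")
  counts <- as.integer(table(factor(category, levels = levels_)))
  tibble(category = levels_, n = counts,
         fraction = counts / max(length(alleles), 1L))
}

#' Export the pipeline's report bundle
#'
#' Writes each table as TSV, the concordance matrix, and a run manifest
#' JSON referencing every output file with its MD5 content digest plus the
#' configuration and seed. The manifest carries no timestamps, so reruns
#' with identical configuration and seed are byte-identical.
#'
#' @param outdir Output directory (created if needed).
#' @param tables Named list of data frames to write (`<name>.tsv` each).
#' @param config Configuration list echoed into the manifest.
#' @param seed Integer seed echoed into the manifest.
#' @param inputs Optional named character vector of input file paths to
#'   digest into the manifest.
#' @return The manifest, invisibly.
#' @export
export_reports <- function(outdir, tables, config = list(), seed = NA,
                           inputs = character()) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  files <- character()
  for (nm in names(tables)) {
    path <- file.path(outdir, paste0(nm, ".tsv"))
    .write_tsv(tables[[nm]], path)
    files[nm] <- path
  }
  digests <- tools::md5sum(unname(files))
  input_digests <- if (length(inputs)) tools::md5sum(unname(inputs)) else
    character()
  cfg <- config
  cfg$genes <- unname(cfg$genes)
  manifest <- list(
    package = "ighvpop",
    version = as.character(utils::packageVersion("ighvpop")),
    seed = seed,
    config = cfg,
    outputs = lapply(seq_along(files), function(i)
      list(name = names(files)[i], file = basename(files[[i]]),
           md5 = unname(digests[i]))),
    inputs = lapply(seq_along(input_digests), function(i)
      list(file = basename(inputs[i]), md5 = unname(input_digests[i])))
  )
  jsonlite::write_json(manifest, file.path(outdir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
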