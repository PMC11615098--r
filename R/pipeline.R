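# End-to-end orchestration: simulate -> germline genotyping -> leader
# classification -> population CNV summary -> repertoire annotation ->
# expressed-allele inference -> anchored haplotypes -> chromosome-resolved
# CNV -> fold change -> concordance -> report bundle.

#' Build and validate a pipeline run configuration
#'
#' Thresholds default to the working values of the underlying stages: mean
#' quality 33, abundance `min_count` 2 and `min_gene_fraction` 0.1,
#' identity floor 85%, haplotype filters `min_reads` 50 and `min_k` 3.6,
#' anchor IGHJ6.
#'
#' @param sim An `ighv_sim_config` describing the synthetic inputs.
#' @param outdir Output directory for the report bundle.
#' @param min_q,min_count,min_gene_fraction,identity_floor Germline
#'   thresholds.
#' @param min_reads,min_k,anchor_gene,min_anchor_fraction Haplotype
#'   thresholds.
#' @param reference_seed Seed for the synthetic reference panel.
#' @return A validated list of class `ighv_run_config`.
#' @export
run_config <- function(sim = sim_config(), outdir = tempfile("ighvpop_run"),
                       min_q = 33, min_count = 2L, min_gene_fraction = 0.1,
                       identity_floor = 85, min_reads = 50L, min_k = 3.6,
                       anchor_gene = "IGHJ6", min_anchor_fraction = 0.1,
                       reference_seed = 7191L) {
  if (min_k < 0) stop("min_k must be >= 0", call. = FALSE)
  if (min_reads < 0) stop("min_reads must be >= 0", call. = FALSE)
  if (min_gene_fraction < 0 || min_gene_fraction > 1) {
    stop("min_gene_fraction must be in [0, 1]", call. = FALSE)
  }
  if (identity_floor < 0 || identity_floor > 100) {
    stop("identity_floor must be in [0, 100]", call. = FALSE)
  }
  structure(list(sim = sim, outdir = outdir, min_q = min_q,
                 min_count = min_count,
                 min_gene_fraction = min_gene_fraction,
                 identity_floor = identity_floor, min_reads = min_reads,
                 min_k = min_k, anchor_gene = anchor_gene,
                 min_anchor_fraction = min_anchor_fraction,
                 reference_seed = reference_seed),
            class = "ighv_run_config")
}

#' Run the full synthetic-data pipeline
#'
#' Generates the synthetic reference and population, processes the germline
#' amplicons and the expressed repertoire, reconciles the two call sets,
#' and writes the report bundle with a digest manifest. Participants whose
#' IGHJ6 anchor is not heterozygous are skipped for haplotype-level
#' analyses (logged in the skip table), matching the anchor method's
#' applicability.
#'
#' @param config An `ighv_run_config`.
#' @param quiet Suppress progress messages (default `TRUE`).
#' @return Invisibly, a list with every intermediate table and the
#'   manifest.
#' @export
run_pipeline <- function(config = run_config(), quiet = TRUE) {
  say <- function(...) if (!quiet) message(...)
  sim <- config$sim
  say("reference + population (seed ", sim$seed, ")")
  ref <- synthetic_reference(genes = sim$genes, seed = config$reference_seed)
  truth <- simulate_population(ref, sim)

  say("germline amplicons")
  amp <- emit_amplicon_reads(truth)
  germ <- genotype_germline(
    amp$reads, ref, min_q = config$min_q,
    min_count = config$min_count,
    min_gene_fraction = config$min_gene_fraction,
    identity_floor = config$identity_floor
  )
  leaders <- classify_leaders(germ$calls, ref$db)
  leader_summary <- summarize_leader_variation(leaders)
  pfm <- position_frequency_matrix(leaders, ref$db)
  zyg <- genotype_genes(germ$calls, genes = sim$genes,
                        participants = sprintf("P%03d",
                                               seq_len(sim$n_participants)))
  pop <- summarize_population(zyg)

  say("expressed repertoire")
  rep_ <- emit_repertoire(truth)
  ann <- annotate_rearrangements(rep_$reads, ref$db, ref$j_db,
                                 identity_floor = config$identity_floor)
  expressed <- infer_expressed_alleles(ann$rearrangements, ref$db)

  say("haplotypes")
  hap_tables <- list()
  hap_dup <- list()
  gene_states <- list()
  expr_tables <- list()
  skipped <- list()
  for (p in unique(ann$rearrangements$participant)) {
    rr <- ann$rearrangements[ann$rearrangements$participant == p, ,
                             drop = FALSE]
    ex <- expressed[expressed$participant == p, , drop = FALSE]
    hm <- tryCatch(
      reconstruct_haplotypes(rr, ex, anchor_gene = config$anchor_gene,
                             min_anchor_fraction =
                               config$min_anchor_fraction),
      error = function(e) e
    )
    if (inherits(hm, "error")) {
      skipped[[p]] <- tibble(participant = p,
                             reason = conditionMessage(hm))
      next
    }
    hap_tables[[p]] <- dplyr::bind_cols(tibble(participant = p), hm$table)
    cnv <- call_haplotype_cnv(hm, min_reads = config$min_reads,
                              min_k = config$min_k)
    hap_dup[[p]] <- cnv$haplotype_dup
    gene_states[[p]] <- cnv$gene_states
    expr_tables[[p]] <- expression_table(hm)
  }
  haplotypes <- bind_rows(hap_tables)
  haplotype_dup <- bind_rows(hap_dup)
  cnv_states <- bind_rows(gene_states)
  expression <- bind_rows(expr_tables)
  fold <- if (nrow(expression)) {
    expression_fold_change(expression, haplotype_dup)
  } else {
    tibble()
  }

  say("concordance")
  expressed_sets <- expressed |>
    group_by(.data$participant, .data$gene) |>
    summarise(alleles = list(sort(unique(.data$allele_name))),
              .groups = "drop")
  germline_sets <- zyg |>
    filter(.data$state != "no_coverage") |>
    select("participant", "gene", "alleles")
  cells <- compare_calls(germline_sets, expressed_sets)
  categories <- tally_categories(
    unlist(germline_sets$alleles), ref$db)

  tables <- list(
    calls = germ$calls |> select(-"snvs", -"sequence"),
    stages = germ$stages,
    leader_classifications = leaders |>
      select("call_id", "participant", "gene", "allele_key", "category"),
    leader_summary = leader_summary,
    leader_pfm_nt = pfm$nt,
    zygosity = zyg,
    population_cnv = pop,
    expressed_alleles = expressed,
    haplotypes = haplotypes,
    cnv_states = cnv_states,
    expression = expression,
    fold_change = fold,
    concordance = cells |> select(-"germline_alleles",
                                  -"expressed_alleles"),
    allele_categories = categories,
    skipped_participants = bind_rows(skipped)
  )
  tables <- tables[vapply(tables, function(t) !is.null(t) && nrow(t) > 0,
                          logical(1))]
  manifest <- export_reports(config$outdir, tables,
                             config = unclass(sim), seed = sim$seed)
  invisible(list(
    reference = ref, truth = truth, germline = germ, leaders = leaders,
    leader_summary = leader_summary, pfm = pfm, zygosity = zyg,
    population = pop, rearrangements = ann$rearrangements,
    expressed = expressed, haplotypes = haplotypes,
    haplotype_dup = haplotype_dup, cnv_states = cnv_states,
    expression = expression, fold_change = fold, concordance = cells,
    categories = categories, skipped = bind_rows(skipped),
    manifest = manifest
  ))
}
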