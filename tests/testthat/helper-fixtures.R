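# Shared fixtures. Heavy seeded simulations are computed once per test run
# and cached; every fixture is deterministic in its stated seed.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, fn) {
  if (!exists(name, envir = .fixtures, inherits = FALSE)) {
    assign(name, fn(), envir = .fixtures)
  }
  get(name, envir = .fixtures, inherits = FALSE)
}

# Hand-built three-allele database with short, fully known sequences.
# Layout per allele: leader1 (1-6), intron (7-17), leader2 (18-20),
# v_region (21-32), rss (33-39); spliced leader "ATGGAC"+"TGT" -> "MDC".
tiny_db <- function() {
  mk <- function(l1, v) paste0(l1, "GTAAGTCCCAG", "TGT", v, "CACAGTG")
  alleles <- tibble::tibble(
    gene = c("IGHV1-2", "IGHV1-2", "IGHV3-23"),
    allele_id = c("01", "02", "01"),
    sequence = c(mk("ATGGAC", "TGTGCAGCCTGG"),
                 mk("ATGGAC", "TGTGCAGCCAGG"),
                 mk("ATGTTC", "AATTCGGCCTGG")),
    source = c("IMGT", "IgPDb/OGRDB", "IMGT")
  )
  regions <- do.call(rbind, lapply(alleles$gene, function(g) NULL))
  keys <- paste0(alleles$gene, "*", alleles$allele_id)
  regions <- tibble::tibble(
    allele_key = rep(keys, each = 5),
    region_name = rep(c("leader1", "intron", "leader2", "v_region", "rss"),
                      3),
    start = rep(c(1L, 7L, 18L, 21L, 33L), 3),
    end = rep(c(6L, 17L, 20L, 32L, 39L), 3)
  )
  reference_db(alleles, regions)
}

# Small synthetic panel reused across unit tests.
small_ref <- function() {
  fixture("small_ref", function() {
    synthetic_reference(genes = c("IGHV1-2", "IGHV1-69", "IGHV3-23",
                                  "IGHV4-59"),
                        alleles_per_gene = 3L, seed = 11L)
  })
}

# Small error-free simulation through the germline pipeline.
small_clean_run <- function() {
  fixture("small_clean_run", function() {
    ref <- small_ref()
    cfg <- sim_config(n_participants = 6L, genes = ref$db$alleles$gene |>
                        unique(), dup_rate = 0.2, amplicon_depth = 40L,
                      per_base_error = 0, n_vdj = 500L, seed = 31L,
                      anchor_het_prob = 1)
    truth <- simulate_population(ref, cfg)
    amp <- emit_amplicon_reads(truth)
    germ <- genotype_germline(amp$reads, ref)
    list(ref = ref, cfg = cfg, truth = truth, amp = amp, germ = germ)
  })
}

# --- acceptance-scale fixtures -------------------------------------------

# Germline genotyping experiment: 30 participants x 10 genes, depth 200.
crit_germline_run <- function(per_base_error, seed) {
  key <- sprintf("crit_germline_%g_%d", per_base_error, seed)
  fixture(key, function() {
    ref <- synthetic_reference(seed = 7191L)
    cfg <- sim_config(n_participants = 30L, amplicon_depth = 200L,
                      per_base_error = per_base_error, seed = seed)
    truth <- simulate_population(ref, cfg)
    amp <- emit_amplicon_reads(truth)
    germ <- genotype_germline(amp$reads, ref)
    zyg <- genotype_genes(germ$calls, genes = cfg$genes,
                          participants = sprintf("P%03d",
                                                 seq_len(cfg$n_participants)))
    list(ref = ref, cfg = cfg, truth = truth, germ = germ, zyg = zyg)
  })
}

# Expressed-repertoire experiment: richer panel for per-gene averaging of
# duplication effects (see the methods vignette): 12 participants, 20 genes,
# 6 alleles per gene, dup_rate 0.25, 5000 VDJs per haplotype, boost 2,
# heterozygous IGHJ6 anchor.
panel20 <- function() {
  c(sprintf("IGHV1-%d", c(2, 3, 8, 18, 24, 46, 58, 69)),
    sprintf("IGHV2-%d", c(5, 26, 70)),
    sprintf("IGHV3-%d", c(7, 9, 23, 30, 33)),
    sprintf("IGHV4-%d", c(4, 34, 59)), "IGHV5-51")
}

crit_expressed_run <- function() {
  fixture("crit_expressed_run", function() {
    genes <- panel20()
    ref <- synthetic_reference(genes = genes, alleles_per_gene = 6L,
                               seed = 7191L)
    cfg <- sim_config(n_participants = 12L, genes = genes, dup_rate = 0.25,
                      amplicon_depth = 200L, n_vdj = 10000L, seed = 404L,
                      anchor_het_prob = 1, usage_boost = 2)
    truth <- simulate_population(ref, cfg)
    rep_ <- emit_repertoire(truth)
    ann <- annotate_rearrangements(rep_$reads, ref$db, ref$j_db)
    expressed <- infer_expressed_alleles(ann$rearrangements, ref$db)
    hd <- list(); gs <- list(); et <- list()
    for (p in unique(ann$rearrangements$participant)) {
      rr <- ann$rearrangements[ann$rearrangements$participant == p, ,
                               drop = FALSE]
      hm <- reconstruct_haplotypes(rr, expressed[expressed$participant == p,
                                                 , drop = FALSE])
      cnv <- call_haplotype_cnv(hm)
      hd[[p]] <- cnv$haplotype_dup
      gs[[p]] <- cnv$gene_states
      et[[p]] <- expression_table(hm)
    }
    list(ref = ref, cfg = cfg, truth = truth, rep = rep_, ann = ann,
         expressed = expressed,
         haplotype_dup = dplyr::bind_rows(hd),
         cnv_states = dplyr::bind_rows(gs),
         expression = dplyr::bind_rows(et))
  })
}

# Truth per-gene chromosome-resolved duplication state (distinct expressed
# V segments per chromosome), the quantity the allele-count method can see.
truth_cnv_states <- function(truth) {
  truth$genotype |>
    dplyr::group_by(participant, chromosome, gene) |>
    dplyr::summarise(nd = dplyr::n_distinct(v_segment), .groups = "drop") |>
    dplyr::group_by(participant, gene) |>
    dplyr::summarise(
      state = c("none", "single_haplotype_dup",
                "both_haplotype_dup")[sum(nd > 1L) + 1L],
      .groups = "drop")
}

# Planted distinct full-length sequences per participant+gene.
truth_sequences <- function(truth) {
  unique(truth$genotype[, c("participant", "gene", "sequence")])
}
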