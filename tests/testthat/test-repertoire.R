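test_that("k_factor obeys its binomial Bayes-factor contract", {
  expect_identical(k_factor(0, 100), 0)
  expect_identical(k_factor(5, 0), 0)
  # non-decreasing in support at fixed total
  ks <- k_factor(0:100, 100)
  expect_true(all(diff(ks) >= -1e-12))
  # independent recomputation of the stated formula
  for (a in c(1, 2, 7, 10, 60)) {
    p <- max(a / 100, 0.01)
    expected <- max(0, log10(dbinom(a, 100, p) / dbinom(a, 100, 0.01)))
    expect_equal(k_factor(a, 100), expected, tolerance = 1e-12)
  }
  # the 3.6 working threshold falls between 2 and 10 supporting reads of 100
  expect_lt(k_factor(2, 100), 3.6)
  expect_gt(k_factor(10, 100), 3.6)
  expect_error(k_factor(1, 10, error_rate = 0.7), "error_rate")
  expect_error(k_factor(-1, 10), ">= 0")
})

rep_fixture <- function() {
  fixture("rep_small", function() {
    ref <- small_ref()
    cfg <- sim_config(n_participants = 2L,
                      genes = unique(ref$db$alleles$gene),
                      dup_rate = 0.3, shm_rate = 0, n_vdj = 1500L,
                      anchor_het_prob = 1, seed = 53L)
    truth <- simulate_population(ref, cfg)
    rep_ <- emit_repertoire(truth)
    ann <- annotate_rearrangements(rep_$reads, ref$db, ref$j_db)
    list(ref = ref, cfg = cfg, truth = truth, rep = rep_, ann = ann)
  })
}

test_that("annotation recovers V and J calls exactly on mutation-free reads", {
  fx <- rep_fixture()
  ann <- fx$ann$rearrangements
  expect_identical(nrow(fx$ann$discards), 0L)
  expect_true(all(ann$v_identity_pct == 100))
  expect_true(all(ann$v_mutation_count == 0L))
  m <- dplyr::inner_join(ann, fx$rep$truth, by = "sequence_id")
  expect_true(all(m$j_call == m$j_truth))
  # v_call names the planted allele's base gene; exact segment matches truth
  expect_true(all(m$v_segment ==
                    fx$truth$genotype$v_segment[
                      match(m$copy_id, fx$truth$genotype$copy_id)]))
  # unique-VDJ collapse: one row per distinct simulated sequence
  expect_identical(nrow(ann),
                   dplyr::n_distinct(fx$rep$reads$sequence,
                                     fx$rep$reads$participant))
  expect_identical(sum(ann$duplicate_count) + nrow(fx$ann$discards),
                   nrow(fx$rep$reads))
})

test_that("expressed-allele inference honours support and junction rules", {
  fx <- rep_fixture()
  ex <- infer_expressed_alleles(fx$ann$rearrangements, fx$ref$db)
  # inferred set equals the planted expressed set per participant+gene
  planted <- fx$truth$genotype |>
    dplyr::distinct(participant, gene, v_segment)
  inferred <- ex |> dplyr::distinct(participant, gene, v_segment)
  expect_setequal(paste(inferred$participant, inferred$v_segment),
                  paste(planted$participant, planted$v_segment))

  # clonal expansion: many reads, one junction -> suppressed
  seg <- planted$v_segment[1]
  clone <- tibble::tibble(
    sequence_id = sprintf("c%02d", 1:12), participant = "PX",
    sequence = paste0(seg, "AAAATTTT", "G"), v_call = "IGHV1-2*01",
    j_call = "IGHJ6*01", v_identity_pct = 100, v_mutation_count = 1L,
    j_mutation_count = 0L, v_segment = seg, junction = "AAAATTTT",
    junction_length = 8L, duplicate_count = 1L
  )
  expect_identical(nrow(infer_expressed_alleles(clone, fx$ref$db)), 0L)
  # same support with diverse junctions passes
  clone$junction <- sprintf("AAAATT%02d", 1:12)
  expect_identical(nrow(infer_expressed_alleles(clone, fx$ref$db)), 1L)
})

test_that("haplotype reconstruction requires a heterozygous anchor", {
  fx <- rep_fixture()
  p <- "P001"
  rr <- fx$ann$rearrangements[fx$ann$rearrangements$participant == p, ]
  hm <- reconstruct_haplotypes(rr)
  expect_identical(sort(hm$anchor_alleles),
                   sort(unique(fx$truth$anchors$j_allele[
                     fx$truth$anchors$participant == p])))
  # two bins with roughly 50/50 reads
  bins <- tapply(hm$table$reads, hm$table$anchor_allele, sum)
  expect_lt(abs(bins[1] / sum(bins) - 0.5), 3 * sqrt(0.25 / sum(bins)))
  # per-haplotype proportions sum to 1
  et <- expression_table(hm)
  sums <- tapply(et$proportion, et$anchor_allele, sum)
  expect_true(all(abs(sums - 1) < 1e-9))

  # homozygous anchor participant is rejected with the specified error
  ref <- small_ref()
  cfg <- sim_config(n_participants = 1L,
                    genes = unique(ref$db$alleles$gene), shm_rate = 0,
                    n_vdj = 300L, anchor_het_prob = 0, seed = 57L)
  truth <- simulate_population(ref, cfg)
  ann <- annotate_rearrangements(emit_repertoire(truth)$reads, ref$db,
                                 ref$j_db)
  expect_error(reconstruct_haplotypes(ann$rearrangements),
               "anchor not heterozygous")
})

test_that("cnv calling applies the read-count and k filters", {
  mk_hmap <- function(reads_extra) {
    tab <- tibble::tibble(
      anchor_allele = c("IGHJ6*02", "IGHJ6*02", "IGHJ6*03"),
      gene = "IGHV1-69",
      allele_name = c("IGHV1-69*01", "IGHV1-69*02", "IGHV1-69*01"),
      reads = c(400L, reads_extra, 380L)
    )
    tab$gene_reads <- c(rep(400L + reads_extra, 2), 380L)
    tab$k <- k_factor(tab$reads, tab$gene_reads)
    structure(list(participant = "PX", anchor_gene = "IGHJ6",
                   anchor_alleles = c("IGHJ6*02", "IGHJ6*03"),
                   table = tab),
              class = "ighv_haplotype_map")
  }
  # extra allele with 49 reads: excluded, gene is not duplicated
  cnv49 <- call_haplotype_cnv(mk_hmap(49L))
  expect_identical(cnv49$gene_states$cnv_state, "none")
  # 50 reads (k passes): single-haplotype duplication
  cnv50 <- call_haplotype_cnv(mk_hmap(50L))
  expect_identical(cnv50$gene_states$cnv_state, "single_haplotype_dup")
  # filters only shrink the called set
  strict <- call_haplotype_cnv(mk_hmap(50L), min_reads = 500L)
  expect_identical(strict$gene_states$cnv_state, "unresolved")
})

test_that("fold change is 1 for identical usage and omits undefined genes", {
  expr <- tibble::tibble(
    participant = "P1",
    anchor_allele = rep(c("J*01", "J*02"), each = 2),
    gene = rep(c("g1", "g2"), 2),
    unique_vdj_count = c(50L, 50L, 50L, 50L),
    proportion = c(0.5, 0.5, 0.5, 0.5)
  )
  dup <- tibble::tibble(
    participant = "P1", anchor_allele = rep(c("J*01", "J*02"), each = 2),
    gene = rep(c("g1", "g2"), 2),
    n_passing = c(2L, 1L, 1L, 1L), dup = c(TRUE, FALSE, FALSE, FALSE)
  )
  fc <- expression_fold_change(expr, dup)
  expect_identical(fc$gene, "g1")
  expect_identical(fc$fold_change, 1)
  expect_identical(attr(fc, "omitted"), "g2")
  # difference variant
  fc_d <- expression_fold_change(expr, dup, variant = "difference")
  expect_identical(fc_d$fold_change, 0)
})
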