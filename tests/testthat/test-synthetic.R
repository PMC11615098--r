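test_that("identical seed and config give byte-identical outputs", {
  ref <- small_ref()
  cfg <- sim_config(n_participants = 3L,
                    genes = unique(ref$db$alleles$gene),
                    amplicon_depth = 20L, n_vdj = 200L, seed = 9L)
  t1 <- simulate_population(ref, cfg)
  t2 <- simulate_population(ref, cfg)
  expect_identical(t1$genotype, t2$genotype)
  expect_identical(t1$anchors, t2$anchors)
  expect_identical(emit_amplicon_reads(t1)$reads,
                   emit_amplicon_reads(t2)$reads)
  expect_identical(emit_repertoire(t1)$reads, emit_repertoire(t2)$reads)
})

test_that("dup_rate bounds copy numbers and planted rates are recovered", {
  ref <- small_ref()
  genes <- unique(ref$db$alleles$gene)
  cfg0 <- sim_config(n_participants = 4L, genes = genes, dup_rate = 0,
                     seed = 2L)
  t0 <- simulate_population(ref, cfg0)
  copies0 <- dplyr::count(t0$genotype, participant, gene, chromosome)
  expect_true(all(copies0$n == 1L))

  cfg1 <- sim_config(n_participants = 4L, genes = genes, dup_rate = 1,
                     seed = 2L)
  t1 <- simulate_population(ref, cfg1)
  copies1 <- dplyr::count(t1$genotype, participant, gene, chromosome)
  expect_true(all(copies1$n == 2L))

  # binomial recovery over >= 1000 chromosome-gene draws
  cfg <- sim_config(n_participants = 125L, genes = genes, dup_rate = 0.2,
                    seed = 3L)
  tr <- simulate_population(ref, cfg)
  draws <- dplyr::count(tr$genotype, participant, gene, chromosome)
  p_hat <- mean(draws$n == 2L)
  se <- sqrt(0.2 * 0.8 / nrow(draws))
  expect_lt(abs(p_hat - 0.2), 3 * se)
})

test_that("mutate_allele plants exactly the reported substitutions", {
  db <- small_ref()$db
  key <- db$alleles$allele_key[1]
  seqfull <- db$alleles$sequence[1]
  spans <- ighvpop:::.spans_of(db, key)
  set.seed(5)
  m0 <- mutate_allele(seqfull, spans, 0L)
  expect_identical(m0$sequence, seqfull)
  expect_identical(nrow(m0$snvs), 0L)
  m1 <- mutate_allele(seqfull, spans, 1L)
  expect_identical(ighvpop:::.hamming(m1$sequence, seqfull), 1L)
  m3 <- mutate_allele(seqfull, spans, 3L)
  diff_abs <- ighvpop:::.mismatch_positions(m3$sequence, seqfull)
  # truth positions are emitted sorted, so they line up with the scan
  expect_identical(diff_abs, spans$v_region[1] + m3$snvs$position - 1L)
  expect_identical(
    vapply(diff_abs, function(p) substr(m3$sequence, p, p), character(1)),
    m3$snvs$alt
  )
  expect_error(mutate_allele(seqfull, spans, 1L, "promoter"),
               "region unavailable")
})

test_that("recombine_leader swaps leader part 1 and nothing else", {
  db <- small_ref()$db
  a <- db$alleles$allele_key[db$alleles$gene == "IGHV1-2"][1]
  b <- db$alleles$allele_key[db$alleles$gene == "IGHV3-23"][1]
  sa <- db$alleles$sequence[match(a, db$alleles$allele_key)]
  spans <- ighvpop:::.spans_of(db, a)
  donor <- extract_region(db, b, "leader1")
  rec <- recombine_leader(sa, spans, donor)
  expect_identical(substr(rec$sequence, rec$spans$leader1[1],
                          rec$spans$leader1[2]), donor)
  expect_identical(substr(rec$sequence, rec$spans$v_region[1],
                          rec$spans$v_region[2]),
                   extract_region(db, a, "v_region"))
  # classifying an error-free read of the product names the donor
  cl <- classify_leader(donor, a, db)
  expect_identical(cl$category, "mismatch")
  expect_true(b %in% cl$donor_alleles[[1]])
  expect_error(recombine_leader(sa, spans, extract_region(db, a, "leader1")),
               "no-op recombination")
})

test_that("amplicon reads follow the primer + allele + error model", {
  run <- small_clean_run()
  amp <- run$amp
  # depth x copies reads per participant, all mapping back to truth by name
  counts <- dplyr::count(amp$truth, participant)
  copies <- dplyr::count(run$truth$genotype, participant)
  expect_identical(counts$n, copies$n * run$cfg$amplicon_depth)
  expect_identical(anyDuplicated(amp$reads$read_id), 0L)
  # error-free: after primer trimming every read is an exact allele sequence
  tr <- trim_primers(amp$reads, run$ref$primers)
  expect_identical(nrow(tr$discards), 0L)
  expect_true(all(tr$reads$sequence %in% run$truth$genotype$sequence))

  # planted error rate recovered within 3 binomial SD
  ref <- small_ref()
  cfg <- sim_config(n_participants = 2L,
                    genes = unique(ref$db$alleles$gene),
                    amplicon_depth = 30L, per_base_error = 0.002,
                    seed = 13L)
  truth <- simulate_population(ref, cfg)
  amp2 <- emit_amplicon_reads(truth)
  sg <- ighvpop:::.subgroup_of(amp2$truth$gene)
  i <- match(amp2$truth$copy_id, truth$genotype$copy_id)
  templates <- paste0(
    ref$primers$fwd[match(sg, ref$primers$subgroup)],
    truth$genotype$sequence[i],
    ighvpop:::.revcomp(ref$primers$rev[match(sg, ref$primers$subgroup)])
  )
  n_err <- sum(mapply(function(a, b) ighvpop:::.hamming(a, b),
                      amp2$reads$sequence, templates))
  n_bases <- sum(nchar(templates))
  expected <- n_bases * 0.002
  expect_lt(abs(n_err - expected), 3 * sqrt(n_bases * 0.002 * 0.998))
})

test_that("repertoire sampling follows anchors and usage weights", {
  ref <- small_ref()
  genes <- unique(ref$db$alleles$gene)
  # no duplication, boost irrelevant: uniform gene usage, 50/50 anchors
  cfg <- sim_config(n_participants = 1L, genes = genes, dup_rate = 0,
                    shm_rate = 0, n_vdj = 10000L, anchor_het_prob = 1,
                    seed = 21L)
  truth <- simulate_population(ref, cfg)
  rep_ <- emit_repertoire(truth)
  tab <- table(rep_$truth$gene)
  p0 <- 1 / length(genes)
  se <- sqrt(p0 * (1 - p0) / nrow(rep_$truth))
  expect_true(all(abs(tab / nrow(rep_$truth) - p0) < 3 * se))
  jtab <- table(rep_$truth$j_truth)
  expect_identical(length(jtab), 2L)
  expect_lt(abs(jtab[1] / sum(jtab) - 0.5),
            3 * sqrt(0.25 / sum(jtab)))
  # reads trace back to exactly one truth record
  expect_identical(anyDuplicated(rep_$truth$sequence_id), 0L)
  expect_setequal(rep_$reads$read_id, rep_$truth$sequence_id)

  # duplicated gene with boost 2: ~2x usage on the duplicated haplotype
  cfg2 <- sim_config(n_participants = 6L, genes = genes, dup_rate = 0.3,
                     shm_rate = 0, n_vdj = 8000L, usage_boost = 2,
                     seed = 22L)
  truth2 <- simulate_population(ref, cfg2)
  rep2 <- emit_repertoire(truth2)
  counts <- rep2$truth |>
    dplyr::count(participant, chromosome, gene) |>
    dplyr::group_by(participant, chromosome) |>
    dplyr::mutate(prop = n / sum(n)) |>
    dplyr::ungroup()
  dup <- truth2$usage[truth2$usage$n_copies > 1L, ]
  ratios <- vapply(seq_len(nrow(dup)), function(i) {
    own <- counts$prop[counts$participant == dup$participant[i] &
                         counts$chromosome == dup$chromosome[i] &
                         counts$gene == dup$gene[i]]
    other <- counts$prop[counts$participant == dup$participant[i] &
                           counts$chromosome != dup$chromosome[i] &
                           counts$gene == dup$gene[i]]
    if (length(own) == 1L && length(other) == 1L) own / other else NA_real_
  }, numeric(1))
  # exclude haplotype pairs where the partner chromosome is also duplicated
  partner_dup <- mapply(function(p, ch, g) {
    any(dup$participant == p & dup$chromosome != ch & dup$gene == g)
  }, dup$participant, dup$chromosome, dup$gene)
  ratios <- ratios[!partner_dup & !is.na(ratios)]
  expect_gt(length(ratios), 3)
  expect_true(all(ratios > 1.3 & ratios < 3.0))
})
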