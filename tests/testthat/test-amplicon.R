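make_reads <- function(seqs, q = 37L, ids = NULL) {
  tibble::tibble(
    read_id = ids %||% sprintf("r%03d", seq_along(seqs)),
    sequence = seqs,
    quality = ighvpop:::.qual_string(nchar(seqs), q)
  )
}
`%||%` <- function(a, b) if (is.null(a)) b else a

test_that("trim_primers tolerates up to max_mismatches and logs discards", {
  primers <- tibble::tibble(subgroup = 1L, fwd = "ACGTACGTAC",
                            rev = "TTGGCCAATT")
  insert <- "AAACCCGGGTTTAAACCCGGG"
  clean <- paste0(primers$fwd, insert, ighvpop:::.revcomp(primers$rev))
  mm1 <- clean
  substr(mm1, 1, 1) <- "T"  # 1 mismatch in forward primer
  mm3 <- clean
  substr(mm3, 1, 3) <- "TTT"  # 3 mismatches
  naked <- paste0("GGGGGGGGGG", insert, "CCCCCCCCCC")
  res <- trim_primers(make_reads(c(clean, mm1, mm3, naked)), primers,
                      max_mismatches = 2L)
  expect_identical(res$reads$read_id, c("r001", "r002"))
  expect_identical(unique(res$reads$sequence), insert)
  expect_identical(sort(res$discards$read_id), c("r003", "r004"))
  expect_identical(nrow(res$reads) + nrow(res$discards), res$n_in)
  # qualities trimmed to the same window
  expect_identical(nchar(res$reads$quality), nchar(res$reads$sequence))
})

test_that("quality_filter keeps mean >= threshold, boundary inclusive", {
  hi <- make_reads("ACGTACGT", q = 37L, ids = "hi")
  lo <- make_reads("ACGTACGT", q = 20L, ids = "lo")
  # half Q30, half Q36: mean exactly 33 is retained
  boundary <- tibble::tibble(
    read_id = "edge", sequence = "ACGTACGT",
    quality = paste0(ighvpop:::.qual_string(4L, 30L),
                     ighvpop:::.qual_string(4L, 36L))
  )
  malformed <- tibble::tibble(read_id = "bad", sequence = "ACGTACGT",
                              quality = "!!")
  res <- quality_filter(rbind(hi, lo, boundary, malformed), min_mean_q = 33)
  expect_setequal(res$reads$read_id, c("hi", "edge"))
  expect_identical(res$discards$reason[res$discards$read_id == "bad"],
                   "malformed_quality")
  expect_identical(res$discards$reason[res$discards$read_id == "lo"],
                   "low_quality")
})

test_that("dereplicate collapses exact sequences and conserves counts", {
  reads <- make_reads(c(rep("AAAA", 3), "CCCC"))
  uniq <- dereplicate(reads)
  expect_identical(nrow(uniq), 2L)
  expect_identical(uniq$count, c(3L, 1L))
  expect_identical(uniq$sequence[1], "AAAA")
  set.seed(8)
  rnd <- make_reads(replicate(60, ighvpop:::.random_dna(12L)))
  expect_identical(sum(dereplicate(rnd)$count), nrow(rnd))
  alldiff <- dereplicate(make_reads(c("AA", "CC", "GG")))
  expect_true(all(alldiff$count == 1L))
})

test_that("abundance_filter applies count then gene-fraction thresholds", {
  uniq <- tibble::tibble(
    query_id = sprintf("u%d", 1:4), participant = "P1",
    sequence = c("A", "C", "G", "T"),
    count = c(50L, 40L, 10L, 1L),
    gene = c("g1", "g1", "g1", "g2")
  )
  kept <- abundance_filter(uniq, min_count = 2L, min_gene_fraction = 0.1)
  # singleton gone; 50/100 and 40/100 retained; 10/100 exactly at 0.1 kept
  expect_setequal(kept$query_id, c("u1", "u2", "u3"))
  kept2 <- abundance_filter(uniq, min_count = 2L, min_gene_fraction = 0.2)
  expect_setequal(kept2$query_id, c("u1", "u2"))
  # monotonicity in min_count on simulated noisy uniques
  run <- small_ref()
  cfg <- sim_config(n_participants = 2L,
                    genes = unique(run$db$alleles$gene),
                    amplicon_depth = 60L, per_base_error = 0.002,
                    seed = 17L)
  truth <- simulate_population(run, cfg)
  amp <- emit_amplicon_reads(truth)
  tr <- trim_primers(amp$reads, run$primers)
  u <- ighvpop:::.provisional_genes(dereplicate(tr$reads), run$db)
  prev <- NULL
  for (mc in c(1L, 2L, 4L, 8L)) {
    now <- abundance_filter(u, min_count = mc)$query_id
    if (!is.null(prev)) expect_true(all(now %in% prev))
    prev <- now
  }
})

test_that("abundance filtering removes error-derived uniques, keeps alleles", {
  run <- small_ref()
  cfg <- sim_config(n_participants = 3L,
                    genes = unique(run$db$alleles$gene),
                    amplicon_depth = 200L, per_base_error = 0.002,
                    seed = 19L)
  truth <- simulate_population(run, cfg)
  amp <- emit_amplicon_reads(truth)
  tr <- trim_primers(amp$reads, run$primers)
  u <- ighvpop:::.provisional_genes(dereplicate(tr$reads), run$db)
  kept <- abundance_filter(u)
  is_true <- function(df) paste(df$participant, df$sequence) %in%
    paste(truth$genotype$participant, truth$genotype$sequence)
  err_in <- sum(!is_true(u))
  err_out <- sum(!is_true(kept))
  expect_gt(err_in, 50)               # the error cloud exists
  expect_lt(err_out / err_in, 0.05)   # >= 95% of it removed
  truth_seqs <- unique(truth$genotype[, c("participant", "sequence")])
  expect_true(all(paste(truth_seqs$participant, truth_seqs$sequence) %in%
                    paste(kept$participant, kept$sequence)))
})

test_that("assign_allele finds exact and novel matches with paper-style names", {
  db <- small_ref()$db
  key <- "IGHV1-2*02"
  seqfull <- db$alleles$sequence[match(key, db$alleles$allele_key)]
  call <- assign_allele(seqfull, db, segment = "full")
  expect_identical(call$allele_key, key)
  expect_identical(call$identity_pct, 100)
  expect_false(call$is_novel)

  # plant a single V-region substitution; the parent stays closest and the
  # novel name carries the RefPosAlt token
  spans <- ighvpop:::.spans_of(db, key)
  vstart <- spans$v_region[1]
  pos <- 288L
  ref_base <- substr(seqfull, vstart + pos - 1L, vstart + pos - 1L)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mut <- seqfull
  substr(mut, vstart + pos - 1L, vstart + pos - 1L) <- alt
  call2 <- assign_allele(mut, db, segment = "full")
  expect_identical(call2$allele_key, key)
  expect_true(call2$is_novel)
  expect_identical(call2$novel_name,
                   sprintf("%s_%s288%s", key, ref_base, alt))
  expect_identical(call2$snvs[[1]]$region, "v_region")
  expect_identical(call2$snvs[[1]]$position, pos)
  expect_error(assign_allele("ACGT", reference_db(
    tibble::tibble(gene = character(), allele_id = character(),
                   sequence = character(), source = character()),
    tibble::tibble(allele_key = character(), region_name = character(),
                   start = integer(), end = integer()))),
    "empty reference")
})

test_that("assignment matches an exhaustive independent scan", {
  db <- small_ref()$db
  v_ref <- ighvpop:::.v_regions(db)
  set.seed(23)
  for (i in 1:30) {
    parent <- sample(names(v_ref), 1)
    q <- v_ref[[parent]]
    n_mut <- sample(0:3, 1)
    if (n_mut > 0) {
      pos <- sample(nchar(q), n_mut)
      for (p in pos) {
        substr(q, p, p) <- sample(setdiff(c("A", "C", "G", "T"),
                                          substr(q, p, p)), 1)
      }
    }
    call <- assign_allele(q, db, segment = "v_region")
    # oracle: plain full scan with strsplit-based comparison
    qc <- strsplit(q, "")[[1]]
    ids <- vapply(sort(names(v_ref)), function(k) {
      rc <- strsplit(v_ref[[k]], "")[[1]]
      if (length(rc) != length(qc)) return(-Inf)
      100 * mean(qc == rc)
    }, numeric(1))
    expect_identical(call$allele_key, names(ids)[which.max(ids)])
    expect_lt(abs(call$identity_pct - max(ids)), 1e-9)
  }
})

test_that("call_regulatory_snvs recovers planted regulatory variants", {
  db <- small_ref()$db
  key <- db$alleles$allele_key[1]
  seqfull <- db$alleles$sequence[1]
  spans <- ighvpop:::.spans_of(db, key)
  expect_identical(nrow(call_regulatory_snvs(seqfull, key, db)), 0L)
  # plant an intron SNV at intron position 12
  p <- spans$intron[1] + 11L
  ref_base <- substr(seqfull, p, p)
  alt <- setdiff(c("A", "C", "G", "T"), ref_base)[1]
  mut <- seqfull
  substr(mut, p, p) <- alt
  snvs <- call_regulatory_snvs(mut, key, db)
  expect_identical(nrow(snvs), 1L)
  expect_identical(snvs$region, "intron")
  expect_identical(snvs$position, 12L)
  expect_identical(snvs$ref, ref_base)
  expect_identical(snvs$alt, alt)
  # leader1 position 19, the style of the leader logogram tokens
  p19 <- spans$leader1[1] + 18L
  ref19 <- substr(seqfull, p19, p19)
  alt19 <- setdiff(c("A", "C", "G", "T"), ref19)[1]
  mut19 <- seqfull
  substr(mut19, p19, p19) <- alt19
  snvs19 <- call_regulatory_snvs(mut19, key, db)
  expect_identical(snvs19$region, "leader1")
  expect_identical(snvs19$position, 19L)
  # truncated reference: skipped with warning
  trunc <- reference_db(
    tibble::tibble(gene = "IGHV1-2", allele_id = "09",
                   sequence = "TGTGCAGCCTGG", source = "IgPDb/OGRDB"),
    tibble::tibble(allele_key = "IGHV1-2*09", region_name = "v_region",
                   start = 1L, end = 12L)
  )
  expect_warning(out <- call_regulatory_snvs("TGTGCAGCCTGG", "IGHV1-2*09",
                                             trunc),
                 "truncated")
  expect_identical(nrow(out), 0L)
})

test_that("name_novel formats and orders SNV tokens deterministically", {
  snv <- function(pos, ref, alt) {
    tibble::tibble(region = "v_region", position = as.integer(pos),
                   ref = ref, alt = alt)
  }
  expect_identical(name_novel("IGHV6-1*01", snv(288, "C", "T")),
                   "IGHV6-1*01_C288T")
  two <- rbind(snv(288, "C", "T"), snv(10, "A", "G"))
  expect_identical(name_novel("X*01", two), "X*01_A10G_C288T")
  expect_identical(name_novel("X*01", two[2:1, ]), "X*01_A10G_C288T")
  expect_error(name_novel("X*01", snv(integer(), character(), character())),
               "at least one")
})

test_that("pipeline stages conserve read counts", {
  run <- small_clean_run()
  st <- run$germ$stages
  tr_row <- st[st$stage == "trim_primers", ]
  expect_identical(tr_row$n_in,
                   tr_row$n_out +
                     sum(run$germ$discards$reason %in%
                           c("too_short", "primer_not_found")))
  qf_row <- st[st$stage == "quality_filter", ]
  expect_identical(qf_row$n_in,
                   qf_row$n_out +
                     sum(run$germ$discards$reason %in%
                           c("malformed_quality", "low_quality")))
  # dereplication conserves reads into counts
  expect_identical(sum(run$germ$uniques$count),
                   st$n_out[st$stage == "quality_filter"])
})
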