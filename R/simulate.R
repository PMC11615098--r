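# Synthetic-data generator: diploid truth genotypes over an IGHV panel,
# germline amplicon reads, and IGHJ6-anchored expressed repertoires.
#
# The generator defines the study conditions every downstream stage is tested
# against: 0-2 allele copies per chromosome per gene (duplications planted at
# dup_rate), novel alleles as 1-3 V-region SNVs, leader part 1 SNVs and
# cross-gene leader recombinants ("mismatch" leaders), substitution-only
# sequencing error, and low-level somatic mutation in IgM reads.

#' Build a validated simulation configuration
#'
#' Defaults reflect the data structure the analyses assume: a cohort of
#' matched-donor scale (8 participants), duplication planted on 15% of
#' chromosomes per gene, novel V-region alleles on 10% of planted copies,
#' leader SNVs on 6% and leader recombinants on 20% of copies (the two
#' observed leader-variation rates), amplicon depth 200 at a 0.002/base
#' substitution error, 5000 rearrangements per repertoire at somatic mutation
#' rate 0.005/base, and a 2-fold usage boost for duplicated genes.
#'
#' @param n_participants Number of simulated participants.
#' @param genes Gene panel (must exist in the reference used downstream).
#' @param dup_rate Probability a chromosome carries 2 copies of a gene.
#' @param novel_snv_rate Probability a planted copy is a novel allele
#'   carrying 1-3 V-region SNVs.
#' @param leader_snv_rate Probability a planted copy carries one leader1 SNV.
#' @param leader_recomb_rate Probability a planted copy has its leader1
#'   swapped for another gene's leader (a "mismatch" leader).
#' @param amplicon_depth Germline reads per gene copy per participant.
#' @param per_base_error Substitution error probability per base (amplicons).
#' @param n_vdj Rearrangements per expressed repertoire.
#' @param shm_rate Per-base somatic substitution probability in expressed
#'   reads.
#' @param usage_boost Multiplicative usage increase for a gene duplicated on
#'   a haplotype (total gene weight = base x boost, shared across the two
#'   copies).
#' @param anchor_het_prob Probability a participant is heterozygous for the
#'   IGHJ6 anchor.
#' @param seed Integer seed; identical seed + config give byte-identical
#'   outputs.
#' @return A list of class `ighv_sim_config`.
#' @export
sim_config <- function(n_participants = 8L,
                       genes = .DEFAULT_PANEL,
                       dup_rate = 0.15,
                       novel_snv_rate = 0.10,
                       leader_snv_rate = 0.06,
                       leader_recomb_rate = 0.20,
                       amplicon_depth = 200L,
                       per_base_error = 0.002,
                       n_vdj = 5000L,
                       shm_rate = 0.005,
                       usage_boost = 2,
                       anchor_het_prob = 0.5,
                       seed = 1L) {
  probs <- c(dup_rate = dup_rate, novel_snv_rate = novel_snv_rate,
             leader_snv_rate = leader_snv_rate,
             leader_recomb_rate = leader_recomb_rate,
             per_base_error = per_base_error, shm_rate = shm_rate,
             anchor_het_prob = anchor_het_prob)
  if (any(probs < 0 | probs > 1)) {
    stop("probabilities must lie in [0, 1]: ",
         paste(names(probs)[probs < 0 | probs > 1], collapse = ", "),
         call. = FALSE)
  }
  if (novel_snv_rate + leader_snv_rate + leader_recomb_rate > 1) {
    stop("novel_snv_rate + leader_snv_rate + leader_recomb_rate must not ",
         "exceed 1 (modification events are exclusive per copy)",
         call. = FALSE)
  }
  counts <- c(n_participants = n_participants, amplicon_depth = amplicon_depth,
              n_vdj = n_vdj)
  if (any(counts < 1)) {
    stop("counts must be positive: ",
         paste(names(counts)[counts < 1], collapse = ", "), call. = FALSE)
  }
  if (usage_boost <= 0) stop("usage_boost must be > 0", call. = FALSE)
  structure(list(
    n_participants = as.integer(n_participants), genes = genes,
    dup_rate = dup_rate, novel_snv_rate = novel_snv_rate,
    leader_snv_rate = leader_snv_rate,
    leader_recomb_rate = leader_recomb_rate,
    amplicon_depth = as.integer(amplicon_depth),
    per_base_error = per_base_error, n_vdj = as.integer(n_vdj),
    shm_rate = shm_rate, usage_boost = usage_boost,
    anchor_het_prob = anchor_het_prob, seed = as.integer(seed)
  ), class = "ighv_sim_config")
}

#' Plant SNVs in one region of an allele sequence
#'
#' Substitutes `n_snvs` distinct positions inside the named region; the
#' replacement base never equals the reference base. Positions in the
#' returned truth list are 1-based within the region.
#'
#' @param sequence Full-length allele sequence.
#' @param spans Named list of `c(start, end)` region spans (as from the
#'   reference database).
#' @param n_snvs Number of substitutions.
#' @param region_name Region to mutate (default `v_region`).
#' @return List with `sequence` (mutated copy) and `snvs` (tibble `region`,
#'   `position`, `ref`, `alt`).
#' @export
mutate_allele <- function(sequence, spans, n_snvs,
                          region_name = "v_region") {
  if (!region_name %in% names(spans)) {
    stop("region unavailable: ", region_name, call. = FALSE)
  }
  span <- spans[[region_name]]
  width <- span[2] - span[1] + 1L
  if (n_snvs > width) stop("n_snvs exceeds region length", call. = FALSE)
  if (n_snvs == 0L) {
    return(list(sequence = sequence, snvs = .snv_tibble()))
  }
  local_pos <- sort(sample.int(width, n_snvs))
  abs_pos <- span[1] + local_pos - 1L
  ref <- vapply(abs_pos, function(p) substr(sequence, p, p), character(1))
  alt <- .random_alt(ref)
  list(
    sequence = .apply_substitutions(sequence, abs_pos, alt),
    snvs = .snv_tibble(rep(region_name, n_snvs), local_pos, ref, alt)
  )
}

#' Swap the leader part 1 of one allele for another's
#'
#' Models the "mismatch" class of leader variation: the recipient keeps its
#' V-region (and everything downstream of leader part 1) but carries the
#' donor's leader part 1.
#'
#' @param recipient_sequence,recipient_spans Recipient full sequence and
#'   region spans.
#' @param donor_leader1 Donor leader part 1 sequence (must differ from the
#'   recipient's).
#' @return List with `sequence` and updated `spans` (spans shift if the two
#'   leaders differ in length).
#' @export
recombine_leader <- function(recipient_sequence, recipient_spans,
                             donor_leader1) {
  if (!"leader1" %in% names(recipient_spans)) {
    stop("recipient lacks a leader1 span", call. = FALSE)
  }
  sp <- recipient_spans[["leader1"]]
  own <- substr(recipient_sequence, sp[1], sp[2])
  if (identical(own, donor_leader1)) {
    stop("no-op recombination: donor leader identical to recipient's",
         call. = FALSE)
  }
  before <- if (sp[1] > 1L) substr(recipient_sequence, 1L, sp[1] - 1L) else ""
  after <- substr(recipient_sequence, sp[2] + 1L, nchar(recipient_sequence))
  delta <- nchar(donor_leader1) - nchar(own)
  spans <- lapply(names(recipient_spans), function(r) {
    s <- recipient_spans[[r]]
    if (r == "leader1") c(s[1], s[2] + delta) else s + delta
  })
  names(spans) <- names(recipient_spans)
  list(sequence = paste0(before, donor_leader1, after), spans = spans)
}

#' Simulate a diploid population over an IGHV panel
#'
#' Each participant gets two chromosomes. Per gene per chromosome the copy
#' number is 1, or 2 with probability `dup_rate`; alleles are drawn uniformly
#' (with replacement, so identical-allele duplications occur and exercise the
#' allele-count method's documented blind spot). Each copy independently
#' receives at most one modification: novel V-region SNVs
#' (`novel_snv_rate`, 1-3 SNVs), a single leader1 SNV (`leader_snv_rate`),
#' or a cross-gene leader recombination (`leader_recomb_rate`). Each
#' chromosome is assigned one IGHJ6 allele; participants are anchor-
#' heterozygous with probability `anchor_het_prob`.
#'
#' @param reference A list from [synthetic_reference()] (elements `db`,
#'   `j_db`, `primers`), or an `ighv_refdb` (then `j_db` must be supplied).
#' @param config An `ighv_sim_config`.
#' @param j_db Optional IGHJ allele tibble when `reference` is a bare
#'   `ighv_refdb`.
#' @return A list of class `ighv_truth` with elements `genotype` (one row
#'   per planted gene copy: participant, gene, chromosome, copy, base
#'   allele, canonical planted name, full sequence, V-segment, event type,
#'   truth SNVs, leader donor), `anchors`, `usage` (per-chromosome per-gene
#'   weights and expected usage proportions), and the `config`/reference
#'   handles.
#' @export
simulate_population <- function(reference, config, j_db = NULL) {
  if (inherits(reference, "ighv_refdb")) {
    db <- reference
    if (is.null(j_db)) stop("j_db required when passing a bare ighv_refdb",
                            call. = FALSE)
    primers <- NULL
  } else {
    db <- reference$db
    j_db <- reference$j_db
    primers <- reference$primers
  }
  missing_genes <- setdiff(config$genes, unique(db$alleles$gene))
  if (length(missing_genes)) {
    stop("gene(s) absent from reference: ",
         paste(missing_genes, collapse = ", "), call. = FALSE)
  }
  set.seed(config$seed)

  spans_cache <- lapply(setNames(db$alleles$allele_key, db$alleles$allele_key),
                        function(k) .spans_of(db, k))
  leader_cache <- vapply(db$alleles$allele_key, function(k)
    substr(db$alleles$sequence[match(k, db$alleles$allele_key)],
           spans_cache[[k]]$leader1[1], spans_cache[[k]]$leader1[2]),
    character(1))

  geno <- list()
  anchors <- list()
  participants <- sprintf("P%03d", seq_len(config$n_participants))
  for (p in participants) {
    het <- runif(1) < config$anchor_het_prob
    j_alleles <- if (het) sample(j_db$allele, 2L) else
      rep(sample(j_db$allele, 1L), 2L)
    anchors[[p]] <- tibble(participant = p, chromosome = 1:2,
                           j_allele = j_alleles)
    for (chrom in 1:2) {
      for (gene in config$genes) {
        n_copies <- 1L + rbinom(1L, 1L, config$dup_rate)
        fam <- .gene_alleles(db, gene)
        for (cp in seq_len(n_copies)) {
          base_key <- sample(fam$allele_key, 1L)
          seqfull <- fam$sequence[match(base_key, fam$allele_key)]
          spans <- spans_cache[[base_key]]
          event <- "none"
          snvs <- .snv_tibble()
          donor <- NA_character_
          name <- base_key
          u <- runif(1)
          if (u < config$novel_snv_rate) {
            event <- "novel"
            mu <- mutate_allele(seqfull, spans, sample(1:3, 1L), "v_region")
            seqfull <- mu$sequence
            snvs <- mu$snvs
            name <- name_novel(base_key, mu$snvs)
          } else if (u < config$novel_snv_rate + config$leader_snv_rate) {
            event <- "leader_snv"
            mu <- mutate_allele(seqfull, spans, 1L, "leader1")
            seqfull <- mu$sequence
            snvs <- mu$snvs
          } else if (u < config$novel_snv_rate + config$leader_snv_rate +
                       config$leader_recomb_rate) {
            event <- "leader_recomb"
            own_leader <- leader_cache[[base_key]]
            donors <- db$alleles$allele_key[
              db$alleles$gene != gene & leader_cache != own_leader]
            donor <- sample(donors, 1L)
            rec <- recombine_leader(seqfull, spans, leader_cache[[donor]])
            seqfull <- rec$sequence
            spans <- rec$spans
          }
          vsp <- spans[["v_region"]]
          geno[[length(geno) + 1L]] <- tibble(
            participant = p, gene = gene, chromosome = chrom, copy = cp,
            base_allele = base_key, allele_name = name,
            sequence = seqfull,
            v_segment = substr(seqfull, vsp[1], vsp[2]),
            event = event, snvs = list(snvs), leader_donor = donor
          )
        }
      }
    }
  }
  genotype <- bind_rows(geno)
  genotype$copy_id <- sprintf("%s_%s_c%d_%d", genotype$participant,
                              genotype$gene, genotype$chromosome,
                              genotype$copy)

  # per-chromosome gene usage: weight 1, or usage_boost when duplicated on
  # that chromosome; shared equally across the copies of the gene
  usage <- genotype |>
    group_by(.data$participant, .data$chromosome, .data$gene) |>
    summarise(n_copies = dplyr::n(), .groups = "drop_last") |>
    mutate(weight = ifelse(.data$n_copies > 1L, config$usage_boost, 1)) |>
    mutate(expected_proportion = .data$weight / sum(.data$weight)) |>
    ungroup()

  structure(list(
    genotype = genotype, anchors = bind_rows(anchors), usage = usage,
    config = config, db = db, j_db = j_db, primers = primers
  ), class = "ighv_truth")
}

#' @export
print.ighv_truth <- function(x, ...) {
  cat("IGHV simulation truth:", length(unique(x$genotype$participant)),
      "participants,", length(unique(x$genotype$gene)), "genes,",
      nrow(x$genotype), "planted gene copies\n")
  invisible(x)
}

#' Emit germline amplicon reads from a simulated population
#'
#' One amplicon template per planted gene copy: subgroup forward primer +
#' full allele sequence + reverse-complemented reverse primer, sequenced to
#' `amplicon_depth` with i.i.d. substitution errors at `per_base_error`.
#' Qualities are constant Q37 except Q20 at error positions. Read names
#' encode the participant (not the truth); the returned `truth` table maps
#' every read back to its planted copy.
#'
#' @param truth An `ighv_truth` from [simulate_population()].
#' @param primers Optional primer tibble (`subgroup`, `fwd`, `rev`); defaults
#'   to the primers bundled with the truth object.
#' @return List with `reads` (tibble `read_id`, `participant`, `sequence`,
#'   `quality`) and `truth` (tibble `read_id`, `copy_id`, `participant`,
#'   `gene`, `chromosome`, `copy`, `allele_name`).
#' @export
emit_amplicon_reads <- function(truth, primers = NULL) {
  config <- truth$config
  primers <- primers %||% truth$primers
  if (is.null(primers)) stop("no primers available", call. = FALSE)
  sg <- .subgroup_of(truth$genotype$gene)
  missing_sg <- setdiff(unique(sg), primers$subgroup)
  if (length(missing_sg)) {
    stop("no primers for subgroup(s): ", paste(missing_sg, collapse = ", "),
         call. = FALSE)
  }
  set.seed(config$seed + 1L)
  i <- match(sg, primers$subgroup)
  templates <- paste0(primers$fwd[i], truth$genotype$sequence,
                      .revcomp(primers$rev[i]))
  depth <- config$amplicon_depth
  idx <- rep(seq_len(nrow(truth$genotype)), each = depth)
  seqs <- templates[idx]
  mut <- .mutate_sequences(seqs, config$per_base_error)

  participant <- truth$genotype$participant[idx]
  ord <- order(participant)  # stable within, already grouped by participant
  read_id <- sprintf("%s_amp%06d", participant,
                     stats::ave(seq_along(idx), participant, FUN = seq_along))
  qual <- .qual_string(nchar(seqs), 37L)
  for (r in which(lengths(mut$positions) > 0L)) {
    qual[r] <- .apply_substitutions(
      qual[r], mut$positions[[r]],
      rep(intToUtf8(33L + 20L), length(mut$positions[[r]])))
  }
  reads <- tibble(read_id = read_id, participant = participant,
                  sequence = mut$sequences, quality = qual)
  truth_map <- tibble(
    read_id = read_id,
    copy_id = truth$genotype$copy_id[idx],
    participant = participant,
    gene = truth$genotype$gene[idx],
    chromosome = truth$genotype$chromosome[idx],
    copy = truth$genotype$copy[idx],
    allele_name = truth$genotype$allele_name[idx]
  )
  list(reads = reads, truth = truth_map)
}

#' Emit an anchored expressed (IgM) repertoire from a simulated population
#'
#' Each rearrangement picks a chromosome (50/50), then a gene copy on that
#' chromosome with probability proportional to usage (a duplicated gene's
#' weight is `usage_boost`, split across its copies), and concatenates the
#' copy's V-region, a random 8-20 nt junction, and the chromosome's IGHJ6
#' allele. Somatic substitutions are applied at `shm_rate` per base.
#'
#' @param truth An `ighv_truth`.
#' @return List with `reads` (FASTQ-ready tibble) and `truth` (AIRR-style
#'   truth tibble: `sequence_id`, `participant`, `chromosome`, `gene`,
#'   `v_truth`, `j_truth`, `junction`).
#' @export
emit_repertoire <- function(truth) {
  config <- truth$config
  set.seed(config$seed + 2L)
  geno <- truth$genotype
  usage <- truth$usage
  j_seq <- setNames(truth$j_db$sequence, truth$j_db$allele)

  out_reads <- vector("list", config$n_participants)
  out_truth <- vector("list", config$n_participants)
  participants <- unique(geno$participant)
  for (pi in seq_along(participants)) {
    p <- participants[pi]
    g <- geno[geno$participant == p, , drop = FALSE]
    if (nrow(g) == 0L) stop("participant with zero gene copies: ", p,
                            call. = FALSE)
    u <- usage[usage$participant == p, , drop = FALSE]
    # per-copy sampling weight = gene weight / n_copies, within chromosome
    key <- paste(g$chromosome, g$gene)
    ukey <- paste(u$chromosome, u$gene)
    w <- u$weight[match(key, ukey)] / u$n_copies[match(key, ukey)]
    n <- config$n_vdj
    chrom <- 1L + rbinom(n, 1L, 0.5)
    pick <- integer(n)
    for (ch in 1:2) {
      rows <- which(g$chromosome == ch)
      sel <- which(chrom == ch)
      pick[sel] <- sample(rows, length(sel), replace = TRUE,
                          prob = w[rows])
    }
    jl <- sample(8:20, n, replace = TRUE)
    junction <- vapply(jl, .random_dna, character(1))
    anch <- truth$anchors[truth$anchors$participant == p, , drop = FALSE]
    j_allele <- anch$j_allele[match(chrom, anch$chromosome)]
    seqs <- paste0(g$v_segment[pick], junction, j_seq[j_allele])
    mut <- .mutate_sequences(seqs, config$shm_rate)
    ids <- sprintf("%s_vdj%06d", p, seq_len(n))
    out_reads[[pi]] <- tibble(
      read_id = ids, participant = p, sequence = mut$sequences,
      quality = .qual_string(nchar(seqs), 37L)
    )
    out_truth[[pi]] <- tibble(
      sequence_id = ids, participant = p, chromosome = chrom,
      gene = g$gene[pick], v_truth = g$allele_name[pick],
      copy_id = g$copy_id[pick], j_truth = j_allele, junction = junction
    )
  }
  list(reads = bind_rows(out_reads), truth = bind_rows(out_truth))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
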