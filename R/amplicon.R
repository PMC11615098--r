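# Germline amplicon pipeline: primer trimming, quality filtering,
# dereplication, abundance filtering, closest-match allele assignment,
# regulatory-region SNV calling, and novel-allele naming.
#
# Alignment contract: exact match, then equal-length positionwise
# comparison; end-gap-free pairwise alignment (match +1, mismatch -1, gap
# open -4, extend -1) only when lengths differ. Identity is
# matches / aligned V-region columns. Indels are never reported as SNVs.

#' Remove subgroup primers from amplicon reads
#'
#' Locates the forward primer at the 5' end and the reverse-complemented
#' reverse primer at the 3' end, each allowing up to `max_mismatches`
#' substitutions, and removes both. Reads lacking either primer (for every
#' supplied subgroup pair) are discarded and logged.
#'
#' @param reads Tibble with `read_id`, `sequence`, `quality` (and optionally
#'   `participant`).
#' @param primers Tibble with columns `subgroup`, `fwd`, `rev`.
#' @param max_mismatches Maximum substitutions tolerated per primer
#'   (default 2).
#' @return List with `reads` (trimmed, plus a `subgroup` column), `discards`
#'   (tibble `read_id`, `reason`), and `n_in`.
#' @export
trim_primers <- function(reads, primers, max_mismatches = 2L) {
  n_in <- nrow(reads)
  if (n_in == 0L) {
    return(list(reads = reads, discards = tibble(read_id = character(),
                                                 reason = character()),
                n_in = 0L))
  }
  rc_rev <- .revcomp(primers$rev)
  min_len <- max(nchar(primers$fwd) + nchar(primers$rev)) + 1L
  too_short <- nchar(reads$sequence) < min_len
  discards <- tibble(read_id = reads$read_id[too_short],
                     reason = rep("too_short", sum(too_short)))
  ok <- reads[!too_short, , drop = FALSE]
  if (nrow(ok) == 0L) {
    return(list(reads = ok, discards = discards, n_in = n_in))
  }

  n_pair <- nrow(primers)
  fwd_mm <- matrix(0L, nrow(ok), n_pair)
  rev_mm <- matrix(0L, nrow(ok), n_pair)
  for (j in seq_len(n_pair)) {
    fwd_mm[, j] <- .prefix_mismatches(ok$sequence, primers$fwd[j])
    rev_mm[, j] <- .suffix_mismatches(ok$sequence, rc_rev[j])
  }
  total <- fwd_mm + rev_mm
  best <- max.col(-total, ties.method = "first")
  bi <- cbind(seq_len(nrow(ok)), best)
  pass <- fwd_mm[bi] <= max_mismatches & rev_mm[bi] <= max_mismatches

  discards <- bind_rows(discards,
                        tibble(read_id = ok$read_id[!pass],
                               reason = rep("primer_not_found", sum(!pass))))
  kept <- ok[pass, , drop = FALSE]
  bkeep <- best[pass]
  flen <- nchar(primers$fwd)[bkeep]
  rlen <- nchar(primers$rev)[bkeep]
  len <- nchar(kept$sequence)
  kept$sequence <- substr(kept$sequence, flen + 1L, len - rlen)
  kept$quality <- substr(kept$quality, flen + 1L, len - rlen)
  kept$subgroup <- primers$subgroup[bkeep]
  list(reads = kept, discards = discards, n_in = n_in)
}

#' Filter reads by mean Phred quality
#'
#' Reads with mean Phred score below `min_mean_q` are removed; the boundary
#' is inclusive (mean exactly `min_mean_q` is kept). Reads whose quality
#' string length does not match the sequence are rejected with a parse
#' error logged.
#'
#' @param reads Read tibble.
#' @param min_mean_q Minimum mean Phred score (default 33).
#' @return List with `reads`, `discards`, `n_in`.
#' @export
quality_filter <- function(reads, min_mean_q = 33) {
  n_in <- nrow(reads)
  malformed <- nchar(reads$quality) != nchar(reads$sequence)
  ok <- reads[!malformed, , drop = FALSE]
  mq <- .mean_phred(ok$quality)
  keep <- mq >= min_mean_q
  discards <- bind_rows(
    tibble(read_id = reads$read_id[malformed],
           reason = rep("malformed_quality", sum(malformed))),
    tibble(read_id = ok$read_id[!keep],
           reason = rep("low_quality", sum(!keep)))
  )
  list(reads = ok[keep, , drop = FALSE], discards = discards, n_in = n_in)
}

#' Collapse reads into unique sequences
#'
#' Exact-sequence dereplication per participant; counts are conserved
#' (the counts of the uniques sum to the number of input reads).
#'
#' @param reads Read tibble (a `participant` column is honoured; absent, all
#'   reads are treated as one sample).
#' @return Tibble of unique sequences sorted by count (descending):
#'   `query_id`, `participant`, `sequence`, `count`, `mean_quality`.
#' @export
dereplicate <- function(reads) {
  if (!"participant" %in% names(reads)) reads$participant <- "S1"
  reads$.mq <- .mean_phred(reads$quality)
  uniq <- reads |>
    group_by(.data$participant, .data$sequence) |>
    summarise(count = dplyr::n(), mean_quality = mean(.data$.mq),
              .groups = "drop") |>
    arrange(.data$participant, desc(.data$count), .data$sequence)
  uniq |>
    group_by(.data$participant) |>
    mutate(query_id = sprintf("%s_u%05d", .data$participant,
                              row_number())) |>
    ungroup() |>
    select("query_id", "participant", "sequence", "count", "mean_quality")
}

#' Remove low-abundance unique sequences
#'
#' Two conditions: `count >= min_count`, and `count >= min_gene_fraction`
#' times the non-singleton reads provisionally assigned to the unique's gene
#' for that participant. Singletons are excluded from the fraction
#' denominator: with a per-base error model most error-derived uniques are
#' singletons, and counting them would starve true alleles of a many-copy
#' duplicated gene out of their own denominator. Because the denominator
#' does not depend on `min_count`, raising either threshold never enlarges
#' the retained set.
#'
#' @param uniques Unique-sequence tibble carrying a `gene` column
#'   (provisional best-match assignment).
#' @param min_count Minimum read count (default 2).
#' @param min_gene_fraction Minimum fraction of the participant's
#'   non-singleton reads for that gene (default 0.1).
#' @return The retained rows of `uniques`.
#' @export
abundance_filter <- function(uniques, min_count = 2L,
                             min_gene_fraction = 0.1) {
  if (!"gene" %in% names(uniques)) {
    stop("uniques must carry a provisional 'gene' column", call. = FALSE)
  }
  uniques |>
    group_by(.data$participant, .data$gene) |>
    mutate(.gene_total = sum(.data$count[.data$count >= 2L])) |>
    ungroup() |>
    filter(.data$count >= min_count,
           .data$count >= min_gene_fraction * .data$.gene_total) |>
    select(-".gene_total")
}

# ---------------------------------------------------------------------------
# Assignment internals

# Precomputed matcher over a reference database.
.make_matcher <- function(db, segment = c("full", "v_region")) {
  segment <- match.arg(segment)
  keys <- db$alleles$allele_key
  spans <- lapply(setNames(keys, keys), function(k) .spans_of(db, k))
  if (segment == "full") {
    seqs <- setNames(db$alleles$sequence, keys)
  } else {
    seqs <- vapply(setNames(keys, keys), function(k) {
      sp <- spans[[k]]$v_region
      substr(db$alleles$sequence[match(k, keys)], sp[1], sp[2])
    }, character(1))
  }
  exact <- new.env(parent = emptyenv(), size = length(seqs))
  for (k in keys) assign(seqs[[k]], k, envir = exact)
  list(
    segment = segment, keys = keys, seqs = seqs,
    raws = lapply(seqs, charToRaw), lens = nchar(seqs),
    spans = spans, truncated = setNames(db$alleles$truncated, keys),
    genes = setNames(db$alleles$gene, keys), exact = exact
  )
}

# Map absolute reference positions to (region, local position) given spans.
# In v_region segment mode spans collapse to a single v_region of the
# segment's own coordinates.
.map_positions <- function(spans, pos) {
  region <- rep(NA_character_, length(pos))
  local <- integer(length(pos))
  for (r in names(spans)) {
    s <- spans[[r]]
    inside <- pos >= s[1] & pos <= s[2]
    region[inside] <- r
    local[inside] <- pos[inside] - s[1] + 1L
  }
  list(region = region, local = local)
}

# End-gap-free alignment of query vs reference; returns mismatch positions
# in reference coordinates, indel flag, and per-v-region column counts.
.align_compare <- function(query, refseq, v_span) {
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = 1, mismatch = -1,
                                                  baseOnly = TRUE)
  pw <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(query), Biostrings::DNAString(refseq),
    type = "overlap", substitutionMatrix = mat,
    gapOpening = 4, gapExtension = 1
  )
  ap <- strsplit(as.character(Biostrings::alignedPattern(pw)), "")[[1]]
  as_ <- strsplit(as.character(Biostrings::alignedSubject(pw)), "")[[1]]
  refpos <- cumsum(as_ != "-") +
    (Biostrings::start(Biostrings::subject(pw)) - 1L)
  both <- ap != "-" & as_ != "-"
  mism <- both & ap != as_
  v_cols <- sum(both & refpos >= v_span[1] & refpos <= v_span[2])
  v_mm <- sum(mism & refpos >= v_span[1] & refpos <= v_span[2])
  list(
    mismatch_pos = refpos[mism],
    alt = ap[mism],
    total_mm = sum(mism),
    indel = any(ap == "-") || any(as_ == "-"),
    v_cols = v_cols, v_mm = v_mm
  )
}

# Core single-query assignment against a matcher. Returns a plain list.
.assign_one <- function(query, matcher, identity_floor = 85) {
  exact <- get0(query, envir = matcher$exact, inherits = FALSE)
  if (!is.null(exact)) {
    return(list(key = exact, identity = 100, mm = 0L,
                pos = integer(), alt = character(), indel = FALSE,
                unassignable = FALSE))
  }
  qlen <- nchar(query)
  qraw <- charToRaw(query)
  cand <- matcher$keys[matcher$lens == qlen &
                         (matcher$segment == "v_region" |
                            !matcher$truncated)]
  best <- NULL
  for (k in cand) {
    pos <- which(qraw != matcher$raws[[k]])
    if (matcher$segment == "full") {
      vs <- matcher$spans[[k]]$v_region
      v_len <- vs[2] - vs[1] + 1L
      v_mm <- sum(pos >= vs[1] & pos <= vs[2])
    } else {
      v_len <- qlen
      v_mm <- length(pos)
    }
    identity <- 100 * (v_len - v_mm) / v_len
    if (is.null(best) || identity > best$identity ||
        (identity == best$identity &&
         (length(pos) < best$mm ||
          (length(pos) == best$mm && k < best$key)))) {
      best <- list(key = k, identity = identity, mm = length(pos),
                   pos = pos, alt = NULL, indel = FALSE)
    }
  }
  if (is.null(best) || best$identity < identity_floor) {
    # slow path: end-gap-free alignment against every allele (covers
    # length-discordant queries and truncated records)
    for (k in matcher$keys) {
      vs <- if (matcher$segment == "full") matcher$spans[[k]]$v_region else
        c(1L, matcher$lens[[k]])
      al <- .align_compare(query, matcher$seqs[[k]], vs)
      identity <- if (al$v_cols > 0)
        100 * (al$v_cols - al$v_mm) / al$v_cols else 0
      if (is.null(best) || identity > best$identity ||
          (identity == best$identity &&
           (al$total_mm < best$mm ||
            (al$total_mm == best$mm && k < best$key)))) {
        best <- list(key = k, identity = identity, mm = al$total_mm,
                     pos = al$mismatch_pos, alt = al$alt, indel = al$indel)
      }
    }
  }
  if (is.null(best$alt)) {
    best$alt <- vapply(best$pos, function(p) substr(query, p, p),
                       character(1))
  }
  best$unassignable <- best$identity < identity_floor
  best
}

# Build the SNV tibble for an accepted assignment.
.best_snvs <- function(best, matcher) {
  if (length(best$pos) == 0L) return(.snv_tibble())
  spans <- if (matcher$segment == "full") matcher$spans[[best$key]] else
    list(v_region = c(1L, matcher$lens[[best$key]]))
  mp <- .map_positions(spans, best$pos)
  refseq <- matcher$seqs[[best$key]]
  ref <- vapply(best$pos, function(p) substr(refseq, p, p), character(1))
  keep <- !is.na(mp$region)
  .snv_tibble(mp$region[keep], mp$local[keep], ref[keep], best$alt[keep])
}

#' Assign the closest reference allele to a query sequence
#'
#' Compares the query against every allele of the database and selects the
#' match with the highest V-region identity; ties are broken by fewer total
#' mismatches, then by lexicographically smallest allele name. In
#' `segment = "full"` mode the query is a full-length amplicon and SNVs are
#' reported for every region; in `"v_region"` mode the query is a bare
#' V-segment. A best identity below `identity_floor` flags the call
#' `unassignable`. Any V-region SNV makes the call novel, named per
#' [name_novel()].
#'
#' @param query Nucleotide string.
#' @param db An `ighv_refdb`.
#' @param segment `"full"` or `"v_region"`.
#' @param identity_floor Percent identity below which the call is flagged
#'   unassignable (default 85).
#' @param query_id Optional identifier carried into the result.
#' @return One-row tibble: `query_id`, `gene`, `allele_id`, `allele_key`,
#'   `identity_pct`, `mismatches`, `indel`, `is_novel`, `novel_name`,
#'   `unassignable`, and a list-column `snvs` of SNV records
#'   (`region`, `position`, `ref`, `alt`; positions 1-based within region).
#' @export
assign_allele <- function(query, db, segment = c("full", "v_region"),
                          identity_floor = 85, query_id = "query") {
  segment <- match.arg(segment)
  if (nrow(db$alleles) == 0L) stop("empty reference database", call. = FALSE)
  matcher <- .make_matcher(db, segment)
  .finish_call(.assign_one(query, matcher, identity_floor), matcher,
               query_id)
}

.finish_call <- function(best, matcher, query_id) {
  snvs <- .best_snvs(best, matcher)
  v_snvs <- snvs[snvs$region == "v_region", , drop = FALSE]
  is_novel <- !best$unassignable && nrow(v_snvs) > 0L
  tibble(
    query_id = query_id,
    gene = unname(matcher$genes[[best$key]]),
    allele_id = sub("^.*\\*", "", best$key),
    allele_key = best$key,
    identity_pct = best$identity,
    mismatches = best$mm,
    indel = best$indel,
    is_novel = is_novel,
    novel_name = if (is_novel) name_novel(best$key, v_snvs) else "",
    unassignable = best$unassignable,
    snvs = list(snvs)
  )
}

#' Assign alleles to a table of unique sequences
#'
#' Vectorised driver over [assign_allele()]'s contract; the reference is
#' indexed once and reused for every query.
#'
#' @param uniques Tibble with `query_id`, `sequence` (and any other columns,
#'   which are preserved).
#' @param db An `ighv_refdb`.
#' @inheritParams assign_allele
#' @return `uniques` with the allele-call columns appended.
#' @export
assign_alleles <- function(uniques, db, segment = c("full", "v_region"),
                           identity_floor = 85) {
  segment <- match.arg(segment)
  if (nrow(db$alleles) == 0L) stop("empty reference database", call. = FALSE)
  matcher <- .make_matcher(db, segment)
  calls <- lapply(seq_len(nrow(uniques)), function(i) {
    .finish_call(.assign_one(uniques$sequence[i], matcher, identity_floor),
                 matcher, uniques$query_id[i])
  })
  dplyr::bind_cols(uniques, bind_rows(calls)[, -1L])
}

# Cheap provisional gene/key assignment (no SNV bookkeeping) used to build
# the abundance-filter denominators.
.provisional_genes <- function(uniques, db, identity_floor = 85) {
  matcher <- .make_matcher(db, "full")
  n <- nrow(uniques)
  gene <- character(n)
  key <- character(n)
  identity <- numeric(n)
  for (i in seq_len(n)) {
    best <- .assign_one(uniques$sequence[i], matcher, identity_floor)
    gene[i] <- unname(matcher$genes[[best$key]])
    key[i] <- best$key
    identity[i] <- best$identity
  }
  uniques$gene <- gene
  uniques$provisional_key <- key
  uniques$provisional_identity <- identity
  uniques
}

#' Call SNVs in the regulatory regions of an assigned sequence
#'
#' Pairwise comparison of the query against its assigned reference allele,
#' reporting SNVs in the leader part 1/2, intron and RSS with region-local
#' 1-based positions. V-region SNVs are excluded (they belong to the allele
#' call itself); indels are flagged via the `indel` attribute, never
#' reported as SNVs. Truncated reference records have no regulatory spans
#' and yield a warning plus an empty record set.
#'
#' @param sequence Full-length query sequence.
#' @param allele_key Assigned allele.
#' @param db An `ighv_refdb`.
#' @return SNV tibble (`region`, `position`, `ref`, `alt`) with attribute
#'   `indel`.
#' @export
call_regulatory_snvs <- function(sequence, allele_key, db) {
  row <- .allele_row(db, allele_key)
  if (row$truncated) {
    warning("assigned allele ", allele_key,
            " is truncated; regulatory regions skipped")
    return(structure(.snv_tibble(), indel = FALSE))
  }
  spans <- .spans_of(db, allele_key)
  refseq <- row$sequence
  if (nchar(sequence) == nchar(refseq)) {
    pos <- .mismatch_positions(sequence, refseq)
    alt <- vapply(pos, function(p) substr(sequence, p, p), character(1))
    indel <- FALSE
  } else {
    al <- .align_compare(sequence, refseq, spans$v_region)
    pos <- al$mismatch_pos
    alt <- al$alt
    indel <- al$indel
  }
  ref <- vapply(pos, function(p) substr(refseq, p, p), character(1))
  mp <- .map_positions(spans, pos)
  keep <- !is.na(mp$region) & mp$region != "v_region"
  structure(.snv_tibble(mp$region[keep], mp$local[keep], ref[keep],
                        alt[keep]),
            indel = indel)
}

#' Derive the name of a novel allele
#'
#' Base allele name plus underscore-joined `RefPosAlt` tokens in ascending
#' position order (positions count from the V-region start, 1-based,
#' ungapped), e.g. `IGHV6-1*01` + (288, C, T) -> `"IGHV6-1*01_C288T"`.
#'
#' @param base_allele Closest-match allele key.
#' @param snvs SNV tibble; only `v_region` rows are used.
#' @return The derived name.
#' @export
name_novel <- function(base_allele, snvs) {
  snvs <- snvs[snvs$region == "v_region", , drop = FALSE]
  if (nrow(snvs) == 0L) {
    stop("name_novel requires at least one v_region SNV", call. = FALSE)
  }
  snvs <- snvs[order(snvs$position), , drop = FALSE]
  paste(c(base_allele,
          .snv_token(snvs$position, snvs$ref, snvs$alt)), collapse = "_")
}

#' Run the full germline genotyping pipeline on amplicon reads
#'
#' Orchestrates primer trimming, quality filtering, dereplication,
#' provisional gene assignment, abundance filtering, and final allele
#' assignment with regulatory SNV calls. Read counts are conserved at every
#' stage (input = retained + discarded).
#'
#' @param reads Read tibble (merged amplicon reads; duplicate PCR runs are
#'   pooled by simple concatenation upstream).
#' @param reference A [synthetic_reference()]-style list or an `ighv_refdb`.
#' @param primers Primer tibble; defaults to `reference$primers`.
#' @param min_q Minimum mean Phred score (default 33).
#' @param max_primer_mismatch Per-primer mismatch tolerance (default 2).
#' @param min_count,min_gene_fraction Abundance thresholds (defaults 2, 0.1).
#' @param identity_floor Unassignable threshold (default 85).
#' @return List with `calls` (final per-unique allele calls, with
#'   `support_count` and a `sequence` column), `uniques` (all uniques with
#'   provisional genes), `discards`, and `stages` (per-stage read counts).
#' @export
genotype_germline <- function(reads, reference, primers = NULL,
                              min_q = 33, max_primer_mismatch = 2L,
                              min_count = 2L, min_gene_fraction = 0.1,
                              identity_floor = 85) {
  db <- if (inherits(reference, "ighv_refdb")) reference else reference$db
  primers <- primers %||%
    (if (!inherits(reference, "ighv_refdb")) reference$primers else NULL)
  if (is.null(primers)) stop("primers required", call. = FALSE)

  tr <- trim_primers(reads, primers, max_primer_mismatch)
  qf <- quality_filter(tr$reads, min_q)
  uniq <- dereplicate(qf$reads)
  uniq <- .provisional_genes(uniq, db, identity_floor)
  kept <- abundance_filter(uniq, min_count, min_gene_fraction)

  calls <- assign_alleles(
    kept |> select(-"gene", -"provisional_key", -"provisional_identity"),
    db, segment = "full", identity_floor = identity_floor
  )
  calls <- calls |>
    filter(!.data$unassignable) |>
    mutate(support_count = .data$count)

  stages <- tibble(
    stage = c("trim_primers", "quality_filter", "dereplicate",
              "abundance_filter"),
    n_in = c(tr$n_in, qf$n_in, nrow(qf$reads), nrow(uniq)),
    n_out = c(nrow(tr$reads), nrow(qf$reads), nrow(uniq), nrow(kept)),
    unit = c("reads", "reads", "reads->uniques", "uniques")
  )
  list(calls = calls, uniques = uniq,
       discards = bind_rows(tr$discards, qf$discards), stages = stages)
}

#' Export allele calls as a TSV
#'
#' One row per call with SNVs flattened to a `region:pos:ref>alt`
#' semicolon-separated list.
#'
#' @param calls Calls tibble from [genotype_germline()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_calls <- function(calls, path) {
  out <- calls
  out$snvs <- vapply(calls$snvs, function(s) {
    if (nrow(s) == 0L) return("")
    paste(sprintf("%s:%d:%s>%s", s$region, s$position, s$ref, s$alt),
          collapse = ";")
  }, character(1))
  out$sequence <- NULL
  .write_tsv(out, path)
}
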