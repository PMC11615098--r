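# Expressed-repertoire analysis: rearrangement annotation, simplified
# expressed-allele inference, IGHJ-anchored haplotype reconstruction with a
# binomial Bayes-factor confidence (k), chromosome-resolved duplication
# calling, and duplication-linked expression fold change.
#
# "Unique VDJ" means a distinct full-length nucleotide sequence after exact
# duplicate collapse; it is the unit of expression counting throughout.

#' Annotate rearrangements with V and J allele calls
#'
#' Each read is assigned the best V (highest V-region alignment identity;
#' ties by fewer mismatches then lexicographically smallest name, as in
#' [assign_allele()]) and the best J by terminal alignment.
#' `v_mutation_count` is the mismatch count to the assigned germline V.
#' Exact duplicate nucleotide sequences are collapsed first, yielding
#' "unique VDJ" units. Reads whose V identity falls below `identity_floor`
#' are logged and dropped.
#'
#' @param reads Read tibble (`read_id`, `sequence`, optionally
#'   `participant`).
#' @param db An `ighv_refdb` of V alleles.
#' @param j_db Tibble of J alleles (`allele`, `sequence`).
#' @param identity_floor Minimum V identity percent (default 85).
#' @return List with `rearrangements` (tibble: `sequence_id`, `participant`,
#'   `sequence`, `v_call`, `j_call`, `v_identity_pct`, `v_mutation_count`,
#'   `j_mutation_count`, `v_segment`, `junction`, `junction_length`,
#'   `duplicate_count`) and `discards`.
#' @export
annotate_rearrangements <- function(reads, db, j_db, identity_floor = 85) {
  if (!"participant" %in% names(reads)) reads$participant <- "S1"
  uniq <- reads |>
    group_by(.data$participant, .data$sequence) |>
    summarise(sequence_id = min(.data$read_id),
              duplicate_count = dplyr::n(), .groups = "drop")

  v_seqs <- .v_regions(db)
  v_keys <- sort(names(v_seqs))
  j_keys <- sort(j_db$allele)
  j_seqs <- setNames(j_db$sequence, j_db$allele)

  n <- nrow(uniq)
  lens <- nchar(uniq$sequence)
  # probes are scanned in sorted-key order with a strict improvement rule,
  # so ties go to the lexicographically smallest allele name
  scan_best <- function(keys, seqs, side) {
    best <- list(key = rep(NA_character_, n), mm = rep(Inf, n),
                 len = rep(NA_integer_, n))
    for (L in sort(unique(nchar(seqs[keys])))) {
      grp <- keys[nchar(seqs[keys]) == L]
      okl <- which(lens >= L)
      if (length(okl) == 0L) next
      tab <- if (side == "prefix") {
        .prefix_mismatch_table(uniq$sequence[okl], unname(seqs[grp]))
      } else {
        .suffix_mismatch_table(uniq$sequence[okl], unname(seqs[grp]))
      }
      for (j in seq_along(grp)) {
        better <- okl[tab[, j] < best$mm[okl]]
        best$key[better] <- grp[j]
        best$mm[better] <- tab[match(better, okl), j]
        best$len[better] <- L
      }
    }
    best
  }
  bv <- scan_best(v_keys, v_seqs, "prefix")
  bj <- scan_best(j_keys, j_seqs, "suffix")
  best_v <- bv$key; best_v_mm <- bv$mm; best_v_len <- bv$len
  best_j <- bj$key; best_j_mm <- bj$mm; best_j_len <- bj$len

  v_identity <- 100 * (best_v_len - best_v_mm) / best_v_len
  assignable <- !is.na(best_v) & !is.na(best_j) &
    v_identity >= identity_floor &
    lens >= best_v_len + best_j_len
  discards <- tibble(sequence_id = uniq$sequence_id[!assignable],
                     reason = rep("unassignable", sum(!assignable)))

  out <- uniq[assignable, , drop = FALSE]
  vl <- best_v_len[assignable]
  jl <- best_j_len[assignable]
  sl <- lens[assignable]
  out$v_call <- best_v[assignable]
  out$j_call <- best_j[assignable]
  out$v_identity_pct <- v_identity[assignable]
  out$v_mutation_count <- as.integer(best_v_mm[assignable])
  out$j_mutation_count <- as.integer(best_j_mm[assignable])
  out$v_segment <- substr(out$sequence, 1L, vl)
  out$junction <- substr(out$sequence, vl + 1L, sl - jl)
  out$junction_length <- nchar(out$junction)
  out <- out |>
    select("sequence_id", "participant", "sequence", "v_call", "j_call",
           "v_identity_pct", "v_mutation_count", "j_mutation_count",
           "v_segment", "junction", "junction_length", "duplicate_count") |>
    arrange(.data$participant, .data$sequence_id)
  list(rearrangements = out, discards = discards)
}

#' Infer the expressed allele set from annotated rearrangements
#'
#' Simplified germline inference: per gene, reads with
#' `v_mutation_count <= max_mut` (relative to the best known allele) are
#' grouped by their exact V segment; a segment supported by at least
#' `min_support` unique VDJs carrying at least `min_junctions` distinct
#' junctions is emitted as an expressed allele. Segments matching a known
#' allele keep its name; others receive derived novel names
#' (see [name_novel()]). The junction-diversity rule suppresses clonally
#' expanded somatic variants (many reads, one junction).
#'
#' @param rearrangements Tibble from [annotate_rearrangements()].
#' @param db An `ighv_refdb`.
#' @param min_support Minimum unique-VDJ support (default 10).
#' @param min_junctions Minimum distinct junctions (default 3).
#' @param max_mut Maximum mutations to the closest known allele for a read
#'   to enter inference (default 3, covering novel alleles with up to three
#'   V-region SNVs).
#' @return Tibble: `participant`, `gene`, `allele_name` (canonical),
#'   `v_segment`, `support`, `n_junctions`, `is_novel`.
#' @export
infer_expressed_alleles <- function(rearrangements, db, min_support = 10L,
                                    min_junctions = 3L, max_mut = 3L) {
  v_seqs <- .v_regions(db)
  seg_to_key <- setNames(names(v_seqs), v_seqs)

  cand <- rearrangements |>
    filter(.data$v_mutation_count <= max_mut) |>
    group_by(.data$participant,
             gene = sub("\\*.*$", "", .data$v_call),
             .data$v_segment) |>
    summarise(support = dplyr::n(),
              n_junctions = dplyr::n_distinct(.data$junction),
              .groups = "drop") |>
    filter(.data$support >= min_support,
           .data$n_junctions >= min_junctions)

  if (nrow(cand) == 0L) {
    return(tibble(participant = character(), gene = character(),
                  allele_name = character(), v_segment = character(),
                  support = integer(), n_junctions = integer(),
                  is_novel = logical()))
  }
  name <- character(nrow(cand))
  is_novel <- logical(nrow(cand))
  for (i in seq_len(nrow(cand))) {
    hit <- unname(seg_to_key[cand$v_segment[i]])
    if (!is.na(hit)) {
      name[i] <- hit
      is_novel[i] <- FALSE
    } else {
      call <- assign_allele(cand$v_segment[i], db, segment = "v_region")
      name[i] <- if (call$is_novel) call$novel_name else call$allele_key
      is_novel[i] <- call$is_novel
    }
  }
  cand$allele_name <- .canonical_name(name)
  cand$is_novel <- is_novel
  # keep the gene of the named allele (guards against rare cross-gene
  # provisional calls)
  cand$gene <- sub("\\*.*$", "", cand$allele_name)
  cand |>
    select("participant", "gene", "allele_name", "v_segment", "support",
           "n_junctions", "is_novel") |>
    arrange(.data$participant, .data$gene, .data$allele_name)
}

#' Binomial log10 Bayes factor for haplotype allele support (k-value)
#'
#' `k = log10[ Binom(a | n, p_true) / Binom(a | n, error_rate) ]` with
#' `p_true = max(a/n, error_rate)`, floored at 0; `a = allele_reads`,
#' `n = haplotype_gene_reads`. `k` is 0 when `a = 0` or `n = 0`, and is
#' non-decreasing in `a` at fixed `n`. Alleles with `k` below the working
#' threshold (3.6 by default downstream) are deemed unsubstantial.
#'
#' @param allele_reads Reads supporting the allele on the haplotype.
#' @param haplotype_gene_reads Total reads for the gene on that haplotype.
#' @param error_rate Assumed mis-assignment rate (default 0.01; must be in
#'   (0, 0.5)).
#' @return Numeric vector of k values (log10 scale, >= 0).
#' @export
k_factor <- function(allele_reads, haplotype_gene_reads,
                     error_rate = 0.01) {
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must be in (0, 0.5)", call. = FALSE)
  }
  a <- as.numeric(allele_reads)
  n <- as.numeric(haplotype_gene_reads)
  if (any(a < 0) || any(n < 0)) stop("counts must be >= 0", call. = FALSE)
  len <- max(length(a), length(n))
  a <- rep_len(a, len)
  n <- rep_len(n, len)
  k <- numeric(len)
  ok <- n > 0 & a > 0
  p_true <- pmax(a[ok] / n[ok], error_rate)
  k[ok] <- (dbinom(a[ok], n[ok], p_true, log = TRUE) -
              dbinom(a[ok], n[ok], error_rate, log = TRUE)) / log(10)
  pmax(k, 0)
}

#' Reconstruct the two haplotypes of one participant from an anchor gene
#'
#' Requires a heterozygous anchor: exactly two anchor alleles, each carrying
#' at least `min_anchor_fraction` of the anchor-gene reads (unequal anchor
#' allele expression is tolerated down to that floor). Every rearrangement
#' is binned by its anchor allele; per gene per bin, V alleles are tallied
#' (by nearest expressed-allele segment when an inference table is supplied,
#' else by annotated `v_call`) and a [k_factor()] confidence is attached.
#'
#' @param rearrangements One participant's annotated rearrangements.
#' @param expressed Optional [infer_expressed_alleles()] table for the same
#'   participant.
#' @param anchor_gene Anchor gene name (default `"IGHJ6"`).
#' @param min_anchor_fraction Minor-allele floor (default 0.1).
#' @param error_rate Passed to [k_factor()].
#' @return Object of class `ighv_haplotype_map`: list with `participant`,
#'   `anchor_gene`, `anchor_alleles` (length 2), and `table` (tibble:
#'   `anchor_allele`, `gene`, `allele_name`, `reads`, `gene_reads`, `k`).
#' @export
reconstruct_haplotypes <- function(rearrangements, expressed = NULL,
                                   anchor_gene = "IGHJ6",
                                   min_anchor_fraction = 0.1,
                                   error_rate = 0.01) {
  participant <- unique(rearrangements$participant)
  if (length(participant) != 1L) {
    stop("reconstruct_haplotypes expects a single participant", call. = FALSE)
  }
  anchored <- rearrangements |>
    filter(sub("\\*.*$", "", .data$j_call) == anchor_gene)
  if (nrow(anchored) == 0L) {
    stop("anchor not heterozygous: no ", anchor_gene, " reads for ",
         participant, call. = FALSE)
  }
  tab <- sort(table(anchored$j_call), decreasing = TRUE)
  frac <- tab / sum(tab)
  passing <- names(frac)[frac >= min_anchor_fraction]
  if (length(passing) != 2L) {
    stop("anchor not heterozygous: ", participant, " has ",
         length(passing), " ", anchor_gene,
         " allele(s) above the minor-fraction floor", call. = FALSE)
  }
  anchored <- anchored |> filter(.data$j_call %in% passing)

  anchored$allele_name <- .haplotype_allele_names(anchored, expressed)
  table_ <- anchored |>
    group_by(anchor_allele = .data$j_call,
             gene = sub("\\*.*$", "", .data$allele_name),
             .data$allele_name) |>
    summarise(reads = dplyr::n(), .groups = "drop") |>
    group_by(.data$anchor_allele, .data$gene) |>
    mutate(gene_reads = sum(.data$reads)) |>
    ungroup() |>
    mutate(k = k_factor(.data$reads, .data$gene_reads, error_rate)) |>
    arrange(.data$anchor_allele, .data$gene, .data$allele_name)

  structure(list(participant = participant, anchor_gene = anchor_gene,
                 anchor_alleles = sort(passing), table = table_),
            class = "ighv_haplotype_map")
}

# Assign each rearrangement an allele name: nearest expressed-allele
# V segment of its gene when an inference table is available, else the
# annotated v_call (novel reads keep the closest known name).
.haplotype_allele_names <- function(rearr, expressed) {
  if (is.null(expressed) || nrow(expressed) == 0L) {
    return(.canonical_name(rearr$v_call))
  }
  out <- character(nrow(rearr))
  gene_of_call <- sub("\\*.*$", "", rearr$v_call)
  for (g in unique(gene_of_call)) {
    rows <- which(gene_of_call == g)
    cand <- expressed[expressed$gene == g, , drop = FALSE]
    if (nrow(cand) == 0L) {
      out[rows] <- .canonical_name(rearr$v_call[rows])
      next
    }
    cand <- cand[order(cand$allele_name), , drop = FALSE]
    segs <- cand$v_segment
    mm <- matrix(Inf, length(rows), nrow(cand))
    for (j in seq_along(segs)) {
      L <- nchar(segs[j])
      okl <- nchar(rearr$v_segment[rows]) == L
      if (any(okl)) {
        mm[okl, j] <- .prefix_mismatches(rearr$v_segment[rows][okl],
                                         segs[j])
      }
    }
    out[rows] <- cand$allele_name[max.col(-mm, ties.method = "first")]
  }
  out
}

#' @export
print.ighv_haplotype_map <- function(x, ...) {
  cat("Haplotype map for", x$participant, "anchored on", x$anchor_gene,
      "(", paste(x$anchor_alleles, collapse = " / "), "):",
      nrow(x$table), "allele-haplotype rows\n")
  invisible(x)
}

#' Call chromosome-resolved copy-number states from a haplotype map
#'
#' Per haplotype, a gene is duplicated when more than one allele passes the
#' `min_reads` and `min_k` filters. The gene state is `both_haplotype_dup`,
#' `single_haplotype_dup`, `none`, or `unresolved` (no allele passes the
#' filters on either haplotype). Filters only ever shrink the called set;
#' same-allele duplications on one haplotype are invisible to this method.
#'
#' @param hmap An `ighv_haplotype_map` (or its `table` plus `participant`).
#' @param min_reads Minimum supporting reads (default 50).
#' @param min_k Minimum k-value (default 3.6).
#' @return List with `gene_states` (tibble: `participant`, `gene`,
#'   `cnv_state`) and `haplotype_dup` (tibble: `participant`,
#'   `anchor_allele`, `gene`, `n_passing`, `dup`).
#' @export
call_haplotype_cnv <- function(hmap, min_reads = 50L, min_k = 3.6) {
  tab <- hmap$table
  tab$pass <- tab$reads >= min_reads & tab$k >= min_k
  hap <- tab |>
    group_by(.data$anchor_allele, .data$gene) |>
    summarise(n_passing = sum(.data$pass), .groups = "drop") |>
    mutate(dup = .data$n_passing > 1L,
           participant = hmap$participant)
  gene_states <- hap |>
    group_by(.data$gene) |>
    summarise(
      cnv_state = if (sum(.data$n_passing) == 0L) "unresolved"
      else c("none", "single_haplotype_dup",
             "both_haplotype_dup")[sum(.data$dup) + 1L],
      .groups = "drop"
    ) |>
    mutate(participant = hmap$participant) |>
    select("participant", "gene", "cnv_state")
  list(gene_states = gene_states,
       haplotype_dup = hap |>
         select("participant", "anchor_allele", "gene", "n_passing", "dup"))
}

#' Per-haplotype gene expression proportions
#'
#' Unique-VDJ counts per gene per haplotype, normalised as a proportion of
#' that haplotype's unique VDJs (proportions per haplotype sum to 1).
#'
#' @param hmap An `ighv_haplotype_map`.
#' @return Tibble: `participant`, `anchor_allele`, `gene`,
#'   `unique_vdj_count`, `proportion`.
#' @export
expression_table <- function(hmap) {
  hmap$table |>
    group_by(.data$anchor_allele, .data$gene) |>
    summarise(unique_vdj_count = sum(.data$reads), .groups = "drop_last") |>
    mutate(proportion = .data$unique_vdj_count /
             sum(.data$unique_vdj_count)) |>
    ungroup() |>
    mutate(participant = hmap$participant) |>
    select("participant", "anchor_allele", "gene", "unique_vdj_count",
           "proportion")
}

#' Duplication-linked expression fold change per gene
#'
#' Compares expression between haplotypes carrying a duplication of a gene
#' and haplotypes without one, on a per-gene basis (avoiding the effect of
#' variable expression between genes):
#' `fold_change = mean(proportion | duplicated) / mean(proportion | not)`.
#' The subtraction variant (`difference`) is available behind a flag. Genes
#' lacking a duplicated or a non-duplicated haplotype are omitted, with the
#' reason recorded in the `omitted` attribute.
#'
#' @param expression Row-bound [expression_table()] output across
#'   participants.
#' @param haplotype_dup Row-bound `haplotype_dup` tables from
#'   [call_haplotype_cnv()].
#' @param variant `"ratio"` (default) or `"difference"`.
#' @return Tibble: `gene`, `n_dup_haplotypes`, `n_nondup_haplotypes`,
#'   `mean_prop_dup`, `mean_prop_nondup`, `fold_change`; attribute
#'   `omitted` lists genes without both haplotype classes.
#' @export
expression_fold_change <- function(expression, haplotype_dup,
                                   variant = c("ratio", "difference")) {
  variant <- match.arg(variant)
  merged <- expression |>
    left_join(haplotype_dup |>
                select("participant", "anchor_allele", "gene", "dup"),
              by = c("participant", "anchor_allele", "gene")) |>
    mutate(dup = !is.na(.data$dup) & .data$dup)
  per_gene <- merged |>
    group_by(.data$gene) |>
    summarise(
      n_dup_haplotypes = sum(.data$dup),
      n_nondup_haplotypes = sum(!.data$dup),
      mean_prop_dup = mean(.data$proportion[.data$dup]),
      mean_prop_nondup = mean(.data$proportion[!.data$dup]),
      .groups = "drop"
    )
  defined <- per_gene$n_dup_haplotypes > 0 & per_gene$n_nondup_haplotypes > 0
  omitted <- per_gene$gene[!defined]
  out <- per_gene[defined, , drop = FALSE]
  out$fold_change <- if (variant == "ratio") {
    out$mean_prop_dup / out$mean_prop_nondup
  } else {
    out$mean_prop_dup - out$mean_prop_nondup
  }
  structure(out, omitted = omitted)
}
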