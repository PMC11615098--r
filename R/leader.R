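# Leader-sequence variation: classify each called allele's observed leader
# part 1 as reference / SNV / mismatch, and summarise positional nucleotide
# and amino-acid variation (logogram data).
#
# "Mismatch" requires an exact full-length match to another allele's
# reference leader; an observed leader that differs from its own reference
# and matches no other allele is SNV even when it carries several SNVs.
# Novel alleles and truncated-reference alleles are excluded (no reference
# leader to compare against).

#' Classify an observed leader part 1 sequence
#'
#' @param observed_leader Observed leader part 1 nucleotide string.
#' @param allele_key Allele assigned from the V-region.
#' @param db An `ighv_refdb`.
#' @param lidx Optional precomputed [leader_index()] (computed on the fly
#'   otherwise).
#' @return One-row tibble: `allele_key`, `category` (one of `reference`,
#'   `SNV`, `mismatch`, `indel-leader`, `unclassifiable`), list-columns
#'   `snvs` (leader SNV records, category `SNV`) and `donor_alleles`
#'   (alleles whose reference leader exactly matches, category `mismatch`),
#'   and `observed_leader`.
#' @export
classify_leader <- function(observed_leader, allele_key, db, lidx = NULL) {
  out <- function(category, snvs = .snv_tibble(), donors = character()) {
    tibble(allele_key = allele_key, category = category,
           snvs = list(snvs), donor_alleles = list(donors),
           observed_leader = observed_leader)
  }
  row <- .allele_row(db, allele_key)
  spans <- .spans_of(db, allele_key)
  if (row$truncated || !"leader1" %in% names(spans)) {
    return(out("unclassifiable"))
  }
  ref_leader <- substr(row$sequence, spans$leader1[1], spans$leader1[2])
  if (identical(observed_leader, ref_leader)) {
    return(out("reference"))
  }
  lidx <- lidx %||% leader_index(db)
  hit <- lidx[[observed_leader]]
  donors <- setdiff(hit, allele_key)
  if (length(donors)) {
    return(out("mismatch", donors = donors))
  }
  if (nchar(observed_leader) != nchar(ref_leader)) {
    return(out("indel-leader"))
  }
  pos <- .mismatch_positions(observed_leader, ref_leader)
  snvs <- .snv_tibble(
    rep("leader1", length(pos)), pos,
    vapply(pos, function(p) substr(ref_leader, p, p), character(1)),
    vapply(pos, function(p) substr(observed_leader, p, p), character(1))
  )
  out("SNV", snvs = snvs)
}

#' Classify the leaders of a table of germline allele calls
#'
#' Extracts the observed leader part 1 from each called sequence (by the
#' assigned allele's span; length-discordant sequences are aligned first),
#' excluding novel calls and calls against truncated references, and runs
#' [classify_leader()] on each.
#'
#' @param calls Calls tibble from [genotype_germline()] (must carry
#'   `sequence`, `allele_key`, `is_novel`, `indel`).
#' @param db An `ighv_refdb`.
#' @return Tibble with one row per call: participant/gene bookkeeping plus
#'   the [classify_leader()] columns.
#' @export
classify_leaders <- function(calls, db) {
  lidx <- leader_index(db)
  rows <- lapply(seq_len(nrow(calls)), function(i) {
    key <- calls$allele_key[i]
    ref <- .allele_row(db, key)
    spans <- .spans_of(db, key)
    meta <- tibble(
      call_id = calls$query_id[i],
      participant = if ("participant" %in% names(calls))
        calls$participant[i] else NA_character_,
      gene = calls$gene[i]
    )
    if (calls$is_novel[i] || ref$truncated ||
        !"leader1" %in% names(spans)) {
      return(dplyr::bind_cols(meta, tibble(
        allele_key = key, category = "unclassifiable",
        snvs = list(.snv_tibble()), donor_alleles = list(character()),
        observed_leader = NA_character_)))
    }
    seq <- calls$sequence[i]
    obs <- if (nchar(seq) == nchar(ref$sequence)) {
      substr(seq, spans$leader1[1], spans$leader1[2])
    } else {
      NA_character_  # indel somewhere; leader coordinates unsafe
    }
    if (is.na(obs)) {
      return(dplyr::bind_cols(meta, tibble(
        allele_key = key, category = "indel-leader",
        snvs = list(.snv_tibble()), donor_alleles = list(character()),
        observed_leader = NA_character_)))
    }
    dplyr::bind_cols(meta, classify_leader(obs, key, db, lidx))
  })
  bind_rows(rows)
}

#' Summarise leader variation per gene
#'
#' Counts and fractions of `reference`, `SNV` and `mismatch` leaders per
#' gene over classifiable alleles (`unclassifiable` and `indel-leader`
#' excluded from the denominator).
#'
#' @param classifications Output of [classify_leaders()].
#' @return Tibble: `gene`, `n_classifiable`, `n_reference`, `n_snv`,
#'   `n_mismatch`, `frac_reference`, `frac_snv`, `frac_mismatch`.
#' @export
summarize_leader_variation <- function(classifications) {
  cl <- classifications |>
    filter(.data$category %in% c("reference", "SNV", "mismatch"))
  cl |>
    group_by(.data$gene) |>
    summarise(
      n_classifiable = dplyr::n(),
      n_reference = sum(.data$category == "reference"),
      n_snv = sum(.data$category == "SNV"),
      n_mismatch = sum(.data$category == "mismatch"),
      .groups = "drop"
    ) |>
    mutate(
      frac_reference = .data$n_reference / .data$n_classifiable,
      frac_snv = .data$n_snv / .data$n_classifiable,
      frac_mismatch = .data$n_mismatch / .data$n_classifiable
    )
}

#' Positional frequency matrices of leader variation (logogram data)
#'
#' For every leader position, counts observed bases split into
#' reference-base and novel-base occurrences, across classifiable leaders of
#' the `reference` and `SNV` categories (a mismatch leader matches a
#' different reference exactly, so its bases are not "novel"). The
#' amino-acid analogue translates each observed leader part 1 spliced to the
#' assigned allele's reference leader part 2.
#'
#' @param classifications Output of [classify_leaders()].
#' @param db An `ighv_refdb`.
#' @return List with `nt` and `aa` tibbles: `position`, `base`/`residue`,
#'   `count`, `status` (`reference` or `novel`). Column sums per position
#'   equal the number of sequences covering it.
#' @export
position_frequency_matrix <- function(classifications, db) {
  cl <- classifications |>
    filter(.data$category %in% c("reference", "SNV"))
  nt_rows <- list()
  aa_rows <- list()
  for (i in seq_len(nrow(cl))) {
    key <- cl$allele_key[i]
    obs <- cl$observed_leader[i]
    ref <- extract_region(db, key, "leader1")
    L <- nchar(obs)
    ob <- strsplit(obs, "")[[1]]
    rb <- strsplit(ref, "")[[1]][seq_len(L)]
    nt_rows[[i]] <- tibble(
      position = seq_len(L), base = ob,
      status = ifelse(ob == rb, "reference", "novel")
    )
    l2 <- extract_region(db, key, "leader2")
    pep_obs <- strsplit(as.character(.translate_spliced_leader(obs, l2)),
                        "")[[1]]
    pep_ref <- strsplit(as.character(translate_leader(db, key)), "")[[1]]
    aa_rows[[i]] <- tibble(
      position = seq_along(pep_obs), residue = pep_obs,
      status = ifelse(pep_obs == pep_ref[seq_along(pep_obs)],
                      "reference", "novel")
    )
  }
  nt <- bind_rows(nt_rows) |>
    count(.data$position, .data$base, .data$status, name = "count") |>
    arrange(.data$position, .data$base, .data$status)
  aa <- bind_rows(aa_rows) |>
    count(.data$position, .data$residue, .data$status, name = "count") |>
    arrange(.data$position, .data$residue, .data$status)
  list(nt = nt, aa = aa)
}
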