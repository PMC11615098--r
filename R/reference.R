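# Reference model: a validated full-length IGHV allele database with named
# region spans (leader part 1, intron, leader part 2, V-region, RSS).
#
# Coordinates are 1-based inclusive in ungapped allele space throughout; the
# IMGT gapped numbering is deliberately not modelled (variants are reported in
# ungapped style, e.g. C288T counted from the V-region start).

#' Construct a validated IGHV reference database
#'
#' Low-level constructor used both by [load_reference()] and by the synthetic
#' reference generator. Records missing any of the leader1/intron/leader2/rss
#' spans are loaded but flagged `truncated`; a missing or empty `v_region`
#' span is an error.
#'
#' @param alleles Tibble with columns `gene`, `allele_id`, `sequence`,
#'   `source` (one of `"IMGT"`, `"IgPDb/OGRDB"`, `"prior-study"`, `"novel"`).
#' @param regions Tibble with columns `allele_key`, `region_name`, `start`,
#'   `end` (1-based inclusive).
#' @return An object of class `ighv_refdb`: a list with elements `alleles`
#'   (tibble, one row per allele with an `allele_key = gene*allele_id` column,
#'   `subgroup` and `truncated` flags) and `regions`.
#' @export
reference_db <- function(alleles, regions) {
  alleles <- as_tibble(alleles)
  regions <- as_tibble(regions)
  alleles$allele_key <- paste0(alleles$gene, "*", alleles$allele_id)
  if (anyDuplicated(alleles$allele_key)) {
    dup <- alleles$allele_key[duplicated(alleles$allele_key)]
    stop("duplicated allele record(s): ", paste(unique(dup), collapse = ", "),
         call. = FALSE)
  }
  if (any(grepl("[^ACGT]", alleles$sequence))) {
    bad <- alleles$allele_key[grepl("[^ACGT]", alleles$sequence)]
    stop("non-ACGT or gap characters in sequence of: ",
         paste(bad, collapse = ", "), call. = FALSE)
  }
  alleles$subgroup <- .subgroup_of(alleles$gene)
  regions$start <- as.integer(regions$start)
  regions$end <- as.integer(regions$end)
  if (!all(regions$region_name %in% .REGION_ORDER)) {
    stop("unknown region name(s): ",
         paste(setdiff(unique(regions$region_name), .REGION_ORDER),
               collapse = ", "), call. = FALSE)
  }

  lens <- setNames(nchar(alleles$sequence), alleles$allele_key)
  truncated <- logical(nrow(alleles))
  names(truncated) <- alleles$allele_key
  for (key in alleles$allele_key) {
    sp <- regions[regions$allele_key == key, , drop = FALSE]
    sp <- sp[match(.REGION_ORDER, sp$region_name), , drop = FALSE]
    sp <- sp[!is.na(sp$region_name), , drop = FALSE]
    if (!"v_region" %in% sp$region_name) {
      stop("allele ", key, ": v_region span absent", call. = FALSE)
    }
    if (any(sp$start > sp$end)) {
      stop("allele ", key, ": span with start > end", call. = FALSE)
    }
    if (any(sp$end > lens[[key]]) || any(sp$start < 1L)) {
      stop("allele ", key, ": span outside sequence bounds", call. = FALSE)
    }
    vr <- sp[sp$region_name == "v_region", ]
    if (vr$end < vr$start) stop("allele ", key, ": empty v_region",
                                call. = FALSE)
    # spans must be ordered leader1 < intron < leader2 < v_region < rss and
    # non-overlapping
    if (nrow(sp) > 1L && any(diff(sp$start) <= 0 |
                             sp$start[-1] <= sp$end[-nrow(sp)])) {
      stop("allele ", key, ": overlapping or out-of-order region spans",
           call. = FALSE)
    }
    truncated[[key]] <- !all(.REGION_ORDER %in% sp$region_name)
  }
  alleles$truncated <- unname(truncated[alleles$allele_key])

  db <- structure(list(alleles = alleles, regions = regions),
                  class = "ighv_refdb")
  db
}

#' @export
print.ighv_refdb <- function(x, ...) {
  cat("IGHV reference database:", nrow(x$alleles), "alleles across",
      length(unique(x$alleles$gene)), "genes (",
      sum(x$alleles$truncated), "truncated )\n")
  invisible(x)
}

#' Load an IGHV allele reference from FASTA plus a region-annotation TSV
#'
#' FASTA headers follow the dialect `GENE*ALLELE|SOURCE`
#' (e.g. `IGHV1-69*01|IMGT`). The regions table is a TSV with columns
#' `allele_key`, `region_name`, `start`, `end`; coordinates are 1-based
#' inclusive positions in the allele sequence.
#'
#' @param fasta_path Path to the allele FASTA.
#' @param regions_path Path to the regions TSV.
#' @return An `ighv_refdb` (see [reference_db()]).
#' @export
load_reference <- function(fasta_path, regions_path) {
  seqs <- Biostrings::readDNAStringSet(fasta_path)
  headers <- names(seqs)
  m <- regexec("^([^*|]+)\\*([^|]+)\\|(.+)$", headers)
  parsed <- regmatches(headers, m)
  bad <- headers[vapply(parsed, length, integer(1)) != 4L]
  if (length(bad)) {
    stop("malformed FASTA header(s), expected 'GENE*ALLELE|SOURCE': ",
         paste(bad, collapse = "; "), call. = FALSE)
  }
  alleles <- tibble(
    gene = vapply(parsed, `[`, character(1), 2L),
    allele_id = vapply(parsed, `[`, character(1), 3L),
    sequence = unname(as.character(seqs)),
    source = vapply(parsed, `[`, character(1), 4L)
  )
  regions <- utils::read.delim(regions_path, stringsAsFactors = FALSE)
  reference_db(alleles, regions)
}

#' Write a reference database back to FASTA + regions TSV
#'
#' Inverse of [load_reference()]; the round trip reproduces sequences and
#' spans byte-identically.
#'
#' @param db An `ighv_refdb`.
#' @param fasta_path,regions_path Output paths.
#' @return Invisibly, a character vector of the two paths.
#' @export
write_reference <- function(db, fasta_path, regions_path) {
  seqs <- Biostrings::DNAStringSet(db$alleles$sequence)
  names(seqs) <- paste0(db$alleles$allele_key, "|", db$alleles$source)
  Biostrings::writeXStringSet(seqs, fasta_path, width = 80L)
  .write_tsv(db$regions[, c("allele_key", "region_name", "start", "end")],
             regions_path)
  invisible(c(fasta_path, regions_path))
}

#' Export a reference database as JSON
#'
#' @param db An `ighv_refdb`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
export_reference_json <- function(db, path) {
  jsonlite::write_json(
    list(alleles = db$alleles, regions = db$regions),
    path, dataframe = "rows", auto_unbox = TRUE, digits = NA
  )
  invisible(path)
}

# Region spans of one allele as a named list of c(start, end).
.spans_of <- function(db, allele_key) {
  sp <- db$regions[db$regions$allele_key == allele_key, , drop = FALSE]
  out <- lapply(seq_len(nrow(sp)), function(i) c(sp$start[i], sp$end[i]))
  names(out) <- sp$region_name
  out[intersect(.REGION_ORDER, names(out))]
}

.allele_row <- function(db, allele_key) {
  i <- match(allele_key, db$alleles$allele_key)
  if (is.na(i)) stop("unknown allele: ", allele_key, call. = FALSE)
  db$alleles[i, , drop = FALSE]
}

#' Extract a named region of an allele
#'
#' @param db An `ighv_refdb`.
#' @param allele_key Allele key, e.g. `"IGHV1-69*01"`.
#' @param region_name One of `leader1`, `intron`, `leader2`, `v_region`,
#'   `rss`.
#' @return The exact nucleotide substring of the region.
#' @export
extract_region <- function(db, allele_key, region_name) {
  row <- .allele_row(db, allele_key)
  sp <- .spans_of(db, allele_key)
  if (!region_name %in% names(sp)) {
    stop("region unavailable (truncated record): ", allele_key, " has no ",
         region_name, " span", call. = FALSE)
  }
  substr(row$sequence, sp[[region_name]][1], sp[[region_name]][2])
}

#' Translate the spliced leader of an allele
#'
#' Splices leader part 1 + leader part 2 (intron removed) and translates in
#' frame from position 1 of leader part 1 with the standard genetic code. An
#' internal stop codon is flagged via the `internal_stop` attribute but the
#' translation is still returned.
#'
#' @param db An `ighv_refdb`.
#' @param allele_key Allele key.
#' @return Peptide string with attribute `internal_stop` (logical).
#' @export
translate_leader <- function(db, allele_key) {
  l1 <- extract_region(db, allele_key, "leader1")
  l2 <- extract_region(db, allele_key, "leader2")
  .translate_spliced_leader(l1, l2)
}

# Translation core shared with the observed-leader amino-acid logogram.
.translate_spliced_leader <- function(leader1, leader2) {
  spliced <- paste0(leader1, leader2)
  if (nchar(spliced) %% 3L != 0L) {
    stop("frame error: spliced leader length ", nchar(spliced),
         " not divisible by 3", call. = FALSE)
  }
  aa <- as.character(Biostrings::translate(
    Biostrings::DNAString(spliced), no.init.codon = TRUE
  ))
  internal_stop <- grepl("\\*", substr(aa, 1L, nchar(aa) - 1L))
  structure(aa, internal_stop = internal_stop)
}

#' Index reference alleles by their leader part 1 sequence
#'
#' Only non-truncated records carrying a `leader1` span contribute. Used by
#' [classify_leader()] to detect "mismatch" leaders: an observed leader that
#' exactly equals the reference leader of a *different* allele.
#'
#' @param db An `ighv_refdb`.
#' @return Named list mapping each distinct leader1 sequence to the character
#'   vector of allele keys carrying it.
#' @export
leader_index <- function(db) {
  keys <- db$alleles$allele_key[!db$alleles$truncated]
  keys <- keys[vapply(keys, function(k)
    "leader1" %in% names(.spans_of(db, k)), logical(1))]
  leaders <- vapply(keys, function(k) extract_region(db, k, "leader1"),
                    character(1))
  split(unname(keys), leaders)
}

# All alleles of one gene, as a tibble slice.
.gene_alleles <- function(db, gene) {
  db$alleles[db$alleles$gene == gene, , drop = FALSE]
}

# V-region sequence of every allele, named by allele_key.
.v_regions <- function(db) {
  vapply(db$alleles$allele_key, function(k)
    extract_region(db, k, "v_region"), character(1))
}
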