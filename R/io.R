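#' Read a FASTQ file into a tibble
#'
#' Reads are returned as a tibble with columns `read_id`, `sequence` and
#' `quality` (Sanger/Phred+33 encoding), the representation used by all
#' read-level operations in the package.
#'
#' @param path Path to an uncompressed or gzipped FASTQ file.
#' @return A tibble with columns `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  qs <- Biostrings::readQualityScaledDNAStringSet(path)
  tibble(
    read_id = sub("\\s.*$", "", names(qs)),
    sequence = as.character(qs),
    quality = as.character(Biostrings::quality(qs))
  )
}

#' Write reads to a FASTQ file
#'
#' @param reads Tibble with columns `read_id`, `sequence`, `quality`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  seqs <- Biostrings::DNAStringSet(reads$sequence)
  names(seqs) <- reads$read_id
  qual <- Biostrings::PhredQuality(reads$quality)
  qs <- Biostrings::QualityScaledDNAStringSet(seqs, qual)
  Biostrings::writeQualityScaledXStringSet(qs, path)
  invisible(path)
}

#' Read an AIRR rearrangement TSV
#'
#' Accepts the standard AIRR Rearrangement column names; only the columns
#' present are returned, with `sequence_id` and `sequence` mandatory.
#'
#' @param path Path to a tab-separated rearrangement file.
#' @return A tibble of rearrangements.
#' @export
read_rearrangements <- function(path) {
  df <- as_tibble(utils::read.delim(path, stringsAsFactors = FALSE))
  req <- c("sequence_id", "sequence")
  missing <- setdiff(req, names(df))
  if (length(missing)) {
    stop("rearrangement file lacks required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
  df
}

#' Write a rearrangement table as AIRR-style TSV
#'
#' @param rearrangements Tibble of rearrangements.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_rearrangements <- function(rearrangements, path) {
  .write_tsv(rearrangements, path)
}
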