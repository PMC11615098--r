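# Internal low-level helpers shared across modules.

.BASES <- c("A", "C", "G", "T")
.REGION_ORDER <- c("leader1", "intron", "leader2", "v_region", "rss")

# Hamming distance between two equal-length strings.
.hamming <- function(a, b) {
  sum(charToRaw(a) != charToRaw(b))
}

# 1-based positions at which two equal-length strings differ.
.mismatch_positions <- function(a, b) {
  which(charToRaw(a) != charToRaw(b))
}

.random_dna <- function(n) {
  paste(sample(.BASES, n, replace = TRUE), collapse = "")
}

.revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# Replace single bases at `positions` with `alts` (both vectors, same length).
.apply_substitutions <- function(seq, positions, alts) {
  for (i in seq_along(positions)) {
    substr(seq, positions[i], positions[i]) <- alts[i]
  }
  seq
}

# For each reference base, draw a uniformly random different base.
.random_alt <- function(ref) {
  vapply(ref, function(b) sample(setdiff(.BASES, b), 1L), character(1),
         USE.NAMES = FALSE)
}

# Sprinkle i.i.d. substitution errors over a character vector of sequences.
# Returns list(sequences=..., positions=list of integer vectors).
.mutate_sequences <- function(seqs, rate) {
  lens <- nchar(seqs)
  n_err <- rbinom(length(seqs), lens, rate)
  pos_list <- vector("list", length(seqs))
  hit <- which(n_err > 0L)
  for (i in hit) {
    pos <- sort(sample.int(lens[i], n_err[i]))
    ref <- vapply(pos, function(p) substr(seqs[i], p, p), character(1))
    seqs[i] <- .apply_substitutions(seqs[i], pos, .random_alt(ref))
    pos_list[[i]] <- pos
  }
  list(sequences = seqs, positions = pos_list)
}

# Mean Phred score of a Sanger-encoded (offset 33) quality string.
.mean_phred <- function(qual) {
  vapply(qual, function(q) mean(utf8ToInt(q)) - 33, numeric(1),
         USE.NAMES = FALSE)
}

# Constant-quality string of given length (Phred q, offset 33).
.qual_string <- function(len, q = 37L) {
  vapply(len, function(l) strrep(intToUtf8(33L + q), l), character(1))
}

# Character matrix (positions x sequences) for equal-length strings; used for
# vectorised prefix/suffix mismatch counting.
.char_matrix <- function(x, width) {
  matrix(unlist(strsplit(substr(x, 1L, width), "", fixed = TRUE),
                use.names = FALSE),
         nrow = width)
}

# Mismatches of every string in `x` (all at least `width` long) against the
# first `width` characters, vs a single probe of length `width`.
.prefix_mismatches <- function(x, probe) {
  w <- nchar(probe)
  m <- .char_matrix(x, w)
  pc <- strsplit(probe, "", fixed = TRUE)[[1]]
  as.integer(colSums(m != pc))
}

.suffix_mismatches <- function(x, probe) {
  w <- nchar(probe)
  .prefix_mismatches(substr(x, nchar(x) - w + 1L, nchar(x)), probe)
}

# Mismatch counts of every string in `x` against every probe (all probes
# the same width, every string at least that wide): builds the character
# matrix once. Returns an n x length(probes) integer matrix.
.prefix_mismatch_table <- function(x, probes) {
  w <- unique(nchar(probes))
  stopifnot(length(w) == 1L)
  m <- .char_matrix(x, w)
  out <- matrix(0L, length(x), length(probes))
  for (j in seq_along(probes)) {
    pc <- strsplit(probes[j], "", fixed = TRUE)[[1]]
    out[, j] <- as.integer(colSums(m != pc))
  }
  out
}

.suffix_mismatch_table <- function(x, probes) {
  w <- unique(nchar(probes))
  stopifnot(length(w) == 1L)
  .prefix_mismatch_table(substr(x, nchar(x) - w + 1L, nchar(x)), probes)
}

# SNV token "C288T" -> list(pos, ref, alt); and back.
.snv_token <- function(position, ref, alt) {
  paste0(ref, position, alt)
}

.parse_snv_token <- function(token) {
  m <- regmatches(token, regexec("^([ACGT])([0-9]+)([ACGT])$", token))[[1]]
  if (length(m) != 4L) {
    stop("malformed SNV token: ", token, call. = FALSE)
  }
  list(position = as.integer(m[3]), ref = m[2], alt = m[4])
}

# Canonical allele name: base name plus "_" separated SNV tokens sorted by
# position, so germline and expressed novel calls compare equal.
.canonical_name <- function(name) {
  vapply(name, function(nm) {
    parts <- strsplit(nm, "_", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(nm)
    toks <- parts[-1]
    pos <- vapply(toks, function(t) .parse_snv_token(t)$position, integer(1))
    paste(c(parts[1], toks[order(pos)]), collapse = "_")
  }, character(1), USE.NAMES = FALSE)
}

# Subgroup integer from an IGHV gene name, e.g. IGHV4-38-2 -> 4.
.subgroup_of <- function(gene) {
  as.integer(sub("^IGHV([0-9]+).*$", "\\1", gene))
}

.snv_tibble <- function(region = character(), position = integer(),
                        ref = character(), alt = character()) {
  tibble(region = region, position = as.integer(position),
         ref = ref, alt = alt)
}

# Write a data frame as a plain TSV with stable ordering (no row names).
.write_tsv <- function(df, path) {
  df <- as.data.frame(df)
  for (j in seq_along(df)) {
    if (is.list(df[[j]])) {
      df[[j]] <- vapply(df[[j]], function(x) paste(unlist(x), collapse = ";"),
                        character(1))
    }
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
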