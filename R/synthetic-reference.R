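# Synthetic full-length IGHV reference panel.
#
# The generator emulates the structure of a curated IGHV germline database:
# per-gene allele families differing by a handful of V-region SNVs,
# gene-specific leader part 1 sequences (46 nt, ATG-initiated), a spliced
# leader in frame (46 + 11 = 57 nt), per-gene intron lengths, a fixed-length
# V-region (296 nt) and a canonical heptamer-23-spacer-nonamer RSS. It is a
# synthetic stand-in: sequences are random within those structural
# constraints, not real IMGT records.

.DEFAULT_PANEL <- c("IGHV1-2", "IGHV1-18", "IGHV1-69", "IGHV2-5",
                    "IGHV3-23", "IGHV3-30", "IGHV4-34", "IGHV4-59",
                    "IGHV5-51", "IGHV6-1")

.L1_LEN <- 46L
.L2_LEN <- 11L
.V_LEN <- 296L
.RSS_LEN <- 39L

# Mutate `n` distinct positions of `seq` drawn from `candidates`.
.scatter_snvs <- function(seq, n, candidates) {
  pos <- sort(sample(candidates, n))
  ref <- vapply(pos, function(p) substr(seq, p, p), character(1))
  .apply_substitutions(seq, pos, .random_alt(ref))
}

#' Generate a synthetic IGHV reference panel
#'
#' Builds a deterministic (seeded) allele database plus matching subgroup
#' primers and an IGHJ6 allele set, structured like the references the
#' germline and repertoire pipelines consume. Alleles of one gene share the
#' gene's leader/intron/RSS and differ at 3 dedicated V-region positions per
#' allele (pairwise Hamming distance >= 3, so single planted SNVs cannot
#' flip the closest match). Leader part 1 is unique to each gene, which makes
#' leader-recombination events detectable as exact cross-gene matches.
#'
#' @param genes Character vector of IGHV gene names (subgroup parseable from
#'   the name); defaults to a 10-gene panel spanning subgroups 1-6.
#' @param alleles_per_gene Alleles generated per gene (`*01`, `*02`, ...).
#' @param seed Integer seed; identical inputs give a byte-identical panel.
#' @return List with elements `db` (an `ighv_refdb`), `j_db` (tibble of
#'   IGHJ6 alleles: `allele`, `sequence`), and `primers` (tibble `subgroup`,
#'   `fwd`, `rev`).
#' @export
synthetic_reference <- function(genes = .DEFAULT_PANEL,
                                alleles_per_gene = 4L,
                                seed = 7191L) {
  stopifnot(alleles_per_gene >= 1L, length(genes) >= 1L)
  set.seed(seed)
  subgroups <- sort(unique(.subgroup_of(genes)))

  # subgroup-level consensus sequences
  sg_v <- setNames(lapply(subgroups, function(s) .random_dna(.V_LEN)),
                   subgroups)
  sg_l1 <- setNames(lapply(subgroups, function(s)
    paste0("ATG", .random_dna(.L1_LEN - 3L))), subgroups)
  sg_l2 <- setNames(lapply(subgroups, function(s) .random_dna(.L2_LEN)),
                    subgroups)

  allele_rows <- list()
  region_rows <- list()
  src_cycle <- c("IMGT", "IMGT", "IgPDb/OGRDB", "prior-study")
  for (gi in seq_along(genes)) {
    gene <- genes[gi]
    sg <- as.character(.subgroup_of(gene))
    # gene-level backbone: ~8% divergence from the subgroup V consensus, a
    # gene-unique leader1 (positions 5..40 mutated), gene-specific intron
    v_base <- .scatter_snvs(sg_v[[sg]], 24L, 1:.V_LEN)
    l1 <- .scatter_snvs(sg_l1[[sg]], 6L, 5:40)
    intron <- .random_dna(80L + 7L * gi)
    rss <- paste0("CACAGTG", .random_dna(.RSS_LEN - 16L), "ACAAAAACC")
    # each allele owns 3 private V-region positions
    own_pos <- matrix(sample.int(.V_LEN, 3L * alleles_per_gene),
                      nrow = alleles_per_gene)
    for (ai in seq_len(alleles_per_gene)) {
      v <- v_base
      if (ai > 1L) {
        pos <- sort(own_pos[ai, ])
        ref <- vapply(pos, function(p) substr(v, p, p), character(1))
        v <- .apply_substitutions(v, pos, .random_alt(ref))
      }
      seqfull <- paste0(l1, intron, l2 <- sg_l2[[sg]], v, rss)
      key <- sprintf("%s*%02d", gene, ai)
      allele_rows[[key]] <- tibble(
        gene = gene, allele_id = sprintf("%02d", ai), sequence = seqfull,
        source = src_cycle[((ai - 1L) %% length(src_cycle)) + 1L]
      )
      offs <- cumsum(c(0L, nchar(l1), nchar(intron), nchar(l2), nchar(v)))
      lens <- c(nchar(l1), nchar(intron), nchar(l2), nchar(v), nchar(rss))
      region_rows[[key]] <- tibble(
        allele_key = key, region_name = .REGION_ORDER,
        start = offs + 1L, end = offs + lens
      )
    }
  }

  db <- reference_db(bind_rows(allele_rows), bind_rows(region_rows))

  # IGHJ6 alleles: shared backbone, 2 private positions per allele
  # (pairwise Hamming distance 4) so one somatic mutation cannot flip the
  # anchor assignment
  j_base <- .random_dna(62L)
  j_pos <- matrix(sample.int(62L, 6L), nrow = 3L)
  j_seq <- vapply(1:3, function(i) {
    pos <- sort(j_pos[i, ])
    ref <- vapply(pos, function(p) substr(j_base, p, p), character(1))
    .apply_substitutions(j_base, pos, .random_alt(ref))
  }, character(1))
  j_db <- tibble(allele = sprintf("IGHJ6*%02d", 1:3), sequence = j_seq)

  primers <- tibble(
    subgroup = subgroups,
    fwd = vapply(subgroups, function(s) .random_dna(20L), character(1)),
    rev = vapply(subgroups, function(s) .random_dna(20L), character(1))
  )

  list(db = db, j_db = j_db, primers = primers)
}
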