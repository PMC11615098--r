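---
title: "Methods: IGHV diversity from germline amplicons and IgM repertoires"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: IGHV diversity from germline amplicons and IgM repertoires}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ighvpop)
```

## The problem

The immunoglobulin heavy-chain variable (IGHV) locus is among the most
polymorphic and structurally variable regions of the human genome: single
nucleotide variants create allelic series for each of ~50 functional IGHV
genes, and larger structural events duplicate or delete whole gene
segments. Characterising an individual's germline IGHV *genotype* — which
alleles they carry, on which chromosome, and at what copy number — matters
because germline variation shapes the expressed antibody repertoire.

`ighvpop` implements a desk-scale, fully testable version of a combined
analysis design:

1. **Germline path.** Full-length IGHV amplicons (leader part 1, intron,
   leader part 2, V-region, recombination signal sequence) are processed
   into per-participant allele calls, regulatory-region variants, and
   allele-count copy-number genotypes.
2. **Expressed path.** Bulk IgM VDJ rearrangements are annotated, the
   expressed allele set is inferred, and haplotypes are reconstructed from
   a heterozygous IGHJ6 anchor, giving chromosome-resolved duplication
   calls and duplication-linked expression fold changes.
3. **Reconciliation.** Calls from the two paths are compared per
   participant per gene (Jaccard concordance).

Because the real study data are sequencing-run scale, every stage here is
driven by a seeded synthetic-data generator whose truth tables make
parameter-recovery claims testable.

## The reference model

An allele record is a full-length nucleotide sequence with named region
spans. Coordinates are **1-based inclusive and ungapped** throughout;
variants are reported in `RefPosAlt` style (e.g. `C288T`) with V-region
positions counted from the V-region start. The IMGT gapped numbering and
its negative leader positions are deliberately not modelled internally —
ungapped coordinates are unambiguous for the substitution-centric logic
used here, and an exporter could map leader positions to the conventional
negative numbering if needed.

Truncated records (V-region only) are first-class: they can serve as
assignment targets but are excluded from leader/RSS comparisons and from
leader classification, which need a reference to compare against.

## Allele assignment

The closest-match rule is: highest percent identity over the V-region,
ties broken by fewer total mismatches, then by lexicographically smallest
allele name. Identity is `matches / aligned V-region columns`.

Numerically, assignment uses three tiers: an exact-sequence hash, an
equal-length positionwise comparison, and — only when lengths differ — an
end-gap-free pairwise alignment (match +1, mismatch −1, gap open −4,
extend −1, via `Biostrings::pairwiseAlignment`). Indels are flagged but
never reported as SNVs. A best identity below the 85% floor marks a query
`unassignable`; the floor prevents cross-subgroup nonsense calls and is
configurable. Any V-region SNV relative to the winner makes the call a
candidate novel allele, named `BASE_RefPosAlt[_RefPosAlt...]` with tokens
in ascending position order so that independently derived names compare
equal after canonicalisation.

## The germline amplicon pipeline

Stage order and defaults:

| stage | rule | default |
|---|---|---|
| primer trimming | both primers located with ≤ `max_mismatches` substitutions | 2 |
| quality filter | mean read Phred ≥ `min_q` (boundary kept) | 33 |
| dereplication | exact-sequence collapse per participant | — |
| abundance filter | `count ≥ min_count` and `count ≥ min_gene_fraction ×` non-singleton gene reads | 2, 0.1 |
| assignment | closest match as above | floor 85% |

Two choices deserve comment. *Mean* quality is used for the Q33 rule
(common dereplication-tool usage; the minimum-quality reading would
discard essentially everything at realistic error rates). The abundance
fraction's denominator **excludes singletons**: under a per-base
substitution error model almost all error-derived uniques are singletons,
and counting their mass would starve the true alleles of a gene duplicated
on both chromosomes (four copies sharing one denominator) out of the
filter. With singletons excluded the denominator no longer depends on
`min_count`, which also makes "raising `min_count` never enlarges the
retained set" a structural property rather than an empirical one.

Duplicate PCR runs of one sample are pooled by simple concatenation before
dereplication.

## Leader classification

Observed leader part 1 sequences of called alleles fall into exactly one
class:

* **reference** — equals the assigned allele's own reference leader;
* **mismatch** — exactly equals the reference leader of a *different*
  allele (the donors are reported); this is the signature of either
  convergent SNVs or recombination between highly homologous genes;
* **SNV** — differs from the own reference and matches no other allele,
  with positional records; a multi-SNV leader is still SNV — exact match
  is the only unambiguous boundary for the mismatch class;
* length-discordant leaders are flagged `indel-leader` and excluded from
  counts, as are novel alleles and truncated references (no reference
  leader to compare against).

Classification uses leader part 1 only; position-frequency (logogram)
matrices count reference vs novel bases per position over the
`reference` + `SNV` classes (a mismatch leader matches a different
reference exactly, so its bases are not novel), with an amino-acid
analogue built by splicing the observed leader part 1 to the reference
leader part 2 and translating from position 1.

## Copy-number genotyping

Per participant per gene, the zygosity state is a pure function of the
number of unique alleles: 1 homozygous, 2 heterozygous, >2 duplicated,
0 no-coverage. Unique alleles are counted on **full-length** sequence
identity by default, since alleles can share a V-region while differing in
the intron or leader; a `v_region` identity mode exists for sensitivity
analysis. Population summaries use covered participants as the per-gene
denominator. Two blind spots are inherent to the allele-count method and
are asserted as expected negatives in the tests: duplications of
*identical* alleles are invisible, and deletions are never called (a
single unique allele may simply be homozygosity).

## Repertoire analysis

Rearrangements are annotated by best V (V-region identity, same tie-break
as assignment) and best J (terminal alignment); exact duplicate sequences
are collapsed first, and the resulting "unique VDJ" — a distinct
full-length nucleotide sequence — is the unit of all expression counting.

**Expressed-allele inference** is a deliberately simplified version of
germline-inference tools: per gene, reads within `max_mut` mismatches of
the closest known allele vote with their *exact* V segment; a segment
needs ≥ 10 unique VDJs and ≥ 3 distinct junctions to be emitted. The
junction-diversity rule suppresses clonally expanded somatic variants.
`max_mut` defaults to 3 because novel alleles may legitimately carry up to
three V-region SNVs; a cutoff of 1 would make such alleles undiscoverable
by construction, while the support and junction filters keep somatic
artefacts out.

**Haplotype reconstruction** requires a heterozygous anchor (IGHJ6 by
default): exactly two anchor alleles each carrying ≥ 10% of anchor reads
(tolerating unequal anchor-allele expression down to that floor);
participants failing this are rejected with an explicit error, matching
the anchor method's applicability. Every rearrangement is binned by its
anchor allele; per gene per bin, allele support is tallied and given a
confidence

\[ k = \log_{10} \frac{\mathrm{Binom}(a \mid n, p)}{\mathrm{Binom}(a
\mid n, e)}, \qquad p = \max(a/n, e), \]

with `a` the allele's reads, `n` the gene's reads on that haplotype and
`e` an assumed mis-assignment rate (default 0.01), floored at 0. This is
an explicit reimplementation contract: the published haplotyping tool's
internal Bayesian machinery is not reproduced, but `k` is used the same
way — as a pass/fail filter at 3.6, alongside a minimum of 50 supporting
reads. A gene is duplicated on a haplotype when more than one allele
passes both filters; states are `none`, `single_haplotype_dup`,
`both_haplotype_dup`, or `unresolved` when nothing passes.

**Fold change** is the ratio of mean per-haplotype expression proportions,
duplicated over non-duplicated, computed per gene to avoid confounding by
between-gene expression differences. The ratio form is used because
reported values of the form "5.2-fold" are ratios; a subtraction variant
sits behind a flag. Undefined genes (no duplicated or no non-duplicated
haplotype) are omitted with a reason.

## The synthetic-data generator

The generator defines the study conditions rather than merely providing
fixtures. Each participant carries two chromosomes; per gene per
chromosome the copy number is 1 or (with probability `dup_rate`) 2, with
alleles drawn uniformly *with replacement* — so identical-allele
duplications occur at their natural rate and exercise the blind spot. Each
planted copy receives at most one modification event (the rates are
therefore exclusive draws, keeping truth tables unambiguous):

* novel V-region alleles (1–3 SNVs), default rate 0.10 — about the
  fraction of novel alleles a diverse cohort yields;
* a single leader-1 SNV, default 0.06, and cross-gene leader
  recombination ("mismatch" leaders), default 0.20 — the two observed
  leader-variation rates;
* `dup_rate` defaults to 0.15 per chromosome, within the 10–30% per-gene
  duplication prevalences seen for commonly duplicated IGHV genes.

Amplicons are forward primer + full allele + reverse-complemented reverse
primer at depth 200 with substitution-only errors at 0.002/base (Q37
bases, Q20 at error positions) — a merged-read, indel-free model
appropriate for the SNV-centric allele logic. Repertoires pick a
chromosome 50/50, then a gene copy proportional to usage: a duplicated
gene's total weight is `usage_boost` (default 2), shared across its
copies, so the *expected proportion ratio* between a duplicated and a
non-duplicated haplotype is about the boost (slightly less after
renormalisation). Rearrangements are V-region + random 8–20 nt junction +
the chromosome's IGHJ6 allele, with somatic substitutions at 0.005/base —
an IgM-like, naive-biased rate consistent with the inference assumptions.

The synthetic reference panel mirrors the structure of a curated database
(ATG-initiated 46 nt leader part 1, in-frame 57 nt spliced leader, 296 nt
V-region, heptamer/nonamer RSS, per-gene intron lengths; alleles of one
gene ≥ 3 V-region differences apart; IGHJ6 alleles 4 differences apart so
a single somatic mutation cannot flip the anchor) but its sequences are
random within those constraints — it is a synthetic stand-in, not IMGT
data. Consequently, passing tests demonstrate *method* correctness and
parameter recovery under the stated error models, not performance on real
amplicons, whose primer-site polymorphism, chimeras, platform-specific
error profiles and indels are out of scope here.

## Problem sizes and experiment design

The test-suite and acceptance-script experiments use, as the package's
study conditions: a 30-participant × 10-gene cohort at depth 200 for
germline recovery (error-free and 0.002/base); and a 12-participant ×
20-gene panel with 6 alleles per gene, `dup_rate` 0.25, a heterozygous
IGHJ6 anchor and 5 000 VDJs per haplotype for the haplotype/CNV/
fold-change experiment. The richer panel gives each gene several
duplicated haplotypes to average over, which is what makes per-gene
fold-change estimates stable; with sparser duplication the estimate's
denominator (mean non-duplicated proportion) is inflated by the
undetectable identical-allele duplications and single-haplotype noise.

## Known limitations

* Indel-containing novel alleles are flagged but not named.
* Deletion calling, D-gene haplotyping and multi-anchor reconciliation
  are out of scope.
* Same-allele duplications are invisible to both the germline
  (allele-count) and expressed (per-haplotype allele-count) methods; both
  paths therefore *underestimate* duplication, and the tests assert this
  as the expected behaviour rather than working around it.
* Concordance uses Jaccard on canonicalised allele-name sets per
  participant-gene cell; other denominators (per-allele pooling) would
  give different headline numbers.

## Reproducing the experiments

```sh
Rscript scripts/acceptance.R --seed 1 --out results/acceptance.json
```

re-runs both experiments end to end and writes the recovered quantities
(allele recovery, zygosity and duplication-rule accuracy, leader-variant
recovery, oracle agreement, chromosome-binning accuracy, CNV-state
accuracy, mean fold change under a 2× boost, mean concordance, and a
bundle-determinism flag) as JSON. All randomness derives from `--seed`.
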