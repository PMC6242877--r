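---
title: "Methods: comparative miRNA repertoire evolution"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: comparative miRNA repertoire evolution}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirevol)
```

This vignette is the package's own account of the models and procedures it
implements, the parameters that matter, and the choices made where the
design was genuinely open.

## Coordinates and formats

All coordinates inside the package are 0-based half-open; GFF3 and
outfmt6 (1-based inclusive) are converted exactly once, at the I/O
boundary, so no off-by-one drift can accumulate between modules. U is
normalised to T on input: the pipeline mixes genomic and small-RNA
sequence space and a single DNA alphabet avoids pointless case analysis.
Conservation score tracks are held sparsely per contig; positions without
data return `NA`, never 0, because genuine conservation tracks have gaps
and a fabricated zero would bias binned statistics downward.

Readers reject malformed records (with file and line context) rather than
repairing them silently: a reversed BED interval or a non-binary matrix
cell is always an upstream bug worth surfacing.

## Locus curation

A candidate locus passes curation when it satisfies two independent
filters; they commute, so their order is irrelevant.

**Hairpin structure.** The fold must (a) contain exactly one terminal
loop, (b) pair at least 60% of annotated arm bases *with the opposite
arm*, (c) place the two arms on opposite sides of the loop, and (d) pair
no arm base within its own arm. Criterion (b) is deliberately the
miRNA/miRNA\* duplex rather than "paired anywhere": random sequences of
hairpin-like base composition pair plenty of arm bases somewhere, but
rarely arm-against-arm in register. All thresholds are function
arguments.

**Folding engine.** `fold_hairpin()` defaults to `engine = "auto"`:
ViennaRNA's `RNAfold` when the binary is on the PATH, otherwise a
built-in Nussinov-style maximum base-pairing dynamic programme
(Watson–Crick + GU, minimum loop 3 nt, deterministic traceback that
prefers leaving the 3′ base unpaired and otherwise the outermost
partner). The thermodynamic engine is the field standard and is what the
structure criteria were calibrated with; the fallback keeps the package
functional without it, at the cost of a more permissive fold. Both
engines drop *lonely* (unstacked) base pairs from the returned structure
— isolated pairs are essentially unstable, and retaining them inflates
spurious arm pairing in shuffled controls.

**Read duplex evidence.** A read is assigned to an arm when at least 80%
of its span lies within the arm extended by 3 nt on each side — slack for
imprecise Drosha/Dicer ends. The locus passes with ≥ 1 read on each arm
and ≥ 10 reads in total. A rejected locus with both arms covered can
later be *rescued* if it is homologous to an accepted locus (orthogroup
membership): processing evidence plus homology outweighs shallow
coverage.

**Known vs novel.** A hairpin is *known* when a database mature aligns
within it ungapped with at most one mismatch, on the sense strand;
anything else is *novel*.

## Orthogroups and presence calls

Clustering follows CD-HIT's greedy-incremental semantics: sequences
sorted by length (descending; ties broken lexicographically by ID so the
result is reproducible), the first unassigned sequence seeds a cluster,
and each later sequence joins the first cluster (in creation order) whose
representative it matches at ≥ 80% identity. Identity is the number of
identical positions in a global alignment divided by the shorter
sequence's length — CD-HIT's global-identity convention; with match 1,
mismatch 0 and free gaps the aligner maximises identical positions
(equivalently the LCS). Because the input order is canonicalised
internally, permuting the input does not change the output.

Homology hits are filtered at e-value ≤ 1e-6 and ≥ 40 aligned nt. Synteny
support asks whether the nearest protein-coding gene upstream or
downstream of the query locus is a homolog of the corresponding flank of
the subject hit ("at least one pair" suffices, and a containing gene
counts as both flanks); for reverse-orientation hits the subject flanks
are swapped first. Presence evidence is ranked annotated >
synteny-homolog > unaligned-read, direct annotation being the strongest
claim, and the matrix keeps the highest-ranking source per cell.

## Dollo parsimony

Under Dollo (exactly one gain, any number of subsequent losses) the
loss-minimising reconstruction is closed-form: the gain sits on the
branch above the MRCA of the present leaves, and one loss on the stem of
each maximal all-absent subtree below the gain node. For a binary tree
this optimum is unique — placing the gain any higher adds at least one
loss, and splitting a subtree loss into deeper losses adds at least one
more. The test suite verifies this against exhaustive enumeration of all
single-gain internal-state assignments for every presence vector on a
5-leaf tree.

Characters present at the root are assigned to a synthetic *root stem*
branch whose length is a user argument (`root_stem_length`), since trees
rarely date their own stem; the root row is reported separately. Branch
IDs are the sorted, `+`-joined tip labels of the clade below the branch,
which makes outputs stable across tree re-orderings. Net gain rate is
(gains − losses)/branch length, in events per Myr.

Seed-family turnover reuses the same machinery with rows keyed by 7-nt
seed: a species retains a seed while *any* of its loci carries it, so the
loss of one orthogroup can be compensated by another family member — the
per-seed character stays present.

## Genomic origins

**Repeat-derived calls.** Each repeat sequence that produced a hit is
shuffled `n_shuffles` times (default 1000) by mononucleotide permutation
(a dinucleotide-preserving segment-swap shuffle is available behind a
flag); every miRNA is locally aligned against every shuffle and the
maximum observed bit score is the null threshold. A real hit is accepted
only with alignment ≥ 30 nt and bit score *strictly above* the threshold.
Bit scores come from the ungapped Karlin–Altschul transform
$S' = (\lambda S - \ln K)/\ln 2$ with match +1 / mismatch −2; $\lambda$
is solved numerically from the scoring scheme under uniform base
composition and $K$ is pinned in the scoring configuration (0.621, the
published ungapped value for this scheme). Per-repeat sub-seeds are
derived from the user seed so that enlarging `n_shuffles` extends the
shuffle set instead of replacing it — the threshold is then
non-decreasing in the shuffle count, and bit-for-bit reproducible at a
fixed seed. The threshold is always recomputed per run, never cached: it
depends on the miRNA set, the repeat set and the scoring scheme.

**Antisense couples** need ≥ 95% overlap of at least one of the two loci,
on opposite strands. Because a sequencing error in a read of a highly
expressed miRNA can map antisense and fabricate a partner locus, the
cross-mapping check compares equal-length reads of the two loci
positionwise and flags pairs within one mismatch, attaching both
abundances so the asymmetry is visible.

**miRtrons** require ≥ 90% reciprocal overlap with an intron on the same
strand *and* passing duplex/structure checks — splicing explains the
precursor's ends, but Dicer processing evidence is still required.

**Duplications.** An orthogroup is duplicated when a species contributes
two member loci at distinct (non-overlapping) genomic positions; two
strands of one interval — an antisense couple — are one locus region,
not paralogs. Tandem means a duplicated pair within 100 kb on one contig
(the window is an argument; "tandem" has no universal definition).

**Genomic context** is majority overlap against 3′UTR, 5′UTR and intron
features, strand-agnostic (antisense relationships are a separate flag),
with ties broken in favour of the rarer annotation (UTR3 > UTR5 >
intron); a locus overlapping no gene is intergenic, and one overlapping a
gene only in coding exons is binned with the genic/intronic class.

## Expression statistics

An orthogroup is *expressed* in a tissue when its read count summed over
species reaches the presence threshold (default 1 read — the weakest
defensible notion of "evidence of expression"; it is an argument and
analyses sensitive to it should vary it). Categories per focal tissue
count the additional expressed tissues: tissue-specific, +1, +2, all
tissues; a silent focal tissue is not-expressed. The proportion test is
the pooled two-proportion z-test, two-sided, without continuity
correction — sidedness is not recoverable from typical reported
p-values, so the default is the conservative two-sided form. Gene-list
overlaps use the exact hypergeometric upper tail with fold enrichment
relative to the expectation $|A||B|/N$.

## Target sites and conservation profiles

Seeds are mature positions 2–8 (1-based); site taxonomy is the canonical
one: 8mer (full 7-nt match + A), 7mer-m8 (full match, no A), 7mer-A1
(positions 2–7 match + A, excluding offsets already counted as 8mers).
"7mer" includes both 7mer classes by default since the narrower reading
cannot be established. Overlapping occurrences are all reported.
context++ efficacy scores are *consumed, never computed* — re-deriving
that model is out of scope — and when absent the context filter is
skipped with a notice instead of silently passing everything.

3′UTR windows run 5 kb downstream of the last exon (strand-aware),
are trimmed back at the first overlapping coding sequence of another
gene, clipped at the contig end, and dropped below 500 nt.

Conservation profiles tile the 7-nt site ± 49 nt into 15 consecutive
7-nt bins with the site in the central bin. The default bin statistic is
the median across sites of per-site bin means; pooling all per-position
scores per bin is available behind `stat = "pooled"` — both are
legitimate readings of a binned median and the per-site form weights
each site equally regardless of track coverage. Confidence intervals are
seeded bootstrap percentile intervals (B = 1000) of the bin median.
Missing positions are excluded from a site's bin mean; a site with a
fully missing bin is excluded from that bin's median — never zero-filled.

## The synthetic-data module

The generators are pure functions of a configuration object and its seed:
identical seeds give byte-identical outputs, and every simulated object
carries its ground-truth labels so downstream tests never re-derive
truth.

* **Dollo histories** place one gain per orthogroup on a branch drawn
  proportionally to branch length (the root stem included, default
  10 Myr) and losses by a Poisson process (default 0.004/Myr, a regime
  where most histories remain uniquely recoverable) on branches strictly
  below the gain; all-absent histories are discarded and redrawn,
  mirroring the ascertainment of observable orthogroups. Two-way
  (non-Dollo) transitions are deliberately not simulated — the inference
  stage assumes Dollo, and violating that assumption is a separate
  negative-control exercise.
* **Hairpins** are arm + loop + reverse-complemented arm with a chosen
  number of injected mismatches, so the stem pairs by construction.
  **Read stacks** draw Poisson counts per arm (default mean 30) with
  ±1 nt end wobble (imprecise processing without a full isomiR model)
  and per-base errors (default 1%).
* **The planted genome** (one 60-kb contig) carries three protein-coding
  genes, repeat families with genomic copies, and one locus per origin
  class — intronic, miRtron (sized exactly to a 60-nt intron), 3′UTR,
  intergenic, an antisense couple at identical coordinates, a tandem
  pair 10 kb apart, and a repeat-derived hairpin sharing a 30-nt block
  with a repeat consensus.
* **UTR alignments** diverge per-species copies of a reference by
  substitutions (8%) and deletions (2%), never inside planted 8mer
  sites; per-base scores are Beta-distributed (bounded in [0, 1] like
  real conservation scores) with mean 0.8 inside sites, 0.3 in the
  background, and a 10-nt linear decay between them.

What the simulations do *not* emulate — realistic error profiles,
indels, isomiR distributions, assembly artefacts, alignment error in the
MSAs, repeat families with internal structure — bounds what passing
tests show: they validate the algorithms against their own model
assumptions, not the pipeline's robustness to every pathology of real
data.

Problem sizes in the shipped tests and acceptance script (500 simulated
histories, 100 + 100 curation calibration loci, 1000 null z-test
replicates, 6-gene UTR sets, 50-shuffle null thresholds) are chosen so
the full suite completes in well under a minute of compute while keeping
the Monte-Carlo noise far from the asserted bounds; all scale up by
argument.

## Known limitations

* The Nussinov fallback maximises pairing, not stability; with it the
  structure filter is measurably more permissive on shuffled controls
  than with the thermodynamic engine (the calibration numbers are
  recomputed in `scripts/acceptance.R`).
* The greedy clusterer is exact but quadratic in the number of
  representatives; it is meant for curated miRNA sets (hundreds to
  thousands of loci), not genome-scale clustering.
* Synteny support takes the gene-homology map as input; inferring gene
  orthology is out of scope.
* The internal local aligner stands in for a full BLAST search at desk
  scale; precomputed outfmt6 hit tables are the scalable input path.
* Statistical sidedness and the presence threshold are defaults with
  arguments, not claims about any particular dataset.
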