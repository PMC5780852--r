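---
title: "Marker selection and tree inference: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Marker selection and tree inference: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(markertree)
```

## The problem

Genomes recovered from metagenomes (MAGs) are usually draft-quality and
frequently lack assembled 16S rRNA genes, so placing them taxonomically
requires protein markers instead. A *single-copy marker gene* for a genome
set is a gene family present exactly once in every genome; the concatenated
protein alignment of such families supports a well-resolved species tree,
and the single-copy requirement protects the analysis from hidden paralogy.
Because draft genomes are incomplete, no predefined marker set fits every
genome collection — the set has to be rediscovered for each one.
`markertree` automates that discovery from per-genome protein FASTA files
and precomputed profile-HMM annotations, then builds the concatenated
alignment and a bootstrapped tree.

## Pipeline model

The pipeline is a composition of six stages.

**1. Annotation.** Each genome's proteins carry hits against PFAM profile
HMMs, supplied as HMMER3 `--domtblout` tables. Hits with full-sequence
e-value above the cutoff (default `1e-10`, kept when exactly equal) are
discarded and each gene keeps only its best surviving hit, so a gene
contributes at most one profile. `markertree` ranks by full-sequence
e-value — HMMER's own primary sort — with ties broken by larger bit score,
then lexicographically smaller accession; the two tie levels make the
assignment a pure function of the hit set, independent of row order.
Version suffixes (`PF00012.20` → `PF00012`) are stripped so counts
aggregate across PFAM point releases. Running `hmmsearch` itself is out of
scope, as is gene prediction: nucleotide input is detected (≥ 95% of pooled
residues in `{A,C,G,T,N,U}`) and aborts with a pointer to a gene caller.

**2. Marker selection.** Assignments are tallied into a genome × profile
copy-number matrix; the markers are exactly the profiles with count 1 in
every genome. This is deliberately strict — a profile multi-copy in a
single genome, or missing from one, is discarded — which is what makes the
marker set shrink monotonically as genomes are added. An empty marker set
is a warning plus structured empty outputs (exit status 3 in the CLI), not
a crash, because distant genome sets can legitimately share nothing.
`evalue_sweep()` recomputes the whole chain from the raw hits at each
cutoff; that is the only self-consistent reading, since a cutoff change can
alter which gene wins a profile and hence every downstream count.

**3. Alignment.** Each marker family (one protein per genome) is aligned
with the built-in progressive aligner: a guide tree from 3-mer count cosine
distances clustered by UPGMA, then leaf-to-root profile–profile global
alignment (Needleman–Wunsch with affine gaps, BLOSUM62, gap open −11 /
extend −1 — the standard protein defaults). Column pair scores between
profiles are averaged over residue pairs so the gap penalties stay on the
single-sequence scale whatever the profile sizes; gap characters and
unknown residues (anything outside the 20-letter alphabet maps to X for
scoring, but is emitted unchanged) score 0 against everything. A gap run of
length *k* costs `open + k·extend`, end gaps included. Family members are
sorted by genome id before clustering, making the result independent of
input order. An external aligner (e.g. MUSCLE or MAFFT) can be substituted
per run via a `{input}`/`{output}` command template; its output is
validated against the alignment invariants (equal row lengths, rows de-gap
to their inputs). Per-marker alignments are concatenated in ascending
accession order — concatenation order is otherwise arbitrary, and fixing it
makes runs reproducible — with a partition map recording each marker's
1-based inclusive span.

**4. Trimming.** Highly variable or gapped columns are removed with a
conserved-block procedure in the Gblocks tradition, applied to the
concatenated alignment (the pipeline's stage order is align → concatenate →
trim → tree). Each column is classified from the count *f* of its most
frequent residue: *nonconserved* when *f* is below a strict majority
(`floor(n/2)+1`), *highly conserved* at `ceiling(0.85·n)`, *conserved*
between, and *gap* under the gap rule (default: any gap character rejects
the column). Blocks are then selected by (1) rejecting gap columns together
with the maximal nonconserved runs touching them, (2) rejecting surviving
nonconserved runs longer than 8, (3) shrinking each surviving segment to
its outermost highly-conserved columns, and (4) dropping segments shorter
than 10. All five parameters are exposed in `trim_config()`; exact parity
with the Gblocks binary is not claimed — the stated rules are the
contract, and an independently coded brute force of them is the test
oracle. `trim = "none"` bypasses the stage (useful for short toy
alignments, which rule 4 would otherwise annihilate).

**5. Tree.** Pairwise distances use the Kimura protein correction
`d = −ln(1 − p − 0.2p²)` of the mismatch fraction *p* over columns where
neither row has a gap or X. The correction becomes undefined as *p* grows;
when `1 − p − 0.2p² ≤ 0.05` the distance is capped at a fixed, documented
5.2 — finite so neighbor joining always runs. The tree is standard
Saitou–Nei neighbor joining (via `ape::nj`, with labels sorted first so
input order is irrelevant, and negative branch lengths clamped to zero
with the deficit recorded). Support values come from a true column
bootstrap: columns resampled with replacement, one tree per replicate, and
each internal edge of the point tree labelled with the rounded percentage
of completed replicates containing the same bipartition. Replicates in
which some pair loses all comparable columns are skipped and counted. The
default is 100 replicates, configurable to 1000 for final figures; 100
keeps desk-scale runs interactive while support estimates remain stable
(binomial SE ≤ 5 points). The ML alternative (FastTree and its SH-like
local supports) is reachable through the external command template; note
that SH-like supports and true bootstrap percentages are not the same
quantity. The output tree is unrooted; `midpoint_root = TRUE` midpoint
roots the written copy for display only.

**6. COG categorization.** PFAM profiles and COGs are joined through
shared GO terms in the `pfam2go`/`cog2go` external2go files: a PFAM maps
to every COG annotated with at least one common GO id. A marker counts
once toward each distinct one-letter category in the union of its mapped
COGs' categories — multi-category markers are counted in every category,
unweighted, so category totals can exceed the number of mapped markers.
Only a fraction of profiles can be mapped this way; unmapped markers are
reported separately rather than silently dropped. In typical bacterial
marker sets category J (translation and ribosome biogenesis) dominates,
reflecting how much of the universal single-copy core is ribosomal.

## The synthetic genome sets

`generate_fixture()` creates genome sets with fully known answers so every
stage — and the end-to-end topology claim — is testable without any
database download. A species tree is drawn by sequential random attachment
(each new leaf splits a uniformly chosen edge) with exponential branch
lengths rescaled so the expected root-to-leaf path equals `tree_depth`.
Every family evolves along it under the 20-state symmetric model: on a
branch of length *b* a site changes with probability
`(19/20)(1 − exp(−20b/19))`, uniformly to one of the other 19 residues.
This matrix composes exactly across branches, so the expected leaf-to-leaf
mismatch at path length *t* has the closed form
`(19/20)(1 − exp(−20t/19))` — which is what the simulator's Monte-Carlo
test checks. The model is deliberately simpler than JTT (it is closed-form
checkable); the pipeline's distance estimator remains the Kimura
correction, and topology recovery — not branch-length unbiasedness — is
the criterion.

The default configuration is 8 genomes, 10 marker families of 200
residues, 3 multi-copy families (an independently re-evolved duplicate
planted in 1–2 random genomes), 2 patchy families (deleted from 1–2
genomes), a strong true hit (e-value 1e-50) per gene, decoy cross-hits at
e-value 1e-3 on 10% of genes, two family-less decoy genes per genome, and
`tree_depth = 0.5` — the upper end of what the recovery property is
expected to tolerate. Everything is bit-reproducible from the seed.

What the fixtures do *not* emulate: indels (fixtures are gap-free, so
trimming is exercised by separately constructed gapped alignments), domain
architecture (one profile per gene), annotation noise beyond the planted
decoys, and real PFAM/COG releases (the shipped `synthetic_*` mapping
files are hand-written miniatures). Passing on fixtures therefore
demonstrates the pipeline's logic, not the biological adequacy of PFAM
annotation on any particular genome collection.

## Numerical choices and degenerate inputs

* Ties everywhere are resolved deterministically: best-hit ties by score
  then accession; alignment DP ties by a fixed state order; NJ label order
  by sorting; marker and concatenation order by ascending accession.
* The Kimura cap (5.2) and the negative-branch clamp keep the distance
  matrix finite and the tree drawable on saturated or tiny inputs.
* A pair with zero comparable columns is an error at the point estimate
  and a skipped-and-counted replicate inside the bootstrap.
* An alignment fully consumed by trimming is an error that names the two
  escape hatches (`trim_config()`, `trim = "none"`).
* Genes whose every hit fails the cutoff simply vanish from the
  annotation table; genomes that lose all genes still occupy an all-zero
  row of the copy-number matrix, correctly forcing an empty marker set.

## Validation problem sizes

The shipped tests and the acceptance script validate, per run: 200 random
copy-number matrices (≤ 20 × ≤ 500) against a brute-force marker oracle;
20 seeded fixtures (5–12 genomes, 60-residue families — marker recovery
does not depend on family length, so short families keep the check quick)
for exact planted-marker recovery; nested-subset monotonicity on 8-genome
fixtures; 100 random additive matrices (4–12 taxa) for NJ exactness
(RF 0, path-distance error < 1e-9); 10 end-to-end seeds at the default
configuration with 100 bootstraps each; 500 random column-class strings
against an independent brute force of the trimming rules; byte-identical
reruns; and 50 Newick write/parse round trips plus FASTA/domtblout
read-back identity.

## Known limitations

* At `tree_depth` near the 0.5 upper bound, end-to-end topology recovery
  is not certain: across seeds roughly 7–9 of 10 runs recover the true
  tree exactly (RF 0). Two failure modes both involve very short internal
  branches drawn from the exponential: (a) with ~2000 columns, a branch of
  ~0.01 substitutions/site can be swamped by sampling noise even under a
  perfect alignment; and (b) the Kimura correction is not the inverse of
  the simulation's substitution model, so transformed distances are
  slightly non-additive at high divergence and neighbor joining can
  mis-resolve a ~0.02 branch even from noise-free expected distances. At
  moderate depths (≤ 0.3) recovery is essentially certain. Real analyses
  with hundreds of markers sit far to the easy side of this regime, but
  very deep, sparsely sampled genome sets inherit the same caveat — as
  they would under any distance method.
* Neighbor joining over corrected distances replaces the ML step a
  practitioner might prefer for publication figures; the external command
  template exists precisely so FastTree (JTT) can produce the final tree
  while `markertree` still discovers the markers, builds and trims the
  alignment, and writes the partitions.
* The GO-join PFAM→COG mapping is intentionally shallow (no GO graph
  traversal); it under-maps relative to eggNOG-style orthology, matching
  its role as a descriptive summary rather than an annotation method.
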