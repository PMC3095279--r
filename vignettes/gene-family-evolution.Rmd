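---
title: "Methods: gene-family molecular evolution with famevol"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: gene-family molecular evolution with famevol}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famevol)
```

# Scope and model

`famevol` implements the analysis chain of a gene-family expansion study:
family identification, phylogeny, duplication-mechanism classification,
Ka/Ks estimation, molecular-clock dating, and motif-architecture
comparison. This vignette records the models, the tunable parameters with
their defaults and rationale, the numerical conventions, and what the
synthetic-data tests do and do not establish. It states no empirical result
that the test suite does not itself compute.

# Family identification

Membership is decided by the literal 8-residue regular expression
`H.K....D` (the HKD catalytic motif), not by a profile HMM: the membership
criterion in this workflow is *the presence of two HKD domains*, and
profile scanning is deliberately out of scope — domain calls (C2, PX, PH,
signal peptide) arrive as an input table from whatever annotation tool the
user trusts.

* `min_separation = 50` residues between the starts of two HKD hits. The
  two catalytic motifs of an active enzyme lie hundreds of residues apart;
  the threshold only prevents one degenerate region from being counted
  twice. No published value exists for this separation; 50 is our choice
  and is configurable.
* Pseudogenes: an in-frame stop codon before the final codon of the CDS
  (after trimming a trailing partial codon).
* Subfamily: C2 if a C2 domain is present; PXPH if PX and PH are both
  present; SP if a signal peptide is present and none of C2/PX/PH;
  otherwise unclassified. Conflicting annotation sets are resolved by the
  fixed precedence **C2 > PXPH > SP** with a warning — a deterministic rule
  for noisy inputs rather than a biological claim.

# Phylogeny

Distances are p-distances (proportion of differing sites) computed after
*complete deletion* — every alignment column containing a gap in any row is
removed. No model correction is applied; this matches the distance used in
the workflow this package systematizes, and for the closely related
sequences the pipeline targets, p-distance is monotone enough for NJ.

The NJ agglomeration is the standard Saitou–Nei Q-criterion algorithm with
two conventions the package commits to:

* **Tie-breaking.** When several pairs tie for the minimal Q (within
  1e-12), the pair whose subtrees contain the lexicographically smallest
  leaf ids is joined. This makes tree topology a pure function of the
  distance matrix.
* **Negative branches.** A negative NJ branch length is clamped to 0 and
  the deficit moved to its sister branch, preserving the path length
  between the two joined nodes — common NJ practice.

On additive matrices these conventions never fire and the tree's
leaf-to-leaf path lengths reproduce the input exactly (tested to 1e-9 on
random additive matrices).

Bootstrap resamples alignment columns with replacement to the original
length, rebuilds the tree per replicate, and scores each internal edge by
the percentage of replicates containing the same bipartition (branch
lengths and rooting ignored). Each replicate derives its seed
deterministically from the root seed and the replicate index, so raising
the replicate count leaves earlier replicates unchanged. A replicate whose
resampled alignment has no comparable sites is skipped and removed from
the denominator (rare; impossible unless gaps dominate).

Subgroup labels (the α, β/γ, δ, ε, ζ, φ style clade names) are propagated
from user-supplied anchor leaves: each unlabeled leaf takes the label of
the smallest enclosing clade whose anchors are unanimous; if the nearest
anchors disagree the leaf is left unclassified. Because the NJ tree is
unrooted, "clade" here means the subtree under the stored basal
trifurcation; conflicting-anchor cases are conservative by design. Merged
labels (such as a combined β/γ) are expressed by giving both anchor sets
the same label string.

# Duplication classification

Paralog pairs are same-species cherries (two-leaf sister clades) of the
family tree, optionally filtered by bootstrap support.

* **Tandem**: same chromosome and at most `max_intervening = 1` gene
  between the two copies in the gene order — "same or neighboring
  intergenic regions" read strictly. Gene order ranks genes by start
  coordinate; strand is ignored.
* **Segmental**: among the `window = 10` protein-coding genes upstream and
  downstream of each copy (family members excluded, flanks truncated at
  chromosome ends), at least `min_conserved = 1` one-to-one homologous
  pair. The smallest conserved-flank count accepted as segmental in
  published tables of this kind is 1, hence the default.
* Tandem takes precedence over segmental: physical adjacency is the
  stronger signal.
* The homology map is an *input*; the package does not decide what
  "conserved" means at the sequence level.

Flank conservation is counted as an exact maximum bipartite matching
(augmenting paths) between the two flank sets, with homology edges only.
A greedy scan would be order-dependent and could break the symmetry
`count(A,B) = count(B,A)` when one flank gene has several homologs; exact
matching is still one-to-one (a single promiscuous homolog contributes at
most 1), is symmetric, and is monotone in the window size. Flank sets have
at most 20 genes, so exact matching costs nothing.

# Ka/Ks (Nei–Gojobori 1986)

Each codon position contributes a synonymous-site fraction equal to the
number of its three single-base mutations that preserve the amino acid,
divided by the number that do not create a stop codon (mutations to stops
are excluded from the denominator — the dominant convention among NG86
implementations). `S` and `N` are averaged over the two sequences. Codon
pairs differing at 2–3 positions are scored by equal-weight averaging over
all substitution orderings that avoid stop intermediates; if every
ordering is blocked (not reachable for sense codons under the standard
code), all orderings are used as a fallback. Proportions `pS = Sd/S`,
`pN = Nd/N` are corrected with Jukes–Cantor, `d = -(3/4)ln(1 - 4p/3)`.

Numerical conventions:

* `p >= 3/4` is saturation: the corresponding distance is reported as
  `NA`, never extrapolated.
* `Ka = Ks = 0` gives ω = `NA` (undefined, not 1); `Ks = 0 < Ka` gives
  ω = `Inf`.
* Only the standard genetic code is supported.

The published analyses this package generalizes used a closed-source
estimator for Ka/Ks; `famevol` standardizes on NG86 + Jukes–Cantor — the
classical method in that tool's repertoire — because it is exactly
specifiable and testable against brute-force enumeration (all 61 sense
codons, and pathway enumeration for arbitrary codon pairs, in the test
suite). Numerical agreement with any particular published Ks value is
therefore not claimed; the *dating arithmetic* downstream is tested
against printed (Ks, date) pairs directly.

**Sliding windows** are laid out on nucleotide coordinates exactly as
printed ("300 bp window, 50 bp step"): offsets 0, 50, 100, … while a full
window fits, giving `floor((L - window)/step) + 1` windows. Whether such
windows should snap to codon boundaries is not specified anywhere we know
of; the package's declared convention is to keep the printed nt
coordinates and drop codons only partially covered by a window from that
window's score. A window covering the whole alignment reproduces the
global estimate exactly.

**Mean Ks for dating** discards values above 2.0 (saturation cutoff)
before averaging; an empty set after filtering yields `NA`.

# Dating

`T = Ks / (2λ)` with per-species clock rates λ (substitutions per
synonymous site per year): Arabidopsis 1.5e-8, rice 6.5e-9, poplar 9.1e-9,
grape 6.5e-9, shipped as defaults and overridable. Ages are reported in Ma
(1e6 years) rounded **half-up** to 2 decimals — matching the precision of
published tables, and distinct from R's banker's rounding — while raw
values are kept for downstream math. A mean Ks above 2.0 is dated with a
warning rather than refused.

One documented quirk of the source material for the shipped example table:
its running text attributes 25.09 Ma to grape and 88.39 Ma to Arabidopsis,
while the table itself and the `T = Ks/2λ` arithmetic give
0.7527 → 25.09 Ma with the Arabidopsis rate and 1.1491 → 88.39 Ma with the
grape rate. The package follows the table and the formula; we flag the
textual inconsistency here without guessing intent.

# Motif architecture

Motif *discovery* (MEME-style) is replaced by scanning user-supplied
regular expressions — discovery is a well-served external task, scanning
is the reusable computation. Matches are non-overlapping, leftmost-first.
Hits are partitioned relative to the two HKD domains: N-terminal (hit ends
before HKD1), middle (hit overlaps the span from HKD1 start to HKD2 end),
C-terminal (hit starts after HKD2). A motif is "shared" between two
subfamilies when its within-group prevalence reaches 0.5 in both; the
lenient default reflects that individual members are known to lose single
motifs without the motif ceasing to be characteristic of the subfamily.
Per-clade motif *counts* from de novo discovery on real data are not
reproducible from regexes alone and are not targets of this package.

# Synthetic data: the stated world

`simulate_genome()` states its world once, in `sim_config()` defaults
chosen to mirror the magnitudes of the motivating study:

* 5 segmental pairs and 1 tandem pair (the counts reported for the poplar
  and grape family, respectively), 4 singleton members, 2 single-HKD
  decoys, 1 premature-stop pseudogene.
* `flank_retention = 0.35`: each of the 20 flanking genes of a segmental
  pair keeps its homolog independently with this probability, giving
  conserved-flank counts with mean 7 — inside the published range 1–12.
* `target_ks = 0.25`, `omega = 0.2`: recent duplicates under purifying
  selection, matching the 0.206–0.251 mean-Ks range of the recent
  duplications in the motivating data.
* 300-codon family genes, 200-codon flank genes, 4 chromosomes × 70
  background genes (large enough that three insertion slots per chromosome
  have non-overlapping 10-gene flanks).

Sequence evolution is event-count based: per lineage, Poisson numbers of
synonymous and nonsynonymous events with expectations `S·Ks/2` and
`N·ω·Ks/2` (NG86 site counts of the ancestor), applied one at a time by
sampling a codon in proportion to its current number of legal single-base
changes of the required class; stops are never created, and planted motif
residues (the H/K/D anchors and the `IYIENQFF` core) are frozen against
nonsynonymous change — which is exactly the biological constraint the
motifs represent. This design matches the estimator's site definitions,
making recovery targets sharp; it does not emulate transition/transversion
bias, codon-usage bias, indels, or rate heterogeneity. Family backbones
exclude histidine outside planted motifs so decoys carry exactly one HKD
by construction.

Consequences for interpreting green tests: membership recovery, mechanism
recovery and the 10%-level Ks recovery are statements about this stated
world (no alignment error, one-to-one homology, clock-like evolution). On
real data, alignment quality, annotation errors and homology-calling
thresholds dominate — the package externalizes all three as inputs.
Flanking-Ks dating of a single pair uses as few as one 200-codon flank
gene, so individual dates scatter around `Ks_true/(2λ)` with a relative
error that can reach ~20%; the end-to-end test asserts 30% per pair.

# Known limitations

* p-distance NJ only; no model-corrected distances, ML or Bayesian trees.
* NG86 only; no YN00/ML codon models, no transition/transversion
  weighting.
* Strict clock, point estimates only; no confidence intervals on dates.
* Homology, domain calls, alignments and motif regexes are inputs, not
  inferences.
* Transposition-mediated duplication is not detectable from gene order
  and is reported as "undetermined".
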