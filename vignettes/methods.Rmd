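---
title: "Detecting additional ITSs in rRNA operons: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting additional ITSs in rRNA operons}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# The problem

In euglenids and kinetoplastids the mature large-subunit rRNA is not one
molecule: extra internal transcribed spacers (additional ITSs) inside the
28S gene are excised during maturation, leaving the 28S in up to 13
associated fragments. Detecting these spacers from genome assemblies is a
structure problem, not a sequence problem: ITSs have no conserved sequence
or fold, so the only reliable signal is a *length anomaly in a divergent
region between conserved helices* of the rRNA secondary structure. This
package implements that reasoning end to end: recover the operon from an
assembly, anchor it to the conserved structure, flag anomalous inter-helix
expansions, classify them, and ask whether the resulting fragmentation
pattern can descend from a single ancestral gain.

# Operon recovery

Candidate contigs are located with an internal seed-and-extend local
search rather than an external aligner call, so the pipeline is
self-contained and the filtering thresholds — the actual method — are
applied to reproducible scores. Exact `seed_k = 12`-mer matches are
clustered by subject position; clusters split on subject gaps > 600 nt,
diagonal jumps > 700 nt, or backward query jumps (a true homology on the
strand under test advances through the query; reverse-strand artifacts of
self-complementary helices walk it backwards, and tandem copies restart
it). Each cluster window is resolved by an exact affine-gap local DP
(match +1, mismatch −2, gap open −5, extend −2; a length-*g* gap costs
`gap_open + (g-1)*gap_extend`), banded around the seeded diagonals with
±200 nt slack for indel drift. Masked re-search rounds give every seeded
repeat its own hit. The DP within the seeded window dominates an x-drop
extension in sensitivity; the `xdrop` knob in `scoring_params()` is
reserved for a future streaming extension and currently unused.

E-values use the ungapped Karlin–Altschul statistic `E = K m n exp(-λS)`
under uniform base composition. λ solves `Σ p_i p_j exp(λ s_ij) = 1` by
root finding and K follows the classical lattice computation (convolved
score distributions); both are recomputed whenever the scores change, and
for +1/−2 they reproduce the published ungapped BLASTN constants
(λ = 1.3327, K = 0.621). Gapped corrections are deliberately out of scope:
at the `E < 1e-5` gate the strong rDNA hits in play are orders of magnitude
below threshold either way.

The coverage gate keeps a contig only if its depth exceeds
`cov_factor = 5` times the genome average. "Average" defaults to the
**length-weighted median** of per-contig depths: on a small assembly the
deep multi-copy rDNA contigs themselves would inflate a mean and make a
5×-above-average rule self-defeating; the median is immune as long as rDNA
is a minority of assembled length. Length-weighted and unweighted means are
selectable for strict parity with coverage definitions used elsewhere.

Strand is chosen per contig by majority hit score; minus-strand contigs
are annotated in reverse-complement space and intervals flipped back, which
makes the strand-involution property (`annotate(revcomp(x))` equals
`annotate(x)` with intervals mirrored) hold by construction and testable.
Segment layouts incompatible with one strand raise a structured
"inconsistent layout" error — the automated stand-in for manual misassembly
screening. ITS1/ITS2 are inferred as the gaps between mapped rRNA segments,
never aligned directly (they are too divergent to map by homology).

# Anchors, regions, and the expansion rule

The helix map lists anchors (conserved helices, yeast-style numbering) as
template intervals; `project_anchors()` converts each anchor to alignment
columns through the template row's gap pattern and then to every row's
unaligned coordinates. An anchor fully gapped in a row is ABSENT and
bridged — real LSUs do lose helices — with the skip recorded. Per row,
anchor lengths plus inter-anchor region lengths must sum to the sequence
length; this conservation identity is enforced in tests.

A focal species is flagged in a region iff

    length > exp_factor * stat(background lengths)   AND
    length - stat >= min_abs

with `exp_factor = 4`, `stat = median`, `min_abs = 30` nt. Choices:

* **4×** is the method's headline fold-change for calling a divergent-region
  expansion a candidate ITS.
* **median** background is robust when another lineage independently
  carries an ITS at the same site (shared sites exist); `max` mode gives
  the strictest reading of "longer than in other species".
* **`min_abs` = 30 nt** guards the scale-free 4× rule where the background
  is a few nt (any insertion would otherwise trivially exceed 4×). The
  degenerate all-zero background is decided entirely by this guard.
* **Virtual terminus regions are excluded by default**
  (`include_termini = FALSE`): an internal spacer must be flanked by
  structure on both sides, whereas beyond the outermost mapped helix the
  molecule simply ends — length variation there is end heterogeneity, and
  an ancestral deletion of a terminal stub in part of the taxa would
  otherwise masquerade as an "expansion" in the rest.
* The focal/background sets are explicit parameters (default: each species
  against all others), since the comparison set is a genuine modelling
  choice.

Classification is total and ordered: registry site → `known_ITS`; else SSU
domain → `ssu_expansion` (SSU expansions are retained in the mature 18S
and are never ITSs); else 5.8S/LSU → `novel_candidate`; spacer-domain
variation is tagged `spacer_variation` and never counted. Fragment
arithmetic is then `fragments = 28S-domain ITS calls + 1`.

ORF screening reads "longer than 20 amino acids" strictly (≥ 21 aa
reported), requires an ATG initiator and runs to the in-frame stop (or the
sequence end, flagged partial); an alternative stop-to-stop mode exists
because ORF conventions differ. Cross-ITS homology is all-vs-all best
local alignment; a pair is *reported* homologous at identity ≥ 0.7 over
≥ 50 aligned columns — a report threshold, not a classification input,
because short perfect micro-matches between random sequences reach
identity 1.0 trivially. Folding is base-pair maximization (Watson–Crick +
GU, minimum loop 3, deterministic traceback preferring the unpaired branch
and then the smallest partner) — a sanity annotation for helix anchors,
not a thermodynamic model.

# Cross-lineage comparison

Shared sites are registry entries of different lineages with the same
flanking-anchor pair; a column-window tolerance mode exists for
registry-free comparisons. The parsimony layer treats a site (or the
pooled "any 28S ITS present" character) as binary on a supplied tree:
`min_state_changes()` is Fitch counting generalized to polytomies
(Hartigan's majority-vote sets, cost = children − max votes), invariant
under re-rooting; `gain_scenarios()` adds the two constrained readings —
minimum gains with loss forbidden (number of maximal all-present clades)
and minimum losses under a single gain at the MRCA of carriers. Equal
gain/loss costs are the default because the claim being tested is
qualitative; `gains_no_loss >= 2` on every candidate topology is the
machine-checkable statement that the character cannot be traced to the
common ancestor. The package takes the tree as input and the analysis
scripts run both candidate resolutions of the deep euglenozoan branching,
because that branching is unresolved.

# What the generator simulates (and what it does not)

`sim_config()` defaults encode the study conditions: a 2000/300/160/400/
3500 nt SSU/ITS1/5.8S/ITS2/LSU operon; compact hairpin core anchors
(12 nt strands, 12 nt loops) dense enough that inter-helix divergent
regions are ~40 nt, as in real rRNA where helices tile the molecule; an
8-taxon tree (outgroup, two diplonemids, two euglenids, a
prokinetoplastid, two metakinetoplastids) with pairwise divergence kept
under ~0.2 substitutions/site; Jukes–Cantor substitutions with per-class
rate multipliers core 0.1 / ES 2.0 / spacer 3.0; geometric indels (mean
8 nt, rate 0.01 events per eligible site per unit branch length) confined
to ES/spacer classes so anchors survive; five planted LSU sites per
ITS-bearing lineage, three shared, insert lengths 200–500 nt of uniform
random composition (planted ITSs deliberately have no structure); and an
assembly model with rDNA at 20× baseline depth among random decoy contigs
whose total length dominates the assembly, as rDNA is a small fraction of
any real genome. Alternate rDNA contigs are emitted reverse-complemented
to exercise strand handling. Everything is a deterministic function of the
seed; bundles are byte-identical under the same config.

What it does **not** emulate: sequencing error and read-level artifacts
(the pipeline consumes assembled contigs by design), alignment error (the
true MSA is emitted, so detection is tested separately from alignment
quality; a re-alignment hook exists for integration runs), long-range
helix pairings (anchors are compact hairpins), rate heterogeneity beyond
the three classes, base-compositional bias, and the nonconventional
introns of real diplonemid genomes. Passing on these bundles therefore
demonstrates the detection logic, not robustness to a poor input
alignment — on real data the structure-aware MSA is the user's
responsibility, exactly as it is manual curation in practice.

# Numerical and interface conventions

* Internal coordinates are 1-based inclusive throughout (the native
  GFF3/IRanges convention); the helix-map and segment TSV formats are
  0-based half-open on disk and are converted at the single read/write
  point, with a round-trip test pinning the conversion.
* RNA `U` is normalized to `T` on input; folding treats T as U. Ambiguity
  codes beyond `N` are rejected loudly: the assemblies in scope are
  unambiguous consensus sequences, and silent remapping would corrupt
  identity statistics.
* Hit ordering is deterministic: E-value ascending, then score descending,
  then subject/query id; GFF3 output orders by (contig, start); every
  report is byte-stable across reruns.
* The curated site registry shipped in `inst/extdata/` encodes the
  published eITS1–13/kITS1–7 inventory, the three shared pairs, and the
  domain split (12 euglenid and 5 kinetoplastid sites interrupt the 28S;
  eITS1 and kITS1–2 flank the 5.8S, which reconciles the site numbering
  with the per-lineage 28S counts). Its flanking-anchor pairs are
  *schematic stand-ins* labelled as such — the file is curation, not
  computation, and real helix coordinates can be substituted without
  touching code.
* Problem sizes in the tests and the acceptance script — 20 + 20 bundles
  of the default 8-taxon configuration, 1000 sequences for the ORF oracle,
  200 trees for the parsimony oracle, structures to length 20 for the
  folding oracle, 100 pairs for the alignment oracle — were chosen as the
  smallest sets at which the stochastic checks are decisive.

# Known limitations

* E-values are ungapped-regime approximations; they are used as a filter
  at 10⁻⁵, not as reported statistics.
* Segment boundaries on diverged contigs are homology-approximate: local
  alignment ends where similarity fades, so annotated rRNA ends can be
  off by tens of nt. ITS calls do not depend on them (they come from the
  anchor projection).
* `novel_candidate` calls inherit every weakness of the input MSA; a
  misaligned helix produces phantom expansions. The projection
  monotonicity check catches gross distortions only.
* Polytomies are handled in parsimony but branch lengths are ignored
  there; no likelihood-based ancestral reconstruction is attempted.
* The external-tool adapters (tabular hit import, external fold engines)
  are interface-tested only; no external database search is reimplemented.
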