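---
title: "Annotating insect neuropeptide precursors with npmine"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Annotating insect neuropeptide precursors with npmine}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(npmine)
```

## The problem

Insect neuropeptides are short signalling peptides released from larger
precursor proteins (prohormones). A precursor carries an N-terminal signal
peptide, one or more bioactive mature peptides, and acidic spacer segments;
the mature peptides are excised at mono- or dibasic prohormone-convertase
sites, trimmed by carboxypeptidase, and often modified further — a
C-terminal glycine is converted into an amide, and an N-terminal glutamine
can cyclise to pyroglutamate. Because these rules are largely sequence-
local, a neuropeptidome can be predicted *in silico* from proteomes or
translated transcriptome assemblies, which is how parasitoid-wasp
neuropeptidomes have been catalogued. `npmine` packages that workflow as
tested, offline-runnable code: homology scanning, signal-peptide and
cleavage-site prediction, mature-peptide excision with PTM annotation,
family classification by C-terminal consensus motifs, conservation shading
and sequence-logo statistics, and distance-based phylogenies with
bootstrap supports.

## The processing model

### Signal peptides

`predict_signal_peptide()` is a transparent two-component score, not a
neural network. For every candidate signal length $c \in [10, 45]$ it
computes

$$\mathrm{score}(c) = w_h\,h(c) + w_c\,b(c) - \text{penalties},$$

where $h(c)$ is the mean Kyte–Doolittle hydropathy of the best window
(default 8 residues) whose end lies 4–7 residues before the cut — the
hydrophobic core must abut the cleavage region, which prevents downstream
candidates from re-using the same core — rescaled from $[-4.5, 4.5]$ to
$[0,1]$; and $b(c)$ is the (−3,−1) rule: 0.5 for a small neutral residue
(A/G/S/C/T/V) at −1 and 0.5 at −3. A proline at −1/+1 costs 0.3 and each
charged residue (D/E/K/R) inside the hydrophobic window costs 0.1. Defaults
$w_h = 0.6$, $w_c = 0.4$, threshold 0.45; all are config-surfaced. The
first candidate attaining the maximum wins, so ties resolve toward the
most N-terminal position. External predictions (e.g. from a dedicated
tool) can be injected per record with
`load_external_signal_annotations()` and always override the heuristic.

Because candidates stop at 45 and the window is bounded, appending
residues after position 60 can never change a prediction — a property the
test suite asserts.

### Cleavage rules

`find_cleavage_sites()` applies a tiered codification of the classical
mono-/dibasic conventions for insect prohormones:

| tier   | condition                                  | confidence |
|--------|--------------------------------------------|-----------|
| `KR`   | always cleave after the R                  | high      |
| `RR`   | cleave unless an exclusion fires           | medium    |
| `KK`, `RK` | basic residue required at −3/−5/−7     | low       |
| mono-`R`   | basic residue required at −3/−5/−7     | medium    |

Exclusions (all tiers except `KR`): proline at P1′ or within the two
residues N-terminal of the cut, or a cysteine within three residues of the
site. Mono-K never cleaves. Runs of consecutive basic residues (e.g.
`KRR`) resolve to the rightmost admissible site, so each run yields one
cut. The whole table ships as editable YAML
(`inst/extdata/cleavage_rules.yaml`) because every downstream count
depends on it. The engine is validated against an independent brute-force
evaluator over all strings of length ≤ 6 on the adversarial alphabet
{A,K,R,P,C} plus thousands of seeded longer strings — the enumeration is
capped there because the full space of length-12 strings is ~$3\times10^8$.

A known consequence of the −3/−5/−7 mono-R rule: mature regions that
themselves contain regularly spaced arginines (the sNPF RSPSL-RLRFamide
motif is the canonical example) carry internally admissible sites that
published peptide calls treat as silent. The manual-curation step of the
original workflow is exactly what suppressed those; `npmine` reports what
the rules imply and leaves suppression to rule-file overrides.

### Excision and PTM annotation

`excise_peptides()` cuts the propeptide at the called sites, trims the
trailing K/R run of each fragment (carboxypeptidase step; all trailing
basics are removed, matching published mature peptides, none of which end
in K/R), converts a terminal glycine into an amide flag, flags N-terminal
glutamine as pyroglutamate (glutamate is never cyclised here, following
the published convention), and tags fragments shorter than 4 residues or
with a D/E fraction above 50% as spacers. Coordinates are 0-based
half-open internally and 1-based inclusive in reports.
`cysteine_census()` reports cysteine positions counted from the C-terminus
(final residue = −1), pairing even counts into `n/2` putative disulfides
and flagging odd counts without assigning topology.

### Family classification

`classify_by_motif()` matches peptides against a YAML registry of ~33
family motifs — terminal consensus patterns plus amidation/pyroglutamate
expectations and cysteine minimums (e.g. `...F-G-L/I-amide` for
allatostatin A, `...RSPSL/Y-RLRF-amide` for sNPF, `...WFGPRL-amide` for
tryptopyrokinin, `CRGxxx` with two cysteines for elevenin). Among matching
motifs the one with the most constrained positions wins; ties break
alphabetically. On the bundled three-species table of published peptides
the registry assigns 98.7%; the two documented misses are one divergent
NPLP1 paracopy (`PSYTLGRLFVIPVATa`) and one PVK paracopy with a
pyrokinin-like PRLamide ending (`SSQGQLTLGGYTPRLa`) — both families whose
paracopies are heterogeneous by nature.

`homology_scan()` is the offline stand-in for translated-database BLAST
mining: targets are scored against a labelled query set by in-package
Smith–Waterman (affine gaps, BLOSUM62) and inherit the family of the best
query when the score reaches a self-score ratio (default 0.25, reported
per hit so users can re-screen, mirroring the "checked manually" step).
Nucleotide inputs are translated once through all six frames
(`six_frame_translate()`, standard code by default, table id
configurable) and then scanned as proteins — equivalent coverage with a
simpler core. E-value statistics and seeded word heuristics are out of
scope.

### Comparative statistics

`global_align()` is Needleman–Wunsch with affine gaps, defaulting to the
ClustalX slow-accurate parameters (gap opening 10, extension 0.1). The
substitution matrix is a parameter: BLOSUM62 by default with PAM250
bundled as the classic alternative; the Gonnet series is not shipped
because no trustworthy offline source of its entries is available, and
identity-level conclusions on near-identical neuropeptides are
matrix-insensitive. A gap of length $L$ costs $\text{open} +
\text{extend}\times L$ in every aligner here. `progressive_align()` uses
the center-star strategy with "once a gap, always a gap" merging and a
deterministic merge order, so input order cannot change the columns.
Short homologous paracopies are aligned gaplessly by C-terminal anchoring
(`cterm_anchor_align()`), mirroring how terminal consensus motifs are
aligned manually in the literature; the progressive aligner is reserved
for full precursors.

`percent_identity()` offers both denominator conventions
(`ungapped_columns` default, `all_columns` available) because published
identity scores rarely state which their tool used.
`conservation_shading()` reproduces the dark (100%) / grey (≥ 80%)
figure convention. `sequence_logo()` computes per-column information
$R_i = \log_2 20 - (H_i + e_n)$ with the small-sample correction
$e_n = 19/(2 n \ln 2)$; gaps are excluded from the counts and negative
corrected values clamp to zero.

### Phylogenetics

`p_distance()` (pairwise deletion; Poisson correction by flag) feeds
`nj_tree()`, a from-scratch Saitou–Nei implementation: join the pair
minimising $Q(i,j) = (n-2)\,d(i,j) - S_i - S_j$, two-point branch
lengths, negative estimates clamped to zero with the deficit shifted to
the sister branch (the convention distance packages use), and Q-ties
broken by the lexicographically smallest taxon pair so output is
deterministic. `bootstrap_support()` resamples columns with replacement,
rebuilds NJ per replicate and reports the percentage of replicates
containing each internal bipartition of the full-data tree; all supports
are retained in the tree (display layers conventionally hide values
below 50, which is a rendering rule, not data filtering). p-distance was
chosen as the default model because the original analysis does not name
one; on the near-identical precursors this workflow targets the choice is
immaterial. Trees serialise as Newick through `ape`.

## The synthetic study

`synthetic_config()` + `generate_study()` produce precursor sets with
known ground truth so every stage is testable without downloads. A
synthetic precursor is: signal peptide (Met + short polar n-region +
hydrophobic core of L/I/F/M + small residues at −3/−1), then per paracopy
an acidic spacer (> 50% D/E by construction, so the spacer filter always
recognises it) closed by `KR`, the mature peptide, an amide-donor G where
the family is amidated, and a cleavage signal drawn from
KR 70% / RR 15% / mono-R 10% / KK 5% — percentages chosen once to
exercise every rule tier. Seven default family templates (CCAP, AKH, a
long FMRFamide, tachykinin with five paracopies, myosuppressin, kinin,
AST-CCC) were selected because their mature regions are *cleavage-clean*:
embedded between their flanks they contain no internally admissible sites
under the rule table (checked by hand; sNPF-like motifs fail this and are
deliberately absent). Each template's allowed signal classes follow from
the table itself — e.g. CCAP admits only `KR` because its C-terminal
cysteine triggers the cysteine exclusion for every other tier, and the
mono-R signals of FMRFa/myosuppressin rely on the arginine inside the
mature peptide as the −3 upstream basic.

Evolution along the species tree substitutes each non-frozen site with
probability $1 - e^{-\text{rate}\times\text{branch length}}$, uniformly
over a 16-residue alphabet that excludes K/R/C/P — substitutions can
destroy true cleavage signals (the realistic failure mode the recovery
thresholds budget for) but never fabricate new ones, and consensus-motif
positions are frozen. There is no indel process, so alignment columns
stay homologous by construction and truth coordinates remain valid. The
default species tree is three shallow cherries
(`((s1:0.1,s2:0.1):0.08,(s3:0.1,s4:0.1):0.08,(s5:0.1,s6:0.1):0.08)`),
reflecting the high precursor conservation among closely related taxa
that motivates this kind of mining in the first place.

What the generator does **not** emulate: matrix-structured substitution
preferences, indels, alternative splicing, partial 5′ contigs, assembly
errors, and convertase-context effects beyond the rule table. Passing the
recovery gates therefore demonstrates internal consistency of the
pipeline under its own assumptions, not field performance on raw TSA
data.

## Problem sizes and gates used by the test suite

- rate 0, default families, 6 species: 78 truth peptides — recovery and
  flag correctness must be 100%.
- rate 0.02 (seed-pinned): recovery ≥ 95%, family accuracy ≥ 95%.
- 200 fresh precursors: signal cleavage within ±2 residues for ≥ 90%.
- cleavage engine ≡ brute force: exhaustive ≤ 6 over {A,K,R,P,C} + 3000
  seeded strings of length 7–12.
- aligners ≡ exhaustive enumeration on all pairs of length ≤ 3 strings
  over {A,C,D}, plus score agreement with an independent aligner
  (`Biostrings::pairwiseAlignment`) on random longer pairs.
- NJ recovers 50/50 random additive matrices (n ≤ 8) and the generator's
  6-taxon tree at rate 0.05 with 4 precursors per family (~2 000
  concatenated sites, enough for every internal edge to accumulate
  substitutions).
- bootstrap supports reproducible at a fixed seed; 100% on a perfectly
  supported split; 100 vs 1000 replicates agree within 5 points for
  clades ≥ 90%.

## A worked example

```{r example}
cfg <- synthetic_config(seed = 42, substitution_rate = 0)
sim <- generate_study(cfg)
p <- sim$species$s1[[2]]          # the synthetic AKH precursor of species s1
p$record$residues
ann <- annotate_precursor(p$record, species = "s1")
ann$signal$cleavage_index
ann$peptides[, c("sequence", "start", "end", "amidated", "pyroglutamate",
                 "family")]
format_peptide_notation(ann$peptides$sequence[1],
                        ann$peptides$amidated[1],
                        ann$peptides$pyroglutamate[1])
```

## Known limitations

- The signal heuristic approximates, and will not reproduce, the scores
  of neural-network predictors; the override file is the bridge for
  production use.
- The mono-R tier over-predicts inside arginine-rich mature regions (see
  above); curation happens through the rule YAML, not hard-coded
  exceptions.
- Disulfide connectivity, furin-type RXXR processing, intermolecular
  bridges (bursicon heterodimers) and mass-spectrometric validation are
  out of scope.
- The motif registry is a transcription of published consensus
  statements plus the regularities of the bundled three-species table;
  heterogeneous families (NPLP1, and the PRXamide complex) retain
  documented misclassifications.
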