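# npmine — neuropeptide precursor mining and annotation

`npmine` predicts and annotates insect neuropeptide precursors
(prohormones) from protein or transcript sequences, the workflow used to
catalogue parasitoid-wasp neuropeptidomes from public sequence databases.
It is aimed at researchers who want that pipeline as reproducible,
offline-runnable code: every stage is an ordinary R function with tests,
and a synthetic precursor generator with ground truth makes the whole
chain verifiable end to end.

A precursor is modelled as

```
signal peptide | spacer K R | peptide (G) K R | spacer ... | spacer
```

and the pipeline recovers the parts:

1. **Signal peptide** — a transparent heuristic scoring each candidate
   cleavage position `c ∈ [10, 45]` as
   `0.6·h(c) + 0.4·b(c) − penalties`, where `h` is rescaled
   Kyte–Doolittle hydropathy of the best core window abutting the
   cleavage region and `b` is the (−3,−1) small-residue rule; external
   predictions can override per record.
2. **Cleavage sites** — a tiered mono-/dibasic rule table (`KR` always;
   `RR` unless excluded; `KK`/`RK`/mono-`R` only with a basic residue at
   −3/−5/−7; proline and cysteine exclusions; rightmost site per basic
   run), fully overridable from YAML.
3. **Mature peptides** — excision, trailing K/R trimming, amide-donor G
   removal (`...a` notation), N-terminal Q → pyroglutamate (`pQ...`),
   cysteine census from the C-terminus, spacer filtering.
4. **Family assignment** — C-terminal consensus motifs for ~33 families
   (FGL/I-amide allatostatins, RSPSL/Y-RLRF-amide sNPF, FxPRL-amide
   pyrokinins, ...) plus Smith–Waterman homology against a labelled
   query set with a self-score-ratio threshold.
5. **Comparative analysis** — Needleman–Wunsch with ClustalX-style
   parameters (gap open 10, extend 0.1), percent identity under both
   denominator conventions, dark/grey conservation shading, sequence-logo
   information `R_i = log2(20) − (H_i + e_n)`.
6. **Phylogenies** — p-distance (pairwise deletion), Saitou–Nei
   neighbor joining with deterministic tie-breaking, column-bootstrap
   supports, Newick I/O.

## A worked example

```r
library(npmine)

cfg <- synthetic_config(seed = 42, substitution_rate = 0)
sim <- generate_study(cfg)
p <- sim$species$s1[[2]]          # synthetic AKH-family precursor
p$record$residues
#> [1] "MTSNLIFIIIMLLAQAEDSDAKRQLNFSTGWGKRSNEED"

ann <- annotate_precursor(p$record, species = "s1")
ann$signal$cleavage_index         # predicted signal length
#> [1] 16
ann$peptides[, c("sequence", "amidated", "pyroglutamate", "family")]
#>   sequence amidated pyroglutamate family
#> 1 QLNFSTGW     TRUE          TRUE    AKH
format_peptide_notation("QLNFSTGW", amidated = TRUE, pyroglutamate = TRUE)
#> [1] "pQLNFSTGWa"
```

The precursor is cut after the two `KR` signals, the trailing basics and
the amide-donor glycine are removed, the N-terminal glutamine is marked
as pyroglutamate, and the peptide's `STGW`-amide ending classifies it as
an adipokinetic hormone — printed `pQLNFSTGWa` in the standard shorthand
(trailing `a` = amide, leading `pQ` = pyroglutamate).

The bundled table of published mature peptides from three wasp species
(`published_peptides()`) reproduces textbook observations directly, e.g.
the crustacean cardioactive peptide is invariant across species:

```r
tab <- published_peptides()
ccap <- tab$sequence[tab$family == "CCAP"]
percent_identity(global_align(ccap[1], ccap[2]))
#> [1] 100
```

`run_pipeline()` chains everything from a YAML config (inputs, query
set, thresholds) and writes annotation reports, per-family logo/shading
tables, NJ trees and presence/paracopy matrices plus a checksummed
`MANIFEST.tsv`; `inst/scripts/npannotate` is a thin command-line wrapper
with `annotate`, `fixtures`, `tree` and `classify` subcommands.

## Layout

- `R/` — seqio, signal, cleavage, classify, comparative, phylo,
  synthetic, pipeline modules; `src/` — Rcpp affine-gap alignment core
- `inst/extdata/` — family motif registry (YAML), cleavage rule table
  (YAML), published three-species peptide table (TSV)
- `vignettes/neuropeptide-annotation.Rmd` — the model, its assumptions,
  parameter choices and limitations
- `tests/testthat/` — unit, property (brute-force/enumeration oracles)
  and acceptance tests
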