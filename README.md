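# cascadesign

Rational design of antibody-like binders against linear epitopes of
amyloidogenic proteins, in R.

Aggregation of peptides such as the 37-residue islet amyloid polypeptide
(IAPP) proceeds through intermolecular β-sheet contacts. A practical way
to interfere is a *complementary peptide*: a short sequence that pairs in
β-strand geometry with a chosen linear epitope of the target, grafted
into the binding loop of a small scaffold — a single-domain antibody
(sdAb) or a fibronectin type-III monobody — to make an expressible,
conjugatable reagent. `cascadesign` implements the full computational
side of that workflow for structural biologists and protein engineers:

* **Fragment mining** — detect backbone hydrogen bonds with the DSSP
  electrostatic criterion
  (`E = 0.084·332·(1/r_ON + 1/r_CH − 1/r_OH − 1/r_CN)` kcal/mol, bond if
  `E < −0.5`), find β-strand pairings as hydrogen-bond ladders, and index
  every paired sub-window in a queryable fragment library.
* **Cascade assembly** — link overlapping library fragments into
  full-length complementary peptides (paratopes) for an epitope, ranked
  by the complementarity score `C = mean(log10(1 + n_i))` over
  per-position support counts, then by a smoothed
  hydropathy/charge solubility score.
* **Epitope scanning** — tile a target (the mature human IAPP sequence
  ships as a fixture, with its disulfide-bonded N-terminus masked) with
  explicit or auto-enumerated 7–9-residue windows and keep the best
  design per window, plus a small-side-chain negative control
  (`SGAAAGSGS`).
* **Scaffold grafting** — apply cysteine-substitution schemes
  (`C23AC97A`/`C23AC97V`), N-terminal truncations (`N-4-`, `N-8-`), loop
  replacements and paratope grafts (core, or the full designed loop
  `GS<paratope>EEE`) to configurable templates, with canonical construct
  names (`FETLTLR(BC)-wt(FG)`, `DesAb_9-17`, …), byte-exact edit replay,
  and FASTA/TSV emission.
* **Synthetic sheets** — an ideal pleated-sheet generator (3.47 Å rise,
  4.85 Å strand spacing) plants known target↔partner pairings so the
  entire pipeline is testable offline against brute-force oracles.

Results are tibbles throughout and compose with the tidyverse; fitted
panels and libraries have `tidy()`/`glance()` and `autoplot()` methods.

## Worked example

Design a binder for IAPP residues 9–17 from a structure with a known
complementary strand, then graft it into the disulfide-free sdAb
scaffold:

```r
library(cascadesign)

# a two-strand sheet pairing the epitope with a partner strand
planted <- plant_complement_sheets(c("9-17" = "TQRLANFLV"), seed = 42)
detect_strand_pairs(planted$structures[[1]])
#> # A tibble: 1 × 12
#>   source_id    target_chain target_start target_end target_seq comp_chain
#>   <chr>        <chr>               <int>      <int> <chr>      <chr>
#> 1 planted_9-17 A                       1          9 TQRLANFLV  B
#> # ℹ 6 more variables: comp_start <int>, comp_end <int>, comp_seq <chr>,
#> #   orientation <chr>, register <int>, n_hbonds <int>

lib <- build_library(planted$structures, symmetric = TRUE)
lib
#> <fragment_library> 56 keys, 56 observations (window 3-9)

designs <- cascade_assemble(lib, "TQRLANFLV")
tidy(designs)
#> # A tibble: 1 × 7
#>   epitope_seq paratope_seq orientation  c_score solubility min_support
#>   <chr>       <chr>        <chr>          <dbl>      <dbl>       <int>
#> 1 TQRLANFLV   ESWYDIACW    antiparallel   0.625      0.101           1
```

The single mined pairing covers the whole window, so the cascade returns
its partner strand (read N→C) as the one candidate: `c_score = 0.625` is
the mean of `log10(1 + n_i)` over the nine epitope positions (each
supported by 1–6 overlapping sub-window observations), and the
solubility score (0.101, higher = more soluble) ranks it for expression.
Grafting it as a full designed loop into the cysteine-free sdAb gives a
sequence-ready construct named after its window:

```r
sdab <- substitute_cysteines(example_scaffolds()$sdAb, "AA")
graft(sdab, "CDR3", designs$paratope_seq[1], mode = "full_loop",
      label = "9-17")
#> <construct> DesAb_9-17 (124 aa, scaffold sdAb, 3 edits)
```

`run_pipeline(run_config(...))` wires the same steps end to end — mine →
library → scan → graft — writing the library, panel and construct
FASTA/manifest; the `exec/cascadesign` script exposes `fixtures` and
`pipeline` subcommands for shell use. The shipped scaffold templates are
synthetic stand-ins (see `inst/extdata/scaffolds_synthetic.yaml`);
supply your own YAML for exact published scaffolds.

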