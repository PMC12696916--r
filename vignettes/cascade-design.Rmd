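---
title: "Methods: fragment-based complementary peptide design and scaffold grafting"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: fragment-based complementary peptide design and scaffold grafting}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cascadesign)
```

## The design problem

Amyloidogenic proteins such as the 37-residue islet amyloid polypeptide
(IAPP) aggregate through intermolecular β-sheet contacts. A complementary
peptide — a short sequence that pairs in β-strand geometry with a chosen
linear epitope of the target — can block those contacts, and becomes a
practical reagent once grafted into the binding loop of a small
antibody-like scaffold (a single-domain antibody, sdAb, or a fibronectin
type-III monobody). `cascadesign` implements this workflow end to end:

1. **mine** β-strand-paired peptide fragments from protein structures,
2. **assemble** complementary peptides (paratopes) for epitope windows by
   linking overlapping fragments (the cascade procedure),
3. **scan** a target sequence with epitope windows and rank designs,
4. **graft** the designs into configurable scaffold templates, emitting
   sequence-ready construct panels.

The premise of the cascade procedure is empirical: if a peptide has been
observed facing a sub-sequence of the epitope across a β-sheet in a real
structure, that pairing is geometrically plausible, and overlapping
observed pairings can be chained into a full-length partner.

## Strand pairing as a hydrogen-bond ladder

"Pairing in a β-strand conformation" is operationalised with the
DSSP electrostatic criterion, the community standard for backbone
hydrogen bonds. For donor N–H and acceptor C=O,

$$E = 0.084 \cdot 332 \cdot \left( \frac{1}{r_{ON}} + \frac{1}{r_{CH}} -
\frac{1}{r_{OH}} - \frac{1}{r_{CN}} \right) \ \mathrm{kcal\,mol^{-1}},$$

with a bond called when $E < -0.5$ kcal/mol. The amide hydrogen is
reconstructed geometrically (1.0 Å from N along the direction bisecting
the two backbone bonds at N, pointing away from them), so input
structures need only N, CA, C and O coordinates. Chain-first residues and
prolines have no amide hydrogen and never donate; donor and acceptor must
be at least 3 residues apart within a chain.

Each hydrogen bond supports exactly one residue-to-residue pairing
diagonal: antiparallel diagonals have constant $i+j$, parallel diagonals
constant $j-i$, with the slanted parallel ladder bonds attributed to
their diagonal by donor side. Bonded pairs on a diagonal are clustered
(bridging gaps of at most one unbonded pair — directly bonded pairs
alternate along a pleated ladder), a cluster qualifies as a ladder when
it carries at least two hydrogen bonds (an isolated bond is a turn or
coil contact, not a strand pairing), and each run is extended by the
terminal pleat pair at each end when both partners remain in-chain: the
outermost pair of a pleat carries no bond of its own because its bonds
would lie beyond the strand termini. This last rule is a deliberate
departure from the strict DSSP bridge definition, which systematically
drops the terminal pair of every ladder (a chain-first residue cannot
donate); with it, an ideal two-strand sheet of length $L$ is mined as a
single fragment of length $L$, which is the behaviour the rest of the
pipeline builds on. Runs shorter than `min_len` (default 3) are
discarded, and orientation is assigned from the sign of the summed dot
products of consecutive CA–CA steps along the two sides.

Every mining function is checked against brute-force oracles — an
all-pairs energy scan for `detect_hbonds()` and an exhaustive
interval enumeration for `detect_strand_pairs()` — and all results are
invariant under rigid motions of the input.

## The fragment library and the cascade

`build_library()` indexes every contiguous sub-window (lengths 3–9 by
default, spanning the 7–9-residue paratopes the scanning mode produces)
of every mined fragment under its target-side subsequence and
orientation. Identical observations accumulate counts, so counts are
additive over input structures; windows containing `X` (nonstandard
residues) are excluded. A pairing is evidence in both directions, so the
pipeline indexes each fragment and its side-swapped twin
(`symmetrize_pairs()`); the plain builder indexes fragments exactly as
mined so that the count-conservation invariant (total observations =
sub-window sum) stays exact.

`cascade_assemble()` links fragments left to right across the epitope:
seeds match an epitope prefix; an extension must start inside the
covered region, overlap it by at least `overlap_min = 2` positions, and
agree *exactly* with the already-placed complementary residues across
the overlap; mixing orientations within one candidate is not allowed. A
candidate is complete when every epitope position is covered. The search
is breadth-limited (`beam_width = 64` partial assemblies per coverage
depth) — exhaustive whenever the number of compatible partials stays
below the beam, which holds for every library size used in the tests,
where the assembly is verified against a depth-first enumeration oracle.
These linking rules (minimum overlap 2, exact agreement, per-orientation
assembly) are the smallest set that makes assembly well-posed and
oracle-checkable; they are package design decisions, as is the support
bookkeeping: the per-position support $n_i$ sums the counts of all used
fragments covering position $i$, so designs assembled from densely
tiled, repeatedly observed pairings rank above sparsely supported ones.

Candidates are scored by the complementarity score

$$C = \frac{1}{L} \sum_{i=1}^{L} \log_{10}(1 + n_i),$$

which is 0 with no support and strictly increasing in every count, and
by a simplified intrinsic solubility score: per residue,
$z = 0.6\,(-\hat H) + 0.4\,\hat q$ with $\hat H$ the Kyte–Doolittle
hydropathy rescaled to $[-1, 1]$ and $\hat q = 1$ for D, E, K, R (else
0), smoothed by a centred moving average of width `min(7, length)`
(reduced to odd) and averaged. Both coefficient choices are documented
configuration: the solubility score reproduces the *ranking intuition*
of published intrinsic-solubility predictors (charge helps, hydrophobic
stretches hurt), not any published score numerically. Ranking is
$C$ descending, then solubility, then lexicographic — fully
deterministic. No "high enough" cutoff is imposed; thresholds are left
to the user, since none is published.

## Epitope scanning and the IAPP panel

`scan_epitopes()` runs the cascade per window and keeps the top design;
windows are processed independently, so permuting them permutes the
panel. The shipped target is the mature 37-residue human IAPP sequence
(UniProt P10997, processed chain), with residues 1–8 masked: the
N-terminal region contains the Cys2–Cys7 disulfide and is not a useful
linear epitope. The canonical nine windows (9–17 … 30–37, lengths 7–9)
follow no simple generative rule, so explicit window lists are
first-class input; `enumerate_windows()` (length 7, step 3, final window
stretched to the target end up to length 9) is a convenience that
reproduces their spirit, not their exact list. A deterministic negative
control over the small-side-chain alphabet (S, G, A; the 9-mer is
`SGAAAGSGS`) accompanies every panel.

## Scaffold grafting grammar

Scaffold templates carry a sequence, loop sites (sdAb: CDR3; monobody:
BC and FG), numbered residues (the conserved sdAb cysteines C23/C97,
resolved through a `numbering_offset` because published numbering
schemes need not equal raw sequence position), and an N-terminal region.
Four edit operations compose in a canonical order (truncate →
substitute → replace loop → graft) so that names are deterministic:

* `substitute_cysteines()` — scheme AA (C23A, C97A) or AV (C23A, C97V),
  removing the conserved disulfide for cytosolic expression and
  conjugation chemistry;
* `truncate_n_terminus()` — `N-4-`/`N-8-` style shortening, never into a
  site;
* `replace_loop()` — e.g. FG ← `AAAAS`, `EGYYSSY`, `PTSDYG`;
* `graft()` — core mode inserts the bare paratope, full-loop mode the
  complete designed CDR3 architecture `GS<paratope>EEE`.

Every construct records its edit list; replaying the edits on the
unedited template must reproduce the construct sequence byte for byte,
and lengths obey the conservation identity (template − replaced +
inserted − truncated). Canonical names (`FETLTLR(BC)-wt(FG)`,
`N-8-FETLTLR(BC)-AAAAS(FG)`, `DesAb_9-17`, `DesAb_neg`, …) round-trip
through `parse_construct_name()`; en-dashes in printed window labels are
normalised to ASCII hyphens on output and accepted on input.

The shipped templates are explicitly synthetic stand-ins — a VHH-like
framework composed so that its conserved cysteines sit at raw indices 23
and 97, and the public wild-type tenth fibronectin type-III domain — and
the YAML scaffold config exists precisely so that real template
sequences can be supplied.

## The synthetic sheet generator

`build_ideal_sheet()` turns strand specifications into an idealised
pleated sheet: rise 3.47 Å per residue along the strand axis, 4.85 Å
between adjacent strand axes, CA pleat amplitude 0.8 Å — the canonical
pleated-sheet spacings — with hydrogen-bonding groups alternating sides
along each strand. Strand phases are chosen so the requested
orientation's ladder forms, and each strand's axis offset starts from
the exact register geometry and is refined by a deterministic grid
search (±1.2 Å, 0.02 Å steps) minimising the total backbone hydrogen-bond
energy against the previous strand; this absorbs the slant of parallel
ladders that a flat construction cannot represent exactly. The
construction is deterministic: identical specifications give
bit-identical coordinates.

`plant_complement_sheets()` uses the generator to create structures with
*known* ground truth: chain A carries a chosen target fragment, chain B
a complementary partner drawn reproducibly under a seed from the
standard alphabet without proline (a proline-free partner guarantees
every wide pair keeps at least one donor, so the planted ladder is never
broken). The planted pairs are recorded in a manifest, and the test
suite verifies that mining → library → cascade returns each planted
partner as the top-ranked candidate, across 20 seeds and with planted
pairs optionally split into two overlapping sheets to exercise the
linking step.

What the generator does *not* emulate: side chains and their packing,
β-bulges, bifurcated hydrogen bonds, twist and coil flanks, crystal
contacts, and the redundancy structure of a real structure database.
Passing tests therefore demonstrate the correctness of the mining,
assembly, ranking and grafting machinery under controlled geometry — not
that any particular designed peptide binds its epitope, which in this
workflow is established by wet-lab characterisation.

## Numerical and degenerate-input choices

* Hydrogen-bond energies use a 6 Å N···O prefilter; the oracle tests run
  without it. Cutoff −0.5 kcal/mol (DSSP's).
* Residues missing any backbone atom are kept but ineligible for mining;
  nonstandard residues become `X` and never enter the library.
* Empty structure lists give an empty library with a warning; an
  uncoverable epitope gives an empty candidate list, not an error; an
  epitope containing `X` is an error.
* Ties are broken lexicographically everywhere; all orderings are total,
  so identical inputs give identical outputs.
* Problem sizes: oracle comparisons run on sheets of ≤ 30 residues and
  libraries of ≤ 50 fragments; planted-recovery uses 20 seeds; the
  end-to-end panel uses the full 9-window IAPP fixture. These sizes keep
  every brute-force oracle exact while exercising all code paths.

## Known limitations

* The library treats sequence windows as exchangeable evidence: no
  weighting by resolution, redundancy or local geometry of the source
  structures.
* Parallel pairings are supported and tested, but the default pipeline
  conditions (like the scanning workflow they model) are dominated by
  antiparallel evidence; register and orientation are the only
  "hydrogen-bonding pattern" axes exposed.
* The solubility score is a ranking heuristic, not a calibrated
  predictor; the complementarity score is a documented package
  definition, since no closed form is published for the workflow it
  models.
* Structure-based verification of grafted loop conformations is out of
  scope; the package stops at sequence-ready constructs.
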