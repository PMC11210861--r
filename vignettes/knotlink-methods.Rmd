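---
title: "Methods: dimerization analysis for cystine-knot TGF-β ligands"
author: "knotlink authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: dimerization analysis for cystine-knot TGF-β ligands}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(knotlink)
```

## The question

TGF-β family ligands are synthesized as precursors — signal sequence,
prodomain, mature cystine-knot domain — and signal as dimers, usually
linked by an interchain disulfide through a conserved cysteine. Two
*C. elegans* ligands, TIG-2 (BMP subfamily) and TIG-3 (TGF-β/Activin
subfamily), behave genetically as if they act together in the immune
response to bacterial pathogens. knotlink implements the computational
evidence chain for asking whether such a pair could function as a
heterodimer: precursor annotation, cysteine accounting, predicted-structure
interface analysis, dimer-support scoring, and the survival-based
genetic-interaction decision procedure itself.

## Precursor annotation

Proprotein convertases of the furin family cleave after basic motifs. The
scanner implements the rule (R/K)-X~n~-(R/K): first and last residues Arg
or Lys, spacer length *n* even with 0 ≤ *n* ≤ 6. Scanning is restricted to
positions downstream of the signal sequence; the signal boundary itself is
an *input* (from a dedicated predictor such as SignalP), not something
this package predicts — bundling a trained predictor would add a heavy
dependency for a step whose output is a single integer per sequence.

Two conventions needed a decision:

* **Overlapping matches.** A motif like `RSRR` contains both the
  4-residue R-X~2~-R match and the terminal `RR` dibasic pair; both imply
  the *same* scission point. `scan_cleavage_sites()` therefore
  deduplicates by `mature_start`, keeping the longest motif, which is how
  multi-basic sites are conventionally named. `dedupe = FALSE` exposes
  every raw match.
* **Knot preservation.** A biologically usable site must leave the whole
  cysteine skeleton on the mature side. With
  `require_knot_downstream = TRUE` a site is kept only if every skeleton
  cysteine lies downstream of the scission point. How far downstream of
  the signal the scan should extend is not specified by any convention we
  know of; we scan the entire chain and rely on this filter, which is the
  stated biological constraint.

The prodomain is defined to *include* the cleavage motif, so
`signal + prodomain + mature` always reconstructs the precursor exactly;
all coordinates at API boundaries are 1-based closed intervals. When a
single split is needed, `select_site()` defaults to the most C-terminal
knot-preserving site — the shortest mature form, i.e. the shortest
disordered leader ahead of the knot — while keeping every site reportable,
since multi-site precursors are common and more than one site can be
functional.

## Cysteine accounting

`assign_knot_connectivity()` encodes two skeletons. Six cysteines get the
canonical growth-factor-knot pairing (C1–C4), (C2–C5), (C3–C6). Eight
cysteines get (C1–C3), (C2–C6), (C4–C7), (C5–C8); this arrangement is
attested for the TIG-3 mature domain and is flagged as such in the
output (`rule = "attested_8_tig3"`) rather than claimed as a general
rule. Any other count raises an explicit "no connectivity rule" error —
never a silent guess. Both rules are perfect matchings: no unpaired
cysteine remains, which is exactly the point — these ligands have no free
cysteine available for an interchain bond.

A second, structure-based route is provided for cross-checking:
`detect_structural_disulfides()` pairs cysteines whose Sγ–Sγ distance is
at most 2.5 Å. The canonical S–S bond is ~2.05 Å; 2.5 Å absorbs predictor
noise while staying far below nonbonded sulfur contacts. No dihedral
criterion is applied, because the upstream analyses report pairings, not
bond geometry. Matching is greedy by increasing distance, which makes the
output deterministic and mutually exclusive.

**The dimerization column.** Whether a candidate retains the interchain
cysteine is read from a pairwise global alignment
(Needleman–Wunsch dynamic programming via Biostrings, BLOSUM62, affine
gaps costing `opening + length × extension`, defaults 10/1) against a
reference family member that keeps the cysteine. A multiple alignment
would be closer to common practice, but only a single reference column is
ever consulted, and a pairwise global alignment answers that with fewer
moving parts. `dimerization_residue()` reports the candidate residue in
the reference cysteine's column, a `substituted` flag (strictly "not C";
a gap is reported distinctly), and the candidate position.

## Interface analysis of predicted dimers

`read_structure()` ingests PDB or mmCIF via bio3d, drops hydrogens, keeps
the highest-occupancy alternate conformer, and interprets the B-factor
column as per-residue pLDDT, following predictor conventions. Residue
numbering follows the file's author numbering; mapping into mature-domain
numbering is done explicitly through the precursor module's offsets,
because mixing the two silently is the classic source of off-by-N errors
in this analysis.

`read_pae()` accepts both JSON dialects in circulation — the AlphaFold-DB
key `predicted_aligned_error` (possibly wrapped in a one-element array)
and the ColabFold key `pae` — and validates the matrix dimension against
the accompanying structure.

Contacts are residue pairs on different chains with minimum heavy-atom
distance ≤ 4 Å (`interchain_contacts()`); distances are computed by a
vectorized all-pairs evaluation, which at the sizes involved (hundreds of
residues per chain) is both simplest and exactly the brute-force
definition the tests check against. Whether the original ChimeraX-based
analysis used plain atom-pair distance or an overlap criterion is not
documented; plain minimum distance is implemented and stated here.

Confidence filtering is strict: a contact is *confident* iff its PAE is
strictly below 5 Å, matching the "PAE < 5 Å" convention for interface
tracks. PAE matrices are asymmetric; the per-contact value defaults to the
mean of the two directions (order-free and symmetric), with `min`/`max`
exposed as options. The per-chain *interface track* is the set of residues
participating in at least one confident contact.

`region_pair_contacts()` reproduces the procomplex-style column analysis:
contacts are split by annotated monomer regions (prodomain vs mature) into
directed columns pro↔pro, pro↔mat, mat↔pro, mat↔mat, plus full↔full (the
union), each with its arithmetic mean PAE — the "column mean" line of such
plots. The annotation must cover every residue; partial coverage is an
error rather than a silent drop.

## Dimer-support verdicts

Mean pLDDT, pTM and ipTM are consumed as predictor outputs; they cannot be
recomputed without the predictor's trained weights, so the published
values for the TIG complexes ship as a fixture table
(`tig_multimer_metrics()`) and are *interpreted*, not reproduced.

`classify_dimer_support()` applies two thresholds: structure confident iff
mean pLDDT ≥ 70 (the conventional cutoff, inclusive), and dimer supported
iff ipTM ≥ 0.55. No published ipTM support threshold exists; across the
ligand panel the supported complexes score 0.78–0.88 and the unsupported
homodimer ~0.29, so 0.55 sits in the wide empty margin between the two
groups. It is a configuration default with its rationale recorded here,
not a claim about ipTM semantics; both flags are monotone in their metric
by construction.

`benchmark_panel_compare()` formalizes "grouping with" a benchmark panel
as 1-nearest-neighbour under Euclidean distance on the vector
(mean pLDDT / 100, pTM, ipTM) — all three components on the unit scale,
matching how such panels are plotted. 1-NN was chosen over clustering
because the benchmark question is "which side of the panel is this
candidate closest to?", and 1-NN answers it deterministically with no
tuning parameters.

## Survival statistics and the interaction call

`km_estimate()` is the product-limit estimator with the standard tie
convention (censored-at-t records remain at risk for deaths at t).
`logrank_test()` is the Mantel–Cox test assembled from its formula: at
each distinct death time, observed minus expected deaths under the
pooled-risk null, variance by the hypergeometric formula
$d \frac{n_1}{n}\left(1-\frac{n_1}{n}\right)\frac{n-d}{n-1}$, and
$\chi^2 = (\sum(O_1-E_1))^2 / \sum V$ with one degree of freedom. Both are
implemented from scratch in this package — they are part of the decision
procedure under study — and the test suite checks them against the
independent `survival` package implementations.

The genetic-interaction call follows the epistasis logic for survival
phenotypes. Both single mutants must first be significantly worse than
wild type (otherwise `inconclusive` — there is no phenotype to compose).
Then, in order:

1. double significantly *better* than the worse single → `antagonistic`;
2. double significantly worse than *both* singles → `independent`
   (additivity of two disrupted pathways);
3. double not significantly different from *either* single →
   `same-pathway` (loss of either subunit already abolishes the shared
   function);
4. anything else → `inconclusive`.

Antagonism is tested first because a double mutant that is better than the
worse single cannot satisfy the other patterns, and the "partially
antagonistic" phenotype (better than one single, indistinguishable from
the other) should not fall through to `inconclusive`. Direction of effect
("worse") is taken from the sign of the log-rank observed-minus-expected
score rather than median survival, which stays defined under heavy
censoring. The *worse single* is identified by a direct log-rank between
the singles, falling back to the larger standardized excess versus
wild type when they are not separable.

Significance is per-comparison at α = 0.05, mirroring the per-comparison
asterisk convention of survival figures in this field; a Bonferroni flag
(α/3 across the double-vs-single and single-vs-single tests) is available
but off by default.

## Synthetic data: what it emulates, and what it does not

Every pipeline input can be generated with recorded ground truth:

* `gen_precursor()` — precursors with planted signal, motifs and cysteine
  skeleton. Filler residues are drawn from the 17 amino acids that are
  not C, R or K, so *every* basic residue and cysteine in the output is
  planted: scans and inventories can be checked against ground truth
  exactly. Spacer residues inside planted motifs may be basic (as in
  `RSRR` itself); they only add submatches at the same scission point.
* `gen_dimer_structure()` — two 8 Å-spaced backbone chains with a planted
  interface brought to exactly 3.5 Å (minimum heavy-atom distance)
  against a ≥ 10 Å decoy separation, bimodal PAE (2 Å interface, 20 Å
  background; the ColabFold writer emits integer PAE, the AF-DB writer
  floats, to exercise both parsers), and pLDDT in the B-factor column.
* `gen_knot_structure()` — a single chain whose planted disulfide pairs
  have their Sγ atoms placed 2.03 Å apart at isolated bond sites;
  unpaired cysteines stay far from every site.
* `gen_survival()` — exponential event times (constant hazard, chosen
  over Weibull for closed-form moment checks) with administrative
  censoring at the assay horizon. Arms: wild type `h`, singles
  `h·r_A`, `h·r_B`; the double mutant gets `h·r_A·r_B` (independent),
  `max` of the singles (same-pathway), or the *smaller* single hazard
  (antagonistic: suppression to the milder phenotype). Defaults
  `h = 0.1/day`, `r = 2.5`, 100 animals per arm, 14-day horizon — cohort
  sizes and effect magnitudes in the range of published *C. elegans*
  pathogen-survival assays.

All randomness flows from one seed with fixed per-component offsets, so
generating one kind of output never shifts another.

These fixtures are deliberately schematic. The structures have no real
fold, rotamers or clashes; PAE is bimodal rather than smoothly varying;
survival is memoryless, whereas real killing curves are often sigmoidal;
there is no frailty or batch structure. Passing tests therefore
demonstrate that the *logic* — scanning, splitting, pairing, filtering,
testing, calling — is correct against known ground truth, not that the
pipeline is robust to predictor pathologies or to non-proportional
hazards in real cohorts.

The stand-in ligand sequences (`synthetic_tig2_precursor()`,
`synthetic_tig3_precursor()`, `synthetic_bmp2_like_reference()`) are in
the same spirit: deterministic synthetic sequences carrying every
*published* annotation feature of TIG-2 and TIG-3 isoform B at the
published coordinates — RSRR/KVKR sites with 134-/116-residue mature
forms, the 6- and 8-cysteine skeletons, the prodomain cysteines at 60/70,
the lysine in the dimerization column (position 80 and 81 respectively) —
without being the real sequences, which are not redistributed with this
package. A window around the dimerization column is kept
sequence-identical across the three (offset by one residue in TIG-3, up
to the Cys→Lys swap), mimicking the strong local conservation that
anchors this column in real family alignments and making the alignment
column assignment stable.

## Numerical choices and degenerate inputs

* Ties in disulfide matching are resolved smallest-distance-first;
  ties in 1-NN benchmarking by panel order (deterministic input order).
* The log-rank variance term skips event times with a single subject at
  risk (`n = 1`), where the hypergeometric variance is undefined; a zero
  total variance yields statistic 0, p = 1 (identical cohorts).
* Contact extraction at the cutoff boundary is inclusive (≤ 4 Å);
  confidence filtering is exclusive (PAE < 5 Å) — both as conventionally
  printed.
* Empty results are empty tables, not errors (no motif matches, no
  contacts); *structural* impossibilities (single-chain contact request,
  unsupported cysteine count, annotation gaps, PAE dimension mismatch)
  are errors.
* Problem sizes in the test suite: 30-dimer oracle sweeps, 2000 null and
  500 alternative log-rank simulations (n = 50 and 200 per arm), and 200
  cohort simulations per generative model (n = 100 per arm, r = 2.5) —
  the scale at which the binomial check on the type-I error is
  informative while the whole suite stays fast.

## Known limitations

* The 8-cysteine pairing rule is attested for one ligand; other
  8-cysteine family members may pair differently.
* ipTM ≥ 0.55 is a panel-derived default, not a universal threshold;
  borderline complexes (ipTM 0.4–0.6) deserve manual inspection.
* The interaction call assumes proportional-hazards-like monotone
  severity orderings; crossing survival curves can defeat the
  O−E-sign direction heuristic.
* Signal peptides, isoform discovery and structure prediction itself are
  out of scope: their outputs are this package's inputs.
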