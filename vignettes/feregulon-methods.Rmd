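---
title: "Methods: regulon fingerprinting under chemically induced iron deficiency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regulon fingerprinting under chemically induced iron deficiency}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(feregulon)
```

# The experimental system

A lipophilic bidentate N,N ligand acting as a copper ionophore bypasses
the copper-import machinery of *Saccharomyces cerevisiae* and delivers
cuprous ions into the cell, where they damage mitochondrial iron-sulphur
clusters. Because the yeast iron regulons sense iron-sulphur cluster
status rather than iron itself, the treatment imposes *functional* iron
deficiency: the Aft1/2 iron-uptake regulon switches on, the Cth2
iron-sparing programme degrades ARE-containing transcripts, and the Yap5
iron-surplus regulon eases off, all while copper-specific regulons (Ace1
up, Mac1 down) respond to the copper load itself. feregulon implements
the computational side of such a study: replicate fold-change calling,
two-condition regulon fingerprinting, motif-based candidate-target
nomination, a Fra2-dependence statistic, and the supporting binding and
coordination-geometry calculations.

# Fold changes and the one-SD significance rule

Expression is handled as RPKM (reads per kilobase of transcript per
million mapped reads); `compute_rpkm()` applies the standard
`count * 1e9 / (length * total_reads)` conversion when raw counts are
supplied.

For a comparison of a test group against a reference group (always
wild-type untreated in the standard design), `fold_changes()` divides
each test replicate by the reference-group mean. The design is unpaired
— the replicate cultures are independent — so per-replicate pairing
would be arbitrary; dividing by the reference mean keeps the replicate
spread of the test group visible in the reported SD. Down-regulated
genes are summarised on the reciprocal (fold-decrease) scale *before*
averaging, so a gene at one-fifth of its reference level reports a
5-fold decrease with the SD of the per-replicate reciprocals. The
`signed_fold` convention (+fold for up, −fold for down, nothing strictly
inside (−1, 1)) gives fingerprint plots symmetric linear axes without a
log choice.

Two numerical guards matter in practice:

* the reference mean is floored (default 0.1 RPKM, configurable) so
  genes with negligible basal expression produce large-but-finite folds
  and a `low-reference` flag rather than infinities;
* on the reciprocal scale, test replicates are floored the same way, so
  an all-zero treated gene yields a finite fold-decrease plus a
  `low-test` flag.

The significance rule is deliberately strict: a change is significant
only if the direction-scale fold minus one replicate SD still exceeds
the threshold (default 2-fold), i.e. `fold − sd > threshold`. Of the
possible readings of "significant if one SD beyond a 2-fold change" this
is the most conservative, and it reproduces the intended boundary
behaviour: a noiseless exactly-2-fold change is *not* significant, while
a 6.2-fold change with SD 3.8 (2.4-fold after subtracting one SD) is.
`threshold_table()` then reproduces "4.5-fold and greater" style tables:
significant genes of one direction at or above the cutoff, sorted by
descending fold.

# The Fra2-dependent fraction

Fra2 helps hold the Aft1/2 activators off DNA in iron-replete cells.
Deleting it de-represses Aft targets partially; treating the deletion
mutant with the ionophore drives the full response. With both mutant
conditions expressed as linear fold changes `S` against the same
wild-type untreated reference, `fra2_fraction()` reports

```
f_dep = (S_untreated − 1) / (S_treated − 1)
```

the proportion of the total induction already present as de-repression
in the untreated mutant. `f_dep = 1` means regulation of that gene runs
entirely through Fra2; `f_dep = 0` means the treatment response is fully
Fra2-independent. Genes whose treated response is within a tolerance
(default 0.05) of no change cannot be partitioned and are flagged rather
than divided; estimates outside [0, 1] (possible under noise) are kept
but flagged `out_of_range`.

# Motif scanning

Two consensi are built in: the Aft1/2 promoter site `PyPuCACCCPu`
(Py = C/T, Pu = A/G; 8 concrete words) and the AU-rich element
`UUAUUUAUU` with its two contiguous octamer derivatives. The octamer
reading follows the established ARE literature, where the functional
element is the nonamer or the nonamer minus one terminal U; a
user-supplied derivative set can replace it by constructing a
`degenerate_consensus()` directly.

Strand policy is biological, not symmetric by default: the ARE is an RNA
element and exists only on the sense strand of the transcript, while the
Aft1 site is a DNA element scanned on both promoter strands. Matching is
exact-string per concrete word (via `Biostrings`), so `N` never matches.
A minus-strand hit is reported at the position of the reverse-complement
instance on the stored sequence, which keeps every reported coordinate
in the coordinate system of the stored region. Overlapping hits are all
found; by default hits at the same start position collapse to the
longest word (a nonamer hit would otherwise always drag in an octamer
hit at the same offset), with `dedupe = "all"` available for analyses
that want the complete multiset.

`extract_regions()` cuts promoters (default 600 nt, a typical yeast
intergenic scale — the window is exposed because no canonical value
exists) upstream of the 5' gene end on the gene's strand, and 3' UTRs
either from annotation or as a downstream window (default 200 nt).
Annotation input is 1-based inclusive; regions truncated at chromosome
edges are flagged rather than dropped.

# The two-condition fingerprint

`assemble_fingerprint()` plots each responding gene at
(x = signed fold under copper + ionophore, y = signed fold under copper
alone), including only genes whose ionophore response is significant and
at least 2-fold. Two least-squares lines summarise the picture
(`fit_group_lines()`): copper-responsive regulons (Ace1, Mac1) respond
equally in both conditions and fall on the diagonal (slope ≈ 1), while
iron-responsive regulons (Aft1/2, Cth2) respond only to the ionophore
and form a near-horizontal band (slope ≈ 0). Fitting is unweighted OLS
on the signed-fold axes — the fingerprint is drawn on linear fold axes,
and the lines are descriptive summaries, not error models. Yap5-class
genes are annotated and reported but excluded from both lines, as their
modest high-iron response belongs to neither group.

`nominate_candidates()` operationalises "regulation previously unknown"
as `class == "unknown"` in the supplied annotation
(`regulon_annotation_default()` ships the regulon assignments of the
named genes). Candidate iron-sparing targets are unknown genes down at
least 2-fold with an ARE in the 3' UTR; candidate iron-uptake targets
are unknown genes up at least 2-fold with a promoter Aft1 site. Every
candidate cites its supporting matches.

# Binding biophysics

For a single overall equilibrium `M + nL <-> MLn` with formation
constant `beta_n`, `solve_mass_balance()` finds the free-ligand root of
the mass-balance equation by bisection (the objective is strictly
increasing in free ligand, so the physical root is unique; 100
bisections reach machine precision, and conservation holds to better
than 1e-9 relative at every point). The tight-binding limit
`[MLn] = min(M_total, L_total/n)` is available as `beta = Inf` and is
what a very tight chelator shows at tens of micromolar ligand.

`fit_breakpoint()` reads the stoichiometry off a titration: a
continuous two-segment least-squares fit (rising segment, then a
plateau with slope constrained ≥ 0) with the breakpoint located by a
coarse-to-fine grid search — derivative-free on purpose, because real
curves have 8–12 points and the SS profile can be locally flat; ties
resolve to the smallest breakpoint. A 2:1 ligand:metal complex
saturates the ligand at 0.5 metal equivalents, so the fitted breakpoint
in equivalents inverts to the stoichiometry (reported both raw and
rounded to the nearest half-integer). Only the overall constant is
modelled; stepwise constants are not resolvable from a single
saturation curve and are out of scope.

`quantify_metal()` is deliberately a calculator: atoms per cell, atoms
per total cell volume, and the accumulated-metal:ionophore mole ratio
under the stated assumption that all added ionophore is taken up. The
underlying per-culture inputs of published ratio experiments are not
part of any dataset, so the function ships with worked arithmetic
examples rather than packaged inputs.

# Coordination geometry

`chelate_geometry()` computes, per metal centre, the bite angle of each
bidentate ligand (donor–metal–donor angle) and the dihedral between the
two chelate planes. Each plane is defined *exactly* by its three atoms
(metal + donor pair) — the minimal faithful reading of "metal–ligand
plane"; a fitted whole-ring plane would drag ring pucker into the
answer. The dihedral is folded into [0, 90] degrees because plane
normals have arbitrary sign. Donors are assigned within a 2.5 Å cutoff
(covering cuprous bis-diimine bond lengths with margin, configurable);
when ligand ids are absent the two pairs are chosen by exhaustive
enumeration of the three pairings of four donors, minimising the summed
within-pair donor–donor distance. That criterion identifies the true
ligands for realistic chelates (tight bites, near-tetrahedral twists);
for wide bites with small inter-plane twists it can genuinely prefer a
cross-ligand pairing, which is why files with ligand identity keep it.
Structures with several complexes report per-complex values and the
mean — deliberately both, since a printed "the bite angle is 81°" may be
either one.

`gen_bischelate()` constructs an ideal bis-chelate with exact bite and
dihedral, which closes the loop: construction followed by measurement
recovers the inputs to below 1e-6 degrees, and the measurement is
invariant under rigid motions to 1e-9 degrees.

Input formats are XYZ and a minimal small-molecule CIF reader (cell
parameters plus the `_atom_site` loop, fractional coordinates
orthogonalised through the standard cell matrix). No installed R
package parses small-molecule CIF, so this subset is implemented here;
symmetry expansion, disorder and refinement metadata are out of scope.

# What the synthetic data emulate — and what they do not

`gen_expression()` draws a five-condition, two-genotype design (wild
type untreated / +Cu / +Cu-ionophore; regulatory mutant untreated /
+Cu-ionophore), three replicates each, with class effects calibrated to
the printed extremes of the study's threshold tables: iron-uptake genes
up 4–27x under the ionophore, copper-detox genes up 4–19x under both
copper conditions, iron-sparing genes down 2–5x, copper-uptake genes
down 5–22x, iron-surplus genes modestly down 1.2–2x. Iron-responsive
genes respond to copper alone only within noise (a near-unity effect
with SD 0.1), which is what makes the iron line of the fingerprint
horizontal. Candidate classes (`cand_aft`, `cand_cth2`, defaults 1 and
9 genes) behave like their parent regulons — candidate effects drawn
from the upper parts of the ranges (up 10–27x, down 3–5x) so that
planted candidates clear the 2-fold significance rule at the default
noise level — but are emitted as `unknown` in the annotation and carry
planted motifs, closing the nomination recovery loop.

Replicate noise is multiplicative log-normal with unit mean,
parameterised by its CV: expression is positive and the printed
per-gene SDs scale roughly with the fold change, which is exactly the
behaviour of multiplicative noise. The default CV of 0.1 is a
calibration choice (triplicate RPKM dispersion is not published beyond
per-gene SDs); `noise_cv = 0` reproduces the analytic expectations
bit-exactly, which the tests use as the noise-free oracle. In the
mutant background, the untreated expectation of an iron-responsive gene
is `baseline * (1 + f * (effect − 1))` with `f` the planted
Fra2-dependent fraction, and the treated expectation is the full
effect, so `fra2_fraction()` recovers `f` by construction.

`gen_regions()` plants one concrete motif instance per eligible gene at
a uniform random position (random strand for promoter sites), and
re-draws the background until the planted instance is the only
occurrence of the designated consensus in that sequence — so ground
truth positions are the unique planted hits and nomination precision is
measurable. Background composition is i.i.d. uniform.

The generator does **not** emulate: read-level sequencing (no FASTQ, no
alignment artefacts), gene-length or GC bias, correlated replicates or
batch effects, realistic yeast promoter composition (AT richness,
nucleosome-free regions), or partial regulon overlap (each gene belongs
to exactly one class). Passing recovery tests therefore demonstrates
that the statistics are implemented correctly and are unbiased under
the stated noise model — not that the pipeline is robust to every
artefact of real RNA-seq.

# Problem sizes and seeds

The test suite and the acceptance script run entirely from generated
data at desk scale: the default simulated study is 209 genes x 15
samples, multi-seed recovery checks use 20 seeds of that design, the
scanner-oracle comparison uses 1,000 random 2-kb sequences, breakpoint
robustness uses 100 noisy curves, and the mass-balance oracle uses a
~1e6-evaluation grid per point. These sizes give the recovery tests
comfortable statistical resolution (3-SE bands on hundreds of genes)
while keeping any single check in the seconds range. All randomness
flows through explicit integer seeds; no function touches the global
RNG state without restoring it (`withr::with_seed`).

# Known limitations

* The significance rule is the strict reading; users wanting the
  permissive reading (fold > threshold regardless of SD overlap) can
  filter on `fold` directly — both quantities are in the table.
* `fra2_fraction()` is a ratio of noisy quantities; near-unity treated
  responses are flagged rather than divided, but mildly out-of-range
  estimates under noise are reported as-is (flagged), not clipped.
* The breakpoint fit assumes one rising segment and one plateau;
  multi-phase curves (e.g. a second adduct forming in rich medium) will
  fit the dominant break only.
* The CIF reader targets small-molecule files with a single
  `_atom_site` loop; it is not a general CIF parser.
```{r session}
sessionInfo()
```
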