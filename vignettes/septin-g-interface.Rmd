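---
title: "Methods: septin G-interface contacts, motifs and nucleotide occupancy"
author: "septG"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: septin G-interface contacts, motifs and nucleotide occupancy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(septG)
```

# Scope and model of the analysis

Septin hetero-oligomers bury every nucleotide-binding pocket inside a
septin–septin "G" dimerization interface. Because some septins are
pseudoGTPases — unable to hydrolyze (or even bind) guanine nucleotide —
the two pockets facing each other across a G interface can hold different
nucleotides, and the interface residues co-evolve with that occupancy.
`septG` implements the quantitative pieces of such an analysis: geometric
contact detection at the interface, annotation of residues to the
canonical GTPase motifs, contact fingerprint comparison between
structures, sequence-level identity/covariation/tree analyses keyed to the
Switch I catalytic threonine, and an occupancy model that connects
per-subunit GTP-bound fractions to a measurable bulk GDP:GTP ratio.

The package deliberately consumes structures as files (experimental
models or externally produced predictions); it performs no structure
prediction, docking, or energy minimization.

# Hydrogen-bond detection

A hydrogen bond is accepted between a donor heavy atom D and an acceptor
heavy atom A when

* the D–A distance is at most `baseDaMax + distanceTolerance`, and
* an angular test passes: when D carries an explicit hydrogen, the best
  D–H–A angle must be at least `baseDhaMin − angleTolerance`; otherwise a
  proxy is used — the D–A–antecedent angle at the acceptor (the
  antecedent being the heavy atom covalently bonded to A, e.g. CG for
  Asp OD1) must be at least `baseDaaMin − angleTolerance`.

Defaults are `baseDaMax = 3.3` Å, `baseDhaMin = 120`°, `baseDaaMin =
90`°, with relaxations of `distanceTolerance = 1.0` Å and
`angleTolerance = 20`°. The relaxed envelope (≤ 4.3 Å, generous angles)
is the convention used throughout the package's interface analyses; the
base values are ordinary geometric H-bond criteria, and all five numbers
are exposed in `hbondCriteria()` so other tools' conventions can be
matched. Donors/acceptors come from a packaged per-residue template
(`donorAcceptorTable()`) covering the 20 standard amino acids and the
guanine/inosine/xanthosine nucleotide series; template atoms absent from
a residue (the γ-phosphate oxygens of GDP, say) simply never match, so
one nucleotide template serves the whole series.

Numerical/edge choices: pairs closer than 1.8 Å are treated as covalent
contamination and skipped; intra-residue pairs and the sequence-adjacent
backbone amide→carbonyl pair (whose geometry is covalently constrained)
are excluded; when a hydrogen-free acceptor also lacks its antecedent
atom the angle test is waived rather than inventing geometry; output is
ordered lexicographically by (donor, acceptor) so reruns diff cleanly.

The proxy-angle route exists because predicted models and many crystal
structures carry no hydrogens; building a hydrogen-placement subsystem
would import a force field's worth of assumptions for little gain at the
4.3 Å envelope used here.

Ligand-pocket contacts (`ligandContacts`) report every residue with a
heavy atom within 4.0 Å of any ligand heavy atom — the conventional
cutoff for pocket diagrams — marking residues that also pass the
H-bond test as `kind = "hbond"`. Steric checks (`clashCheck`) use a
packaged Bondi-style vdW radius table and report pairs whose overlap
(radius sum minus distance) reaches 0.4 Å, a standard severe-clash
threshold.

# Motif annotation and WG-relative offsets

The canonical motifs are located by degenerate patterns: G1/P-loop
`GxxxxGK[S/T]`, G3/Switch II `DxxG`, G4 `[A/G/N/T]KxD`, G5 `[S/A]A[K/L/R]`
(scanned only downstream of a located G4 — the pattern is too short to be
meaningful on its own), each tolerating one mismatch by default with the
mismatch count reported rather than failing; pseudoGTPases with degenerate
motifs therefore still annotate. Switch I (G2) has no reliable sequence
signature and is config-only. The septin-specific Sep4 element and its
three-stranded β meander are treated as one region (`beta_meander`)
anchored on the invariant Trp-Gly: the literal `WG` downstream of G5. The
region spans WG−6 … WG+12 by default, and every β-meander residue carries
a signed WG-relative offset (the WG Trp itself is 0), matching the
field's "−4"/"−2"/"+1" nomenclature for positions such as the conserved
−4 arginine that contacts the bound guanine base.

Because published region boundaries are informal, regex hits define only
the motif cores; a YAML config can override or extend ranges per protein
in author numbering (an editable example for the yeast Cdc3–Cdc10 dimer
ships in `inst/extdata/`). Trans loop 1 and the α4 helix cannot be found
by pattern; they default to windows anchored on G4 (tl1 at G4start−9 …
G4start−4, immediately N-terminal; α4 at G4end+4 … G4end+15, C-terminal),
reflecting their positions in the septin fold. Overlaps between derived
ranges are resolved by a fixed priority (G1 > G2 > G3 > G4 > G5 > tl1 >
α4 > β meander) so no residue ever carries two labels.

`catalyticThrStatus` aligns a query to a reference with a declared
catalytic-Thr position and reports the aligned residue; any non-Thr
residue means "absent" (for a pseudoGTPase any substitution suffices),
and a gap yields "unalignable" rather than a guess.

# Interface fingerprints, diffs and superposition

`buildFingerprint` aggregates cross-chain bonds into a region×region
count matrix whose total always equals the number of bonds. Differential
contacts (`diffFingerprints`) compare two bond sets at residue-pair
granularity by default: contact identity survives hydrogen-placement and
rotamer differences between models, which atom-level identity does not.
An atom-granular mode is available. Mutant or ortholog numbering is
reconciled through `correspondenceMap` (global alignment; bijective on
non-gap columns, substitutions flagged, gaps unmapped), and endpoint
pairs are canonicalized unordered so a donor/acceptor swap between
models does not masquerade as a changed contact.

`superpose` implements the Kabsch least-squares fit via singular value
decomposition (reflections excluded by construction, det(R) = +1 within
1e-6), pairing CA atoms by default — robust to side-chain divergence —
and then reports per-residue displacements for *all* matched residues:
both the maximum heavy-atom displacement and the side-chain centroid
displacement are given, since "residue X moved by N Å" claims in the
literature rarely name a metric. On a constructed fixture where one side
chain is translated 7 Å, both metrics recover 7.00 ± 0.01 Å after a
CA-only fit.

# Sequence evolution

Pairwise alignment is global Needleman–Wunsch/Gotoh under BLOSUM62 with
gap open 10 and gap extend 0.5 (Biostrings). Percent identity defaults to
identical columns over alignment length; published full-length identities
are integer-rounded and mildly parameterization-dependent, so comparisons
against printed values use a ±2 percentage-point band. Distances for
trees are 1 − fractional identity.

Neighbor joining is implemented with two deterministic conventions:
minimal-Q ties are broken by the lexicographically smallest labels in the
candidate clusters (so input order never changes the topology), and
negative branch lengths are clamped to zero with a warning. On additive
matrices the method recovers the generating topology and branch lengths
exactly; the test suite checks 50 random trees (n ≤ 8) and cross-checks
an independent implementation on non-additive input.

Covariation with the catalytic-Thr marker is formalized as a *matching
coefficient*: for each alignment column, residue identities are split
into two blocks in every possible way and the best fraction of sequences
on which the block indicator equals the marker vector (Thr absent) is
reported; 1.0 is perfect covariation. This makes "correlated perfectly"
operational while remaining agnostic about which residues form the
covarying classes. Constant columns are excluded as uninformative;
sequences gapped at a column leave that column's denominator, and
sequences gapped at the marker column are excluded throughout. The
exhaustive partition search is exact for the ≤ 12-sequence,
≤ 6-residue-class alignments this analysis targets.

A center-star progressive aligner (`alignSequences`) is included for
building small MSAs from the package's own pairwise aligner; it is
adequate at the ~12-sequence scale and is not intended to replace a
dedicated MSA tool.

# The occupancy model

`OctamerModel` is a general mixture-of-slots model: slots with copy
numbers, optional within-slot alternatives with mixing weights, and a
GTP-bound fraction per subunit, under 1:1 protein:nucleotide pocket
occupancy. The default `yeastOctamer()` encodes the budding-yeast rod —
2× Cdc3 (GTP-locked: it lacks the catalytic Thr), 2× Cdc10, 2× Cdc12,
and two terminal slots shared by Cdc11 and Shs1 at 1.6:1 — with 40% of
Cdc11 GTP-bound as the scenario that reproduces the measured 2.2:1 bulk
GDP:GTP ratio. Expected GTP per complex is Σ copies × weight × fraction;
the ratio is strictly decreasing in every fraction; an all-GDP model is
flagged infinite rather than silently numeric. `solveFraction` inverts
the ratio in closed form and errors with the attainable interval when a
target is out of range. Hexamers and tetramers are expressible by
construction. The CLI prints ratios to 2 significant figures, matching
how such ratios are reported; full precision is kept in JSON.

A note on inversion and printed precision: a bulk ratio printed as 2.2
constrains the free fraction only to about ±0.02 (ratios 2.15–2.25 map to
fractions 0.393–0.419 under the default model), so round-tripping
"ratio 2.2 → fraction" returns 0.406, which is the printed "40%" scenario
within printing precision.

# Synthetic data: what it emulates and what it does not

Each generator is deterministic under its seed and returns
machine-checkable truth alongside the data (and can write PDB/FASTA plus
a JSON truth sidecar so the file-based interfaces are exercised too):

* `makeHbondDimer` emulates a G-dimer interface: two facing chains with
  k Ser-OG → Asp-OD1 bonds planted at 2.9 Å and a linear proxy angle,
  optional Gaussian coordinate noise, and a > 6 Å exclusion gap for every
  inter-chain atom pair outside the planted donor/acceptor groups (the
  acceptor's covalent antecedent necessarily sits ~4.4 Å from the donor;
  it is neither donor nor acceptor, so the planted list remains the exact
  detector ground truth).
* `makeLigandPocket` emulates pocket diagrams: a nucleotide atom at the
  origin, contact residues placed with their nearest heavy atom at exact
  specified distances in (0, 4) Å, all other residues beyond 4.5 Å.
* `makeCovaryingMSA` emulates a homolog panel with a catalytic-Thr
  present/absent marker, planted perfect columns, noisy columns with a
  stated number of flipped sequences (coefficient max(f, n−f)/n by
  construction), and background columns re-drawn if they accidentally
  covary perfectly.
* `makeIdentityPair` plants an exact substitution count with no indels,
  so the realised identity equals the target.

Residue geometry is idealized from internal coordinates — there is no
rotamer library, no secondary structure, no B-factors, no alternate
conformations beyond what the parsers are tested on. Passing the planted
suites therefore demonstrates the *detectors and estimators* are correct
at their geometric/combinatorial task; it does not validate chemical
realism on experimental structures, where criteria choices (and hydrogen
placement) dominate. The tests run the planted recovery at σ = 0 because
recovery is only guaranteed at ideal geometry; the noise parameter exists
for robustness exploration.

# Problem sizes and determinism in the test suite

The suite uses sizes that keep every property exact and the full run in
about a minute: dimers of 10–25 residues per chain with up to 6 planted
bonds (100 seeds for recovery), random two-chain models of ~20–28
residues (~150–300 atoms; 100 fixtures for the brute-force equivalence),
trees of 5–8 taxa (50 random additive matrices), MSAs of 6–12 sequences ×
15–40 columns, 8-mer pairs against the score-only dynamic-programming
oracle (100 trials), and 10^5 Monte-Carlo octamers checked against the
analytic ratio within 3 standard errors. All randomness is seeded; rerun
outputs of the pipeline functions are byte-identical (numbers formatted
to 6 decimals).

# Open choices made by this package

* Alternate locations: highest occupancy wins, ties broken by
  alphabetical alt-loc id. Author residue numbering is authoritative
  everywhere; nothing is renumbered.
* Which chain of a two-chain experimental dimer corresponds to which
  septin is taken from the entry's own content/metadata (e.g. identifying
  the Cdc10 chain by its residue identities), never guessed from chain
  order.
* Ortholog assignment within an accession panel (which sequence is the
  Cdc11 vs Spr28 homolog of a species) is made by similarity to the named
  reference sequences and reported, not hard-coded.
* Sep4 vs β meander are one region label; users who need a finer split
  can override ranges in the motif config.
* Contact-count granularity (atom vs residue) is explicit: residue-level
  is the default for diffs, both are available, and the fingerprint keeps
  the full residue-pair backing list so either view can be derived.

# Limitations

* No π-cation, salt-bridge-specific, solvent-exposure or water-mediated
  interaction detection; the H-bond detector with relaxed geometry is the
  only contact model.
* Heavy-atom proxy angles are a coarse stand-in for true donor-H
  geometry; absolute bond counts on hydrogen-free models depend on the
  chosen envelope and will not numerically match tools with different
  base criteria.
* The progressive aligner is center-star, not profile-based; use it only
  at small scale.
* The occupancy model is stoichiometric, not kinetic: it says nothing
  about hydrolysis rates or exchange, only about expected pocket content
  given fractions.
* Covariation is a descriptive matching coefficient, not a
  phylogenetically corrected statistic; shared ancestry can inflate it.
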