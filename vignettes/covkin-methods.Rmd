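---
title: "Methods: covalent and allosteric kinase-inhibitor profiling with covkin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: covalent and allosteric kinase-inhibitor profiling with covkin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(covkin)
```

# Scope and model

covkin implements a desk-scale pipeline for profiling covalent protein
kinase inhibitors (CPKIs, compounds carrying an electrophilic
"warhead" able to bond a nucleophilic kinase residue) and allosteric
protein kinase inhibitors (APKIs, compounds binding outside the ATP
pocket) from two kinds of public evidence: curated bioactivity tables
(ChEMBL/BindingDB-style) and X-ray structures of kinase–ligand
complexes. The pipeline has seven analysis stages — compound
standardization, activity curation, warhead detection, analogue-series
decomposition, potency statistics, promiscuity profiling, and structure
triage — plus a deterministic synthetic-data generator that emulates
the statistical structure of the archival data so every stage is
testable without downloads.

Potency is carried throughout as `pPotency`, the negative decadic
logarithm of the molar measurement: a 10,000 nM record maps to 5.0, a
1 nM record to 9.0. All averaging and dispersion screening happens on
this log scale, matching the scale on which replicate variability is
thresholded.

# Compound standardization

Cross-database compound identity requires one canonical string per
molecule. The ordered protocol is: parse; keep the largest organic
fragment (most heavy atoms containing at least one carbon, ties broken
by the lexicographically smallest canonical SMILES); neutralize formal
charges wherever a valence-legal neutral protonation state exists
(quaternary nitrogens and other permanent charges are kept); strip
stereochemistry and isotope labels; emit the OpenBabel canonical form.
Neutralization is applied per fragment before selection; it only moves
hydrogens, so fragment ranking by heavy atoms is unaffected.
Tautomers are deliberately not merged — tautomer canonicalization is
unreliable enough that silently merging records would do more harm
than the duplicate identities it removes.

# Activity curation

A record must be an equality measurement (`relation "="`) of Ki, Kd or
IC50, at most 10,000 nM, from a single-kinase assay; ChEMBL records
must additionally come from direct binding assays (relationship type
"D") with assay confidence 9 and must not carry disqualifying comments
("uncertain", "potential transcription error", "outside typical
range") or contradictory active/inactive annotations. Filters are
evaluated in a fixed order (malformed record, units, relation,
relationship type, measurement type, potency cut-off, assay kinase
count, assay confidence, comment), and a rejected record reports the
first filter it failed, which makes rejection reasons deterministic
and the per-reason report reproducible. The non-potency field checks
run before the nanomolar cut-off because a value is only interpretable
once the measurement claim itself is admissible.

Replicates of one (compound, kinase) pair are averaged on the log
scale, with Ki/Kd taking priority over IC50 when both exist. A pair is
dropped when the sample standard deviation (n−1; zero for a single
record) reaches 1 log unit, or when the averaged potency falls below
the 10 µM equivalent (pPotency 5.0); the cut-off is applied per record
before averaging and once more on the mean so the curated table's
invariant (pPotency ≥ 5, sd < 1) is unconditional. Records lost to
either aggregate rule are counted as rejected, so kept plus rejected
always equals input.

# Warhead detection

Fourteen electrophile patterns are shipped: the twelve analyzed
warheads (aldehyde, alpha-haloketone, acrylate, alkynyl benzoate,
boronic acid, cyanoacrylamide, cyanamide, epoxide, reactive ester,
sulfonyl fluoride, terminal alkyne, vinyl sulfone) plus acrylamide and
heterocyclic urea, which are detected but routed to a separate
"previously studied" class and excluded from the covalent analysis
set. No published SMARTS exist for these definitions, so the defaults
are authored from the depicted warhead structures; each is validated
at load and any can be overridden or extended from a YAML/JSON config.
One source names the missing thirteenth class "alkynyl benzoxaxine"
where its figure says "alkynyl benzoate"; the library uses the
benzoate reading.

Nested motifs are resolved by a specificity rule: a match of a less
specific pattern is suppressed when it is accounted for by an
embedding of a declared more specific partner (cyanoacrylamide over
acrylamide, alkynyl benzoate over terminal alkyne, acrylate over
reactive ester). Because the matching backend exposes unique match
*counts* rather than atom maps, suppression compares counts: the
general pattern is dropped only when it has no more embeddings than
the specific one, so an independent second copy of the motif (for
example a separate plain acrylamide elsewhere in the molecule)
survives. On non-pathological chemistry this is equivalent to
embedding containment; a molecule with two overlapping motifs of the
same pattern at equal counts is the known corner case.

# Analogue series and pairs

Series are built by a compound–core decomposition: 1 to `max_cuts`
(default 3) acyclic single bonds are cut; the fragment holding the
largest ring assembly becomes the core, carrying one attachment point
per cut; every other fragment must hang off the core by exactly one
cut and becomes a substituent. Decompositions whose core has fewer
heavy atoms than twice the combined substituents are discarded, which
keeps cores dominant. Cuttable bonds are any acyclic single bonds
between heavy atoms — amide and ester bonds included, in the spirit of
retrosynthetic fragmentation schemes. Acyclic molecules have no ring
core and yield no decomposition.

Compounds sharing a byte-identical canonical core string form a
series; each compound joins at most one series, through its largest
shared core, and singleton cores form no series. Attachment points in
a core are ordered canonically by isotope-labelling each attachment in
turn and sorting the resulting labelled canonical strings;
symmetry-equivalent attachments tie arbitrarily, which is chemically
equivalent. Every decomposition is exactly invertible
(`reassemble_compound()` restores the member's canonical SMILES), and
the test suite asserts this round trip.

From each series, ordered (covalent, warhead-free) member pairs with
curated activity against the same kinase are emitted when the absolute
potency difference reaches `log10(min_fold)` (default 100-fold, i.e. 2
log units). The delta keeps its sign (covalent minus non-covalent), so
both gains and losses are admitted; a compound matching several
analyzed warheads contributes one pair record per warhead.

# Statistics

The global comparison pools curated pPotency values of the
non-covalent set against each warhead subset: one-way ANOVA
(`stats::aov`) followed by the Tukey–Kramer studentized-range post hoc
(`stats::TukeyHSD`), chosen in its unequal-group-size form because
warhead subsets differ widely in size. Pair-level comparisons use a
two-sided one-sample t-test of the signed deltas against zero. Each
curated (compound, kinase) mean contributes one value; best-potency
variants were considered and rejected as harder to reproduce.
Degenerate inputs are errors, not silent results: groups below two
members, empty distributions, and zero-variance delta sets all raise
typed conditions. Quartiles use the linear-interpolation convention
(type 7). Studentized-range p-values come from R's `ptukey`
integration; the k = 2 identity between the Tukey adjusted p and the
ANOVA p is asserted in tests at 1e-4, the accuracy of that integral.

# Promiscuity

A compound's promiscuity degree (PD) is its number of distinct kinase
accessions with curated activity, binned as PD 1, PD 2–4, PD 5–9, and
PD ≥ 10. PD is invariant to record order and multiplicity. Archival
promiscuity is bounded below by testing coverage — most inhibitors are
annotated with one or two kinases — so the per-class distributions
describe annotated activity only; the report carries this caveat
rather than attempting any coverage correction.

# Structure triage

An X-ray entry qualifies when its resolution is strictly below 3.5 Å,
it holds at least one qualifying ligand, and its title/keyword text
contains at least one of: "allosteric", "activator", "covalent",
"inhibit", "noncompetitive", "uncompetitive" (case-insensitive
substrings). Qualifying ligands are non-polymer components with at
least 6 heavy atoms that are not water or on the editable
ion/buffer/cryoprotectant exclusion list; polymer chains other than
the longest one are recorded as polymer ligand entities and count as
"large peptides" from 4 residues up (both limits configurable — the
field's practice for these judgments is visual and no printed
thresholds exist). Covalent links are read from PDB LINK records and
mmCIF `struct_conn` rows of covalent type, keeping those joining a
ligand atom to a polymer residue. Binding-site letters (A–L) and
ligand types (III, IV, V, VI, activator, multi-site) are accepted as
curated annotations in the record table; geometric site assignment and
the final visual adjudication of each complex are out of scope. The
shipped census tables aggregate a published structural survey:
per-type ligand counts against the prior survey's baseline, and the
thirteen structurally characterized covalent allosteric inhibitors.

# The synthetic generator

The generator defines the conditions the analysis is meant to recover:
analogue series enumerated from up to twelve kinase-inhibitor-like
scaffold templates (33–46 heavy atoms) with one varied substitution
site; a configurable fraction of members converted to warhead-bearing
analogues; a planted covalent potency gain of 2.0 log units over the
series' base potency (Normal(7, 1), truncated to ≥ 5); replicate
measurements with Normal(0, 0.3) log-unit noise, floored at the 10 µM
reporting cut-off (archives only carry qualifying measurements); a
72.5% single-kinase annotation fraction with a decaying tail over
higher promiscuity degrees; and optional per-filter corruption of
records for curation testing. Everything is seeded and byte-stable.

Two generator choices deserve explanation. First, substituents and
warhead moieties are chosen with pairwise distinct attachment
prefixes: under the largest-shared-core assignment rule, two analogues
whose substituents share a first atom (ethyl and propyl, say) would
share a one-atom-deeper core and splinter off a sub-series, so the
shipped substituent set (methyl, ethyl, amino, hydroxyl, F, Cl, Br,
thiol) avoids extendable shared prefixes. Second, scaffolds are drawn
from a fixed template list rather than generated randomly, because the
core-dominance rule requires cores at least twice the heaviest warhead
moiety (the nitrophenyl reactive ester carries 12 heavy atoms) and
random graphs do not guarantee valid, fragmentable chemistry.

What the generator does *not* emulate: real kinome topology and target
correlations, assay heterogeneity beyond log-normal noise, tautomeric
and salt-form diversity, multi-site substitution within one series,
and the scaffold diversity of real archives. Passing recovery tests
therefore demonstrates correctness of the pipeline's logic under the
stated statistical conditions, not fidelity of any particular archival
snapshot; dataset-level counts from specific database versions are
intentionally out of scope.

# Numerical and design notes

- **Recovery threshold.** The planted-effect recovery experiment
  extracts pairs at a 10-fold threshold rather than the analysis
  default of 100-fold. The planted mean gain (2.0 log units) sits
  exactly at the 100-fold cut, so extracting there would censor the
  lower half of the noise distribution and bias the recovered mean
  upward by about 0.8 standard errors; a threshold far below the
  effect leaves the estimate uncensored. The analysis threshold is
  separately exercised by asserting every admitted pair clears 2 log
  units.
- **Problem sizes.** Recovery runs use 12 series × 8 analogues with 3
  covalent members each (≈150–170 pairs) so the standard error of the
  recovered mean gain is ≈ 0.04 log units against a ±0.1 acceptance
  band; calibration uses 1000 null ANOVA replicates, giving a
  three-sigma band of ±2.1 percentage points around the nominal 5%.
- **Determinism.** Detection, decomposition and grouping are
  independent of input order and atom numbering (asserted by
  permutation tests); all simulation randomness flows from a single
  integer seed.
- **Known limitations.** Suppression by match counts (above); no
  tautomer merging; no mutant/wild-type target disambiguation;
  promiscuity is not coverage-corrected; mmCIF reading covers the
  categories the triage needs, not the full dialect.
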