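---
title: "Deriving and mining ligand-contact signature motifs"
author: "cofsig"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Deriving and mining ligand-contact signature motifs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cofsig)
```

## The model

`cofsig` formalises a simple, structure-anchored definition of functional
membership in a cofactor-binding family: a sequence is a candidate for
the reference's function when it carries, in order and at compatible
spacings, the residues that both contact the cofactor in the reference
complex and are conserved across known functional homologs. The central
artifact is the **spaced signature**

$$E_1 \; \{g_1^{min}, g_1^{max}\} \; E_2 \; \cdots \; E_k$$

where each element $E_i$ is a short pattern over the 20 amino-acid
letters plus the wildcard `x` (e.g. `GxxW`), and each adjacent pair is
separated by a bounded number of residues. This is a deterministic,
binary filter in the PROSITE-pattern tradition, not a probabilistic
profile: the reference application — distinguishing the few
light-responsive cobalamin-binding domains from the mass of
light-independent cobalamin enzymes — calls for a crisp, auditable rule
tied to specific chemistry (the tryptophan packing against the adenosyl
group, the glutamate/histidine pair, the corrin-facing glycines, the
axial histidine below the cobalt).

The assumptions are explicit. First, author residue numbering of the
reference is the single coordinate system: contacts, conservation
columns and signature anchors are all expressed in it. Second, the
binding mode of the cofactor is conserved within the functional
subfamily, so contact residues in the reference are informative about
homologs. Third, homology models of true functional analogues stay close
to the reference backbone, so a Cα RMSD gate removes structural
outliers without modelling binding energetics.

## Stages and their parameters

**Tree gate** (`classifyByClade`). "Same branch as the reference" is not
self-defining, so two operationalisations are provided and the choice is
stamped into every output: (i) *negatives rule* — root the tree on the
edge leading to the most recent common ancestor of user-supplied
negative leaves; a query passes when the smallest clade containing it
and the reference holds no negative; (ii) *distance rule* — patristic
distance to the reference at or below a threshold (branch-length units).
With a single negative used as the root outgroup the negatives rule
cannot exclude anything (every reference clade excludes the root), which
is the expected behaviour for a star-like input; exclusion becomes
meaningful when queries nest inside the negatives' clade. Trees come
from external maximum-likelihood runs ingested as newick, or from the
in-package route: uncorrected (or Poisson-corrected) p-distances over
shared non-gap columns followed by neighbor joining, which is exact on
additive matrices — sufficient for the classification contract, and
fully testable offline.

**Structural gate** (`rmsdFilter`, default cutoff 2.0 Å). Models are
paired to the reference by global sequence alignment (BLOSUM62, gap open
10, extend 0.5) — models share their sequence with the reference by
construction, so sequence pairing is better defined than spatial
pairing. Superposition is the closed-form Kabsch solution (SVD with
determinant correction; reflections never returned). The RMSD is
computed over the aligned, paired region (Cα by default; an N/CA/C/O
backbone mode exists for dark/light comparisons of the same protein).
Pairings covering less than 60 % of the shorter chain are treated as
divergence and rejected outright rather than scored.

**Contacts** (`findContacts`, default cutoff 4.0 Å, heavy atoms only).
The cutoff is the standard heavy-atom contact convention wide enough to
capture both hydrogen bonds and hydrophobic packing; no explicit
hydrogen-bond geometry test is applied in this version — the
mainchain/sidechain flag and the ligand-atom list per contact are
deliberately simple, auditable approximations. Contacts may come from
any chain (binding pockets frequently span protomer interfaces), and the
chain is retained in every record. The lower axial metal ligand is
located separately (`axialLigand`): the protein heavy atom nearest the
(single) metal within 3.0 Å; "no residue within range" is a valid
result distinct from an error. For docked ensembles, contacts may be
taken from the best-scoring pose or aggregated as per-residue
frequencies (`contactFrequency`); both modes exist because either is a
defensible reading of ensemble output, and neither is asserted as
canonical.

**Docking geometry** (`dockingBox`). The box is cubic with edge
`ratio × Rg` (default ratio 1.0) centred on the ligand centre of mass.
Rg is computed unweighted about the geometric centre — the coordinate-only
convention of docking-box sizing scripts — while the centre is
mass-weighted; the two centres can differ and both definitions are
documented where they are used. A mass-weighted Rg is available behind a
flag. Docking itself is an adapter boundary: the box is written as
engine-neutral `key = value` lines, poses return as ligand-only PDB
files with scores, and engine settings are recorded as metadata only.

**Conservation** (`columnConservation`). The score is the
modal-residue fraction: count of the most common non-gap residue over
non-gap rows. It is the simplest metric consistent with "conserved
contact residue", trivially bounded in [0, 1], and exactly testable
against planted column frequencies; phylogeny-aware scores are out of
scope. Columns with more than 50 % gaps are masked to 0 — they reflect
indel structure, not substitution signal. The threshold τ for calling an
anchor conserved defaults to 0.8 and is an explicit, reported parameter:
there is no principled universal value, and the derived signature should
always be read together with its τ.

**Signature derivation** (`deriveSignature`). Anchors = contact
positions with conservation ≥ τ. Anchors at most `merge_gap = 4`
residues apart merge into one element, intervening positions rendered
`x`; the default of 4 is chosen so that a `G...P` pair four residues
apart forms a single `GxxxP`-shaped element rather than two fragments.
Elements never begin or end with `x` (leading/trailing wildcards are
absorbed into the gap ranges), which makes `GxxW` the canonical
rendering. Gap ranges widen the observed reference separation by ± 25 %
(rounded, at least 1 residue): family-scale homologs do not preserve
exact loop lengths, and the tolerance is configurable and recorded in
the signature's JSON sidecar together with τ, the contact cutoff and the
source structure id.

**Matching and mining** (`matchSignature`, `scanDatabase`). A hit
requires every element, in order, within its gap window — a binary
filter with no partial-credit scoring (a `min_elements` relaxation
exists but defaults to all elements). Among multiple placements the
lexicographically smallest vector of element starts is reported
("leftmost-tightest"), found by depth-first search with failure
memoisation — a greedy earliest-fit is not sufficient because an early
placement can make later windows infeasible. The scan streams FASTA in
chunks, so memory is constant in database size. Hits are clustered
greedily in CD-HIT style (length-descending, ties by id; each sequence
joins the first representative at or above the identity threshold,
default 0.8) using exact global-alignment identities — no k-mer
prescreen, which is acceptable at the ≤ 10^4-sequence scale this package
targets. Because "n sequences after clustering" is ambiguous between
sequences and clusters, pipeline summaries report both counts. The SSN
weights edges by global percent identity (the metric name is stamped
into the export header) and keeps edges at or above the threshold
(default 40 %).

**Percent identity.** One definition is used everywhere and recorded in
every report: identical aligned pairs divided by alignment columns,
excluding columns gapped in both rows, after global alignment with
BLOSUM62/10/0.5. Published identity figures for this family were
produced by unspecified aligner settings, so comparisons against them
carry a ±3-point tolerance rather than a tighter one.

## What the generators emulate — and what they do not

`generateFamily` emulates a functional subfamily against a decoy
background: positives are i.i.d. uniform 20-letter sequences with each
anchor written at its reference offset with probability equal to the
per-anchor conservation; decoys are rejection-sampled uniform sequences
that do not match the signature (with a hard attempt cap, so an overly
permissive signature fails loudly rather than looping). The truth table
(ids, planted offsets) suffices to score precision and recall of the
entire pipeline without re-deriving anything. `generateToyComplex`
emulates a binding pocket with exact geometric ground truth: each
planted contact has one side-chain atom 3.0–3.9 Å from the nearest
ligand atom, the axial histidine's NE2 sits exactly 2.2 Å from the
metal along a direction chosen to clear the other ligand atoms, and all
other residues stay beyond 6 Å; the construction is audited after
generation and fails rather than silently violating its guarantees.
`generateConservationFixture` plants exact per-column modal counts so
conservation scoring can be checked to machine precision.

These fixtures are deliberately unphysical: residues are schematic
five-atom stubs on a sphere with no rotamers, sterics or secondary
structure, background sequence composition is uniform rather than
natural, and positives share exact anchor offsets with no indels.
Passing tests therefore demonstrate algorithmic correctness — contact
detection equals an all-pairs scan, the scanner equals placement
enumeration, the pipeline recovers a planted signal exactly — not
robustness to real structural noise, compositional bias or alignment
error. The checks against real published structures and sequences play
that complementary role and require the public files described in
`inst/extdata/reference_data/`.

All generators are pure functions of their seed: one explicitly seeded
Mersenne–Twister stream per call, with the caller's RNG state restored,
so identical seeds give byte-identical artifacts.

## Numerical choices and degenerate inputs

Superposition requires at least three non-collinear pairs; collinear
input is rejected (the optimal rotation is not unique) with a rank test
at relative tolerance 1e-8. Rotation validity (orthonormality,
determinant +1) is enforced to 1e-9 in the result class. Neighbor
joining clamps negative branch lengths to zero with a warning. A
single-atom ligand has Rg 0 and therefore no valid docking box — a
degenerate-box error, not a zero-size box. Alternate locations keep the
lowest-sorting altloc identifier per atom site (deterministic, usually
`A`); hydrogens are parsed but excluded from all geometry; atomic masses
come from a standard periodic table and an unknown element is an error,
never a default mass. Water is never extractable as a ligand. Signature
text parsing reports the character position of the first violation; the
text form drops reference anchoring, which the JSON sidecar restores.

## Problem sizes in the test suite

The suite runs entirely on synthetic fixtures at sizes chosen to keep
the oracles exact and the feedback loop fast: 100 random 5–8-point
instances for superposition against a dense rotation-grid search
(agreement within 1e-4 Å), 200 random pairs of 3–8-mers for alignment
against exhaustive path enumeration, a 500-row alignment for
conservation, a 50-positive/200-decoy family for mining, and 8-leaf
additive trees for neighbor joining (patristic recovery within 1e-9).
These sizes are where brute-force enumeration is still exact; the
algorithms themselves have no size-dependent switches.

## Known limitations

- The signature is a hard pattern: a single substituted anchor in a true
  homolog is a miss. Profile or HMM scoring is intentionally out of
  scope.
- Contact detection is distance-only; no interaction typing
  (π-stacking, water-mediated bridges) is attempted.
- Greedy identity clustering is order-dependent by design
  (length-descending) and uses all-pairs alignment, which scales
  quadratically.
- The in-package tree route (p-distance + NJ) is a testable stand-in for
  external maximum-likelihood phylogenetics; model selection and
  bootstrap support belong to the external tool whose newick output the
  package ingests.
- Homology modelling and docking are adapter boundaries: the package
  validates and consumes their outputs but never executes the engines.
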