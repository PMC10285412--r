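---
title: "Structural triage of mitochondrial rRNA variants: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Structural triage of mitochondrial rRNA variants: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mitotriage)
```

## The procedure and its assumptions

The package asks one question per variant: could this base change, judged
from a high-resolution mito-ribosome model, distort structure enough to
produce at least a translational-fidelity phenotype? That is deliberately a
low phenotypic bar — fidelity defects in ribosomes are often well tolerated
and surface only under stress (the classic examples being the two proven
ototoxic 12S variants, which convert a native C•A mismatch at the
aminoglycoside site into a canonical pair). Three assumptions follow:

1. **Base substitutions leave the backbone alone.** Only interactions made
   through base atoms can be *lost* by a substitution; sugar/phosphate
   contacts can at most be *distorted* indirectly. The atom-retention rule
   (`atom_retained()`) codifies this: a bond made through atom X of the
   reference base survives iff the alternate base carries X in the same
   donor/acceptor role (U O2 survives U>C; U O4, G N2 and A N6 do not; G
   N1 flips from donor to acceptor across G>A and counts as lost).
2. **Isostericity decides pair substitutions.** Watson–Crick to mismatch is
   disruptive; Watson–Crick to wobble is tolerated inside a helix but
   disruptive at a terminal pair or when it creates a U•G/G•U tandem;
   wobble to Watson–Crick is tolerated; a native mismatch replaced by a
   canonical pair is disruptive (the stabilizing, ototoxic direction). This
   is a small curated lookup, not a full Leontis–Westhof matrix; it covers
   exactly the configurations the triage rules need.
3. **The secondary-structure map is authoritative.** Any base-mediated
   RNA–RNA contact not present in the map is tertiary, including pairs that
   are canonical in 3-D but single-stranded on the map.

## Verdict rules

`decide_verdict()` applies a fixed precedence, and records each fired rule:

1. disordered position with no usable geometry → *unclear*;
2. disruptive pairing change, lost direct base-mediated tertiary or
   quaternary bond, bridge membership, a ligand contact involving the base
   (water-mediated counts — ligand coordination is often solvated), or any
   pairing change inside a bridge region → *non-silent*;
3. heterologous-equivalent base tolerated and only water-mediated or
   backbone-level interactions affected → *silent*;
4. tolerated pairing change, or all base interactions retained, or no
   interactions at all away from flagged proteins → *silent*;
5. otherwise → *unclear*.

Rule 2's bridge clause reflects the biology of inter-subunit bridges:
mutagenesis of bridge residues produces growth and fidelity defects, so
even an isosterically "tolerated" wobble exchange inside a bridge region is
kept non-silent. Context-dependent pairing effects (a wobble created next
to a polymorphic neighbor pair) resolve under the annotated haplotype
allele, and both context verdicts are reported in the effect's notes — this
makes haplotype sensitivity explicit rather than averaged away.

Proximity to a flagged protein (`PROX`) is evidence but never a verdict
trigger on its own: a base with no structural handle near MRPS12 stays
*unclear*, not non-silent.

## Hydrogen-bond detection

Models carry no hydrogens, so detection is a heavy-atom proxy with three
criteria, all configurable in `hbond_params()`:

- donor–acceptor distance ≤ ideal (3.3 Å) + slop (0.400 Å);
- antecedent–donor–acceptor angle ≥ ideal (120°) − slop (20°), skipped for
  donors with no unique antecedent (water);
- for sp2 nucleobase donors, the acceptor must lie within 35° of the
  donor's base plane, because the donated hydrogen is constrained to that
  plane. Without this test, stacked neighbors in a helix (vertical
  separation ≈ rise) regularly pass the distance and antecedent-angle
  criteria while being chemically unreachable.

The two slops are the published protocol's tolerances; the single ideal
distance and the heavy-atom antecedent angle are this package's explicit
approximation to per-chemistry criteria (the original analysis used a
chemistry-aware desktop tool whose per-donor ideals are not stated).
Intra-residue pairs and sequence-adjacent backbone–backbone contacts are
excluded by default. Detection is monotone in both slops and invariant
under rigid motion, and both properties are tested.

Ligand chemistry uses a generic fallback (every O both donor and acceptor,
every N donor and acceptor), which overestimates donors for ligands such as
NAD; since ligand evidence only asks whether a contact exists at a tier,
this is conservative in the right direction.

## Base pairs, tiers and bridges

Pair detection accepts candidates with C1′–C1′ distance in 8.5–12.0 Å, at
least 2 base–base bonds (1 for wobble/non-canonical candidates), and
inter-base-plane angle ≤ 30°; each residue keeps its best-scoring canonical
pair. These thresholds are not from any publication — they are chosen to
accept canonical A-form geometry generously and are validated against the
generator's ground truth (precision = recall = 1 on every fixture).

Contact tiers codify informal distance language: hydrogen-bonding ≤ 3.7 Å,
packing ≤ 4.5 Å, proximity ≤ 6.0 Å, neighborhood ≤ 15.0 Å. They are nested
by construction and pinned by the curated-table reproduction. When
attributing protein contacts to a variant, the query neighborhood includes
the pair partner and the two sequence neighbors, mirroring how structural
descriptions credit a variant with contacts made one step away. Bridge
status is *member* when the position is in the registry's residue set, and
*neighborhood* when it lies within the proximity tier of a member residue
in the structure.

## The curated evidence table

`curated_variants()` ships 92 rows (83 SSU, 9 LSU) of per-variant evidence
fields, annotations and verdicts for the deafness-associated cohort.
Replay mode (`replay_pipeline()`) pushes each row's evidence through the
same `assign_categories()`/`decide_verdict()` engine used in geometry mode,
so the cohort-level counts are an output of the rules, not a lookup.

Provenance is explicit per row. `text` rows are curated from the published
results narrative. `inferred` rows (one non-silent, 26 silent SSU, 8 silent
LSU) are **synthetic stand-ins** for entries that exist only in the
original supplementary listing: they preserve the published cohort
composition (row counts, subunit split, source and haplotype totals) but
are not traceable to a named variant description and must not be cited
individually. Two judgment calls are also flagged in the table's notes: the
two *unclear* rows are the positions whose published discussion most
directly supports an indeterminate call (one for local disorder, one for a
base with no structural handle near a fidelity protein), and two haplotype
flags among the non-silent rows rest on population-frequency language
rather than an explicit marker statement.

## The synthetic-structure generator

`build_duplex()` assembles idealized planar nucleobase templates (regular
ring polygons with standard-length exocyclic extensions) into helices with
rise 2.8 Å and twist 32.7°/bp. Two liberties keep the fixtures clean
without affecting what they test. First, the pair plane is displaced from
the helix axis and inclined by 10° (as in real A-form helices, where pairs
wrap around the axis); the exact values were chosen so that the full
hydrogen-bond inventory of a duplex equals the planted set and nothing
else. Second, the sugar/phosphate pseudo-backbone sits on an outer cylinder
well outside the base shell: it provides donor/acceptor-complete backbone
atoms at usable positions while never entering hydrogen-bond range of a
base. Only the designated bond distances (2.8–3.0 Å for planted pairs) are
guaranteed — the fixtures exercise detection logic, not force fields — and
the generator verifies its own bond inventory at build time, aborting if a
planted pair does not produce its designated count. Waters are placed
analytically on the perpendicular bisector of their two targets; probe
peptides are translated along an outward axis until the minimum heavy-atom
gap matches the request within 0.01 Å. Generation is seed-deterministic and
byte-stable.

What passing synthetic tests does *not* show: performance on modified
nucleotides, non-ideal geometry of real loops and bulges, or crowded
ribosome interiors where the generous pair-detection window could admit
ambiguous candidates. Those are exactly the situations the optional
real-structure spot checks (`spot_check_structure()`) exist for; the
deposited coordinate files are never required for build or test.

## Numerical choices and degenerate inputs

- Kabsch superposition uses base-R SVD with determinant correction, so a
  reflection is never returned; fewer than 3 paired atoms is an error.
- Minimum residue distances are computed as vectorized all-pairs minima —
  the brute-force semantics directly, cross-checked in tests against an
  independent double loop. A spatial index would be a pure optimization at
  the problem sizes the package handles (per-variant queries against
  single chains) and is deliberately omitted.
- Altlocs collapse to the highest-occupancy copy with a warning; unicode
  primes in atom names are normalized to ASCII; DNA-alphabet input (T) is
  canonicalized to RNA (U) while output labels keep the input alphabet.
- Ties in pair detection break toward more bonds, then toward C1′–C1′
  distance closest to 10.4 Å; the scan order never affects the result.
- A variant at an unmodeled position yields evidence with the disorder flag
  set and empty geometry fields; an unmappable label becomes a row-level
  error that does not abort the run.

## Problem sizes

The test suite and the replay pipeline run on in-memory fixtures: duplexes
of 3–8 base pairs (about 100–300 atoms), scenario structures of the same
scale, and the 92-row curated table. These sizes were chosen because every
property being tested (bond inventories, pair recovery, tier arithmetic,
rule precedence) is scale-free; nothing in the engine behaves differently
at chain length 954 beyond running longer.

## Known limitations

- The hydrogen-bond model is a single-ideal-distance proxy; per-chemistry
  ideals would shift borderline contacts by tenths of an Ångström.
- The packaged 12S secondary map covers the positions the curated table
  uses, not the full molecule; pairs read off the published map image
  without textual confirmation carry `provenance = inferred`.
- The chain-id map for deposited structures is a template by design: chain
  letters must be checked against the local copy before geometry-mode runs
  on real models, and whether the deposited 16S author numbering matches
  gene-relative positions should be verified against the exhibited
  588/2258 and 941/2611 coordinate pairs.
- Geometry mode measures factor distances in whatever frame the supplied
  model is in; for factor-bound structures the intended workflow is to
  superpose onto the reference model first (`superpose_kabsch()` with the
  fidelity protein as the reference chain), matching the original
  protocol's choice of the superposed frame.
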