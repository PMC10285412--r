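# mitotriage

Structural triage of human mitochondrial rRNA variants.

Variants in the 12S and 16S mitochondrial rRNAs (genes *MT-RNR1* and
*MT-RNR2*) are frequently reported in hearing-impaired patients, yet most
lack any biochemical characterization, and sequence conservation is a poor
guide because many suspect positions are not conserved at all. The
operational criterion this package implements is structural: a base change
is **potentially non-silent** when the three-dimensional mito-ribosome model
shows it could distort secondary, tertiary or quaternary structure, ligand
binding or an inter-subunit bridge — enough, at minimum, to induce a
translational-fidelity phenotype. Variants whose base makes no interactions
that the substitution would lose (or whose change is isosterically
tolerated, e.g. a wobble/Watson–Crick exchange) are **silent**; positions
too disordered to judge are **unclear**.

The package is aimed at mitochondrial geneticists and structural
bioinformaticians who want this triage to be reproducible and auditable
rather than narrative: every verdict carries category codes
(`SEC`/`TER`/`QUAT`/`LIG`/`BRG`/`PROX`) and a rule-firing trace.

## What is inside

- **Coordinate mapping** between rCRS genomic positions (`m.1555A>G`) and
  gene-relative rRNA positions (`908A>G`), with the field's dual-label
  format (`908A>G (m.1555A>G)`).
- **Geometry engine**: mmCIF reading (via `bio3d`), heavy-atom
  hydrogen-bond detection with the published tolerances (distance slop
  0.400 Å, angle slop 20°), water-mediated bridges, base-pair detection and
  classification (Watson–Crick / wobble / non-canonical / mismatch),
  secondary-vs-tertiary partition against a pairing map, Kabsch rigid
  superposition, and tiered protein/ligand/bridge contact evidence.
- **Triage rules** converting evidence into a silent / non-silent / unclear
  verdict with an explicit precedence (disorder → disruptive losses →
  heterologous tolerance → tolerated changes → unclear).
- **A curated 92-variant evidence table** (83 SSU, 9 LSU) for the
  deafness-associated cohort, replayable without any structure download.
- **A synthetic-structure generator** (ideal A-form duplexes with planted
  Watson–Crick, wobble and mismatch pairs, bridging waters, probe peptides
  at controlled gaps) so every geometric stage is testable offline.

## Worked example

```r
library(mitotriage)

dual_label("m.1555A>G")
#> [1] "908A>G (m.1555A>G)"

rp <- replay_pipeline()            # curated evidence, no downloads
s  <- summarize_verdicts(rp)
s$non_silent; s$silent; s$unclear
#> [1] 49
#> [1] 41
#> [1] 2
s$categories
#>  SEC  TER QUAT  LIG  BRG PROX
#>   27   16   26    8    8   28
s$haplotype
#> $total
#> [1] 33
#> $non_silent
#> [1] 17
```

Those numbers read: of the 92 cohort variants, 49 are potentially
non-silent and 41 silent (2 unclear); among the non-silent, 27 touch
secondary structure, 16 tertiary, 26 quaternary, 8 ligand binding, 8
inter-subunit bridges, and 28 sit near early-binding or
pathogenic-mutation-harboring proteins; 17 of the 33 haplotype markers are
potentially non-silent.

Geometry mode runs the same rules on coordinates. On a synthetic scenario:

```r
sc  <- make_scenario("wc_disruption")
res <- run_pipeline(sc$variants, sc$model, sc$registries, sc$map)
res$verdicts[, c("label", "categories", "verdict")]
#>               label categories    verdict
#> 1 152U>C (m.799U>C)        SEC non_silent
```

For a real structure, point `run_pipeline()` (or the `exec/mitotriage run`
command line) at a locally downloaded mmCIF, a variant TSV, the packaged
registries (`default_registries()`; fill in the chain-id map for your copy
of the structure) and the packaged 12S map (`default_secondary_map()`).
`spot_check_structure()` compares the published atomic distances (3.217 Å
and 2.39 Å) against such a local model.

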