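---
title: "Sequence-level simulation of modular CRISPR/Cas9 cloning workflows"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sequence-level simulation of modular CRISPR/Cas9 cloning workflows}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plasmidforge)
```

## What the package models

`plasmidforge` turns the wet-lab operations of a modular yeast
metabolic-engineering toolkit into deterministic, verifiable operations on
annotated DNA sequences. Every operation consumes and produces
`dna_molecule` objects — sequence, circular/linear topology, and a feature
table in 0-based half-open coordinates — so a whole engineering campaign
(part entry vectors → single-TU vectors → multi-TU vectors → homology-arm
exchange → marker excision → guide-RNA re-encoding → genome integration)
can be executed and checked in silico before any DNA is ordered.

The simulated chemistry is of four kinds:

1. **Type IIS digestion and sticky-end ligation** (`digest()`,
   `ligate_cyclic()`, `golden_gate()`): enzymes cut at a fixed offset
   outside a non-palindromic recognition sequence, leaving single-stranded
   overhangs; ligation joins fragments whose overhangs are
   reverse-complementary.
2. **Site-specific recombination** (`cre_excise()`): Cre resolves a
   circular molecule carrying directly repeated lox66/lox71 sites into two
   circles, each sealed by a hybrid site.
3. **Short-homology recombineering** (`lambda_red_replace()`): a 90-base
   oligonucleotide with 35-nt terminal homologies replaces whatever lies
   between its two annealing sites with its central 20 nt.
4. **Homologous recombination in the genome**
   (`simulate_integration()`, `simulate_disruption()`): a donor cassette
   flanked by two homology arms replaces the genomic span between the
   arms' inner edges.

## The one-pot Golden Gate model

A one-pot reaction cycles digestion and ligation. Products that still
contain a recognition site are re-cut; products without one accumulate.
The simulator therefore enumerates *all* circular ligation products of the
fragment pool (each input fragment used at most once per product; dimeric
products are outside the default model) and calls **stable** exactly those
free of the enzyme's recognition sequence on either strand. No kinetics,
ligation-fidelity tables, star activity or methylation sensitivity are
modeled: a junction either matches perfectly or does not exist. Hazards a
bench scientist would worry about — duplicated overhangs, palindromic
overhangs, reverse-complement collisions between junctions — are surfaced
as warnings by `fidelity_check()` and by every `golden_gate()` report, but
never change the enumeration.

Fragment bookkeeping uses one convention worth stating: a fragment's `seq`
is the top strand from the top-strand cut on its left to the
bottom-strand cut on its right, so the 4-nt junction duplex appears at
both ends, `left_ov` as prefix and `right_ov` as suffix, both written in
top-strand sense. Two fragments join iff `A$right_ov == B$left_ov`, and a
junction's bases are counted once in the product. This makes the
conservation law exact — for a circular input the fragment lengths minus
one overhang each sum to the parent length — and the tests assert it
exactly, not approximately.

## The part grammar

The toolkit grammar lives in a `syntax_config` (serialisable to YAML), not
in code. The defaults are:

* **Enzymes.** Entry-level assembly uses a BsaI-class enzyme (GGTCTC, 1/5),
  Lvl1→Lvl2 assembly a BsmBI-class enzyme (CGTCTC, 1/5), and homology-arm
  exchange AarI (CACCTGC, 4/8). The grammar names three enzymes rather
  than two because a Lvl1 product must be inert to the enzyme that made it
  yet digestible for the next level — the standard alternating-enzyme
  design of hierarchical Golden Gate systems.
* **Junctions.** Fourteen 4-nt overhangs: four TU-internal junctions
  (vector–promoter, promoter–gene, gene–terminator, terminator–vector),
  four Lvl2 positional junctions, two exchange junctions flanking the
  central section, and four deletion-vector junctions. The concrete 4-mers
  are config data chosen to pass `fidelity_check()` with zero warnings;
  any published set can be substituted without touching code.
* **Vector naming.** `pE8US1.1` encodes chromosome E, locus 8, URA3
  marker, spectinomycin resistance, level 1, sublevel 1; `Z` replaces
  chromosome+locus for Zeta (random-integration) flanks. Lvl1 sublevels
  1–3 encode the TU's position in a later Lvl2 assembly; Lvl2 sublevels 2
  and 3 encode capacity. A Lvl2.2 acceptor closes directly at the
  position-3 junction, so the sublevel-1.2 donor's right junction serves
  as its terminal junction — no filler part is used.

Three structural choices define the integration-vector architecture:

* The two exchange-enzyme (AarI) recognition sites of every integration
  vector sit on the **backbone** side of their cuts. Digestion therefore
  separates a site-free central section (marker + TUs) from a
  site-carrying backbone (origin, resistance, homology arms). An exchange
  between an assembled and an empty vector yields products that retain
  both sites — which is exactly what makes the exchange *reversible* — so
  `exchange_has()` selects its product not by site-freeness but by the
  screen used at the bench: the empty vector's antibiotic resistance plus
  loss of the sfGFP reporter. The reciprocal product is returned too,
  flagged.
* The deletion-vector series carries its AarI sites **inside** the
  lox-flanked marker dropout. Transferring a TU section into an assembled
  deletion vector therefore yields a site-free, stable product:
  the transfer is irreversible, and `transfer_to_del()` can use the plain
  stable-product rule.
* Empty vectors carry both fluorescent reporters (mScarlet and sfGFP)
  inside the entry-level dropout, so every correct assembly is screenable
  by loss of fluorescence (`dropout_check()`), and the arm exchange is
  screenable by loss of sfGFP specifically.

## Cre-lox marker excision

The four lox sites are 34 nt: 13-nt arms around the 8-nt asymmetric spacer
that defines directionality. Defaults are the standard literature
sequences (lox66 right-arm mutant, lox71 left-arm mutant), overridable in
`lox_config()`. Excision is modeled as conservative recombination: for a
circle `... lox71 – marker – lox66 – backbone ...` the backbone circle is
sealed by left-arm(lox71)+spacer+right-arm(lox66) — the inert double
mutant lox72 — and the marker circle by the wild-type loxP. The two
product lengths sum exactly to the input length; the retained product is
the one carrying the replication origin or resistance. Fixtures place
lox71 upstream of the marker so the retained hybrid is lox72; the
`retained_hybrid` config field states the expectation and a warning is
raised if an unusual arm arrangement yields the other hybrid. Inversions
(sites in opposite orientation) are refused rather than modeled.

## Recombineering and guide-RNA re-encoding

`design_oligo()` reads the 35-nt flanks directly off the helper plasmid
around its annotated spacer slot (the rpsL-kanR counter-selectable
cassette on an empty helper, or the current 20-nt spacer on a re-encoded
one), so `lambda_red_replace(helper, design_oligo(spacer, helper))` always
inserts exactly the spacer and always passes `counterselect_check()`.
Homology matching is exact; a mismatch-tolerance knob was deliberately
omitted because recombineering efficiency collapses with mismatches and a
sequence-level simulator should not suggest otherwise. Oligo strand is
ignored (either orientation is accepted): lagging-strand preference
affects efficiency, not product sequence. The replaced arc must be the
minor arc of the circle — replacing the arc that carries the rest of the
plasmid means the homologies were given in the wrong order.

Protospacer scanning is deliberately minimal: all 20-mers adjacent to an
NGG (configurable) PAM on either strand, with the blunt cut 3 bp 5′ of
the PAM (between spacer bases 17 and 18, canonical SpCas9). No on-target
activity scores and no off-target search beyond uniqueness of the target
within the supplied sequence: the simulator answers "where would Cas9
cut", not "which guide is best".

## Homologous recombination in the genome

Integration is exact double-crossover replacement: both arms must match
the genome uniquely (genome-wide), on one strand, in order; the span
between their inner edges is replaced by the cassette. A donor whose arms
match the minus strand is flipped and integrated identically. NHEJ,
indels, partial homology and repeat-mediated rearrangement are out of
scope — in the emulated workflow those phenomena affect *selection*, not
the sequence of a correct integrant. `verify_junctions()` is the
in-silico stand-in for junction colony PCR: each arm/cassette junction
(20 bp each side by default) must occur exactly once in the edited
genome. Telomere truncation is representable as an integration whose
right arm lies at a chromosome end with an empty distal segment; it is a
recipe, not a dedicated operation.

## Promoter-strength normalization

Readings are grouped into batches by medium + instrument, and
normalization never crosses batches. Within a batch the blank level is
the mean of the parent-strain rows and the reference level the mean of
the reference-promoter rows; each sample replicate is normalized
individually as `100 * (f - blank) / (ref - blank)` and replicates are
then averaged — the reference promoter's own mean is exactly 100% and the
blank's exactly 0% by construction. Whether to average replicates before
or after normalization was an open choice; normalizing first matches the
replicate-wise presentation of such assays and keeps the affine-invariance
property exact per replicate. Sub-blank values are reported as-is with a
`negative` flag, never clipped: they are informative noise. No
significance machinery is attached — the assay is descriptive.

## The synthetic fixture generator

`build_fixture_genome()` and `build_fixture_toolkit()` generate, from one
seed, a toy 6-chromosome genome (12 kb per chromosome, 16 named
intergenic loci, three planted 600-bp ORFs as disruption targets) and the
full plasmid complement: one entry vector per part, five empty
integration vectors per locus (sublevels 1.1–2.3, 80 for the default 16
loci) plus a Zeta series, the promoter-assay vector, the dual-reporter
deletion vector and the empty Cas9 helper. Homology arms are 500 bp, the
arm length the emulated toolkit standardises on.

Two implementation details make generation robust for *every* seed, not
just tested ones. First, random segments are scrubbed of the six
recognition motifs in play by deterministically mutating the middle base
of any occurrence. Second, none of those motifs starts with T, ends with
T, or contains TT — so every random segment is generated with terminal
`TT` guards, and no recognition site can ever arise across a segment
boundary. Fixed cassette elements are validated once per grammar by
site-count assertions at build time.

What the fixtures deliberately do **not** emulate: real promoter/gene
sequences (parts are labelled random DNA), codon structure in planted
ORFs (they are positional stand-ins), chromosome-scale features
(centromeres, repeats, GC skew), and any notion of reaction efficiency.
Tests passing on these fixtures therefore demonstrate the *combinatorial
and sequence-arithmetic correctness* of the operations — conservation
laws, inverse laws, product uniqueness, junction fidelity — not
performance on genomic DNA with repetitive content, where arm uniqueness,
spacer uniqueness and motif scarcity must be checked rather than assumed.

## Numerical and problem-size choices

All coordinates are 0-based half-open, circular positions reduced modulo
length, so cut arithmetic has no off-by-one ambiguity. Circular products
are compared through their canonical form (lexicographically minimal
rotation over both strands), making product identity well-defined and
order/rotation-invariant. Ligation enumeration is exhaustive over
single-use fragments (optionally capped dimers); the test suite
cross-checks it against a brute-force permutation/orientation oracle for
pools of up to 5 fragments. The suite exercises full-size fixtures (12-kb
chromosomes, 2.5–5-kb plasmids, the complete 80-vector series) — the
operations are fast enough that no scaled-down shadow configuration is
needed; end-to-end pipeline runs complete in seconds.

## Known limitations

* 3′-overhang Type IIS enzymes are not supported (the built-in grammar
  needs none); blunt ligation is off by default.
* GenBank output is a minimal flat-file dialect (LOCUS topology, features
  with `/label`, origin-spanning features as two-segment joins). It
  round-trips itself exactly and reads well-formed external files, but
  exotic location syntax (`order()`, remote references) is out of scope;
  unknown feature keys are mapped by a user-extensible heuristic table
  and every heuristic mapping is logged.
* Cre inversion (inverted repeats) and multi-site substrates are refused,
  not modeled.
* Integration requires genome-wide arm uniqueness; multi-copy or Zeta
  random integration is representable only by supplying the concrete
  target site.
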