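# plasmidforge

In-silico simulation and planning of modular CRISPR/Cas9 cloning workflows
for yeast metabolic engineering. Every wet-lab operation of a hierarchical
Golden Gate toolkit becomes a deterministic, verifiable operation on
annotated DNA sequences:

* **Type IIS / Golden Gate assembly** at three levels — entry parts into
  single-TU (promoter–gene–terminator) vectors, single-TU into multi-TU
  vectors — with one-pot semantics: the enumeration of every circular
  ligation product and the identification of the *stable* (recognition-site
  free) outcome, plus overhang-fidelity diagnostics.
* **Promoter and gene-disruption vector assembly** with fluorescent
  dropout screening (mScarlet/sfGFP) emulated as declarative product
  filters.
* **Homology-arm exchange** (AarI) between assembled and empty integration
  vectors — reversible by design — and irreversible TU transfer into
  disruption vectors.
* **Cre-lox marker excision** (lox66 × lox71 → lox72), modeling the
  Cre-expressing assembly host that converts any marker-based construct
  into its marker-free twin in one transformation.
* **Single-oligo recombineering** (λ-Red) that re-encodes the 20-nt spacer
  of a Cas9 helper plasmid with one 90-base oligonucleotide against an
  rpsL-kanR counter-selection cassette.
* **CRISPR target scanning and cut simulation** (NGG PAM, blunt cut 3 bp
  5′ of the PAM) and **homology-directed integration/disruption** of donor
  cassettes into a genome, with junction verification.
* **Promoter-strength normalization** of plate-reader / flow-cytometry
  fluorescence tables: parent-strain blank = 0 %, reference promoter
  (TEF1) = 100 %.

A seeded generator builds a complete synthetic mini-toolkit — a toy
6-chromosome genome with 16 named intergenic loci, entry vectors, all 80
empty integration vectors of the level/sublevel series, Zeta-flank
vectors, promoter-assay and deletion vectors, and an empty Cas9 helper —
so everything installs, runs and tests with no external data.

## The core model

A Type IIS enzyme cuts outside its recognition sequence at offsets
(t, b), leaving 5′ overhangs of length b − t. For a circular molecule
with k sites, digestion yields exactly k fragments; a fragment carries its
junction duplexes at both ends, and two fragments ligate iff the
right overhang of one equals the left overhang of the other (top-strand
sense). Conservation is exact: Σ(fragment length − overhang) = parent
length. A one-pot Golden Gate outcome is the set of circular products
with no remaining recognition site. Cre excision of a
`lox71–marker–lox66` circle is conservative recombination into a
marker circle (sealed by loxP) and a retained circle sealed by the inert
double-mutant lox72. Recombineering replaces the segment between two
unique 35-nt homologies with the oligo's central 20 nt. HR integration
replaces the genomic span between the inner edges of two unique 500-bp
homology arms with the donor cassette. Promoter strength is
100·(f − f_blank)/(f_ref − f_blank) per replicate, averaged.

## Worked example

```r
library(plasmidforge)

spec <- fixture_spec(seed = 1)            # 16 loci, 500-bp arms, 6 x 12-kb genome
tk   <- build_fixture_toolkit(spec)
syn  <- spec$syntax

# one-pot Lvl1 assembly: promoter + gene + terminator into an empty vector
l1 <- assemble_lvl1(tk$empties[["pE2US1.1"]], tk$entries[["pL0-TEF1"]],
                    tk$entries[["pL0-hrGFP"]], tk$entries[["pL0-TER1"]], syn)
#> [plasmidforge] assembled pE2US1.1-hrGFP (dropout screen passed)
l1
#> <dna_molecule> pE2US1.1-hrGFP: 2980 bp, circular, 10 feature(s)

# marker-free twin via the Cre host
mex <- cre_excise(l1, syn$lox)
mex
#> <cre_report> retained pE2US1.1-hrGFP_MF (2526 bp, lox72), excised pE2US1.1-hrGFP_excised (454 bp, loxP)

# integrate the marker-free donor at its locus and verify the junctions
edited <- simulate_integration(tk$genome$chromosomes, donor_from_vector(mex$retained))
#> [plasmidforge] integrated 1056-bp cassette at chrE:8000 (replaced 0 bp)
verify_junctions(edited, donor_from_vector(mex$retained))
#>             junction                                      seq count   ok
#> 1  left_arm/cassette ATCGCCCACTCGACACAGGCTTCACCTGCAAAACAGTTAC     1 TRUE
#> 2 cassette/right_arm ACGGTTGAAAAGCAGGTGTTTACTGGGTTGCAGTGTACAG     1 TRUE

# promoter assay: blank -> 0 %, reference -> 100 %
tab <- data.frame(strain = "s",
                  promoter = rep(c("blank", "TEF1", "PRO1"), each = 2),
                  medium = "YNBD", instrument = "plate_reader",
                  replicate = rep(1:2, 3),
                  fluorescence = c(100, 110, 1100, 900, 600, 480))
summarize_library(tab)
#>   promoter medium   instrument n_rep        rep1       rep2 mean_percent negative
#> 1    blank   YNBD plate_reader     2  -0.5586592  0.5586592      0.00000    FALSE
#> 2     PRO1   YNBD plate_reader     2  55.3072626 41.8994413     48.60335    FALSE
#> 3     TEF1   YNBD plate_reader     2 111.1731844 88.8268156    100.00000    FALSE
```

The numbers mean: the assembled 2980-bp Lvl1 plasmid carries the TU and
passed the fluorescent-dropout screen; excision removed the 454-bp
lox-flanked URA3 segment leaving a lox72 scar; integration added the
1056-bp marker-free cassette (lox72 scar + TU between the exchange
junctions) at the intergenic locus with both junctions single-copy; and
in the assay table the reference promoter averages exactly 100 % and the
parent-strain blank exactly 0 % while the test promoter reads ~48.6 % of
reference strength.

A command-line interface is installed with the package
(`exec/plasmidforge`): `fixtures-make`, `assemble-lvl1`, `assemble-lvl2`,
`assemble-pro`, `assemble-del`, `exchange-ha`, `excise-marker`,
`recombineer`, `scan-targets`, `design-grna-oligo`, `verify-helper`,
`design-ha`, `integrate`, `disrupt`, `name parse|make` and
`simulate-pipeline` (the whole campaign end-to-end, writing GenBank
products, the edited genome and a JSON report).

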