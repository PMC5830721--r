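---
title: "Mining labile disulfide bonds: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining labile disulfide bonds: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(disulfidr)
library(dplyr)
```

## The problem

Most disulfide bonds are inert structural staples. A minority are *labile*:
the same cystine is oxidized (bonded) in some X-ray structures of a protein
and validly reduced in others. Lability is an operational proxy for
*allosteric* function — a redox switch whose cleavage changes what the
protein does. `disulfidr` implements the mining pipeline that finds such
bonds in a local corpus of legacy-format PDB files and characterizes every
bond geometrically, together with a synthetic-structure generator that makes
the whole pipeline testable against planted ground truth.

## The mining procedure

A structure enters the corpus only if it declares a resolution of at most
2.5 Å (the conventional quality cutoff for trusting side-chain detail) and
carries no reducing-agent heteroatom. The default reductant blocklist is
`DTT, DTU, DTV, BME, TCE` (dithiothreitol and its isomers,
β-mercaptoethanol, TCEP); it is an argument, so a site-specific list can be
substituted, and an optional free-text scan of crystallization remarks is
deliberately *not* performed by default because those remarks are noisy.

Disulfides are taken from `SSBOND` header records. Both endpoints are mapped
to canonical accession positions, so the same physical bond seen in fifty
crystal forms collapses to one *unique bond* keyed by
`(accession, position pair)`. An optional geometric mode additionally
declares Sγ–Sγ pairs closer than 2.5 Å without an `SSBOND` line; it is off
by default because the header record is the curated signal.

The crux of the method is validating every **absence**. For each structure
chain mapped to an accession with a known bond but no `SSBOND` for it, the
absence is classified:

* `excluded_truncated` — either cysteine lies outside the crystallized
  construct;
* `excluded_mutated` — the aligned residue is not cysteine;
* `excluded_unresolved` — the cysteine is there but its Sγ atom was not
  modelled;
* `missing` — both cysteines are resolved with Sγ atoms and simply not
  bonded. Only this outcome is evidence of lability.

A unique bond is **labile** when it has at least one `present` observation
and at least one valid `missing` observation. Bonds whose measured S–S
distance falls outside ±10% of the 2.038 Å equilibrium length still count as
presence evidence but contribute no geometry to the strain cohorts — the
filter exists to keep poorly modelled bonds out of the statistics, not to
deny that a bond was declared.

Because one crystal can contain several copies of a protein, a single file
may supply both present and missing evidence for the same bond. Each mapped
chain yields one observation, and such bonds are flagged
`same_file_lability` for scrutiny rather than silently merged.

## Geometry and strain

Each bonded cystine is measured from coordinates (figure conventions:
χ1 = N–Cα–Cβ–Sγ, χ2 = Cα–Cβ–Sγ–Sγ′, χ3 = Cβ–Sγ–Sγ′–Cβ′, mirrored primes on
the second residue; α1/α2 are the Cβ–Sγ–Sγ′ bending angles; d = |Sγ–Sγ′|).
Dihedrals use the IUPAC sign convention and live in (−180°, 180°].

The dihedral strain energy, in kJ/mol, is the standard torsional
force-field estimate

$$\mathrm{DSE} = 8.37\,(1+\cos 3\chi_1) + 8.37\,(1+\cos 3\chi_1')
 + 4.18\,(1+\cos 3\chi_2) + 4.18\,(1+\cos 3\chi_2')
 + 14.64\,(1+\cos 2\chi_3) + 2.51\,(1+\cos 3\chi_3).$$

Its range is [0, 84.5] kJ/mol; the relaxed left-handed spiral
(χ = −60, −60, −90, −60, −60) scores 2.51. The barrier constants are
arguments (`constants`) so alternative parameterizations can be swapped in
without touching callers. One numerical note: the χ3 profile
$14.64(1+\cos 2\chi_3) + 2.51(1+\cos 3\chi_3)$ is *not* minimized exactly at
|χ3| = 90° — the 3-fold term drags the minimum to ≈ 97° (value ≈ 2.03
kJ/mol). The 2.51 figure at 90° is a reference value, not the argmin, and the
tests treat it as such.

```{r dse}
dse(-60, -60, -90, -60, -60)
dse(0, 0, 0, 0, 0)
```

## The 20 configurations

Configurations are named from the signs of the five χ angles. Handedness is
the sign of χ3 (RH positive). Shape compares the χ2/χ2′ signs with χ3's:
both equal → spiral, both opposite → staple, one of each → hook. The prefix
reads the χ1/χ1′ signs. For spirals and staples the two sides are
interchangeable, so a mixed prefix is always written `-/+`; hooks have a
distinguished side (the one whose χ2 matches χ3), which is read first, so
mixed-χ1 hooks split into `-/+` and `+/-`. That gives 3 + 3 + 4 = 10 names
per handedness, 20 in all, exactly the side-swap quotient of the 32 sign
vectors — and the name never depends on which cysteine is listed first.
Angles falling exactly on 0° or ±180° are signed `-` by a tie rule and
flagged, so boundary bonds can be excluded from tallies.

The classification rule is isolated in one function
(`classify_configuration()`) so it can be amended without touching callers.
The conventionally allosteric classes are `-RHstaple`, `-LHhook` and
`-/+RHhook`.

```{r config}
classify_configuration(c("-", "-", "-", "-", "-"))$name
classify_configuration(c("-", "-", "+", "-", "-"))$name
```

## Sequence mapping

Residue-level mapping from author numbering to canonical positions uses a
local chain table (TSV: `pdb_id`, `chain_id`, `accession`) plus global
Needleman–Wunsch alignment (match +1, mismatch −1, gap open −5, gap extend
−1, via `Biostrings::pairwiseAlignment`) of the *observed* ATOM-record
sequence against the canonical FASTA sequence. Using observed rather than
SEQRES residues means unresolved residues naturally read as "not observed"
for the truncation check. Alignments under 30% identity are rejected as
implausible; a SIFTS-style per-residue TSV can be supplied to bypass
alignment entirely, and chains mapping to multiple accessions (chimeras) are
dropped with a message. Live mapping services are deliberately out of scope:
everything runs offline.

## Secondary structure and B factors

Secondary-structure context comes from `HELIX`/`SHEET` header records
(helix wins when malformed headers declare both), not from a geometric
re-assignment — no external assignment program is required, and a
residue-level table can be substituted upstream. The B factor of a bond is
the mean over the 12 standard atoms (N, Cα, C, O, Cβ, Sγ × 2), with missing
atoms skipped and counted. The B-factor control compares, per labile bond,
the mean B of its present observations against its missing observations with
a paired t test — if "missing" bonds simply had disordered cysteines, this
comparison would show it.

## Cohort statistics

`summarize_cohorts()` compares all length-filter-passing unique bonds
(optionally restricted to a pre-culled chain list, standing in for homology
culling, which is not re-implemented) against the labile subset:
configuration and secondary-structure-pair frequencies with Pearson χ²
tests, Welch t tests (two-sided; pooled variance available by flag — the
sidedness and variance treatment are choices, made explicit) on DSE, S–S
distance and mean α angle, the allosteric-configuration subset DSE
comparison, and Pearson correlations among the strain measures. Raw p values
are reported without multiple-testing correction. Frequency categories empty
in both cohorts are dropped before χ² testing, since their expected counts
would be zero; metrics that are constant in a synthetic cohort (e.g. a fixed
builder S–S distance) yield `NA` test rows with means rather than errors.
Histograms use the conventional display ranges: DSE 0–60 kJ/mol, d 1.96–2.14
Å, α 95–120°, as relative frequencies.

## The synthetic generator: what it emulates, what it does not

`build_cystine()` constructs the 12 atoms of a cystine from internal
coordinates by natural-extension-reference-frame placement, so any target
(χ1, χ2, χ3, χ2′, χ1′, α1, α2, d) is realized exactly (round-trip error
< 1e−6 by construction; in practice ~1e−13). Bond lengths and angles default
to standard cysteine stereochemistry (N–Cα 1.458 Å, Cα–Cβ 1.530 Å, Cβ–Sγ
1.810 Å, S–S 2.038 Å; N–Cα–Cβ 110.5°, Cα–Cβ–Sγ 114.0°, Cβ–Sγ–Sγ′ 104.0°).
Backbone carbonyls are placed at idealized geometry; fixtures are chemically
plausible but not energy-minimized, which suffices because only the measured
internal coordinates matter downstream.

`generate_ensemble()` inverts the mining rules: it plants, per structure and
bond, one of the states present / stretched-present / reduced / truncated /
mutated / unresolved, plus structure-level decoys (resolution above or
without a value, reducing-agent heteroatoms), and emits legacy PDB files
together with the truth tables mining must reproduce. Non-cysteine residues
are written as a Cα trace — enough for sequence mapping and truncation
logic. Random χ targets stay ≥5° away from sign boundaries so classification
is unambiguous; all randomness derives from the spec seed, making fixture
directories byte-identical across runs.

What the generator does **not** emulate: crystallographic noise and
disorder, alternate conformations beyond the altLoc selection rule,
radiation-induced bond cleavage, crystal packing, or realistic protein
folds. Passing the planted-truth tests therefore demonstrates that the
*bookkeeping* — screening, mapping, absence validation, aggregation — is
exact, not that the biological conclusions transfer to any particular real
corpus.

## Problem sizes and reproducibility

The shipped validation corpus is 20 proteins × 4 structures (80 files, one
planted bond each), which exercises every observation status and exclusion
reason while mining in well under two minutes; the strain-effect check uses
200 bonds per cohort, ample for a Welch test on an effect this size. Output
tables are sorted by (accession, pos_i, pos_j, pdb_id, chain), so re-running
a scan on unchanged inputs is byte-identical.

## End-to-end example

```{r pipeline}
td <- file.path(tempdir(), "demo_corpus")
truth <- run_simulate(td, n_proteins = 5, n_structures = 4, seed = 7)
res <- mine_corpus(td, file.path(td, "chains.tsv"),
                   file.path(td, "sequences.fasta"))
res$bonds |> select(accession, pos_i, pos_j, labile, n_present, n_missing,
                    config, dse)
```

```{r report, fig.width = 6, fig.height = 3.5}
if (any(res$bonds$labile) && sum(!is.na(res$bonds$dse)) > 2) {
  cs <- try(summarize_cohorts(res$bonds, observations = res$observations),
            silent = TRUE)
  if (!inherits(cs, "try-error")) autoplot(cs, which = "dse")
}
```

## Known limitations

* Legacy PDB format only; mmCIF is deliberately excluded because `SSBOND`
  header lines are the curated bond signal this method is built on.
* X-ray structures only; NMR/EM models have no resolution record in the
  sense used by the screen.
* One canonical sequence per accession; isoforms are not handled.
* Homology culling is accepted as an input (a pre-culled chain list), not
  computed.
* The hook-prefix side convention (χ3-matching χ2 side first) is one
  defensible reading of the naming scheme; it is confined to a single
  table-driven function should it need amending.
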