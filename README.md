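# disulfidr

Mining and characterizing **labile disulfide bonds** in protein X-ray
structures.

Most disulfide bonds are permanent structural staples. Some are redox
switches: the same cystine is bonded in one crystal structure of a protein
and validly reduced in another. Such *labile* bonds are enriched in
allosteric disulfides — covalent switches whose cleavage changes protein
function. `disulfidr` is for structural bioinformaticians who want to find
candidate allosteric disulfides in a local structure corpus, and for anyone
needing careful per-bond cystine geometry.

## What it computes

Given a directory of legacy-format PDB files, a chain→accession table and
canonical sequences (FASTA), the pipeline:

1. **screens** structures — resolution ≤ 2.5 Å required, reducing-agent
   heteroatoms (DTT, BME, TCEP, …) excluded;
2. **harvests** disulfides from `SSBOND` records, mapping both cysteines to
   canonical accession positions (local Needleman–Wunsch; no web services);
3. **validates every absence** — a bond missing from a chain counts as
   lability evidence only if both cysteines are present, unmutated, and
   resolved with Sγ atoms; truncated, mutated or unresolved cases are
   excluded with reasons;
4. **aggregates** observations into unique bonds: `labile` ⇔ at least one
   valid present and one valid missing observation;
5. **characterizes** each bond: χ1, χ2, χ3, χ2′, χ1′ dihedrals, α1/α2
   bending angles, S–S distance d (kept within ±10% of the 2.038 Å
   equilibrium length for strain cohorts), the 12-atom B-factor average,
   secondary-structure context, the 20-way sign-based configuration class,
   and the dihedral strain energy

   DSE = 8.37(1+cos 3χ1) + 8.37(1+cos 3χ1′) + 4.18(1+cos 3χ2)
       + 4.18(1+cos 3χ2′) + 14.64(1+cos 2χ3) + 2.51(1+cos 3χ3)  [kJ/mol];

6. **compares cohorts** (all bonds vs labile bonds): configuration and
   secondary-structure χ² tests, Welch t tests on DSE/d/α, the allosteric
   subset (−RHstaple, −LHhook, −/+RHhook) comparison, and a paired B-factor
   control.

A deterministic synthetic-structure generator (`run_simulate()`,
`build_cystine()`) plants bonds with exact target geometry and every decoy
class, so the whole pipeline is validated against ground truth.

## Worked example

```r
library(disulfidr)
library(dplyr)

td <- file.path(tempdir(), "demo_corpus")
run_simulate(td, n_proteins = 5, n_structures = 4, seed = 7)
res <- mine_corpus(td, file.path(td, "chains.tsv"),
                   file.path(td, "sequences.fasta"))

res$verdicts |> filter(status == "excluded")
#> # A tibble: 6 × 3
#>   pdb_id status   reasons
#>   <chr>  <chr>    <chr>
#> 1 Z024   excluded reducing_agent
#> 2 Z033   excluded reducing_agent
#> 3 Z034   excluded no_resolution
#> 4 Z041   excluded resolution_gt_2.5
#> 5 Z052   excluded no_resolution
#> 6 Z053   excluded reducing_agent

res$bonds |> select(accession, pos_i, pos_j, labile, n_present, n_missing,
                    config, d, dse)
#> # A tibble: 5 × 9
#>   accession pos_i pos_j labile n_present n_missing config          d   dse
#>   <chr>     <int> <int> <lgl>      <int>     <int> <chr>       <dbl> <dbl>
#> 1 SYN001       10    28 TRUE           1         1 +/-RHhook    2.04  44.2
#> 2 SYN002       10    32 TRUE           0         1 <NA>        NA     NA
#> 3 SYN003       10    25 FALSE          0         0 <NA>        NA     NA
#> 4 SYN004       10    32 TRUE           1         1 -/+RHspiral  2.04  20.5
#> 5 SYN005       10    39 FALSE          1         0 +RHhook      2.04  24.9
```

Reading the table: `SYN001 10–28` was declared (`SSBOND`) in one included
structure and validly absent (both cysteines resolved, unbonded) in another,
so it is labile; its representative geometry is a `+/-RHhook` with a 2.04 Å
S–S bond carrying 44.2 kJ/mol of torsional strain. `SYN002`'s only presence
evidence failed the ±10% length filter (`n_present` counts strict presents),
so it is flagged labile but contributes no geometry to strain cohorts.
`SYN005` was never validly missing — not labile.

Per-bond geometry of a single file, and classification straight from
dihedrals:

```r
run_geometry(file.path(td, "z013.pdb")) |>     # one row per SSBOND
  select(pdb_id, resnum1, resnum2, config, dse)
#> # A tibble: 1 × 5
#>   pdb_id resnum1 resnum2 config      dse
#>   <chr>    <int>   <int> <chr>     <dbl>
#> 1 Z013        10      28 +/-RHhook  44.2

sides <- build_cystine(cystine_spec(chi = c(-57, -79, 84, -73, -59)))
add_configuration(measure_cystine(sides[sides$residue == 1, ],
                                  sides[sides$residue == 2, ]))
#>    chi1  chi2  chi3 chi2p chi1p alpha1 alpha2     d   dse b_avg ... config
#> 1   -57   -79    84   -73   -59    104    104  2.04  5.00    20     -RHstaple
```

A `-RHstaple` — the archetypal allosteric configuration — at a mere
5.0 kJ/mol of dihedral strain.

Cohort reports and plots:

```r
cs <- run_report(res$bonds, observations = res$observations)
tidy(cs)      # one row per statistical test
glance(cs)    # cohort sizes and headline means
autoplot(cs, which = "dse")
```

A command-line front end wraps the same functions:

```sh
Rscript inst/cli/disulfidr.R simulate --dir corpus --proteins 5 --seed 7
Rscript inst/cli/disulfidr.R scan --input corpus --chains corpus/chains.tsv \
    --fasta corpus/sequences.fasta --out results
Rscript inst/cli/disulfidr.R geometry --file corpus/z013.pdb
Rscript inst/cli/disulfidr.R report --bonds results/bonds.tsv --out report
```

## Scope notes

Legacy PDB format only (the `SSBOND` record is the curated signal the method
is built on); X-ray structures only; homology culling is accepted as an
optional pre-culled chain list rather than recomputed; pathway-enrichment
analysis of the resulting protein lists is out of scope. See the vignette
(`vignettes/labile-disulfide-mining.Rmd`) for the model details, parameter
defaults and design decisions.
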