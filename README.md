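# mitohet

Mitochondrial DNA variants and heteroplasmy from the off-target reads of
whole-exome sequencing.

Exome capture kits co-purify mitochondrial DNA: its high copy number yields
usable "off-target" read coverage over the whole 16,569-base mitochondrial
genome, for free, in every diagnostic exome. `mitohet` turns those reads —
delivered as a samtools-style text pileup over the mitochondrial contig —
into rCRS-referenced SNV calls with quantified heteroplasmy, and provides
the statistical machinery to validate an exome-derived call set against a
gold standard such as diagnostic Sanger sequencing.

The package is aimed at people analysing mitochondrial disease cohorts or
mining existing exome archives for mtDNA variation.

## What it computes

**Heteroplasmy with exact uncertainty.** At a site with total usable depth
*n* and *v* variant reads, the heteroplasmy estimate is *v/n* with the
exact (Clopper–Pearson) binomial interval: the lower bound solves
P(X ≥ v | n, p) = α/2 and the upper solves P(X ≤ v | n, p) = α/2, giving
guaranteed ≥ 95% coverage for every (n, p). Calls require n ≥ 5, v ≥ 3 and
v/n ≥ 0.10 by default (`calling_thresholds()`).

**Artifact flags.** Positions inside the unstable poly-C tract
(m.16184–16193) are flagged unconditionally; a position that looks
heteroplasmic in ≥ 3 unrelated samples is flagged as a recurrent artifact
in every carrier — genuine heteroplasmy is private to an individual.

**Exact platform comparison.** Per-base error rates between two platforms
are compared with the exact Poisson rate-ratio test: conditional on the
total event count, the count on platform A is Binomial(total,
E_A/(E_A+E_B)) under a rate ratio of 1, and the two-sided p-value sums all
point probabilities not exceeding the observed one.

**Liftover.** Calls against a non-rCRS mitochondrial reference (e.g. hg19
chrM) are mapped onto rCRS through a block map derived from a global
pairwise alignment, with alleles re-referenced and reference-strain
differences dropped explicitly.

**Simulation.** `sim_config()` / `simulate_cohort()` generate whole
cohorts — pileups, truth tables, gold-standard call sets — with
kit-specific smooth coverage shapes, an Ori-L coverage dip, binomial
variant-read sampling, an elevated poly-C error rate and recurrent artifact
positions, deterministically from one seed.

The packaged reference (`synthetic_rcrs()`) carries the real NC_012920.1
gene map on true rCRS coordinates, but its nucleotide sequence is synthetic
(generated in code, with the structural anchors the pipeline relies on);
supply a real rCRS FASTA through `load_reference()` for production use.

## Worked example

```r
library(mitohet)

# simulate a six-sample cohort and run the full pipeline against the
# simulator's Sanger-like gold standard
cfg <- sim_config(seed = 7, n_samples = 6, baseline_depth = 40)
sim <- simulate_cohort(cfg)
out <- run_pipeline(sim$pileups, gold_set = sim$gold)

out$screen
#> # A tibble: 6 x 4
#>   sample_id eligible mean_depth n_candidates
#>   <chr>     <lgl>         <dbl>        <int>
#> 1 S01       FALSE          26.3            0
#> 2 S02       FALSE          17.7            0
#> 3 S03       TRUE          122.             1
#> 4 S04       TRUE           39.0            1
#> 5 S05       TRUE           39.8            1
#> 6 S06       FALSE          14.4            0
```

Only samples whose mean per-base depth exceeds 30-fold are screened for
heteroplasmy; each eligible sample recovers exactly its one programmed
heteroplasmic site, with flagged recurrent artifacts excluded:

```r
dplyr::filter(out$calls, het_class == "heteroplasmic",
              !recurrent_artifact, !polyC)
#>   sample_id position ref   alt       v     n   vaf ci_low ci_high gene
#> 1 S03           8408 A     G       122   147 0.830  0.759   0.887 MTATP8
#> 2 S04           2503 A     G        16    65 0.246  0.148   0.369 MTRNR2
#> 3 S05          16225 A     G        87   130 0.669  0.581   0.749 CR
```

Each row is a heteroplasmic call: sample S04, say, carries a variant at
m.2503 in the large rRNA gene at an estimated 24.6% heteroplasmy, with the
exact 95% interval 14.8–36.9% reflecting its 65-fold depth.

The single-site machinery reproduces the published validation numbers
directly from printed counts:

```r
clopper_pearson(3, 17)          # the m.240A>G estimate: 18%, 95% CI 4-43%
#>       v     n estimate conf.low conf.high level
#>       3    17    0.176   0.0380     0.434  0.95

poisson_ratio_test(24, 10, 762174, 762174)
#> Exact Poisson rate-ratio test (conditional binomial, minimum likelihood)
#> counts: 24 vs 10   exposures: 762174 vs 762174
#> rate ratio = 2.4, p-value = 0.02431
```

A thin command-line front end over the same functions lives at
`inst/cli/mitohet.R` (subcommands `call`, `annotate`, `liftover`,
`coverage`, `compare`, `simulate`, `stats`).

## Scope

Downstream of alignment only: no BAM parsing, no realignment, no indel or
deletion calling, no haplogroup assignment, no population-frequency
databases. See the methods vignette
(`vignettes/mtdna-heteroplasmy.Rmd`) for the model, parameter rationale,
simulator assumptions and limitations.
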