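# prercoloc

Genome-wide co-localization and chromatin-openness analysis for
pre-replication-complex (pre-RC) binding sites, in R.

## The problem

Origin licensing in human cells deposits CDC6 and the MCM helicase at
hundreds of thousands of genomic sites. Deciding whether two such peak sets
— say CDC6 peaks and MCM7 peaks, or pre-RC sites and a chromatin factor such
as GRWD1 — occupy the *same* sites requires more than eyeballing browser
tracks. The questions this package answers, for anyone with BED peak sets,
read positions, chromosome sizes and a gene annotation:

- **Windowed co-localization.** What fraction of peak set A has a member of
  set B within *d* bp (the `A_w0.5_B` / `A_wo0.5_B` nested-set notation, with
  *d* = 0.5 kb by default)? Is that fraction higher than for shuffled peaks
  with the same number and lengths, placed at random? The test is a Pearson
  chi-square (df = 1) on observed vs shuffled-null counts.
- **Nested classes.** Chained selection builds classes such as
  `CDC6_w0.5_MCM7_w0.5_sGRWD1_w0.5_SNS`, and reporting arithmetic turns set
  sizes into the quantities people quote: co-localized percentages and mean
  inter-peak intervals (genome length / set size).
- **Signal tracks.** Moving-average read coverage (window 1 kb, evaluated
  every 0.1 kb), RPM-normalized, then either divided by the matched input
  (ChIP) or input-subtracted (FAIRE open chromatin).
- **Profiles.** Aggregation plots of peak density or track signal around
  anchor sites; strand-oriented metagene profiles with ±5 kb flanks and a
  length-scaled gene body; TSS-proximity tests.
- **Condition comparison.** Per-site mean FAIRE signal in ±2 kb windows
  under two conditions (e.g. control vs knockdown siRNA), with a paired
  Wilcoxon signed-rank test and the percent change.

A deterministic synthetic-data generator (peak sets with controlled
co-localization fractions, Poisson-enriched read sets with matched uniform
inputs, per-site knockdown factors, gene annotations) makes the whole
pipeline testable end to end without any sequencing data.

## Worked example

```r
library(prercoloc)

g   <- make_genome(n_chroms = 3, chrom_length = 2e7)       # 60 Mb toy genome
mcm <- simulate_peaks(g, 2000, seed = 1, label = "MCM7")
cdc <- simulate_peaks(g, 2000, fraction = 0.27, window = 500,
                      anchor = mcm, seed = 2, label = "CDC6")

sel <- select_within(cdc, mcm, d = 500)
n_peaks(sel$selected)                       # 540  (27% of 2000)
sel$selected$label                          # "CDC6_w0.5_MCM7"

coloc_test(cdc, mcm, d = 500, n_shuffles = 10, seed = 3)
#> co-localization of 'CDC6' with 'MCM7' within 0.5 kb
#>   observed: 540 / 2000 (27.0%)
#>   shuffled null: 184.4 / 2000 (9.2%) over 10 shuffle(s)
#>   chi-square = 213.16 (df = 1), p = 2.8e-48

mean_peak_interval(g, n_peaks(sel$selected)) / 1000   # 111.1 kb on the toy genome
mean_peak_interval(3e9, 123000) / 1000                # 24.4 kb at genome scale
```

The observed 27.0% is the planted fraction; the shuffled null (~9%) is what
the same number and lengths of peaks recover by chance at this peak density,
and the chi-square confirms the difference. The last two lines are the
reporting arithmetic applied to the toy run and to genome-scale counts
(123,000 selected peaks on a 3×10⁹ bp genome are ~24.4 kb apart on average).

A FAIRE-style two-condition comparison:

```r
sites <- simulate_peaks(g, 1000, seed = 11, label = "sites")
mk <- function(effect, seed) {
  rs <- simulate_reads(g, sites, n_reads = 1.2e5, enrichment = 100,
                       effect = effect, paired_input = TRUE, seed = seed)
  subtract_input(normalize_rpm(bin_reads(rs$sample, g)),
                 normalize_rpm(bin_reads(rs$input, g)))
}
faire_compare(mk(1, 21), mk(0.7, 22), sites)
#> window comparison (+/- 2000 bp, 1000 anchors, paired_wilcoxon)
#>   mean condition 1: 212.5; condition 2: 147.4
#>   percent change: -30.6%; p = 1.19e-164
```

The planted knockdown factor 0.70 comes back as a ~30% signal loss.

The whole analysis can also be driven from one configuration:

```r
run <- run_pipeline(default_demo_config(seed = 1), "demo_out")
cat(summarize_run(run), sep = "\n")
```

which writes BEDs for every layer and nested class, OverlapReports as JSON,
profile TSVs, FAIRE bedGraphs, a manifest with file hashes, and a text
summary. Two runs with the same master seed are byte-identical. A thin CLI
wrapper lives at `inst/cli/prerc-coloc.R` (`run`, `coloc`, `report`
subcommands).

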