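# crossreg

Promoter-level cross-regulation analysis of the NF-κB and IRF
transcription-factor families.

The two families are the major effector arms of the innate immune
response, and one route for crosstalk between them is direct: promoters
of the genes coding for one family's factors can carry binding sites for
the other family. `crossreg` is a tidyverse-native R pipeline for that
kind of promoter census — for computational biologists who want a
scriptable, reproducible version of the classic two-step analysis:

1. **Scan** promoter sequences (1 kb upstream of the TSS) for
   transcription-factor binding sites with position weight matrices and
   IUPAC consensus patterns, on both strands.
2. **Filter by conservation** (phylogenetic footprinting): keep a
   predicted site only if it lies in a conserved alignment region and the
   orthologous promoter of another species carries a site for the same
   factor at the overlapping alignment position.

Around this core the package builds per-gene/per-species family count
tables with overlap detection, AU-rich element (class I/II/III ARE)
classification of 3'UTRs, a Monte-Carlo random-sequence specificity
control, ChIP-seq peak cross-referencing across cell lines, and a fully
seeded synthetic-data generator with exact ground truth for every stage.

## The model in brief

A position frequency matrix with counts `c[b,i]` (column sum `N_i`)
becomes a log-odds PWM over background `q` with pseudocount `p`:

    w[b,i] = log2( ((c[b,i] + p·q[b]) / (N_i + p)) / q[b] )

A window's raw score is the sum of its per-position weights, rescaled to
the **relative score** `(s − s_min)/(s_max − s_min)` in [0, 1] between
the matrix's minimum and maximum attainable scores; windows at or above
the threshold (default 0.80) are hits. Conservation uses a 21-column
moving-average identity profile, regions ≥ 21 columns at ≥ 0.70
identity, and a ≥ 0.5 column-overlap rule for cross-species support. The
background control compares mean counts on the dataset against 100
random 1-kb sequences, with an add-one empirical p-value. Details,
defaults and the reasoning behind them are in the methods vignette
(`vignettes/promoter-crossreg.Rmd`).

All tables are tibbles; coordinates are 0-based half-open
(BED-compatible) throughout.

## Worked example

The package ships a generator that materializes a complete demo dataset
— four-species orthologous promoters with planted IRF3/RELA sites, two
contrasting 3'UTRs, and ChIP-seq peak files — plus a config that runs
every stage:

```r
library(crossreg)
library(dplyr)

cfg <- make_fixtures("demo", seed = 1)   # writes FASTA/peaks/truth/config
res <- run_pipeline(cfg)                 # writes TSV bundle + run log

select(res$counts, gene, species, n_IRF, of_which_IRF3, n_NFKB, of_which_REL)
#> # A tibble: 8 × 6
#>   gene   species    n_IRF of_which_IRF3 n_NFKB of_which_REL
#> 1 gene01 cattle         3             3      3            2
#> 2 gene01 chimpanzee     1             1      4            3
#> 3 gene01 human          1             1      4            3
#> 4 gene01 mouse          2             2      4            3
#> 5 gene02 cattle         4             4      6            5
#> 6 gene02 chimpanzee     3             3      4            3
#> 7 gene02 human          3             3      4            3
#> 8 gene02 mouse          6             6     11            8
```

Each row is one promoter: distinct-interval counts per family, with
"of which" columns for designated members. The planted IRF3 and RELA
sites are recovered in every species (plus chance-level extra hits at
the 0.80 threshold). The background control on the same run:

```r
select(res$background, tf, mean_data, mean_rand, specificity_ratio, empirical_p)
#> # A tibble: 2 × 5
#>   tf    mean_data mean_rand specificity_ratio empirical_p
#> 1 JUN           3      4.74             0.633       0.703
#> 2 SP1           0      0.73             0           1
```

AP-1/JUN sites are as frequent on random sequence as on the demo
promoters (ratio near 1, p ≈ 0.7: not dataset-specific), while SP1's
GC-box is rare on uniform random sequence — the qualitative asymmetry
that makes SP1 the more informative cofactor candidate. And the 3'UTR
stage separates the two designed transcript profiles exactly:

```r
res$utr
#> # A tibble: 2 × 6
#>   utr_id    length at_content n_class_I n_class_II n_class_III
#> 1 utr_long    2100      0.502         4          1           8
#> 2 utr_short     89      0.427         0          0           0
```

`utr_long` is an unstable-transcript profile (one class II cluster, four
class I pentamers, eight AU-rich class III stretches at ~50% AT);
`utr_short` is a short, ARE-free, stable-transcript profile.

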