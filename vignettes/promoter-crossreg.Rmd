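---
title: "Promoter-level cross-regulation analysis of the NF-kB and IRF families"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Promoter-level cross-regulation analysis of the NF-kB and IRF families}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crossreg)
library(dplyr)
```

## The question and the method

The NF-kB and IRF transcription-factor families are the two effector arms
of the innate immune response. One way the two arms can cross-regulate is
at the lowest level of the regulatory hierarchy: if promoters of
IRF-coding genes carry NF-kB binding sites (and vice versa), each family
can directly tune the other's expression. `crossreg` implements a
reusable, fully testable pipeline for this kind of promoter census:

1. **Binding-site scanning.** Promoters (1 kb upstream of the TSS, by
   convention) are scanned with position weight matrices (PWMs) and with
   IUPAC consensus patterns on both strands.
2. **Phylogenetic footprinting.** Predicted sites are filtered by
   cross-species conservation: a site counts as supported only if it falls
   in a conserved alignment region and the orthologous promoter of
   another species carries a site for the same factor at the overlapping
   alignment position.
3. **Count tables.** Hits are rolled up per gene, species and promoter
   variant into per-family counts ("IRF family", "of which IRF3", ...),
   with overlap groups reported separately.
4. **3'UTR characterization.** AU-rich elements (AREs) around the
   `AUUUA` pentamer are classified into the standard three classes to
   contrast transcript-stability profiles of family members.
5. **Background specificity.** Mean motif counts over the dataset are
   compared with counts on freshly generated random 1-kb sequences
   (Monte-Carlo control with an add-one empirical p-value).
6. **ChIP-seq cross-reference.** Predictions are intersected with peak
   files across cell lines, summarizing per-hit support fractions.

Every stage consumes and produces ordinary tibbles, so the pipeline is
scriptable with dplyr verbs, and every stage has a synthetic-data
generator with machine-readable ground truth.

## Scoring model

A position frequency matrix (PFM) with counts $c_{b,i}$ (base $b$, column
$i$, column sum $N_i$) becomes a log-odds PWM over a background
distribution $q_b$ with pseudocount $p$:

$$ w_{b,i} \;=\; \log_2 \frac{(c_{b,i} + p\,q_b) / (N_i + p)}{q_b}. $$

A window's raw score is the sum of its per-position weights; the
*relative score* rescales it into $[0,1]$ between the matrix's minimum
and maximum attainable scores,
$\mathrm{rel} = (s - s_{\min})/(s_{\max} - s_{\min})$. Windows at or above
the relative threshold are reported as hits, on either strand, in
plus-strand coordinates.

```{r scoring}
p <- crossreg_pfms()$IRF3
glance(pfm_to_pwm(p))
scan_pwm(seq_tbl("demo", "TTGAAAGCAAATCGGGACTTTCCA"), pfm_to_pwm(p),
         rel_threshold = 0.8)
```

Numerical details worth knowing:

* **Pseudocount 0.8**, distributed across bases proportionally to the
  background, avoids minus-infinity weights for unobserved bases; both
  the pseudocount and the background are arguments. With a pseudocount of
  exactly 0, unobserved bases score $-\infty$; the relative score then
  uses the finite score range and $-\infty$ windows are never reported.
* Raw scores lie in $[s_{\min}, s_{\max}]$ by construction, so the
  relative score is clamped into $[0,1]$ to absorb one-ulp floating-point
  rounding of the per-column accumulation.
* **Windows containing `N` are skipped** rather than scored: a log-odds
  model gives no principled score to an ambiguous base.
* Hits on both strands at the same interval are both kept (no palindrome
  deduplication); the counting stage deduplicates by interval, and raw
  occurrence counts are reported in parallel, so either counting
  convention is available downstream.
* The default relative threshold is **0.80**, the conventional default of
  ConSite-style scanners; it is a parameter everywhere.

## Conservation filtering

Cross-species support is assessed pairwise against a designated reference
species (human by default), since multi-species statements decompose into
pairwise comparisons ("conserved between human and chimpanzee"). For each
pair:

* the per-column identity (1 when both rows carry the same unambiguous
  base, 0 otherwise, gaps never match) is smoothed with a centered
  moving average (**window 21 columns**, truncated at the edges);
* maximal runs with smoothed identity at or above **0.70** and length at
  least **21 columns** become conserved regions;
* a reference hit is conserved if its alignment-column span intersects a
  conserved region and a same-factor hit in the other species overlaps at
  least **0.5** of that span (all four knobs are config parameters;
  values follow common phylogenetic-footprinting practice).

Whole-promoter identity is reported as percent identical columns, with
both-gap columns excluded from the denominator and single-gap columns
counted as mismatches.

Pre-computed CLUSTAL or aligned-FASTA alignments are consumed directly; a
Needleman-Wunsch global aligner (match 1, mismatch −1, linear gap −2,
deterministic diagonal-up-left tie-breaking) is bundled as plumbing so the
pipeline runs end to end without external aligners. It is pairwise only —
multi-species runs align each species to the reference independently —
and makes no claim to replace a progressive multiple aligner.

## ARE classes on 3'UTRs

AU-rich elements are searched on the sense strand only (they are mRNA
elements). With DNA-normalized sequence (`U` maps to `T`):

* **class II** — clusters of two or more `ATTTA` pentamers whose starts
  differ by at most `cluster_gap = 5` (i.e. overlapping or adjacent);
* **class I** — a singleton pentamer whose flanking `ctx_window = 10`
  bases per side are at least `ctx_at_min = 0.65` AT;
* **class III** — merged maximal unions of 30-bp windows with AT fraction
  at least 0.75 that contain no pentamer.

The class boundaries in the literature are operational rather than
canonical, so all five parameters are explicit arguments with the above
defaults. One consequence of the merged-window definition: raising
`classIII_at_min` shrinks the *covered* class III length monotonically
(window sets are nested), but can occasionally split one merged site into
two, so site counts are not strictly monotone in the cutoff.

```{r are}
classify_are(paste0(strrep("T", 20), "ATTTATTTA", strrep("T", 20)))
```

## Random-sequence background

The specificity control generates `n_rand = 100` i.i.d. random sequences
of `length = 1000` bp (the promoter size) and compares mean motif counts:

```{r background}
pwm_sp1 <- pfm_to_pwm(crossreg_pfms()$SP1)
data_seqs <- random_sequences(20, length = 1000, seed = 42)
specificity_comparison(data_seqs, pwm_sp1, n_rand = 50, seed = 43)
```

The empirical p-value uses the add-one permutation-style estimator
$(1 + \#\{\text{random counts} \ge \text{data mean}\})/(n_{\text{rand}}+1)$,
which cannot return zero. The default background composition is uniform;
a GC-matched mode (composition estimated from the dataset) is available
because published analyses rarely state which was used. For an exact
consensus of width $w$ both-strand scanning of a uniform random sequence
of length $L$ has expected hit count $2(L-w+1)\,4^{-w}$ — the test suite
checks the Monte-Carlo machinery against this closed form.

## Bundled matrices

`crossreg_pfms()` loads eight JASPAR-format matrices (IRF1, IRF2, IRF3,
NFKB1, RELA, REL, JUN/AP-1, SP1). These are **synthetic stand-ins**
constructed from each factor's published consensus (e.g.
`GAAASSAAANY` for IRF3, `TGASTCA` for AP-1, the degenerate GC-box for
SP1) with typical per-column degeneracy — they are not the original
database matrices, whose exact versions are not recoverable. They make
the pipeline and its tests fully reproducible offline; for real analyses
users should pass their own matrix file to `read_jaspar()`.

## The synthetic-data generators

Every stage is validated against generated data with exact truth:

* `plant_motifs()` plants non-overlapping PFM-sampled instances (random
  strand) in i.i.d. background and records every placement.
* `generate_ortholog_family()` emulates the four-species design (human,
  chimpanzee, mouse, cattle; defaults in `make_fixtures()` use
  divergences 0, 0.02, 0.5, 0.3). An ancestral promoter is sampled; each
  species copy substitutes each site with probability equal to its
  divergence outside conserved blocks and a tenth of that inside.
  Substitution replaces the base by a uniformly chosen *different* base,
  so per-site identity between the reference and a diverged species is
  exactly $1-d$ — an interpretable dial that keeps the outside-block
  identity (0.5 at $d=0.5$) well separated from the 0.70 conservation
  cutoff. There are no indels, so the identity alignment is the true
  alignment and conservation calls can be scored against exact truth
  (an aligner-quality confound is deliberately excluded). Planted motif
  instances are copied identically into every species — their positions
  are exempt from substitution — so plants are cross-species conserved by
  construction.
* `generate_synthetic_utr()` assembles UTRs from planted class I/II/III
  features and GC-leaning, pentamer-free spacers whose AT content is
  adjusted toward a target; spacer ends are held at G/C so pentamers
  cannot arise across junctions.
* `generate_peak_file()` covers each true site with probability
  `coverage_fraction` by a 150-300 bp peak (center jitter optional) and
  adds decoy peaks away from true sites.

What the generators deliberately do **not** emulate: indels and
rearrangements, transition/transversion bias, rate heterogeneity,
dinucleotide background structure, and signal-strength distributions of
real ChIP-seq. Passing tests therefore demonstrate correctness of the
algorithms under a clean substitution-and-planting model, not performance
on genome-extracted sequence; published per-gene counts depend on matrix
versions and thresholds and only become comparable when users supply the
original promoter sequences.

## Problem sizes used by tests and the acceptance script

The packaged checks run at desk scale, chosen to keep Monte-Carlo error
well inside the asserted tolerances: 200 random scanner-oracle instances
(motifs up to 6 bp, sequences up to 30 bp); 50 synthetic 1-kb promoters
with 5 planted width-24 near-delta sites each (the 0.80 threshold's
mismatch budget of ~0.2 w columns makes the analytic chance-hit
expectation across the whole experiment about $3\times10^{-4}$, so full
recall with zero decoys is a property of the construction, not luck); one
four-species 1-kb family with two 150-column conserved blocks; 100
random 1-kb background sequences, matching the published control's size.

## Known limitations

* Conservation is pairwise-to-reference; a joint multi-species criterion
  is out of scope.
* PWM scores carry no p-value calibration; the relative-score threshold
  is the only filter.
* "Strong/weak" peak language is not operationalized: ChIP-seq support is
  binary overlap (default `min_bp = 1`), with signal values carried
  through but never thresholded.
* Promoter variants are whatever FASTA records the user supplies; the
  package does not resolve TSS annotation.
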