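---
title: "Calling m5C from bisulfite sequencing: models, filters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Calling m5C from bisulfite sequencing: models, filters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(bsm5c)
```

## The measurement model

Bisulfite converts unmethylated cytosine to uracil (sequenced as T);
5-methylcytosine resists conversion and reads as C. `bsm5c` treats every
read molecule independently: at a reference cytosine with latent
methylation level $m$, the molecule is methylated with probability $m$; a
methylated C is read as C with probability $1 - \mathrm{overconversion}$,
an unmethylated C as T with probability $e$ (the conversion efficiency).
A uniform substitution error $\varepsilon$ follows. The expected observed
C fraction at a site is therefore

$$\mathbb{E}[\hat m] \approx m\,(1-\text{overconversion}) + (1-m)(1-e),$$

which the simulator tests verify against deep simulated coverage. The
estimator is the non-conversion level $\hat m = c/(c+t)$; bases other
than C or T are excluded from its denominator but counted in coverage,
which makes the 80CT filter (below) a guard against sequencing noise
rather than part of the methylation estimate. Incomplete conversion
($e < 1$) inflates $\hat m$ by up to $1-e$ at unmethylated sites — this
is why fully unmethylated spike-in transcripts are carried through the
pipeline: their pooled $\Sigma t/(\Sigma c + \Sigma t)$ measures $e$ per
replicate (QC floor 0.99 by default; failure warns and annotates, it
does not abort, since the downstream filters may still be interpretable
at a known, lower efficiency).

## Conversion-aware mapping

Reads and reference are compared in a three-letter alphabet obtained by
collapsing C to T in both, so a read's conversion status can never
penalize its alignment. The mapper is deliberately minimal: exact k-mer
seeds (first and mid-read k-mer, $k = 20$), full-length ungapped
comparison in collapsed space, mismatch budget
$\lfloor 0.05 \cdot \text{read length}\rfloor$. A read is kept only if
exactly one locus attains the minimal mismatch count (ties are
ambiguous and excluded, the standard unique-only convention in bisulfite
quantification). Mapping is transcript-space: with a transcript set as
reference, splicing is irrelevant, and since the simulator models no
indels the aligner needs no gaps. Pileups take the read base from the
original, uncollapsed read at the aligned offset.

The collapsed alphabet loses information, so repetitive or near-repetitive
references produce ambiguous (hence discarded) reads; coverage also
decays linearly within a read length of transcript ends. Both effects are
visible in the tests, and the generator therefore places sites intended
to pass the coverage filters at least one read length away from the ends
(`cluster$margin`).

## The candidate-site filters

Per replicate and site: coverage $\ge$ 30 (`30RC`), reads showing C
$\ge$ 5 (`5C`), fraction of bases read as C or T $\ge$ 0.80 (`80CT`).
Across replicates: average non-conversion level $\ge$ 0.10 (`10MM`). A
site passing the per-replicate filters in both replicates is a candidate
if the unweighted average of the two $\hat m$ values clears 10 %; a site
passing in exactly one replicate is rescued only if that replicate also
clears the stricter C depth of 7 (`7C`) and its own $\hat m$ clears
10 %. Three readings were fixed here and are exposed as arguments:

* "depth of cytosines" is interpreted as $c$, the number of reads showing
  C at the site — the only reading under which it is a per-site quantity;
* the 10MM average is the unweighted mean of per-replicate $\hat m$
  (`weighted_avg_m` switches to pooled counts); in the single-replicate
  branch it is applied to the passing replicate alone, since an average
  across replicates is unavailable there by construction;
* a replicate entirely absent from the pileup counts as failing, which
  routes the site into the strict fallback rather than erroring.

The two-replicate design is hard-wired as the default;
`allow_any_replicates` generalizes ("all replicates pass" / "exactly one
passes") for other designs.

## Differential methylation

Replicates are pooled within condition (a 2×2 test between two
two-replicate conditions forces pooling) and each site in the candidate
union with nonzero pooled C+T on both sides is tested with a two-sided
Fisher exact test. The two-sided p is the point-probability sum — all
hypergeometric tables with probability not exceeding the observed
table's, with the classical $1 + 10^{-7}$ relative tie tolerance —
because two-sided Fisher conventions differ and this one is verified
against exhaustive enumeration in the tests. Correction is
Benjamini–Hochberg (the field default where only "multiple correction"
is specified; Bonferroni by flag), and significance requires adjusted
$p < 0.01$ *and* $|\Delta m| > 0.1$. The difference rule is two-sided by
default although the motivating use case is methylation gain;
`gain_only` restricts to $\Delta m > 0.1$. Ranking is by adjusted p,
then $|\Delta m|$, then locus, so full ties are reproducible.

## Clone-based targeted sequencing

Each Sanger clone is one original molecule. Clones are globally aligned
to the unconverted reference with bisulfite-aware scoring (reference C
matches clone C *and* T; match +1, mismatch −1, linear gap −2;
traceback prefers diagonal, then up, then left, making alignments
deterministic). Clones deviating more than 20 % in length or falling
below 70 % bisulfite-aware identity are discarded as unalignable. DNA
mode scores top-strand CpG cytosines and uses the non-CpG cytosines —
essentially unmethylated in genomic DNA — as a per-clone conversion
meter (floor 0.95). RNA mode scores every cytosine.

Incomplete conversion produces false-positive methylation calls, and the
qualitative rule "a cytosine whose status is not consistently placed
across clones is unconverted" is operationalized as: a position's C-calls
are flagged X when fewer than $\max(2,\ 0.2\,n)$ clones show C there; a
clone is discarded as incomplete when more than half of its C-calls are
flagged **and** it has at least three flagged calls. The count floor is
this package's addition: without it, a clone carrying a single stray
unconverted cytosine (expected ~26 % of clean clones at $e = 0.99$ over
30 scored positions) would be discarded, which would contradict the
intended specificity of the filter (≤ 5 % false discards, verified over
50 seeded runs). Flagging is a single pass — positions are flagged over
all alignable clones, then clones are discarded, then percents are
computed over kept clones excluding X and missing states. Minimum clone
counts (8 for DNA, 10 for RNA) trigger a low-confidence warning rather
than an abort.

## Association layer

Promoter methylation per sample is the unweighted mean β over the
island's probes, dichotomized at β ≥ 0.30 (boundary inclusive; the cut
is a recorded package default, exposed as `threshold`, since no
published cut exists for the index CpG). Spearman correlation uses
average ranks and the t-approximation; the t-test is pooled-variance by
default with Welch by flag; transcript half-life after transcription
arrest is $\ln 2 / (-\text{slope})$ of the log-linear fit, with a flat
or rising series reported as infinite rather than negative.

For r×2 contingency tables, `chisq_rxc` computes the Pearson statistic
without continuity correction and, when any expected count is below 5
(or on request), the *exact* permutation p-value of that statistic by
full enumeration of tables with the observed margins — the behaviour of
standard clinical statistics packages, and the computation under which
the published cohort p-values reproduce to printed precision; the
asymptotic p differs in the third decimal for the sparser tables. The
enumeration is deterministic (no Monte-Carlo), vectorized over the last
two rows, and guards float ties at $10^{-9}$.

## The simulator as a testing contract

The generator's defaults encode the study design: two conditions × two
biological replicates, 75-base reads at 60× depth, conversion efficiency
0.995, sequencing error 0.001, overconversion 0, two fully unmethylated
spike-ins, and a planted cluster of three consecutive cytosines restored
from 0 to 0.8 — the adjacent-site pattern in which neighbouring
cytosines share one methylation profile. Read counts are fixed
(`round(depth × length / read length)`, uniform random starts) rather
than Poisson by default, trading realism for low-variance tests; a
Poisson option exists. Quality strings are constant and never used. One
master seed drives everything; independent streams (condition,
replicate, clone set) derive sub-seeds through a documented hash
(`derive_seed`), so replicates are independent but byte-reproducible.

What the simulator does **not** model bounds what green tests mean:
no indels, splicing, adapters or quality decay; no rRNA or DNA
contamination; no coverage biases beyond the end effect; no strand
chemistry beyond the sense strand (RNA bisulfite conversion acts on the
single-stranded molecule); spike-in sequences are arbitrary flagged
transcripts, since only their fully unmethylated property is used.
Passing the end-to-end checks therefore demonstrates that the inference
chain is correct under its own forward model, not that it is robust to
every artefact of real libraries.

## Problem sizes and runtime choices

The shipped analyses and tests run at desk scale by design: 4–6
transcripts of 500–700 bases (≈ 1,200 cytosines per condition), ten
seeded end-to-end cluster-recovery runs, twenty 500-site null
calibration runs, fifty-run clone-filter operating characteristics, and
Fisher-oracle sweeps over all 2×2 tables with total ≤ 40. These sizes
put every Monte-Carlo estimate inside a minute or two on one CPU while
keeping the binomial standard errors small relative to the thresholds
they probe.

## Known limitations

Transcript-space ungapped mapping cannot place reads across unmodelled
junctions or indels; parity with genome-scale bisulfite aligners is not
claimed. The exact χ² enumeration is implemented for two-column tables
only (the methylated/unmethylated design); wider tables fall back to the
asymptotic p. The clone consistency rule's recurrence cutoff and discard
thresholds are recorded package defaults, not published values. Survival
modelling and any genome-coordinate annotation of sites are out of
scope.
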