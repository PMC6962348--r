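---
title: "Methods: convergence, clonality, error artifacts, and response prediction"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: convergence, clonality, error artifacts, and response prediction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrconv)
```

# Statistics

A *clone* is a unique TCRB nucleotide rearrangement together with its V-gene
call; the clone identity key is `(cdr3_nt, v_gene)` with the V gene stripped
of allele information (everything after the first `*`). Rows of an ingested
clonotype table sharing the key are merged by summing reads, and clone
frequencies are always recomputed as `read_count / total retained reads` —
a file's own frequency column is used only as an exclusion flag (the
ImmunoSeq-dialect rule dropping rows with a null `productive_frequency`),
because after row exclusion the published frequencies no longer normalise.

*Convergence* groups clones by `(v_gene, cdr3_aa)`; groups with at least
two nucleotide-distinct members are convergent and the statistic is the
summed frequency of all their members. The CDR3 amino-acid string is
compared as reported, anchors included; anchor trimming enters only the
error model's length term. Grouping defaults to productive clones only
(configurable), since non-productive rearrangements cannot express a
receptor. Exact string matching is deliberate and stringent: fuzzy or
functional clustering of similar-but-nonidentical sequences is out of
scope, so the statistic is a lower bound on functional convergence.

*Shannon diversity* is $-\sum_i f_i \log_2 f_i$ (bits), *evenness* divides
by $\log_2 N$, and *clonality* is $1 - \text{evenness}$ — zero for a
perfectly even repertoire, approaching one for a monoclonal one. Evenness
is undefined at $N = 1$ and the functions refuse non-normalised input
(sum-to-1 tolerance $10^{-6}$) rather than silently rescaling. Clonal
overlap is a Jaccard index on nucleotide-level clone keys by default; an
amino-acid-level mode exists for cross-platform comparisons where
nucleotide junctions are not comparable.

# The substitution-error artifact model

A synonymous substitution error in a read of clone $i$ creates a
nucleotide-distinct, amino-acid-identical artifact clone that joins clone
$i$'s convergence group. The model reduces this to four factors: reads
$r_i$, anchor-trimmed CDR3 length $L_i$ (amino acids, so $3L_i$ error-prone
bases per read), a per-base substitution rate $e$, and the probability $s$
that a random CDR3 substitution is synonymous. With
$q = e \cdot s$ and $B_i = 3 L_i r_i$ base calls,

$$P_i = 1 - (1 - q)^{B_i}$$

is the probability that at least one synonymous errored base call occurs
(for an artifact-read threshold $t > 1$ the binomial tail
$P(X \ge t)$, $X \sim \mathrm{Bin}(B_i, q)$ is used). The predicted
artifact-driven convergence of a sample is $\sum_i f_i P_i$. Two design
choices here were genuinely open:

* **Artifact frequency mass.** Artifact clones' own frequencies are $O(e)$
  and are excluded by default (only the parent's frequency counts); a
  switch adds the expected artifact read mass for users who want the total.
* **Observed convergent groups.** The sum runs over *all* productive
  clones by default. An alternative — excluding clones already in an
  observed convergent group, so that genuine biological convergence is not
  attributed to error — is available as `exclude_grouped = TRUE`, but it is
  the wrong default for error-rate fitting: in an error-dominated dataset
  the observed groups *are* the artifact signal, and excluding them
  anti-correlates the prediction with the observation (we measured Spearman
  near −0.9 on simulated cohorts when fitting with the exclusion on).

The synonymous probability $s$ comes from full enumeration of the 61 sense
codons × 9 single-base substitutions (549 events; stop-producing
substitutions count as non-synonymous). Codon-uniform weighting gives
`r round(synonymous_substitution_prob(), 4)` — the conventional "about one
in four". An amino-acid-uniform weighting
(`r round(synonymous_substitution_prob("amino_acid"), 4)`) matches the
codon distribution of this package's uniform back-translation and is the
value used when fitting against repertoires simulated here; using the
mismatched weighting biases the recovered rate by the ratio of the two
values (about one grid step). With real data, codon usage inside the CDR3
is unknown and the codon-uniform value is the sensible default.

**Fitting.** `fit_error_rate()` scans a log-spaced grid (default 13 points
per decade over $[10^{-5}, 10^{-2}]$ errors per base, the plausible range
of residual substitution rates) and maximises the Spearman correlation
between predicted and observed convergence across a cohort, ties broken
toward the smaller rate; grid points with a constant predicted or observed
vector yield an undefined correlation and are recorded as `NA`, failing the
fit only if every point is undefined.

Because Spearman is rank-based, the fit can localise the rate only where
per-clone read counts straddle the model's saturation bend
$r^* \approx 1/(3 L q)$: below saturation the predicted values are a
near-linear (rank-preserving) function of $q$ and the correlation profile
is flat, while far above it the profile flat-tops (everything saturated)
and the smaller-rate tie-break walks to the plateau's left edge. The
packaged recovery experiment (`error_recovery_cohort()`) therefore spreads
the bend across the grid: 20 samples of 2,000 clones with clonality uniform
on [0.05, 0.35]; in half the cohort depth is anti-correlated with clonality
(~1.2 M reads down to ~65 k), producing the big-saturated-clone vs
deep-diffuse-mass rank swaps that identify low rates, and in the other half
depth is log-uniform on [30 k, 1 M] independent of clonality, keeping
shallow low-clonality samples whose unsaturated small-clone mass
distinguishes high rates. Tests assert the median recovered rate over three
seeded cohorts to within one grid step of the grid point nearest the truth;
single cohorts occasionally land two steps off, which is the honest
resolution of a rank statistic on 20 samples.

The model deliberately ignores motif-specific error hotspots, codon-usage
bias within real CDR3s, PCR-derived substitutions, and indel or
homopolymer errors; it is a first-order screen, not an error calibrator.

# The synthetic repertoire generator

`simulate_repertoire()` emulates the statistical structure the analysis
assumes, with full ground truth:

* **Frequencies.** A rank-frequency power law $f_i \propto i^{-s}$; the
  exponent is calibrated by bisection (60 iterations, tolerance 0.005)
  until the *realised* clonality — after deterministic largest-remainder
  apportionment of `depth` reads with a one-read floor per clone — is
  within 0.01 of the target. Unattainable targets raise an error. The true
  clone-frequency law of human peripheral-blood repertoires is not settled;
  the power law is a pragmatic stand-in calibrated only to clonality, and
  conclusions that depend on the exact tail shape should not lean on it.
* **Sequences.** CDR3 junctions are `C…F` with interior residues uniform
  over the 20 amino acids, lengths 8–20 from a discretised normal centred
  near 14–15 (typical of beta-chain junctions); V genes come from 40
  synthetic names with Zipf-like usage. Nucleotide junctions are
  back-translated with uniform random codon choice. Real IMGT gene usage
  and real positional amino-acid biases are *not* modelled, so passing
  tests demonstrate algorithmic correctness, not biological realism.
* **Planted truth.** Convergent groups (sizes 2–4, default mix 70/20/10)
  are planted by rewriting selected clones into synonymous variants of a
  seed clone — identical V gene and amino acids, pairwise-distinct
  nucleotides. Either a group count or a target aggregate frequency can be
  requested; with a target, groups are accumulated from clones small enough
  not to overshoot, stopping within about two minimum clone frequencies of
  the target. With no error injection the metrics module recovers the
  planted aggregate exactly (up to floating-point summation order,
  ~$10^{-18}$).
* **Error injection.** `inject_errors()` substitutes each base of the
  anchor-trimmed CDR3 window of each read independently with probability
  `error_rate` (uniform choice among the three alternatives). Errored reads
  regroup into clones by mutated sequence; synonymous mutations inflate
  convergence, non-synonymous ones create new amino-acid clones, and
  stop-introducing mutations are dropped as non-productive (counted in the
  truth record, which also logs every artifact's parent). Anchor codons are
  left untouched: they are templated, conserved bases whose miscalls would
  break junction recognition upstream of clonotype calling, and this keeps
  the simulator's length convention identical to the model's. For speed,
  single-substitution reads (the vast majority at realistic rates) are
  aggregated by a multinomial draw over the $3W$ possible variants;
  multi-hit reads are realised individually with distinct positions. The
  aggregation is statistically identical to per-read draws.
* **Cohorts.** `generate_cohort()` draws per-subject targets from
  class-conditional distributions calibrated to the responder /
  non-responder feature summaries the classifier is designed around:
  log-normal convergence with medians 0.022 (responders) and 0.008
  (non-responders) and log-sd 0.7 / 0.55 chosen so the 2-sigma ranges match
  the reported spreads (0.006–0.092 and 0.002–0.019), and truncated-normal
  clonality with means 0.24 / 0.133, sd 0.08 / 0.07, truncated to the
  reported ranges. Features are drawn independently within class.
  `simulate_repertoire()` defaults to full study scale (30,000 clones,
  1.5 M reads); `generate_cohort()` defaults to desk scale (3,000 clones,
  150 k reads) because cohort-level experiments multiply per-repertoire
  cost by the cohort size, and the class separation lives in the feature
  targets, not the repertoire size.

All generators are pure functions of (configuration, seed).

# The response classifier

`fit_logistic()` is an unregularised maximum-likelihood binomial GLM (IRLS,
via `stats::glm`) with no feature standardisation; perfectly separable data
return saturated probabilities with the separation flag set rather than an
error, matching standard GLM behaviour. `lgocv()` repeats random
class-stratified splits (train fraction applied per class with floor
rounding — stratification keeps both classes in every 22-sample-scale
training set, which an unstratified default would not guarantee), scores
the held-out samples, and pools all held-out scores into a single
prediction set; the ROC curve, AUC (midrank Mann–Whitney form, equal to the
trapezoidal rule under the tie-collapsed sweep), and Youden-optimal
operating point are computed on that pool. Youden ties are broken toward
the higher specificity, i.e. the higher threshold; PPV comes from the
pooled confusion matrix at the chosen threshold. Everything is reproducible
from one integer seed.

Two properties of pooled cross-validated AUC are worth knowing. First,
on permuted labels it is biased *below* 0.5 at small sample sizes (training
noise anti-correlates with the held-out complement); the null centres on
0.5 only as the cohort grows, which is why the packaged null experiment
uses 200 samples. Second, whether the two-feature model beats the better
single feature on a given small cohort is itself noisy; the ordering test
uses 60-sample cohorts and 20 replicates and asserts the ordering in at
least 80% of them.

# Problem sizes used by the test suite

Unit tests run at a few hundred clones per repertoire. The end-to-end
checks use: 500 random repertoires (≤ 200 clones) for the convergence
oracle; 100 seeded simulations (300 clones, 20 k reads) for planted-truth
recovery; 20-sample × 2,000-clone cohorts, three seeds per rate, for
error-rate recovery at $10^{-4}$, $10^{-3}$, and $8.5\times10^{-3}$;
30 samples (1,500 clones, 100 k reads) for the convergence–clonality
coupling; and twenty 30+30-subject cohorts (600 clones, 36 k reads each)
plus one 100+100 permutation cohort for the classifier ordering and null.

# Limitations

* Substitutions only: no indels, homopolymer errors, chimeras, or PCR
  branching-process amplification noise.
* One chain (TCRB); no TCRA, IGH, or paired-chain support.
* The error-rate fit is a rank-based one-parameter screen; it cannot
  separate sequencing from residual PCR substitutions and inherits the
  identifiability limits described above.
* Synthetic cohorts share none of the immunological covariance structure
  of real cohorts (cancer type, treatment, age); classifier results on
  them validate the machinery, not the biomarker.
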