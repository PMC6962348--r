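# tcrconv

Analysis of T cell receptor beta (TCRB) repertoires from clonotype tables:
convergent-recombination and clonality statistics, a substitution
sequencing-error artifact model, and a two-feature logistic-regression
classifier of immunotherapy response — plus a synthetic repertoire
simulator with planted ground truth so that every stage can be validated
without access to patient data.

## The science

Chronic antigen-driven selection can expand T cell clones whose receptors
share antigen specificity — identical in amino-acid space — while differing
at the nucleotide level, because V(D)J recombination can reach the same
protein through different junctions. **TCR convergence** quantifies this:
for a repertoire with clone frequencies *f_i* (clones = unique TCRB
nucleotide rearrangements), convergence is the aggregate frequency of all
clones that share an allele-stripped V gene and CDR3 amino-acid sequence
with at least one other clone.

Complementary statistics describe clonal expansion: Shannon diversity
*H = −Σ f_i log₂ f_i*, evenness *H / log₂ N* for *N* detected clones, and
**clonality = 1 − evenness**. Clonal overlap between two samples is a
Jaccard index over (CDR3 nucleotide, V gene) clone keys.

Convergence has a failure mode: a *synonymous* substitution sequencing
error turns reads of one clone into a nucleotide-distinct,
amino-acid-identical artifact clone — indistinguishable from true
convergence. The package models the probability that a clone spawns such an
artifact from four factors: its read count *r*, its anchor-trimmed CDR3
length *L* (amino acids), the per-base substitution error rate *e*, and the
probability *s* that a random CDR3 substitution is synonymous (≈ 1/4 by
codon-table enumeration):

    P(artifact) = 1 − (1 − e·s)^(3·L·r)

Summing *f_i · P_i* over clones gives the expected artifact-driven
convergence of a sample; scanning *e* over a log grid and maximising the
Spearman correlation between predicted and observed convergence across a
cohort estimates the platform's residual error rate.

Finally, convergence and clonality measure distinct repertoire features and
can be combined: a logistic regression with the two features as predictors
and clinical response as outcome is evaluated by repeated leave-group-out
cross-validation (random class-stratified 75/25 splits, held-out scores
pooled into one ROC curve), with the operating threshold chosen by
Youden's J.

## A worked example

```r
library(tcrconv)

# simulate a repertoire with planted convergent groups
cfg <- simulation_config(n_clones = 2000, depth = 100000,
                         clonality_target = 0.24, n_true_groups = 20,
                         seed = 7)
sim <- simulate_repertoire(cfg)
repertoire_summary(sim$repertoire)
#>   sample_id n_clones total_reads shannon_bits  evenness clonality convergence
#> 1      sim7     2000       1e+05     8.328108 0.7594631 0.2405369     0.01211
#>   n_convergent_groups
#> 1                  20
sim$truth$true_convergence
#> [1] 0.01211
```

The summary row reports 2,000 clones at 100,000 reads; clonality lands
within 0.01 of the 0.24 target (the simulator calibrates its
frequency-skew exponent by bisection), and the measured convergence
(0.01211) equals the planted aggregate frequency exactly, since no
sequencing errors were injected. With errors on, artifact clones appear and
convergence inflates:

```r
cfg_err <- simulation_config(n_clones = 2000, depth = 100000,
                             clonality_target = 0.24, n_true_groups = 0,
                             error_rate = 1e-3, seed = 7)
sim_err <- simulate_repertoire(cfg_err)
sim_err$truth$realized_convergence_with_errors
#> [1] 0.6454218
```

Classifying a labelled cohort:

```r
cohort <- generate_cohort(11, 11, seed = 1, n_clones = 1000, depth = 60000)
cv <- lgocv(cohort$features, c("convergence", "clonality"),
            n_splits = 2000, seed = 1)
print(cv)
#> Leave-group-out cross-validation (convergence + clonality)
#>   splits: 2000 at train fraction 0.75 (12000 pooled predictions)
#>   pooled AUC: ...
```

Clonotype tables in the ImmunoSeq-flavored dialect (`amino_acid`,
`v_gene`, `v_family`, `reads`, `productive_frequency`) or an AIRR-flavored
dialect (`junction`, `junction_aa`, `v_call`, `duplicate_count`,
`productive`) are read with `read_clonotype_table()`; a full
ingest → summarise → model-errors → classify run is one call to
`run_pipeline()` (see `inst/scripts/tcrconv.R` for the command-line
wrapper).

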