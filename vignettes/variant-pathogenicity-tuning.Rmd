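---
title: "Metaheuristic-tuned gradient boosting for variant pathogenicity: models, encodings, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaheuristic-tuned gradient boosting for variant pathogenicity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

`myelotune` classifies somatic variants from a targeted myeloid NGS panel
as benign or pathogenic. This vignette is the package's own account of the
science inside it: the feature encoding, the tuning objective, the four
optimizers, the evaluation statistics, the synthetic cohort the tests run
on, and the places where the design was genuinely open and a choice had to
be made.

## 1. The classification problem

A targeted myeloid panel (24 genes recurrently mutated in myeloid
neoplasms) produces thousands of called variants per year, each annotated
with its genomic location, variant class (SNV/MNV/INDEL), HGVS coding and
protein consequence, variant allele frequency (VAF), population minor
allele frequency (MAF), and read depth. A biologist labels each variant
benign (0) or pathogenic (1) after manual review. The package learns that
decision as a supervised binary classifier

$$f : \mathbb{R}^{14} \rightarrow \{\text{benign}, \text{pathogenic}\}$$

fit by gradient-boosted trees (XGBoost), with the probability output
additionally mapped to five reporting tiers.

## 2. Feature encoding

`build_feature_vector()` turns one annotated record into 14 numeric
predictors:

| Feature | Meaning | Coding |
|---|---|---|
| `chr` | chromosome | 1–22, X = 23, Y = 24 |
| `POS` | genomic position | raw integer (opaque to the model) |
| `TypeBin` | variant class | SNV = 0, MNV = 1, INDEL = 2 |
| `Exon` | exon ordinal | 0 when intronic |
| `Freq` | VAF | fraction in [0, 1] |
| `MAFbin` | population MAF | value, or −1 when absent |
| `Coverage` | read depth | raw (optional 300× binarization) |
| `Protbin` | protein consequence class | p.? = 0, p.(=) = 1, change = 2 |
| `aarefbin` | reference residue | Arg = 1 ... Cys = 21 |
| `aamutbin` | mutant residue | as above, plus fs/Ter/del/dup = 22 |
| `aarefChemical` | ref polarity group | see below |
| `aamutChemicalVal` | mut polarity group | see below |
| `Grantham` | substitution distance | 5–215, or −1 |
| `varEffectBin` | reading-frame effect | syn = 0, mis = 1, non = 2, fs = 3, unk = −1 |

Polarity groups encode the side-chain chemistry as group.member decimals:
apolar 1.1–1.9 (Ala ... Gly), polar uncharged 2.1–2.7 (Cys ... Tyr),
negatively charged 3.1–3.2 (Asp, Glu), positively charged 4.1–4.3 (His,
Lys, Arg); all non-residue tokens carry 0.0. The missing code 2.2 in the
uncharged series is deliberate — the published grouping skips it, and we
reproduce the published codes verbatim rather than renumbering.

The Grantham distance quantifies the physico-chemical dissimilarity of an
amino-acid substitution from composition, polarity, and molecular volume.
The package embeds the published 1974 matrix as a constant instead of
re-deriving it from the property formula: the properties and their
weighting constants are not part of this package's scope, and the embedded
matrix's range (minimum off-diagonal 5 for Leu/Ile, maximum 215 for
Cys/Trp) is exactly the range the encoding expects. The matrix is checked
in the tests for symmetry, zero diagonal, and both extremes.

**Sentinel policy.** When the protein consequence is not a single-residue
change (`p.?`, `p.(=)`, frameshift, stop, deletion), the residue block is
filled with sentinels: `aarefbin`/`aamutbin` 0 (no residue), polarity 0.0,
`Grantham` −1. A synonymous consequence with a stated residue
(`p.Leu422=`) keeps its reference-side identity. `dup` is grouped with
fs/Ter/del under mutant code 22; the published table only prints the
latter three, so this is a documented convention, not a sourced value.

**Coverage.** The source encoding table is self-contradictory about read
depth (a 300× binarization in the description column, "no encoding" in the
coding column). The package passes raw depth through by default and
exposes the binarization as `codec_dialect(binarize_coverage = 300)`.

**HGVS parsing.** `parse_protein_change()` accepts substitutions
(`p.Lys385Thr`, one-letter `p.V617F`), stop gains (`p.Ser1518Ter`),
frameshifts (`p.Arg123fs`, `p.Lys385IlefsTer12`), single-site and range
deletions/duplications (`p.Gly104del`, `p.Leu747_Ala750del`), delins
(mapped to the `del` mutant token), and the sentinels `p.?`/`p.(=)`.
Anything else is a parse error rather than a silent sentinel: a panel
pipeline emitting an unexpected dialect should fail loudly.

## 3. The tuning objective

Tuning maximizes mean accuracy under stratified k-fold cross-validation
(default 10 folds × 3 repeats) of the gradient-boosted learner on the
balanced training table:

$$\mathrm{Accuracy}(\theta) = \frac{TP + TN}{TP + TN + FP + FN}$$

computed per held-out fold and averaged. `cv_accuracy_fitness()` sorts the
table canonically before partitioning, so the fitness is invariant to
input row order, and fixes the learner to a single thread with a seeded
RNG, so the same (position, table, seed) always returns the same number.
CV folds partition the oversampled table directly (the pipeline's stated
order: split, balance the training side, then cross-validate on it); the
alternative of re-balancing inside every fold is deliberately not the
default, and the known consequence — smoothed copies of one minority row
can fall on both sides of a fold boundary, inflating CV accuracy
estimates — is why the final evaluation always uses the untouched test
split.

Seven hyperparameters are searched inside a box (`default_search_space()`):

| Dimension | Bounds | Decoding |
|---|---|---|
| `nrounds` | [100, 600] | rounded to integer |
| `eta_exponent` | [−5, 0] | learning rate = 10^x |
| `max_depth` | [2, 6] | rounded to integer |
| `gamma` | [0, 1] | as-is |
| `colsample_bytree` | [0.4, 1] | as-is |
| `min_child_weight` | [1, 3] | rounded to integer |
| `subsample` | [0.5, 1] | as-is |

The learning rate is searched on a log10 scale. The default exponent range
is [−5, 0]: tuned optima for this kind of objective typically land around
10^−1, and a cap at 10^−3 would exclude them; the deliberately
slow-learning range [−5, −3] remains available via
`default_search_space(eta_bounds = c(-5, -3))`. The search itself is fully
continuous; integer-valued controls are rounded only at decode time, so
optimizers can report fractional coordinates (e.g. a best depth of 4.71
decodes to 5).

**Class imbalance.** With ~15:1 benign:pathogenic imbalance, accuracy on
raw data is a degenerate objective. `oversample_minority()` grows the
minority class to parity by a smoothed bootstrap: minority rows are
resampled with replacement and the continuous features (`Freq`, `MAFbin`
where present, `Coverage`, `POS`) receive zero-mean Gaussian noise with
per-feature bandwidth = Silverman's rule × a configurable factor
(`jitter`, default 1; 0 degenerates to a plain bootstrap). Jittered values
are snapped back to the source column's empirical measurement quantum (the
smallest observed increment), so synthetic rows live on the same value
grid as real measurements — a VAF recorded at two decimals never spawns
copies at machine precision. Sentinel values (−1) are never jittered, and
majority rows are never touched.

## 4. The four optimizers

All four share one contract: maximize `objective(position)` inside the
box, keep every evaluated position feasible by clipping (projection — the
simplest bound rule, applied uniformly), draw all randomness from one
seeded generator per run (bit-identical reruns), and record a
non-decreasing best-so-far trace with a fixed iteration budget (no early
stopping).

* **Differential evolution** (`de_optimize`), classic rand/1/bin: for each
  member, mutant $v = x_{r1} + F (x_{r2} - x_{r3})$ from three distinct
  partners, binomial crossover at rate CR with one guaranteed mutant
  coordinate, greedy selection; an exact fitness tie is resolved by a fair
  coin. Defaults F = 0.5, CR = 0.9, population 10, 10 generations.
* **Particle swarm** (`pso_optimize`):
  $v \leftarrow \omega v + c_1 r_1 (p_{best} - x) + c_2 r_2 (g_{best} - x)$,
  fresh uniform r per component per term. The inertia weight is ω = 0.5
  and the cognitive/social coefficients are 2.05. The single stated
  "learning rate 0.5" of this algorithm family is interpreted as the
  inertia weight — the only velocity-equation symbol without a stated
  value once c1 and c2 are fixed.
* **Genetic algorithm** (`ga_optimize`), real-coded: per generation the
  top `elitism` fraction (default 0.3 → exactly 3 of 10) survives
  unchanged with cached fitness, a `random_selection` fraction (0.1) is
  admitted uniformly at random to preserve diversity, and the remainder
  are children of rank-weighted parents (selection probability linear in
  rank) combined by one-point crossover at a uniform cut; every non-elite
  gene then mutates with probability 0.5 by uniform resampling within its
  bounds. Population size is invariant.
* **Simulated annealing** (`sa_optimize`): one chain; the candidate is
  $x' = x + \delta \odot r$ with r uniform on [−1, 1] per coordinate,
  projected into the box. Improvements are always accepted; a worsening Δ
  is accepted with the Metropolis probability exp(Δ/T) (maximization
  form — the acceptance rule is stated qualitatively in this algorithm
  family, and Metropolis with geometric cooling T ← 0.95 T is the
  standard concrete choice). δ is expressed per dimension as a fraction
  (default 0.1) of the box range, because a single absolute step is
  meaningless across `nrounds` ∈ [100, 600] and `subsample` ∈ [0.5, 1].
  The best-ever state is returned, not the final one. Default budget 100
  iterations.

Budget accounting is exact and tested: DE and PSO evaluate
population × (iterations + 1); GA evaluates pop + generations × (pop −
elites); SA evaluates 1 + iterations.

## 5. Evaluation statistics

`classification_metrics()` computes accuracy, precision TP/(TP+FP), recall
TP/(TP+FN), specificity TN/(TN+FP), error rate 1 − accuracy, F1 =
TP/(TP + (FN+FP)/2), the Matthews correlation coefficient

$$\mathrm{MCC} = \frac{TP \cdot TN - FP \cdot FN}
{\sqrt{(TP+FP)(TP+FN)(TN+FN)(TN+FP)}}$$

and Cohen's kappa $(p_o - p_e)/(1 - p_e)$ with the expected agreement from
marginal products. Conventions for degenerate inputs: a zero denominator
in precision/recall/specificity/F1 yields 0 with a warning; MCC with an
empty marginal is 0; kappa with degenerate marginals is 1 for perfect
agreement and 0 otherwise. Confusion matrices are oriented rows =
predicted, columns = actual throughout.

Kappa interpretation bands run None (≤ 0.20), Minimal (to 0.39), Weak (to
0.59), Moderate (to 0.79), Strong (to 0.90), Almost perfect (above 0.90).
The published interpretation table this follows skips the 0.60–0.79 band
and stops at 0.20 on the low side; the gap is filled with the standard
"Moderate" label and negative values report "None", so the function is
total on [−1, 1].

`roc_curve()` sweeps the decision threshold over the unique scores (ties
stepped simultaneously) and integrates by the trapezoidal rule; this
equals the normalized Mann–Whitney U statistic with ties counted half,
which the tests verify by brute-force enumeration over all
(positive, negative) pairs, and cross-check against pROC.

`assign_tier()` maps a probability into five ordered tiers using
contiguous half-open intervals — [0, 0.001) Benign, [0.001, 0.05) Likely
benign, [0.05, 0.95) Uncertain, [0.95, 0.99] Likely pathogenic, (0.99, 1]
Pathogenic. The published tier table prints gapped decimal ranges ("0.001
to 0.049", "0.05 to 0.949"); closing the gaps makes the function total and
monotone on [0, 1], which the tests assert on a fine grid.

## 6. The synthetic cohort generator

The real training cohort is clinical data and cannot ship. The generator
(`generate_cohort()`) reproduces its *marginal* structure exactly — by
default 13,221 SNV / 73 MNV / 2,683 INDEL records and 14,957 benign vs
1,020 pathogenic labels over the 24-gene panel — and invents documented
class-conditional distributions for everything else:

* **MAF is the dominant signal**, as in the real data: benign variants are
  population polymorphisms with a recorded MAF 97% of the time
  (Beta(1.6, 10) frequencies recorded at database precision), while
  pathogenic variants have one only 40% of the time, and then vanishingly
  small (Beta(1.3, 60)). The −1 sentinel and the value continuum are both
  informative.
* **VAF is deliberately class-neutral**: both classes draw from the same
  mixture (heterozygous-like mass near 0.5, homozygous-like near 1.0, and
  a subclonal component straddling the 5% review threshold). The
  pathogenicity signal is carried by population frequency and consequence,
  not by allele fraction.
* **Consequences**: pathogenic SNVs/MNVs are enriched for missense and
  nonsense changes and pathogenic INDELs for frameshifts; benign rows skew
  to synonymous and intronic consequences. Missense residue pairs are
  drawn with pathogenic substitutions skewed to high Grantham distance
  ((5 + g)^2.5 weighting) and benign ones to conservative exchanges.
* **Positions** are drawn from a small per-gene lattice of recurrent
  sites, emulating how an amplicon panel calls the same hotspots over and
  over; no real transcript coordinates are claimed. **Coverage** is
  negative-binomial-like, floored near the 300× QC bound, reported at
  amplicon-level granularity.
* **Label noise** (default 0.5%) draws a noise fraction of rows' features
  from the opposite class, keeping the emitted label counts exact while
  making the feature-to-label map probabilistic.

Every emitted record passes the codec's invariants and round-trips through
`write_variants_tsv()` / `load_annotation_table()`.

What passing tests on this cohort do **not** show: the generator does not
target the real cohort's joint feature correlations, per-gene mutation
spectra, or the published headline accuracy on clinical data (testing that
would require the private cohort). It shows that the pipeline's machinery
— encoding, balancing, tuning, training, evaluation, tiering — is correct
and that the model recovers a planted MAF-dominant signal.

## 7. Problem sizes and numerical choices in the test suite

The suite runs entirely on synthetic data at sizes chosen to keep a full
run in the low minutes on one CPU: the cohort-margin checks use the
full-size default cohort (generation only); model-fitting checks use
cohorts of 500–2,000 records with 3–5 fold single-repeat CV; the
parameter-recovery check tunes with DE at population 6 × 5 generations
against a 200-point random-search baseline on the same space and objective
(the tuned result must come within 0.02 of the baseline, and the final
model must reach test AUC ≥ 0.95 with `MAFbin` ranked first in split-count
importance); optimizer convergence is checked on analytic objectives
(3-D sphere, 1-D quadratic) and against the 99.9th percentile of an
exhaustively enumerated 129 × 129 lattice of a 2-D multimodal surface; and
the metric implementations are compared with brute-force oracle
evaluations on 1,000 random confusion matrices and pairwise-enumerated
AUCs. SA's Metropolis rule is verified empirically: at held temperature
the downhill acceptance frequency over 10^4 iterations must match exp(Δ/T)
within three standard errors.

## 8. Known limitations

* The codec trusts the upstream annotation pipeline: it never inspects
  reads or calls variants, and positions are opaque features (no interval
  arithmetic, no liftover).
* Accuracy as a tuning objective is only meaningful after balancing;
  tuning on the raw imbalanced table would reward the majority-class
  predictor.
* CV partitioning of the oversampled table inflates cross-validated
  accuracy relative to the untouched test split (see §3); rely on the test
  split for generalization claims.
* Split-count ("weight") feature importance counts how often a feature is
  used, not how much it contributes per use; high-cardinality features are
  structurally favored. Gain-based importance would rank differently.
* The five tier boundaries are fixed conventions, not calibrated
  probabilities; a deployment should verify calibration on its own data.
* How duplications and delins variants were coded in the original
  encoding scheme is not printed in the source material; the `dup` → 22
  convention here is a documented guess.
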