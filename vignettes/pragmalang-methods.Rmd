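---
title: "Methods: quantifying pragmatic language in tagged language samples"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: quantifying pragmatic language in tagged language samples}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pragmalang)
```

`pragmalang` operationalizes a multi-method computational analysis of
pragmatic language in dialog-act-tagged language samples from two
elicitation contexts: a picture-book narration and a semi-structured
conversation with an examiner. This vignette is the package's own
account of the models it implements, the decisions taken where the
methodology was genuinely open, and what its validation on synthetic
data does and does not establish.

## The transcript dialect and counting rules

Full language-sample transcription conventions (SALT, CHAT) are large;
the package defines a minimal, documented dialect sufficient for the
analyses: `@` header lines carrying id, task, diagnosis, sex, age and
verbal IQ, then one utterance per line as
`<speaker-code> <act-tag><TAB><text>`, with maze spans (false starts,
repetitions, reformulations) in parentheses. The dialect round-trips:
`read_transcript()` and `write_transcript()` are mutually inverse up to
whitespace, which the test suite checks on generated corpora.

Tokenization is deliberately simple and deterministic — whitespace
split, terminal punctuation stripped, case folded, hyphenated forms
kept whole — so that every downstream count has an obvious brute-force
oracle.

Counting follows the clinical convention for this kind of sample: maze
tokens are excluded from the participant word count, filled pauses
("um", "uh", "er", "hm", "mhm"; configurable) are included, and
examiner tokens never count. Two boundary decisions were open and are
fixed as follows: a filled pause *inside* a maze is not counted (maze
exclusion operates on whole spans), and filled pauses are ordinary
tokens in all utterance-level analyses (the convention only addresses
word counts). Narrative transcripts may contain examiner utterances in
the file, but these are excluded from every narrative statistic.

## Dictionary-based word classification

The lexicon module reimplements the LIWC matching convention
generically: named categories of literal entries and trailing-`*`
wildcard stems (prefix match, empty suffix allowed), read from
`%`-delimited `.dic` files. Multi-word entries ("as a result", "in
order to") are supported as n-gram entries matched greedily left to
right within an utterance; a multi-word match counts once and consumes
its tokens, while a single token may match several categories
simultaneously. A token increments a category at most once however many
of that category's entries it matches. Composite categories sum their
constituents without deduplication, mirroring LIWC's summed scales:
affective states and behaviors (simple + complex affect + affective
behaviors), cognitive states and behaviors, and their union.

The shipped `default_lexicon()` is intentionally small — it contains
only published example words for each theoretically derived category
(e.g. *happy, sad, angry, afraid, disgust, surprise, joy, mad* for
simple affect; *shame, pride, guilt* for complex affect; *because,
since, therefore, as a result, in order to* for causal language) — and
exists so that examples, tests and the synthetic generator have a fully
known dictionary. Real analyses should supply their own `.dic` files via
`read_lexicon()`.

Category scores are reported as raw counts and as percents of the
participant word count; with a zero word count percents are missing,
never zero. Whether maze tokens should be classified is not settled by
the conventions above; the package applies the word-count rule uniformly
(mazes excluded) and exposes `count_mazes = TRUE` to flip both the
numerator and the denominator.

## A-priori speech-act sequences

Eight named bigram sequences over adjacent utterances are counted.
Narrative sequences operate on participant utterances only, with
examiner utterances removed *before* pairing: consecutive on-topic
speech (both members statement / question / character speech / sound
effect), consecutive off-topic speech (both nonnarrative / thinking),
and consecutive storytelling effects (both character speech / sound
effect). Conversational sequences are speaker-aware: non-obligatory
response and backchannel (after examiner non-questions),
self-elaboration (participant followed by participant), and expected
(reply/clarification) versus unexpected (backchannel/initiation)
responses after examiner questions.

Two reconstruction decisions deserve emphasis. First, "non-obligatory
response to examiner speech" is under-defined in the hand-coding
literature; the package's default reading is *a non-backchannel
participant response to an examiner non-question*, and
`non_obligatory_includes_backchannel = TRUE` widens it. Second, the
normalization of sequence counts is not standardized; the package
reports raw counts together with sequence-specific opportunity
denominators (number of adjacent pairs whose first member qualifies),
which makes rates comparable across transcripts of very different
lengths. A run of r qualifying utterances contributes r − 1 pairs.

## Markov chains and the divergence rate

Speech-act dynamics are modeled as first-order Markov chains over the
task's tag set plus a `START` boundary state; for conversation the
examiner tags are part of the state space by default, because the
conversational sequences above are speaker-aware. Transition counts are
pooled across a group's transcripts — each transcript contributes
`START → first tag` and its within-transcript bigrams, and no
transition crosses a transcript boundary — then smoothed with a
pseudo-count (`alpha = 0.5` by default, a Jeffreys-style prior). The
smoothing is required: the divergence below needs a strictly positive
reference chain, and observed groups differ in which transitions they
visit. Pooling (rather than averaging per-transcript chains) is the
default because many individual transcripts visit some states only a
handful of times.

Groups are compared with the Kullback–Leibler divergence rate

$$D(P\|Q) \;=\; \sum_i \pi_P(i) \sum_j P(i,j)\,
\ln\frac{P(i,j)}{Q(i,j)},$$

the expected per-step log-likelihood ratio, with $\pi_P$ the stationary
distribution of $P$ obtained by power iteration from the uniform vector
(residual tolerance 1e-10, matched against an eigen-solver in tests).
Because single divergences depend on group ordering, the package reports
forward, reverse, and their mean, and uses the symmetrized value as the
test statistic.

No standard null distribution exists for divergences between chains
estimated from finite transcript collections, so significance comes
from a transcript-level label permutation: group labels are reshuffled
(sizes preserved), both chains re-estimated, and the symmetric
divergence recomputed; the p-value uses the add-one rule
$(1 + \#\{D^{perm} \ge D^{obs}\})/(1 + B)$. Permuting whole transcripts
respects within-transcript dependence. This permutation design is the
package's own documented reconstruction of "divergence with pairwise
p-values" reporting — the calibration test (two groups drawn from one
chain; rejection rate at the 5% level within [0.03, 0.07] over 500
replicates) is what justifies it.

## Latent profile analysis

Subgroup discovery uses a from-scratch latent profile model: a
finite mixture of diagonal-covariance Gaussians over z-scored
indicators, fit by EM. Indicators are standardized by `zscore_matrix()`
(listwise deletion, zero-variance columns are an error) because the
profile indicators mix scales (percents, rates, totals). Covariance
structure is class-varying diagonal — the most common LPA default when
software is unreported — with an equal-variance alternative behind
`equal_variances = TRUE`. Free parameters are counted as
$p = (k-1) + kd + kd$ (mixing weights, means, variances), giving
$\mathrm{AIC} = -2\ell + 2p$ and $\mathrm{BIC} = -2\ell + p\ln n$.

Numerical choices: each fit takes the best of `restarts = 20`
kmeans++-seeded EM runs by log-likelihood; convergence is declared when
the log-likelihood gain falls below `tol = 1e-6`; variances are floored
at `var_floor = 1e-4` (in z-score units) to block degenerate spikes;
restarts that produce a profile with expected membership under one
observation are discarded, and a fit in which all restarts degenerate is
an error rather than a silent fallback. EM's log-likelihood ascent is
asserted on every run in the test suite. Classification quality uses
the normalized entropy $1 - \sum_{ic} -p_{ic}\ln p_{ic} / (n \ln k)$,
which is 1 for crisp assignment, 0 for uniform posteriors, and undefined
(reported missing) for a single profile.

Model selection follows the usual fit-table workflow: `lpa_select()`
fits 1–6 profiles and tabulates AIC, BIC, entropy, smallest/largest
profile proportions, and optionally the bootstrap likelihood ratio test
(BLRT): datasets are simulated from the fitted (k−1)-profile model,
both models are refit to each, and the observed
$2(\ell_k - \ell_{k-1})$ is referred to that parametric-bootstrap null
with an add-one p-value (`n_boot = 100` by default — a desk-scale
setting; failures are resampled up to three times the budget). The
bootstrap fits use the same number of EM restarts as the data fits by
default: an asymmetric protocol (fewer restarts on the bootstrap side)
systematically shrinks the null statistics relative to the observed one
and inflates rejection, an effect large enough to destroy the test's
level in our calibration runs. The
BIC-minimal model and any model containing a profile below 5% are
flagged, but the final choice is left to the analyst, who should also
weigh interpretability and subgroup size. Follow-up composition tests
(`profile_membership_test()`) compare each profile's diagnosis-by-sex
make-up against the remaining sample through the chi-square/Fisher
dispatch described below.

## The statistics harness

Group comparisons use two-factor (diagnosis × sex) ANCOVA with verbal
IQ as covariate, Type-III sums of squares under sum-to-zero coding —
the four cells are unbalanced, so sequential sums would be
order-dependent — with $\eta_p^2 = SS_{eff}/(SS_{eff}+SS_{res})$, and
estimated-marginal-means pairwise contrasts (marginal means at the
covariate mean, equally weighted over the other factor, t tests on the
model residual variance). A Wilks MANCOVA omnibus (Rao's F
approximation from hypothesis/error SSCP matrices) is available, but
per-outcome ANCOVAs are the default report, matching how such results
are conventionally presented. The implementations are hand-rolled on
ordinary least squares and are checked to 1e-8 against `car::Anova`,
`emmeans`, and `stats::anova.mlm` in the test suite.

Categorical outcomes dispatch on the standard rule: Fisher's exact test
(two-sided by the point-probability rule) when at least 20% of expected
cells fall below 5, Pearson chi-square without continuity correction
otherwise. Multiplicity uses Benjamini–Hochberg at FDR .10, applied
per analysis block (one coding system × task family by default) —
block-wise correction is configurable because the correct family is an
analysis decision, not a package decision. Partial Pearson correlations
use the residual-correlation definition with $n-2-q$ degrees of
freedom; inter-rater reliability uses ICC(2,1) (two-way random effects,
absolute agreement, single measure — the specific form is stated
because reliability reports frequently omit it) with the conventional
moderate/good/excellent cutpoints at .5/.75/.9, and percent agreement
for categorical codes.

## The synthetic generator and what passing tests mean

`generate_cohort()` draws transcripts per diagnosis-by-sex group from
explicit generative parameters: a speech-act transition matrix (the
planted dynamics), Poisson utterance counts and lengths, per-token
lexical emission rates into the shipped dictionary categories, maze and
filled-pause injection rates, and Normal covariate distributions. The
background vocabulary is a deterministic list of 500 pseudo-words
guaranteed not to match any dictionary entry, so expected category
percents equal the planted emission rates. Per-transcript seeds are
drawn once from the master seed, making cohorts reproducible and
individual transcripts regenerable.

The default configuration mirrors the study design this pipeline
targets: group sizes 73/27/40/47 (autistic male/female, non-autistic
male/female), verbal IQ means of 102 (SD 16) versus 108 (SD 13) for
autistic versus non-autistic groups, age 12 ± 3 years, transcripts
around 60–70 utterances with ~7-token utterances (comparable to
reported word counts of roughly 400–500 per narrative), and two planted
effects in the directions reported for such cohorts: autistic groups
receive less backchannel transition mass after examiner statements
(0.12 versus 0.32), and female groups emit complex-affect vocabulary at
a higher per-token rate (3.0% versus 1.2%). The magnitudes are the
package's own choice — large enough that recovery at n = 30 per group
is expected with power above 0.8 — because the source literature
reports directions and test statistics, not generative effect sizes.
Tests use 20–40 transcripts per group for speed; problem sizes used by
the validation suite (500 calibration replicates with 200 permutations;
100 profile-recovery runs at n = 150 with 7 indicators; 100 BLRT
replicates with 100 bootstraps at n = 100 with 3 indicators; 1000
replicates for the level checks of the linear-model tests; 50
end-to-end replicates at n = 30 per group) were chosen as the smallest
scales at which the Monte-Carlo error of the checked rates is
comfortably inside the asserted bounds.

What the generator does *not* emulate: real lexical distributions
(tokens are exchangeable given their category), syntax and semantic
coherence, examiner adaptivity, age- or IQ-dependent language change,
hand-coded instruments (narrative-quality ratings, pragmatic-violation
ratings enter only as synthetic fixtures where needed), and any
relationship between a participant's transition matrix and their
lexical rates beyond group membership. Passing the planted-effect tests
therefore shows that the estimators recover the structure they model —
not that real autistic and non-autistic speakers differ, nor that these
effect magnitudes are realistic.

## Degenerate inputs and edge behavior

Zero participant word count yields missing percents; zero opportunities
yield missing rates; `alpha = 0` with unvisited states normalizes rows
over visited support with a warning, and a divergence against a
zero-probability reference is `Inf` with a warning rather than an
error; duplicated-group permutation tests return p = 1 by the add-one
rule; constant outcomes give F = 0, p = 1; constant regression residuals
make partial correlations missing; all-constant ratings make the ICC
missing. Ties in modal profile assignment break toward the
lower-numbered profile.

## Known limitations

First-order chains only — no trigram or hidden-state dynamics; the
divergence rate inherits smoothing bias at small alpha and shrinks
toward zero at large alpha. The LPA is continuous-indicator only
(no mixed categorical-continuous models, no covariates on class
membership). The exact statistic and null of the original
divergence-model reporting, the original LPA software and covariance
structure, and the full novel dictionaries are not public; the
corresponding pieces here are documented reconstructions validated by
calibration, not re-implementations of unpublished code. Printed fit
indices from the motivating study (e.g. its LPA fit table) depend on
undeposited participant data and are not reproduction targets for this
package.
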