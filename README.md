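# pragmalang

Computational analysis of pragmatic language in dialog-act-tagged
language-sample transcripts.

Pragmatic language — the social use of language in context — is typically
quantified by labor-intensive hand coding of transcribed narrative and
conversational samples. `pragmalang` implements the computational side of
that workflow for clinical researchers studying neurodevelopmental
conditions (in particular, diagnosis-by-sex comparisons in autism): it
parses dialog-act-tagged transcripts, classifies words against
theoretically derived dictionaries, counts a-priori speech-act sequences,
compares groups' speech-act dynamics with Markov chains, discovers
participant subgroups with latent profile analysis, and runs the
surrounding group-comparison statistics. A synthetic-transcript generator
with planted group structure makes the entire pipeline testable without
any participant data.

## What it computes

**Transcripts.** A documented SALT-inspired plain-text dialect: `@` header
lines (id, task, diagnosis, sex, age, verbal IQ), then one utterance per
line `P statement<TAB>(the the) the frog left` with mazes (false starts and
reformulations) in parentheses. Word counts exclude maze tokens and
include filled pauses ("um", "uh", ...); examiner tokens never count.

**Lexicon matching.** LIWC-style `.dic` dictionaries with literal entries
and trailing-`*` wildcard stems, multi-word n-gram entries ("as a
result"), and composite categories that sum constituents (affective
states + behaviors, cognitive states + behaviors, affect and cognition).
Categories are reported as counts and as percents of participant word
count.

**Speech-act sequences.** Per-tag percents of participant utterances,
narrative tag diversity (0–7), and eight a-priori bigram sequences:
consecutive on-topic / off-topic / storytelling narrative speech, and
conversational non-obligatory response, backchannel, self-elaboration,
and expected/unexpected responses after examiner questions, each with
sequence-specific opportunity denominators.

**Markov-chain comparison.** Per-group transition matrices over
speech-act states (pooled across transcripts, `START` boundary state,
pseudo-count smoothing), compared by the Kullback–Leibler divergence
rate

D(P‖Q) = Σᵢ π_P(i) Σⱼ P(i,j) ln [ P(i,j) / Q(i,j) ]

with π_P the stationary distribution of P, symmetrized and tested by a
transcript-level label-permutation null with add-one p-values.

**Latent profile analysis.** Diagonal-covariance Gaussian mixtures fit
by EM (kmeans++-seeded restarts), AIC/BIC, normalized classification
entropy, the parametric bootstrap likelihood ratio test (BLRT), a
model-selection table over 1–6 profiles, and profile-membership
chi-square/Fisher tests.

**Statistics harness.** Two-factor Type-III ANCOVA with partial eta
squared and estimated-marginal-means contrasts, Wilks MANCOVA,
chi-square/Fisher dispatch under the 20%-expected-cell rule,
Benjamini–Hochberg adjustment (FDR .10), partial Pearson correlations,
multiple regression with overall-model gating, ICC(2,1), and percent
agreement.

## Worked example

```r
library(pragmalang)

# a synthetic conversation cohort with planted group structure
cfg <- default_synthetic_config(
  "conversation",
  n_per_group = c(asd_male = 30, asd_female = 30,
                  nonasd_male = 30, nonasd_female = 30),
  seed = 7)
cohort <- generate_cohort(cfg, "conversation")

# compare autistic vs non-autistic males' speech-act dynamics
asd_m <- Filter(function(t) t$diagnosis == "asd" & t$sex == "male", cohort)
non_m <- Filter(function(t) t$diagnosis == "non_asd" & t$sex == "male", cohort)
kl_permutation_test(asd_m, non_m, n_perm = 499, seed = 11)
#> Kullback-Leibler divergence-rate permutation test
#>   forward  D(A||B) = 0.0555 nats
#>   reverse  D(B||A) = 0.06646 nats
#>   symmetric        = 0.06098 nats
#>   p = 0.006  (499 label permutations, seed 11)

# planted diagnosis effect on the backchannel-sequence rate
seqs <- cohort_sequences(cohort)
a <- factorial_ancova(seqs$backchannel_seq_rate, seqs$diagnosis,
                      seqs$sex, seqs$viq)
a$table[1, c("effect", "F", "p", "eta_p2")]
#>      effect        F            p    eta_p2
#> 1 diagnosis 118.2969 2.238422e-19 0.5070658
```

The divergence of ~0.06 nats per utterance reflects the lower
backchannel transition mass planted in the autistic groups; the
permutation p of 0.006 says 2 of the 499 label shuffles matched or
exceeded it. The ANCOVA recovers the same planted effect at the outcome
level (ηp² ≈ .51 at these deliberately large synthetic effect sizes).

## Documentation

The methods vignette (`vignettes/pragmalang-methods.Rmd`) describes the
models, their assumptions, all tunable parameters and defaults, what
the synthetic generator does and does not emulate, and known
limitations.
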