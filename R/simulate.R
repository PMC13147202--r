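## Synthetic cohorts with planted group structure: per-group speech-act
## transition matrices, per-category lexical emission rates, maze and
## filled-pause injection, covariate distributions, and Gaussian-mixture
## feature generation for profile-recovery tests. Everything is
## deterministic given a master seed.

## deterministic neutral background vocabulary (CV-syllable pseudo-words),
## filtered so no word matches the shipped lexicon
.background_vocab_env <- new.env(parent = emptyenv())

background_vocabulary <- function(n = 500L, lex = default_lexicon()) {
  key <- paste0("v", n)
  if (!is.null(.background_vocab_env[[key]])) {
    return(.background_vocab_env[[key]])
  }
  cons <- c("b", "d", "f", "g", "k", "l", "m", "n", "p", "r", "s", "t")
  vow <- c("a", "e", "i", "o", "u")
  syl <- as.vector(outer(cons, vow, paste0))
  words <- as.vector(outer(syl, syl, paste0))
  ents <- unlist(lex$categories, use.names = FALSE)
  stems <- ents[endsWith(ents, "*")]
  stems <- substr(stems, 1L, nchar(stems) - 1L)
  lits <- setdiff(ents, ents[endsWith(ents, "*")])
  bad <- words %in% lits
  for (s in stems) bad <- bad | startsWith(words, s)
  words <- words[!bad]
  out <- head(words, n)
  .background_vocab_env[[key]] <- out
  out
}

#' Generative parameters for one diagnosis-by-sex group
#'
#' @param transition Row-stochastic transition matrix over the task's
#'   chain states (including `START`), as from
#'   [conversation_transition()] or [narrative_transition()].
#' @param n_utterances_mean Mean transcript length in utterances
#'   (Poisson, floored at 2).
#' @param utterance_length_mean Mean countable tokens per participant
#'   utterance (1 + Poisson).
#' @param examiner_length_mean Mean tokens per examiner utterance.
#' @param lexical_rates Named per-token emission probabilities for
#'   lexicon categories (the remainder is background vocabulary).
#' @param maze_rate Per-token probability of a maze flag.
#' @param filled_pause_rate Per-token probability of a filled pause.
#' @param viq_mean,viq_sd,age_mean,age_sd Covariate distributions.
#' @param profile_means Optional indicator-mean vector for feature
#'   generation.
#' @return A list of class `"group_params"`.
#' @export
group_params <- function(transition, n_utterances_mean = 60,
                         utterance_length_mean = 7,
                         examiner_length_mean = 6,
                         lexical_rates = c(), maze_rate = 0.05,
                         filled_pause_rate = 0.04,
                         viq_mean = 105, viq_sd = 15,
                         age_mean = 12, age_sd = 3,
                         profile_means = NULL) {
  stopifnot(all(abs(rowSums(transition) - 1) < 1e-8))
  if (any(lexical_rates < 0) || sum(lexical_rates) + filled_pause_rate > 1) {
    stop("invalid emission probabilities", call. = FALSE)
  }
  structure(list(transition = transition,
                 n_utterances_mean = n_utterances_mean,
                 utterance_length_mean = utterance_length_mean,
                 examiner_length_mean = examiner_length_mean,
                 lexical_rates = lexical_rates, maze_rate = maze_rate,
                 filled_pause_rate = filled_pause_rate,
                 viq_mean = viq_mean, viq_sd = viq_sd,
                 age_mean = age_mean, age_sd = age_sd,
                 profile_means = profile_means),
            class = "group_params")
}

.normalize_rows <- function(P) sweep(P, 1, rowSums(P), "/")

#' Parametric conversation transition matrix
#'
#' A turn-taking chain over the speaker-qualified conversation state
#' space. `backchannel_mass` is the probability that an examiner
#' statement is followed by a participant backchannel (the quantity
#' planted lower in autistic groups); `self_continue` is the probability
#' that a participant utterance is followed by another participant
#' utterance (self-elaboration).
#'
#' @param backchannel_mass Backchannel-following-statement probability.
#' @param self_continue Participant self-continuation probability.
#' @return Row-stochastic matrix over [chain_states()] for conversation.
#' @export
conversation_transition <- function(backchannel_mass = 0.30,
                                    self_continue = 0.35) {
  st <- chain_states("conversation")
  P <- matrix(0, length(st), length(st), dimnames = list(st, st))
  ptags <- speech_act_tags("conversation")
  ## participant continuation mix (no backchannel: backchannels rarely chain)
  cont <- c(initiation_statement = 0.30, question = 0.12,
            clarification = 0.30, reply = 0.10, backchannel = 0.02,
            check_in = 0.06, character_speech = 0.04, incomplete = 0.06)
  cont <- cont / sum(cont)
  exam <- c(examiner_question = 0.6, examiner_statement = 0.4)
  P["START", c("examiner_question", "examiner_statement")] <- c(0.7, 0.3)
  for (p in ptags) {
    P[p, names(cont)] <- self_continue * cont
    P[p, names(exam)] <- (1 - self_continue) * exam
  }
  ## examiner question: mostly replies/clarifications
  q_next <- c(reply = 0.50, clarification = 0.18,
              initiation_statement = 0.05, backchannel = 0.04,
              question = 0.04, check_in = 0.01, character_speech = 0.01,
              incomplete = 0.07, examiner_question = 0.05,
              examiner_statement = 0.05)
  P["examiner_question", names(q_next)] <- q_next / sum(q_next)
  ## examiner statement: backchannel mass is the planted parameter
  rest <- c(initiation_statement = 0.22, reply = 0.08,
            clarification = 0.12, question = 0.08, check_in = 0.03,
            character_speech = 0.01, incomplete = 0.05,
            examiner_question = 0.25, examiner_statement = 0.16)
  P["examiner_statement", "backchannel"] <- backchannel_mass
  P["examiner_statement", names(rest)] <-
    (1 - backchannel_mass) * rest / sum(rest)
  .normalize_rows(P)
}

#' Parametric narrative transition matrix
#'
#' Participant-only chain for the picture-book narration task;
#' `off_topic_mass` tunes the probability of drifting into nonnarrative
#' or thinking utterances, `incomplete_mass` of abandoning utterances.
#'
#' @param off_topic_mass,incomplete_mass Planted row masses.
#' @return Row-stochastic matrix over [chain_states()] for narrative.
#' @export
narrative_transition <- function(off_topic_mass = 0.06,
                                 incomplete_mass = 0.05) {
  st <- chain_states("narrative")
  P <- matrix(0, length(st), length(st), dimnames = list(st, st))
  base <- c(statement = 0.62, question = 0.05, character_speech = 0.08,
            sound_effect = 0.05)
  off <- c(nonnarrative = 0.55, thinking = 0.45)
  for (s in st) {
    row <- c(base / sum(base) * (1 - off_topic_mass - incomplete_mass),
             off * off_topic_mass,
             incomplete = incomplete_mass)
    ## storytelling states tend to chain
    if (s %in% c("character_speech", "sound_effect")) {
      row[c("character_speech", "sound_effect")] <-
        row[c("character_speech", "sound_effect")] + 0.18
    }
    P[s, names(row)] <- row / sum(row)
  }
  P
}

#' Synthetic cohort configuration
#'
#' @param groups Named list of [group_params()], one per
#'   diagnosis-by-sex cell (names like `"asd_male"`).
#' @param n_per_group Named integer vector of transcript counts aligned
#'   to `groups`.
#' @param seed Master seed.
#' @return A list of class `"synthetic_config"`.
#' @export
synthetic_config <- function(groups, n_per_group, seed = 1L) {
  stopifnot(identical(sort(names(groups)), sort(names(n_per_group))))
  structure(list(groups = groups, n_per_group = n_per_group, seed = seed),
            class = "synthetic_config")
}

#' Default study-scale configuration
#'
#' Four diagnosis-by-sex groups at the study's sample sizes (73 autistic
#' males, 27 autistic females, 40 non-autistic males, 47 non-autistic
#' females) with the planted effects used throughout the package's
#' calibration: autistic groups carry less backchannel transition mass
#' after examiner statements, and female groups emit complex-affect
#' vocabulary at a higher per-token rate.
#'
#' @param task `"narrative"` or `"conversation"`.
#' @param n_per_group Transcript counts (named: asd_male, asd_female,
#'   nonasd_male, nonasd_female).
#' @param seed Master seed.
#' @param backchannel_mass Length-2 named vector `c(asd=, nonasd=)`.
#' @param complex_affect_rate Length-2 named vector `c(male=, female=)`.
#' @return A `"synthetic_config"`.
#' @export
default_synthetic_config <- function(task = c("conversation", "narrative"),
    n_per_group = c(asd_male = 73, asd_female = 27,
                    nonasd_male = 40, nonasd_female = 47),
    seed = 1L,
    backchannel_mass = c(asd = 0.12, nonasd = 0.32),
    complex_affect_rate = c(male = 0.012, female = 0.030)) {
  task <- match.arg(task)
  mk <- function(diag, sex) {
    trans <- if (task == "conversation") {
      conversation_transition(backchannel_mass = backchannel_mass[[diag]])
    } else {
      narrative_transition(
        off_topic_mass = if (diag == "asd") 0.10 else 0.05,
        incomplete_mass = if (diag == "asd") 0.08 else 0.04)
    }
    group_params(
      transition = trans,
      n_utterances_mean = if (task == "narrative") 60 else 70,
      lexical_rates = c(simple_affective_states = 0.020,
                        complex_affective_states = complex_affect_rate[[sex]],
                        affective_behaviors = 0.010,
                        cognitive_states = 0.020,
                        cognitive_behaviors = 0.010,
                        causal = 0.012,
                        story_elements = if (task == "narrative") 0.03 else 0,
                        characters = if (task == "narrative") 0.05 else 0),
      viq_mean = if (diag == "asd") 102 else 108,
      viq_sd = if (diag == "asd") 16 else 13)
  }
  synthetic_config(
    groups = list(asd_male = mk("asd", "male"),
                  asd_female = mk("asd", "female"),
                  nonasd_male = mk("nonasd", "male"),
                  nonasd_female = mk("nonasd", "female")),
    n_per_group = n_per_group, seed = seed)
}

.sample_chain_path <- function(P, states, n) {
  path <- character(n)
  cur <- match("START", states)
  for (i in seq_len(n)) {
    cur <- sample.int(length(states), 1L, prob = P[cur, ])
    path[i] <- states[cur]
  }
  path
}

#' Generate one synthetic transcript
#'
#' Samples a speech-act path from the group's transition matrix
#' (starting at `START`), then fills participant utterances with tokens
#' drawn from the lexicon categories at the configured per-token rates
#' (background pseudo-words otherwise), injecting filled pauses and maze
#' flags at their per-token rates. Examiner utterances (conversation
#' task) use background tokens only.
#'
#' @param gp A [group_params()].
#' @param task Task name.
#' @param id Transcript id.
#' @param seed Integer seed (fully deterministic given it).
#' @param diagnosis,sex Group labels to attach.
#' @param lex Lexicon whose categories are sampled from.
#' @return A [transcript()] object.
#' @export
generate_transcript <- function(gp, task, id, seed,
                                diagnosis = "asd", sex = "male",
                                lex = default_lexicon()) {
  set.seed(seed)
  states <- rownames(gp$transition)
  n_utt <- max(2L, rpois(1L, gp$n_utterances_mean))
  acts <- .sample_chain_path(gp$transition, states, n_utt)
  is_exam <- acts %in% examiner_tags()
  bg <- background_vocabulary(lex = lex)
  cat_words <- lapply(lex$categories, function(e) {
    e[!grepl(" ", e, fixed = TRUE) & !endsWith(e, "*")]
  })
  rates <- gp$lexical_rates[gp$lexical_rates > 0 &
                              names(gp$lexical_rates) %in% names(cat_words)]
  pool <- c(names(rates), "FILLER", "BG")
  prob <- c(unname(rates), gp$filled_pause_rate,
            1 - sum(rates) - gp$filled_pause_rate)
  ## draw all token-level quantities for the transcript in one pass
  lens <- integer(n_utt)
  lens[is_exam] <- pmax(1L, rpois(sum(is_exam), gp$examiner_length_mean))
  lens[!is_exam] <- 1L + rpois(sum(!is_exam),
                               max(gp$utterance_length_mean - 1, 0))
  Lp <- sum(lens[!is_exam])
  src <- sample(pool, Lp, replace = TRUE, prob = prob)
  pwords <- character(Lp)
  sel <- src == "FILLER"
  if (any(sel)) pwords[sel] <- sample(filled_pause_words(), sum(sel),
                                      replace = TRUE)
  sel <- src == "BG"
  if (any(sel)) pwords[sel] <- bg[sample.int(length(bg), sum(sel),
                                             replace = TRUE)]
  for (cn in names(rates)) {
    sel <- src == cn
    if (any(sel)) pwords[sel] <- sample(cat_words[[cn]], sum(sel),
                                        replace = TRUE)
  }
  pmaze <- runif(Lp) < gp$maze_rate
  ewords <- bg[sample.int(length(bg), sum(lens[is_exam]), replace = TRUE)]
  utts <- vector("list", n_utt)
  ppos <- 0L; epos <- 0L
  for (i in seq_len(n_utt)) {
    L <- lens[i]
    if (is_exam[i]) {
      words <- ewords[epos + seq_len(L)]; epos <- epos + L
      toks <- list(surface = words, normalized = words,
                   is_maze = rep(FALSE, L),
                   is_filled_pause = rep(FALSE, L))
      utts[[i]] <- utterance("examiner", acts[i], tokens = toks)
    } else {
      idx <- ppos + seq_len(L); ppos <- ppos + L
      words <- pwords[idx]
      toks <- list(surface = words, normalized = words,
                   is_maze = pmaze[idx],
                   is_filled_pause = words %in% filled_pause_words())
      utts[[i]] <- utterance("participant", acts[i], tokens = toks)
    }
  }
  transcript(id = id, task = task, diagnosis = diagnosis, sex = sex,
             age = round(rnorm(1L, gp$age_mean, gp$age_sd), 1),
             viq = round(rnorm(1L, gp$viq_mean, gp$viq_sd)),
             utterances = utts)
}

#' Generate a synthetic cohort
#'
#' Per-transcript seeds are drawn once from the master seed (documented
#' splitting: `set.seed(cfg$seed)` then one `sample.int` draw per
#' transcript), so cohorts are reproducible and individual transcripts
#' can be regenerated in isolation.
#'
#' @param cfg A [synthetic_config()].
#' @param task Task name.
#' @param lex Lexicon passed to [generate_transcript()].
#' @return List of transcripts with ids `<group>_<serial>`.
#' @export
generate_cohort <- function(cfg, task = c("conversation", "narrative"),
                            lex = default_lexicon()) {
  task <- match.arg(task)
  total <- sum(cfg$n_per_group)
  set.seed(cfg$seed)
  seeds <- sample.int(.Machine$integer.max - 1L, total)
  out <- vector("list", total)
  pos <- 0L
  for (g in names(cfg$groups)) {
    gp <- cfg$groups[[g]]
    dg <- if (startsWith(g, "asd")) "asd" else "non_asd"
    sx <- if (endsWith(g, "female")) "female" else "male"
    for (i in seq_len(cfg$n_per_group[[g]])) {
      pos <- pos + 1L
      out[[pos]] <- generate_transcript(
        gp, task, id = sprintf("%s_%03d", g, i), seed = seeds[pos],
        diagnosis = dg, sex = sx, lex = lex)
    }
  }
  out
}

#' Draw a feature matrix from a diagonal Gaussian mixture
#'
#' Feeds profile-recovery tests: returns both the draws and the true
#' component labels.
#'
#' @param k Number of components.
#' @param weights Length-k probability vector.
#' @param means,variances k x d matrices.
#' @param n Number of observations.
#' @param seed Integer seed.
#' @return List with `X` (n x d matrix) and `labels` (length-n integer).
#' @export
generate_profile_data <- function(k, weights, means, variances, n, seed) {
  means <- as.matrix(means); variances <- as.matrix(variances)
  stopifnot(length(weights) == k, nrow(means) == k,
            all(dim(means) == dim(variances)), all(variances > 0),
            abs(sum(weights) - 1) < 1e-8)
  set.seed(seed)
  d <- ncol(means)
  z <- sample.int(k, n, replace = TRUE, prob = weights)
  X <- matrix(rnorm(n * d), n, d) * sqrt(variances[z, , drop = FALSE]) +
    means[z, , drop = FALSE]
  colnames(X) <- colnames(means)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(d))
  list(X = X, labels = z)
}

#' Analytic divergence rate between planted transition matrices
#'
#' Applies the same stationary-weighted per-step formula as [kl_rate()]
#' directly to two groups' true transition matrices.
#'
#' @param gp_a,gp_b [group_params()] with identical state spaces.
#' @param direction `"forward"` (D(A||B)), `"reverse"`, or `"symmetric"`
#'   (their mean).
#' @return Non-negative scalar (nats).
#' @export
true_kl <- function(gp_a, gp_b,
                    direction = c("forward", "reverse", "symmetric")) {
  direction <- match.arg(direction)
  A <- as_markov_chain(gp_a$transition)
  B <- as_markov_chain(gp_b$transition)
  switch(direction,
         forward = kl_rate(A, B),
         reverse = kl_rate(B, A),
         symmetric = (kl_rate(A, B) + kl_rate(B, A)) / 2)
}
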