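# Shared fixtures: micro-transcript builders and naive reference oracles.

mk_utt <- function(act, text = "", speaker = "participant") {
  utterance(speaker, act, text = text)
}

mk_trans <- function(utts, task = "narrative", id = "t1",
                     diagnosis = "asd", sex = "male",
                     age = 12, viq = 100) {
  transcript(id = id, task = task, diagnosis = diagnosis, sex = sex,
             age = age, viq = viq, utterances = utts)
}

# transcript from a bare participant tag vector
tag_trans <- function(acts, task = "narrative", id = "t1", ...) {
  mk_trans(lapply(acts, function(a) mk_utt(a, "word")), task = task,
           id = id, ...)
}

# conversation transcript from (speaker, act) pairs
conv_trans <- function(speakers, acts, id = "t1", ...) {
  utts <- mapply(function(s, a) mk_utt(a, "word", speaker = s),
                 speakers, acts, SIMPLIFY = FALSE)
  mk_trans(utts, task = "conversation", id = id, ...)
}

# small random transcript with maze/filled-pause markup for round-trips
random_transcript <- function(seed, task = "narrative") {
  set.seed(seed)
  tags <- speech_act_tags(task)
  words <- c("the", "frog", "left", "um", "boy", "happy", "ran", "fast")
  n <- sample(1:8, 1)
  utts <- lapply(seq_len(n), function(i) {
    L <- sample(1:6, 1)
    w <- sample(words, L, replace = TRUE)
    if (L >= 3 && runif(1) < 0.5) {
      a <- sample(L - 1, 1)
      w[a] <- paste0("(", w[a])
      w[a + 1] <- paste0(w[a + 1], ")")
    }
    mk_utt(sample(tags, 1), paste(w, collapse = " "))
  })
  mk_trans(utts, task = task, id = paste0("r", seed))
}

# naive token-by-token lexicon oracle (single-word entries only):
# double loop over tokens and categories, no shared code with the matcher
naive_category_counts <- function(t, lex, count_mazes = FALSE) {
  counts <- setNames(integer(length(lex$categories)),
                     names(lex$categories))
  for (u in t$utterances) {
    if (u$speaker != "participant") next
    for (i in seq_along(u$tokens$normalized)) {
      if (!count_mazes && u$tokens$is_maze[i]) next
      tok <- u$tokens$normalized[i]
      if (!nzchar(tok)) next
      for (cat in names(lex$categories)) {
        for (e in lex$categories[[cat]]) {
          if (grepl(" ", e, fixed = TRUE)) next
          hit <- if (endsWith(e, "*")) {
            startsWith(tok, substr(e, 1, nchar(e) - 1))
          } else {
            tok == e
          }
          if (hit) {
            counts[[cat]] <- counts[[cat]] + 1L
            break
          }
        }
      }
    }
  }
  for (cn in names(lex$composition)) {
    counts[[cn]] <- sum(counts[lex$composition[[cn]]])
  }
  counts
}

# brute-force sliding-window sequence oracle on (speaker, act) frames
oracle_pairs <- function(speakers, acts, cond_first, cond_second) {
  n <- length(acts)
  if (n < 2) return(0L)
  hits <- 0L
  for (i in seq_len(n - 1)) {
    if (cond_first(speakers[i], acts[i]) &&
        cond_second(speakers[i + 1], acts[i + 1])) {
      hits <- hits + 1L
    }
  }
  hits
}

# brute-force BH step-up definition
bh_oracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  sorted <- p[o] * m / seq_len(m)
  for (i in seq_len(m)) adj[i] <- min(sorted[i:m], 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# two-sided Fisher p by point-probability enumeration for a 2x2 table
fisher_oracle_2x2 <- function(tbl) {
  r1 <- sum(tbl[1, ]); c1 <- sum(tbl[, 1]); N <- sum(tbl)
  lo <- max(0, c1 - (N - r1)); hi <- min(r1, c1)
  probs <- dhyper(lo:hi, r1, N - r1, c1)
  obs <- dhyper(tbl[1, 1], r1, N - r1, c1)
  sum(probs[probs <= obs * (1 + 1e-7)])
}
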