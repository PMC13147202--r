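## Markov chains over speech-act states and the Kullback-Leibler
## divergence rate between two chains,
##
##   D(P || Q) = sum_i pi_P(i) sum_j P(i,j) log( P(i,j) / Q(i,j) )  [nats],
##
## with pi_P the stationary distribution of P, plus a transcript-level
## label-permutation test on the symmetrized rate.

#' Speech-act state space for chain estimation
#'
#' Participant tags plus a `START` boundary state; for the conversation
#' task, examiner tags are interleaved as states by default (conversation
#' sequences are speaker-aware).
#'
#' @param task `"narrative"` or `"conversation"`.
#' @param include_examiner Interleave examiner tags as states (default:
#'   only for conversation).
#' @return Character vector of states, `START` first.
#' @export
chain_states <- function(task = c("narrative", "conversation"),
                         include_examiner = (task == "conversation")) {
  task <- match.arg(task)
  st <- c("START", speech_act_tags(task))
  if (isTRUE(include_examiner)) st <- c(st, examiner_tags())
  st
}

## per-transcript transition count matrix over `states`
transition_counts <- function(t, states) {
  acts <- if ("examiner_question" %in% states) {
    utterance_acts(t)$act
  } else {
    participant_acts(t)
  }
  m <- matrix(0L, length(states), length(states),
              dimnames = list(states, states))
  if (!length(acts)) return(m)
  seqs <- c("START", acts)
  i <- match(seqs[-length(seqs)], states)
  j <- match(seqs[-1], states)
  if (anyNA(i) || anyNA(j)) {
    stop("act tag outside the chain state space in transcript ", t$id,
         call. = FALSE)
  }
  for (k in seq_along(i)) m[i[k], j[k]] <- m[i[k], j[k]] + 1L
  m
}

.smooth_rows <- function(counts, alpha) {
  S <- ncol(counts)
  rs <- rowSums(counts)
  if (alpha > 0) {
    P <- (counts + alpha) / (rs + alpha * S)
  } else {
    P <- counts / ifelse(rs > 0, rs, 1)
    empty <- rs == 0
    if (any(empty)) {
      warning("alpha = 0 with unvisited state(s): ",
              paste(rownames(counts)[empty], collapse = ", "),
              "; rows left on visited support", call. = FALSE)
      P[empty, ] <- 1 / S
    }
  }
  P
}

.new_chain <- function(states, counts, alpha) {
  structure(list(states = states, counts = counts,
                 P = .smooth_rows(counts, alpha), alpha = alpha),
            class = "markov_chain")
}

#' Estimate a speech-act Markov chain from a group of transcripts
#'
#' Transition counts are pooled across transcripts; each transcript
#' contributes a `START` -> first-tag transition followed by its
#' within-transcript bigrams, and no transition crosses a transcript
#' boundary. Rows are smoothed with pseudo-count `alpha`:
#' `P[i,j] = (n[i,j] + alpha) / (n[i,.] + alpha * |S|)`.
#'
#' @param transcripts Nonempty list of transcripts of one task.
#' @param alpha Smoothing pseudo-count (>= 0; default 0.5, Jeffreys-style).
#' @param states State space; defaults to [chain_states()] for the task.
#' @return An object of class `"markov_chain"` with `states`, integer
#'   `counts`, row-stochastic `P`, and `alpha`.
#' @export
estimate_chain <- function(transcripts, alpha = 0.5, states = NULL) {
  if (!length(transcripts)) stop("empty transcript group", call. = FALSE)
  task <- transcripts[[1]]$task
  if (!all(vapply(transcripts, `[[`, character(1), "task") == task)) {
    stop("all transcripts must share one task", call. = FALSE)
  }
  if (alpha < 0) stop("alpha must be >= 0", call. = FALSE)
  if (is.null(states)) states <- chain_states(task)
  counts <- Reduce(`+`, lapply(transcripts, transition_counts,
                               states = states))
  .new_chain(states, counts, alpha)
}

#' Construct a chain from a known transition matrix
#'
#' Wraps an already row-stochastic matrix (e.g. a planted generator
#' matrix) as a `"markov_chain"` so it can be passed to [kl_rate()].
#'
#' @param P Row-stochastic matrix with identical row/column state names.
#' @param states Optional state names (defaults to `rownames(P)`).
#' @return A `"markov_chain"` with zero counts and `alpha = 0`.
#' @export
as_markov_chain <- function(P, states = rownames(P)) {
  P <- as.matrix(P)
  stopifnot(nrow(P) == ncol(P), all(abs(rowSums(P) - 1) < 1e-8))
  if (is.null(states)) states <- paste0("s", seq_len(nrow(P)))
  dimnames(P) <- list(states, states)
  structure(list(states = states,
                 counts = matrix(0L, nrow(P), ncol(P),
                                 dimnames = dimnames(P)),
                 P = P, alpha = 0),
            class = "markov_chain")
}

#' @export
print.markov_chain <- function(x, digits = 3, ...) {
  cat("<markov_chain> ", length(x$states), " states, ",
      sum(x$counts), " observed transitions, alpha=", x$alpha, "\n",
      sep = "")
  print(round(x$P, digits))
  invisible(x)
}

#' Stationary distribution of a chain
#'
#' Power iteration from the uniform vector until the max-norm residual
#' `||pi P - pi||` falls below `tol`.
#'
#' @param chain A `"markov_chain"` (or bare row-stochastic matrix).
#' @param tol Convergence tolerance on the residual.
#' @param max_iter Iteration cap.
#' @return Named probability vector `pi` with `pi P = pi`.
#' @export
stationary_distribution <- function(chain, tol = 1e-10, max_iter = 100000L) {
  P <- if (inherits(chain, "markov_chain")) chain$P else as.matrix(chain)
  S <- nrow(P)
  pi <- rep(1 / S, S)
  for (it in seq_len(max_iter)) {
    nxt <- as.vector(pi %*% P)
    nxt <- nxt / sum(nxt)
    if (max(abs(nxt - pi)) < tol) {
      names(nxt) <- rownames(P)
      return(nxt)
    }
    pi <- nxt
  }
  stop("stationary distribution did not converge; residual ",
       format(max(abs(as.vector(pi %*% P) - pi))), call. = FALSE)
}

#' Kullback-Leibler divergence rate between two chains
#'
#' The per-step divergence of chain `p` from chain `q`, weighting row
#' divergences by the stationary distribution of `p` (nats). Zero iff the
#' two transition matrices agree on all states with positive stationary
#' mass under `p`.
#'
#' @param p,q `"markov_chain"` objects over identical state sets.
#' @param tol Tolerance for the stationary solve.
#' @return Non-negative scalar (`Inf`, with a warning, when `q` has zero
#'   mass where `p` does not).
#' @export
kl_rate <- function(p, q, tol = 1e-12) {
  if (!identical(p$states, q$states)) {
    stop("state sets differ between chains", call. = FALSE)
  }
  .kl_rate_mat(p$P, q$P, tol = tol)
}

.kl_rate_mat <- function(P, Q, tol = 1e-12, pi = NULL) {
  if (is.null(pi)) pi <- stationary_distribution(P, tol = tol)
  pos <- P > 0
  if (any(pos & Q == 0)) {
    bad <- pi[rowSums(pos & Q == 0) > 0] > 0
    if (any(bad)) {
      warning("q has zero probability on p's support; divergence is Inf",
              call. = FALSE)
      return(Inf)
    }
  }
  term <- matrix(0, nrow(P), ncol(P))
  term[pos] <- P[pos] * log(P[pos] / Q[pos])
  sum(pi * rowSums(term))
}

## symmetric mean divergence between chains built from two count matrices
.sym_kl_counts <- function(cA, cB, alpha, tol = 1e-12) {
  PA <- .smooth_rows(cA, alpha)
  PB <- .smooth_rows(cB, alpha)
  (.kl_rate_mat(PA, PB, tol) + .kl_rate_mat(PB, PA, tol)) / 2
}

#' Permutation test for the divergence between two groups' chains
#'
#' The observed statistic is the symmetrized divergence rate
#' `(D(P_A||P_B) + D(P_B||P_A)) / 2` between chains estimated per group.
#' The null is built by reassigning transcript-level group labels at
#' random (group sizes preserved) `n_perm` times and recomputing the
#' statistic; the p-value uses the add-one rule
#' `(1 + #{perm >= obs}) / (1 + n_perm)`.
#'
#' @param group_a,group_b Nonempty lists of transcripts of one task.
#' @param n_perm Number of permutations (>= 1).
#' @param alpha Smoothing pseudo-count for all chain estimates.
#' @param seed Integer seed (the test is fully reproducible given it).
#' @param states Optional state space override.
#' @return An object of class `"kl_test"`: `forward`, `reverse`,
#'   `symmetric`, `p_value`, `n_permutations`, `seed`, `perm_stats`, and
#'   the two estimated chains.
#' @export
kl_permutation_test <- function(group_a, group_b, n_perm = 999,
                                alpha = 0.5, seed = 1L, states = NULL) {
  if (!length(group_a) || !length(group_b)) {
    stop("both groups must be nonempty", call. = FALSE)
  }
  if (n_perm < 1) stop("n_perm must be >= 1", call. = FALSE)
  task <- group_a[[1]]$task
  if (is.null(states)) states <- chain_states(task)
  all_t <- c(group_a, group_b)
  nA <- length(group_a)
  n <- length(all_t)
  S <- length(states)
  arr <- array(0, dim = c(n, S, S))
  for (i in seq_len(n)) arr[i, , ] <- transition_counts(all_t[[i]], states)
  csum <- function(idx) {
    m <- colSums(arr[idx, , , drop = FALSE], dims = 1)
    dimnames(m) <- list(states, states)
    m
  }
  cA <- csum(seq_len(nA)); cB <- csum(nA + seq_len(n - nA))
  PA <- .smooth_rows(cA, alpha); PB <- .smooth_rows(cB, alpha)
  fwd <- .kl_rate_mat(PA, PB)
  rev <- .kl_rate_mat(PB, PA)
  obs <- (fwd + rev) / 2
  set.seed(seed)
  perm_stats <- numeric(n_perm)
  for (b in seq_len(n_perm)) {
    idx <- sample.int(n, nA)
    perm_stats[b] <- .sym_kl_counts(csum(idx), csum(setdiff(seq_len(n), idx)),
                                    alpha)
  }
  p <- (1 + sum(perm_stats >= obs)) / (1 + n_perm)
  structure(list(forward = fwd, reverse = rev, symmetric = obs,
                 p_value = p, n_permutations = n_perm, seed = seed,
                 perm_stats = perm_stats,
                 chain_a = .new_chain(states, cA, alpha),
                 chain_b = .new_chain(states, cB, alpha)),
            class = "kl_test")
}

#' @export
print.kl_test <- function(x, ...) {
  cat("Kullback-Leibler divergence-rate permutation test\n",
      "  forward  D(A||B) = ", format(x$forward, digits = 4), " nats\n",
      "  reverse  D(B||A) = ", format(x$reverse, digits = 4), " nats\n",
      "  symmetric        = ", format(x$symmetric, digits = 4), " nats\n",
      "  p = ", format(x$p_value, digits = 4), "  (",
      x$n_permutations, " label permutations, seed ", x$seed, ")\n",
      sep = "")
  invisible(x)
}
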