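## A-priori speech-act sequence statistics over adjacent utterance pairs.
##
## Narrative sequences are defined on participant utterances only
## (examiner utterances are removed before pairing); conversational
## sequences are speaker-aware and use the full utterance order.

#' Speech-act proportions
#'
#' Each participant tag as a percent of participant utterances; sums to
#' 100 over the task's tag set when the transcript is nonempty.
#'
#' @param t A transcript.
#' @return Named numeric vector over the task's participant tags (`NA`
#'   when there are no participant utterances).
#' @export
speech_act_proportions <- function(t) {
  tags <- speech_act_tags(t$task)
  acts <- participant_acts(t)
  if (!length(acts)) return(setNames(rep(NA_real_, length(tags)), tags))
  100 * table(factor(acts, levels = tags)) / length(acts)
}

#' Speech-act diversity
#'
#' Number of distinct participant speech-act categories used in a
#' narrative transcript (0-7).
#'
#' @param t A narrative transcript.
#' @return Integer in `[0, 7]`.
#' @export
speech_act_diversity <- function(t) {
  if (t$task != "narrative") {
    stop("speech_act_diversity is defined for the narrative task",
         call. = FALSE)
  }
  length(unique(participant_acts(t)))
}

.seq_profile <- function(t, counts, opportunities) {
  stopifnot(all(counts <= opportunities))
  rates <- ifelse(opportunities > 0, counts / opportunities, NA_real_)
  structure(list(transcript_id = t$id, task = t$task, counts = counts,
                 opportunities = opportunities, rates = rates),
            class = "sequence_profile")
}

#' @export
print.sequence_profile <- function(x, ...) {
  cat("<sequence_profile ", x$transcript_id, "> task=", x$task, "\n",
      sep = "")
  print(data.frame(count = x$counts, opportunities = x$opportunities,
                   rate = round(x$rates, 3)))
  invisible(x)
}

#' Narrative a-priori sequence counts
#'
#' Three named bigram sequences over adjacent participant utterances
#' (examiner utterances removed first):
#' * `on_topic_consecutive` — both members in statement / question /
#'   character speech / sound effect;
#' * `off_topic_consecutive` — both members in nonnarrative / thinking;
#' * `storytelling_consecutive` — both members in character speech /
#'   sound effect.
#' A run of length r contributes r-1 pairs. The shared opportunity count
#' is the number of adjacent participant pairs.
#'
#' @param t A narrative transcript.
#' @return A `"sequence_profile"`.
#' @export
count_narrative_sequences <- function(t) {
  if (t$task != "narrative") {
    stop("count_narrative_sequences requires a narrative transcript",
         call. = FALSE)
  }
  acts <- participant_acts(t)
  on_topic <- c("statement", "question", "character_speech", "sound_effect")
  off_topic <- c("nonnarrative", "thinking")
  story <- c("character_speech", "sound_effect")
  n <- length(acts)
  if (n < 2L) {
    z <- setNames(integer(3), c("on_topic_consecutive",
                                "off_topic_consecutive",
                                "storytelling_consecutive"))
    return(.seq_profile(t, z, setNames(rep(0L, 3), names(z))))
  }
  a <- acts[-n]; b <- acts[-1]
  counts <- c(
    on_topic_consecutive = sum(a %in% on_topic & b %in% on_topic),
    off_topic_consecutive = sum(a %in% off_topic & b %in% off_topic),
    storytelling_consecutive = sum(a %in% story & b %in% story))
  opp <- setNames(rep(n - 1L, 3), names(counts))
  .seq_profile(t, counts, opp)
}

#' Conversational a-priori sequence counts
#'
#' Five named speaker-aware bigram sequences over adjacent utterances:
#' * `non_obligatory_response` — examiner non-question followed by a
#'   participant utterance that is not a backchannel;
#' * `backchannel_seq` — examiner non-question followed by a participant
#'   backchannel;
#' * `self_elaboration` — a participant utterance followed by another
#'   participant utterance;
#' * `expected_after_question` — examiner question followed by a
#'   participant reply or clarification;
#' * `unexpected_after_question` — examiner question followed by a
#'   participant backchannel or initiation statement.
#'
#' Opportunities are sequence-specific: pairs whose first member is an
#' examiner non-question (first two sequences), an examiner question
#' (last two), or a participant utterance (self-elaboration).
#'
#' The non-obligatory-response rule (non-backchannel response to examiner
#' non-question) is one documented reading of an under-specified
#' construct; `non_obligatory_includes_backchannel = TRUE` widens it to
#' any participant response.
#'
#' @param t A conversation transcript.
#' @param non_obligatory_includes_backchannel Widen the first rule.
#' @return A `"sequence_profile"`.
#' @export
count_conversation_sequences <- function(t,
    non_obligatory_includes_backchannel = FALSE) {
  if (t$task != "conversation") {
    stop("count_conversation_sequences requires a conversation transcript",
         call. = FALSE)
  }
  ua <- utterance_acts(t)
  n <- nrow(ua)
  nm <- c("non_obligatory_response", "backchannel_seq", "self_elaboration",
          "expected_after_question", "unexpected_after_question")
  if (n < 2L) {
    z <- setNames(integer(5), nm)
    return(.seq_profile(t, z, z))
  }
  s1 <- ua$speaker[-n]; a1 <- ua$act[-n]
  s2 <- ua$speaker[-1]; a2 <- ua$act[-1]
  ex_nonq <- s1 == "examiner" & a1 != "examiner_question"
  ex_q <- s1 == "examiner" & a1 == "examiner_question"
  p1 <- s1 == "participant"
  p2 <- s2 == "participant"
  non_oblig_hit <- if (non_obligatory_includes_backchannel) {
    ex_nonq & p2
  } else {
    ex_nonq & p2 & a2 != "backchannel"
  }
  counts <- setNames(c(
    sum(non_oblig_hit),
    sum(ex_nonq & p2 & a2 == "backchannel"),
    sum(p1 & p2),
    sum(ex_q & p2 & a2 %in% c("reply", "clarification")),
    sum(ex_q & p2 & a2 %in% c("backchannel", "initiation_statement"))), nm)
  opp <- setNames(c(sum(ex_nonq), sum(ex_nonq), sum(p1),
                    sum(ex_q), sum(ex_q)), nm)
  .seq_profile(t, counts, opp)
}

#' Sequence profiles for a cohort
#'
#' @param transcripts List of transcripts, all of one task.
#' @param ... Passed to the task-specific counter.
#' @return Data frame with id, group columns, then `<sequence>_count`,
#'   `<sequence>_opp`, `<sequence>_rate` columns.
#' @export
cohort_sequences <- function(transcripts, ...) {
  rows <- lapply(transcripts, function(t) {
    p <- if (t$task == "narrative") count_narrative_sequences(t)
         else count_conversation_sequences(t, ...)
    cnt <- as.list(p$counts); names(cnt) <- paste0(names(cnt), "_count")
    opp <- as.list(p$opportunities); names(opp) <- paste0(names(p$counts), "_opp")
    rat <- as.list(p$rates); names(rat) <- paste0(names(p$counts), "_rate")
    cbind(data.frame(id = t$id, task = t$task, diagnosis = t$diagnosis,
                     sex = t$sex, viq = t$viq, age = t$age,
                     stringsAsFactors = FALSE),
          as.data.frame(cnt), as.data.frame(opp), as.data.frame(rat))
  })
  do.call(rbind, rows)
}
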