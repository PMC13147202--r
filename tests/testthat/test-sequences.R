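test_that("speech-act proportions are percents of participant utterances summing to 100", {
  t <- tag_trans(c(rep("statement", 4), "question"))
  p <- speech_act_proportions(t)
  expect_equal(unname(p["statement"]), 80)
  expect_equal(unname(p["question"]), 20)
  expect_equal(sum(p), 100)
  one <- tag_trans(rep("thinking", 3))
  expect_equal(unname(speech_act_proportions(one)["thinking"]), 100)
  expect_true(all(is.na(speech_act_proportions(mk_trans(list())))))
  for (s in 1:20) {
    t <- random_transcript(s)
    if (utterance_count(t, "participant") > 0) {
      expect_equal(sum(speech_act_proportions(t)), 100)
    }
  }
})

test_that("speech-act diversity counts distinct narrative tags", {
  expect_equal(speech_act_diversity(mk_trans(list())), 0)
  expect_equal(speech_act_diversity(tag_trans(rep("statement", 5))), 1)
  expect_error(speech_act_diversity(tag_trans("reply", task = "conversation")),
               "narrative")
  for (s in 1:20) {
    t <- random_transcript(s)
    expect_equal(speech_act_diversity(t),
                 length(unique(vapply(t$utterances, `[[`, character(1),
                                      "act"))))
  }
})

test_that("narrative sequences follow their a-priori definitions on fixtures", {
  p <- count_narrative_sequences(
    tag_trans(c("statement", "statement", "sound_effect")))
  expect_equal(unname(p$counts["on_topic_consecutive"]), 2L)
  expect_equal(unname(p$counts["storytelling_consecutive"]), 0L)
  expect_equal(unname(p$opportunities["on_topic_consecutive"]), 2L)

  p2 <- count_narrative_sequences(
    tag_trans(c("character_speech", "sound_effect")))
  expect_equal(unname(p2$counts["storytelling_consecutive"]), 1L)
  expect_equal(unname(p2$counts["on_topic_consecutive"]), 1L)

  p3 <- count_narrative_sequences(
    tag_trans(c("nonnarrative", "thinking", "statement")))
  expect_equal(unname(p3$counts["off_topic_consecutive"]), 1L)

  single <- count_narrative_sequences(tag_trans("statement"))
  expect_true(all(single$counts == 0) && all(single$opportunities == 0))
  expect_error(count_narrative_sequences(
    tag_trans("reply", task = "conversation")), "narrative")
})

test_that("examiner utterances are removed before narrative pairing", {
  utts <- list(mk_utt("statement", "a"),
               mk_utt("examiner_statement", "b", speaker = "examiner"),
               mk_utt("statement", "c"))
  p <- count_narrative_sequences(mk_trans(utts))
  expect_equal(unname(p$counts["on_topic_consecutive"]), 1L)
  # appending an examiner-only tail changes nothing
  more <- mk_trans(c(utts, list(mk_utt("examiner_question", "d",
                                       speaker = "examiner"))))
  expect_equal(count_narrative_sequences(more)$counts, p$counts)
})

test_that("conversational sequences follow their definitions, incl. the question exclusion", {
  p <- count_conversation_sequences(
    conv_trans(c("examiner", "participant"),
               c("examiner_statement", "backchannel")))
  expect_equal(unname(p$counts["backchannel_seq"]), 1L)
  expect_equal(unname(p$opportunities["backchannel_seq"]), 1L)
  expect_equal(unname(p$counts["non_obligatory_response"]), 0L)

  p2 <- count_conversation_sequences(
    conv_trans(c("examiner", "participant"),
               c("examiner_question", "backchannel")))
  expect_equal(unname(p2$counts["backchannel_seq"]), 0L)
  expect_equal(unname(p2$counts["unexpected_after_question"]), 1L)
  expect_equal(unname(p2$counts["expected_after_question"]), 0L)

  p3 <- count_conversation_sequences(
    conv_trans(c("participant", "participant"),
               c("reply", "clarification")))
  expect_equal(unname(p3$counts["self_elaboration"]), 1L)

  p4 <- count_conversation_sequences(
    conv_trans(c("examiner", "participant"),
               c("examiner_question", "reply")))
  expect_equal(unname(p4$counts["expected_after_question"]), 1L)

  p5 <- count_conversation_sequences(
    conv_trans(c("examiner", "participant"),
               c("examiner_statement", "initiation_statement")))
  expect_equal(unname(p5$counts["non_obligatory_response"]), 1L)
  expect_error(count_conversation_sequences(tag_trans("statement")),
               "conversation")
})

test_that("the configurable non-obligatory rule widens to backchannels", {
  t <- conv_trans(c("examiner", "participant"),
                  c("examiner_statement", "backchannel"))
  strict <- count_conversation_sequences(t)
  wide <- count_conversation_sequences(
    t, non_obligatory_includes_backchannel = TRUE)
  expect_equal(unname(strict$counts["non_obligatory_response"]), 0L)
  expect_equal(unname(wide$counts["non_obligatory_response"]), 1L)
})

test_that("question responses are disjoint and bounded by opportunities", {
  cfg <- default_synthetic_config(
    "conversation", n_per_group = c(asd_male = 3, asd_female = 3,
                                    nonasd_male = 3, nonasd_female = 3),
    seed = 7)
  for (t in generate_cohort(cfg, "conversation")) {
    p <- count_conversation_sequences(t)
    expect_lte(p$counts[["expected_after_question"]] +
                 p$counts[["unexpected_after_question"]],
               p$opportunities[["expected_after_question"]])
    expect_true(all(p$counts <= p$opportunities))
    expect_true(all(p$rates >= 0 & p$rates <= 1, na.rm = TRUE))
  }
})

test_that("all counts match the brute-force sliding-window oracle on generated data", {
  on_topic <- c("statement", "question", "character_speech", "sound_effect")
  off <- c("nonnarrative", "thinking")
  story <- c("character_speech", "sound_effect")
  cfgN <- default_synthetic_config(
    "narrative", n_per_group = c(asd_male = 8, asd_female = 8,
                                 nonasd_male = 8, nonasd_female = 8),
    seed = 13)
  for (t in generate_cohort(cfgN, "narrative")) {
    acts <- vapply(Filter(function(u) u$speaker == "participant",
                          t$utterances), `[[`, character(1), "act")
    spk <- rep("participant", length(acts))
    p <- count_narrative_sequences(t)
    expect_equal(unname(p$counts["on_topic_consecutive"]),
                 oracle_pairs(spk, acts,
                              function(s, a) a %in% on_topic,
                              function(s, a) a %in% on_topic))
    expect_equal(unname(p$counts["off_topic_consecutive"]),
                 oracle_pairs(spk, acts,
                              function(s, a) a %in% off,
                              function(s, a) a %in% off))
    expect_equal(unname(p$counts["storytelling_consecutive"]),
                 oracle_pairs(spk, acts,
                              function(s, a) a %in% story,
                              function(s, a) a %in% story))
  }
  cfgC <- default_synthetic_config(
    "conversation", n_per_group = c(asd_male = 8, asd_female = 8,
                                    nonasd_male = 8, nonasd_female = 8),
    seed = 14)
  for (t in generate_cohort(cfgC, "conversation")) {
    ua <- do.call(rbind, lapply(t$utterances, function(u) {
      data.frame(s = u$speaker, a = u$act)
    }))
    p <- count_conversation_sequences(t)
    ex_nonq <- function(s, a) s == "examiner" && a != "examiner_question"
    ex_q <- function(s, a) s == "examiner" && a == "examiner_question"
    expect_equal(unname(p$counts["backchannel_seq"]),
                 oracle_pairs(ua$s, ua$a, ex_nonq,
                              function(s, a) s == "participant" &&
                                a == "backchannel"))
    expect_equal(unname(p$counts["non_obligatory_response"]),
                 oracle_pairs(ua$s, ua$a, ex_nonq,
                              function(s, a) s == "participant" &&
                                a != "backchannel"))
    expect_equal(unname(p$counts["self_elaboration"]),
                 oracle_pairs(ua$s, ua$a,
                              function(s, a) s == "participant",
                              function(s, a) s == "participant"))
    expect_equal(unname(p$counts["expected_after_question"]),
                 oracle_pairs(ua$s, ua$a, ex_q,
                              function(s, a) s == "participant" &&
                                a %in% c("reply", "clarification")))
    expect_equal(unname(p$counts["unexpected_after_question"]),
                 oracle_pairs(ua$s, ua$a, ex_q,
                              function(s, a) s == "participant" &&
                                a %in% c("backchannel",
                                         "initiation_statement")))
  }
})
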