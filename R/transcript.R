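## Transcript data model and plain-text dialect.
##
## One file per participant-task. Header lines start with `@`; each
## utterance is one line `<speaker-code> <act-tag>\t<text>` where the
## speaker code is `P` (participant) or `E` (examiner) and mazes
## (false starts / reformulations) are enclosed in parentheses:
##
##   @id P001
##   @task narrative
##   @diagnosis asd
##   @sex male
##   @age 12.5
##   @viq 104
##   P statement	(the the) the frog left
##
## Counting rules: maze tokens are excluded from word counts; filled
## pauses ("um", "uh", ...) outside mazes are counted; examiner tokens
## are never counted.

#' Tokenize utterance text
#'
#' Splits on whitespace, flags maze spans (parenthesized runs), strips the
#' parentheses from surfaces, lowercases and removes terminal punctuation
#' to form the normalized form, and flags filled pauses by list membership.
#'
#' @param text Utterance text, possibly containing `( ... )` maze spans.
#' @param filled_pauses Filled-pause inventory (normalized forms).
#' @return A list with parallel vectors `surface`, `normalized`, `is_maze`,
#'   `is_filled_pause`.
#' @export
tokenize_utterance <- function(text, filled_pauses = filled_pause_words()) {
  raw <- strsplit(trimws(text), "[[:space:]]+")[[1]]
  raw <- raw[nzchar(raw)]
  n <- length(raw)
  if (n == 0L) {
    return(list(surface = character(0), normalized = character(0),
                is_maze = logical(0), is_filled_pause = logical(0)))
  }
  is_maze <- logical(n)
  depth <- 0L
  surface <- character(n)
  for (i in seq_len(n)) {
    w <- raw[i]
    opens <- lengths(regmatches(w, gregexpr("(", w, fixed = TRUE)))
    closes <- lengths(regmatches(w, gregexpr(")", w, fixed = TRUE)))
    if (depth + opens > 1L || closes > depth + opens) {
      stop("nested or unbalanced maze parentheses in: ", text, call. = FALSE)
    }
    in_maze <- depth > 0L || opens > 0L
    depth <- depth + opens - closes
    surface[i] <- gsub("[()]", "", w)
    is_maze[i] <- in_maze
  }
  if (depth != 0L) stop("unclosed maze parenthesis in: ", text, call. = FALSE)
  keep <- nzchar(surface)
  surface <- surface[keep]
  is_maze <- is_maze[keep]
  normalized <- tolower(sub("[[:punct:]]+$", "", surface))
  list(surface = surface,
       normalized = normalized,
       is_maze = is_maze,
       is_filled_pause = normalized %in% filled_pauses)
}

#' Construct an utterance
#'
#' @param speaker `"participant"` or `"examiner"`.
#' @param act Speech-act tag.
#' @param text Utterance text with maze markup, or `NULL` when `tokens`
#'   is supplied directly.
#' @param tokens Token list as returned by [tokenize_utterance()].
#' @param filled_pauses Filled-pause inventory.
#' @return A list of class `"utterance"`.
#' @export
utterance <- function(speaker, act, text = NULL, tokens = NULL,
                      filled_pauses = filled_pause_words()) {
  speaker <- match.arg(speaker, c("participant", "examiner"))
  if (is.null(tokens)) {
    tokens <- tokenize_utterance(if (is.null(text)) "" else text, filled_pauses)
  }
  structure(list(speaker = speaker, act = act, tokens = tokens),
            class = "utterance")
}

#' Construct a transcript
#'
#' @param id Transcript identifier.
#' @param task `"narrative"` or `"conversation"`.
#' @param diagnosis `"asd"` or `"non_asd"`.
#' @param sex `"male"` or `"female"`.
#' @param age Age in years.
#' @param viq Verbal IQ score.
#' @param utterances List of [utterance()] objects.
#' @param validate Check that act tags are admissible for the task.
#' @return An object of class `"transcript"`.
#' @export
transcript <- function(id, task = c("narrative", "conversation"),
                       diagnosis = c("asd", "non_asd"),
                       sex = c("male", "female"),
                       age = NA_real_, viq = NA_real_,
                       utterances = list(), validate = TRUE) {
  task <- match.arg(task)
  diagnosis <- match.arg(diagnosis)
  sex <- match.arg(sex)
  t <- structure(list(id = as.character(id), task = task,
                      diagnosis = diagnosis, sex = sex,
                      age = as.numeric(age), viq = as.numeric(viq),
                      utterances = utterances),
                 class = "transcript")
  if (validate) validate_transcript(t)
  t
}

validate_transcript <- function(t) {
  ptags <- speech_act_tags(t$task)
  for (u in t$utterances) {
    ok <- if (u$speaker == "participant") u$act %in% ptags
          else u$act %in% examiner_tags()
    if (!ok) {
      stop("tag error: '", u$act, "' is not admissible for ", u$speaker,
           " in task '", t$task, "'", call. = FALSE)
    }
  }
  invisible(t)
}

#' @export
print.transcript <- function(x, ...) {
  cat("<transcript ", x$id, "> task=", x$task, " diagnosis=", x$diagnosis,
      " sex=", x$sex, "\n  ", length(x$utterances), " utterances, ",
      participant_word_count(x), " participant words\n", sep = "")
  invisible(x)
}

.speaker_codes <- c(P = "participant", E = "examiner")

#' Read a transcript file
#'
#' Parses the plain-text transcript dialect described in the package
#' vignette. `x` may be a file path or a character vector of lines.
#'
#' @param x File path (length-1, existing file) or character vector of lines.
#' @param filled_pauses Filled-pause inventory.
#' @return A [transcript()] object.
#' @export
read_transcript <- function(x, filled_pauses = filled_pause_words()) {
  lines <- if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    readLines(x, warn = FALSE)
  } else {
    unlist(strsplit(x, "\n", fixed = TRUE))
  }
  header <- list()
  utts <- list()
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    if (!nzchar(trimws(line))) next
    if (startsWith(line, "@")) {
      m <- regmatches(line, regexec("^@([a-z]+)[ \t]+(.*)$", line))[[1]]
      if (length(m) != 3L) {
        stop("format error at line ", ln, ": malformed header '", line, "'",
             call. = FALSE)
      }
      header[[m[2]]] <- trimws(m[3])
    } else {
      m <- regmatches(line, regexec("^([PE])[ ]+([a-z_]+)\t(.*)$", line))[[1]]
      if (length(m) != 4L) {
        stop("format error at line ", ln, ": malformed utterance '", line,
             "'", call. = FALSE)
      }
      spk <- .speaker_codes[[m[2]]]
      act <- m[3]
      txt <- m[4]
      if (!nzchar(trimws(txt)) && act != "incomplete") {
        warning("empty utterance text at line ", ln,
                " with act '", act, "'", call. = FALSE)
      }
      utts[[length(utts) + 1L]] <-
        utterance(spk, act, text = txt, filled_pauses = filled_pauses)
    }
  }
  req <- c("id", "task", "diagnosis", "sex")
  miss <- setdiff(req, names(header))
  if (length(miss)) {
    stop("format error: missing header field(s): ",
         paste0("@", miss, collapse = ", "), call. = FALSE)
  }
  transcript(id = header$id, task = header$task,
             diagnosis = header$diagnosis, sex = header$sex,
             age = if (is.null(header$age)) NA_real_ else as.numeric(header$age),
             viq = if (is.null(header$viq)) NA_real_ else as.numeric(header$viq),
             utterances = utts)
}

.format_utterance_text <- function(u) {
  s <- u$tokens$surface
  if (!length(s)) return("")
  maze <- u$tokens$is_maze
  ## re-wrap maximal maze runs in parentheses
  open <- maze & !c(FALSE, maze[-length(maze)])
  close <- maze & !c(maze[-1], FALSE)
  s[open] <- paste0("(", s[open])
  s[close] <- paste0(s[close], ")")
  paste(s, collapse = " ")
}

#' Write a transcript file
#'
#' Inverse of [read_transcript()]: emits header lines then one line per
#' utterance, restoring parentheses around maximal maze runs.
#'
#' @param t A [transcript()] object.
#' @param path Output file path, or `NULL` to return the lines invisibly.
#' @return The lines, invisibly.
#' @export
write_transcript <- function(t, path = NULL) {
  hdr <- c(paste("@id", t$id), paste("@task", t$task),
           paste("@diagnosis", t$diagnosis), paste("@sex", t$sex))
  if (!is.na(t$age)) hdr <- c(hdr, paste("@age", format(t$age)))
  if (!is.na(t$viq)) hdr <- c(hdr, paste("@viq", format(t$viq)))
  code <- c(participant = "P", examiner = "E")
  body <- vapply(t$utterances, function(u) {
    paste0(code[[u$speaker]], " ", u$act, "\t", .format_utterance_text(u))
  }, character(1))
  lines <- c(hdr, body)
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

## Counting -----------------------------------------------------------------

#' Participant word count
#'
#' Number of countable participant tokens: maze tokens are excluded,
#' filled pauses outside mazes are included, examiner tokens never count.
#'
#' @param t A transcript.
#' @return Non-negative integer.
#' @export
participant_word_count <- function(t) {
  n <- 0L
  for (u in t$utterances) {
    if (u$speaker != "participant") next
    n <- n + sum(!u$tokens$is_maze & nzchar(u$tokens$normalized))
  }
  n
}

#' Utterance count by speaker
#'
#' @param t A transcript.
#' @param speaker `"participant"` or `"examiner"`.
#' @return Non-negative integer.
#' @export
utterance_count <- function(t, speaker = c("participant", "examiner")) {
  speaker <- match.arg(speaker)
  sum(vapply(t$utterances, function(u) u$speaker == speaker, logical(1)))
}

## vector of participant act tags, examiner utterances dropped
participant_acts <- function(t) {
  acts <- vapply(t$utterances, `[[`, character(1), "act")
  spk <- vapply(t$utterances, `[[`, character(1), "speaker")
  acts[spk == "participant"]
}

## data.frame of (speaker, act) in transcript order
utterance_acts <- function(t) {
  data.frame(
    speaker = vapply(t$utterances, `[[`, character(1), "speaker"),
    act = vapply(t$utterances, `[[`, character(1), "act"),
    stringsAsFactors = FALSE)
}

## normalized countable participant tokens, one element per utterance
participant_token_lists <- function(t, count_mazes = FALSE) {
  out <- list()
  for (u in t$utterances) {
    if (u$speaker != "participant") next
    keep <- nzchar(u$tokens$normalized)
    if (!count_mazes) keep <- keep & !u$tokens$is_maze
    out[[length(out) + 1L]] <- u$tokens$normalized[keep]
  }
  out
}

#' Per-transcript count summary
#'
#' @param transcripts List of transcripts.
#' @return Data frame with id, task, diagnosis, sex, word and utterance
#'   counts (one row per transcript).
#' @export
transcript_summary <- function(transcripts) {
  do.call(rbind, lapply(transcripts, function(t) {
    data.frame(id = t$id, task = t$task, diagnosis = t$diagnosis,
               sex = t$sex, word_count = participant_word_count(t),
               utterance_count_participant = utterance_count(t, "participant"),
               utterance_count_examiner = utterance_count(t, "examiner"),
               stringsAsFactors = FALSE)
  }))
}
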