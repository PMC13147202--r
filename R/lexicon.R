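## LIWC-style dictionaries: named word categories of literal entries and
## trailing-`*` wildcard stems, plus composite categories that sum
## constituent counts. The shipped default lexicon contains only small
## example categories; user-supplied .dic files are the intended route
## for real dictionaries.

#' Construct a lexicon
#'
#' @param categories Named list; each element a character vector of entries.
#'   A trailing `*` marks a wildcard stem (prefix match, empty suffix
#'   allowed). Entries containing spaces are multi-word n-grams.
#' @param composition Named list mapping composite names to character
#'   vectors of constituent category names.
#' @return An object of class `"lexicon"`.
#' @export
lexicon <- function(categories, composition = list()) {
  if (is.null(names(categories)) || anyDuplicated(names(categories))) {
    stop("category names must be present and unique", call. = FALSE)
  }
  categories <- lapply(categories, function(e) {
    e <- tolower(trimws(e))
    dup <- duplicated(e)
    if (any(dup)) {
      warning("duplicate entries deduplicated: ",
              paste(unique(e[dup]), collapse = ", "), call. = FALSE)
    }
    unique(e)
  })
  for (comp in names(composition)) {
    bad <- setdiff(composition[[comp]], names(categories))
    if (length(bad)) {
      stop("composite '", comp, "' references unknown categories: ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
  }
  structure(list(categories = categories, composition = composition),
            class = "lexicon")
}

#' @export
print.lexicon <- function(x, ...) {
  cat("<lexicon> ", length(x$categories), " categories, ",
      length(x$composition), " composites\n", sep = "")
  for (nm in names(x$categories)) {
    cat("  ", nm, ": ", length(x$categories[[nm]]), " entries\n", sep = "")
  }
  invisible(x)
}

#' Read a LIWC-style .dic file
#'
#' Format: a `%`-delimited header block of `id<TAB>category-name` lines,
#' then `entry<TAB>id [id ...]` lines attaching entries to categories.
#'
#' @param path File path or character vector of lines.
#' @param composition Optional composite map, as in [lexicon()].
#' @return A `"lexicon"` object.
#' @export
read_lexicon <- function(path, composition = list()) {
  lines <- if (length(path) == 1L && !grepl("\n", path) && file.exists(path)) {
    readLines(path, warn = FALSE)
  } else {
    unlist(strsplit(path, "\n", fixed = TRUE))
  }
  lines <- lines[nzchar(trimws(lines))]
  pct <- which(trimws(lines) == "%")
  if (length(pct) < 2L) stop("format error: missing % header delimiters",
                             call. = FALSE)
  hdr <- lines[(pct[1] + 1L):(pct[2] - 1L)]
  ids <- character(0)
  for (h in hdr) {
    f <- strsplit(trimws(h), "[ \t]+")[[1]]
    if (length(f) != 2L) stop("format error in header line: ", h,
                              call. = FALSE)
    ids[f[1]] <- f[2]
  }
  cats <- setNames(vector("list", length(ids)), unname(ids))
  cats <- lapply(cats, function(x) character(0))
  body <- if (pct[2] < length(lines)) lines[(pct[2] + 1L):length(lines)] else character(0)
  for (b in body) {
    f <- strsplit(b, "\t")[[1]]
    if (length(f) < 2L) stop("format error in entry line: ", b, call. = FALSE)
    entry <- tolower(trimws(f[1]))
    for (id in strsplit(trimws(f[2]), "[ \t]+")[[1]]) {
      if (!id %in% names(ids)) {
        stop("format error: entry '", entry,
             "' references undeclared category id ", id, call. = FALSE)
      }
      nm <- ids[[id]]
      cats[[nm]] <- c(cats[[nm]], entry)
    }
  }
  lexicon(cats, composition)
}

#' The shipped example lexicon
#'
#' Small theoretically-derived categories (simple and complex affective
#' states, affective and cognitive behaviors, cognitive states, causal
#' markers, story elements, characters) built from published example
#' words, plus the standard composition: affective states + behaviors,
#' cognitive states + behaviors, and their union (affect and cognition).
#' Intended for examples and synthetic data, not as a full dictionary.
#'
#' @return A `"lexicon"` object.
#' @export
default_lexicon <- function() {
  path <- system.file("extdata", "novel_categories.dic",
                      package = "pragmalang", mustWork = TRUE)
  read_lexicon(path, composition = default_composition())
}

#' @rdname default_lexicon
#' @export
default_composition <- function() {
  list(
    affective_states_and_behaviors =
      c("simple_affective_states", "complex_affective_states",
        "affective_behaviors"),
    cognitive_states_and_behaviors =
      c("cognitive_states", "cognitive_behaviors"),
    affect_and_cognition =
      c("simple_affective_states", "complex_affective_states",
        "affective_behaviors", "cognitive_states", "cognitive_behaviors"))
}

#' Match a normalized token against a lexicon
#'
#' @param lex A `"lexicon"`.
#' @param token A single normalized token.
#' @return Character vector of matching category names (possibly several;
#'   multi-word entries are ignored here — see [classify_transcript()]).
#' @export
match_token <- function(lex, token) {
  out <- character(0)
  for (nm in names(lex$categories)) {
    ent <- lex$categories[[nm]]
    ent <- ent[!grepl(" ", ent, fixed = TRUE)]
    stems <- ent[endsWith(ent, "*")]
    lits <- setdiff(ent, stems)
    hit <- token %in% lits ||
      any(startsWith(token, substr(stems, 1L, nchar(stems) - 1L)))
    if (hit) out <- c(out, nm)
  }
  out
}

## split a lexicon into fast lookup tables
.compile_lexicon <- function(lex) {
  single <- list(); stems <- list(); multi <- list()
  for (nm in names(lex$categories)) {
    ent <- lex$categories[[nm]]
    mw <- grepl(" ", ent, fixed = TRUE)
    st <- !mw & endsWith(ent, "*")
    single[[nm]] <- ent[!mw & !st]
    stems[[nm]] <- substr(ent[st], 1L, nchar(ent[st]) - 1L)
    for (e in ent[mw]) {
      w <- strsplit(e, " ", fixed = TRUE)[[1]]
      key <- paste(w, collapse = " ")
      multi[[key]] <- list(words = w,
                           cats = unique(c(multi[[key]]$cats, nm)))
    }
  }
  lens <- if (length(multi)) {
    sort(unique(vapply(multi, function(m) length(m$words), integer(1))),
         decreasing = TRUE)
  } else integer(0)
  list(single = single, stems = stems, multi = multi, multi_lens = lens)
}

## category counts over one utterance's normalized token vector
.count_tokens <- function(toks, comp) {
  counts <- setNames(integer(length(comp$single)), names(comp$single))
  n <- length(toks)
  if (n == 0L) return(counts)
  consumed <- logical(n)
  ## greedy left-to-right n-gram pass (longest first at each position)
  if (length(comp$multi_lens)) {
    i <- 1L
    while (i <= n) {
      hit_len <- 0L
      for (L in comp$multi_lens) {
        if (i + L - 1L > n) next
        key <- paste(toks[i:(i + L - 1L)], collapse = " ")
        m <- comp$multi[[key]]
        if (!is.null(m)) {
          counts[m$cats] <- counts[m$cats] + 1L
          consumed[i:(i + L - 1L)] <- TRUE
          hit_len <- L
          break
        }
      }
      i <- i + max(hit_len, 1L)
    }
  }
  rest <- toks[!consumed]
  if (length(rest)) {
    ## a token increments a category at most once, even if it matches
    ## several of the category's entries
    for (nm in names(counts)) {
      hit <- rest %in% comp$single[[nm]]
      for (s in comp$stems[[nm]]) hit <- hit | startsWith(rest, s)
      counts[[nm]] <- counts[[nm]] + sum(hit)
    }
  }
  counts
}

#' Classify a transcript against a lexicon
#'
#' Accumulates category counts over countable participant tokens (maze
#' tokens excluded by default, consistent with [participant_word_count()]),
#' fills composite categories from the composition map, and reports each
#' category as a percent of participant word count. Multi-word entries are
#' matched greedily left to right within utterances and consume their
#' tokens; single-token entries may match several categories at once.
#'
#' @param t A transcript.
#' @param lex A `"lexicon"`.
#' @param count_mazes Include maze tokens in matching and in the word-count
#'   denominator.
#' @return A list of class `"category_profile"` with `transcript_id`,
#'   `word_count`, `counts`, `percents` (percents are `NA` when the word
#'   count is zero).
#' @export
classify_transcript <- function(t, lex, count_mazes = FALSE) {
  comp <- .compile_lexicon(lex)
  counts <- setNames(integer(length(lex$categories)), names(lex$categories))
  for (toks in participant_token_lists(t, count_mazes = count_mazes)) {
    counts <- counts + .count_tokens(toks, comp)
  }
  for (cn in names(lex$composition)) {
    counts[[cn]] <- sum(counts[lex$composition[[cn]]])
  }
  wc <- participant_word_count(t)
  if (count_mazes) {
    wc <- sum(vapply(participant_token_lists(t, count_mazes = TRUE),
                     length, integer(1)))
  }
  percents <- if (wc > 0) 100 * counts / wc else counts * NA_real_
  structure(list(transcript_id = t$id, word_count = wc,
                 counts = counts, percents = percents),
            class = "category_profile")
}

#' @export
print.category_profile <- function(x, ...) {
  cat("<category_profile ", x$transcript_id, "> word_count=", x$word_count,
      "\n", sep = "")
  print(data.frame(count = x$counts, percent = round(x$percents, 2)))
  invisible(x)
}

#' Category profiles for a cohort
#'
#' @param transcripts List of transcripts (unique ids).
#' @param lex A `"lexicon"`.
#' @param count_mazes See [classify_transcript()].
#' @return Data frame: one row per transcript with id, group columns,
#'   word count, then `<category>_count` and `<category>_pct` columns in
#'   stable order.
#' @export
cohort_profiles <- function(transcripts, lex, count_mazes = FALSE) {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids)) {
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "), call. = FALSE)
  }
  rows <- lapply(transcripts, function(t) {
    p <- classify_transcript(t, lex, count_mazes = count_mazes)
    cnt <- as.list(p$counts); names(cnt) <- paste0(names(cnt), "_count")
    pct <- as.list(p$percents); names(pct) <- paste0(names(pct), "_pct")
    cbind(data.frame(id = t$id, task = t$task, diagnosis = t$diagnosis,
                     sex = t$sex, viq = t$viq, age = t$age,
                     word_count = p$word_count, stringsAsFactors = FALSE),
          as.data.frame(cnt), as.data.frame(pct))
  })
  do.call(rbind, rows)
}
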