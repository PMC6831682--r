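# Per-trial scoring of one-minute response streams: response classification
# (correct / nonword / repetition), the graded fluency score WE, the
# successive-similarity score RE, the syllable-neighbour proportion SN, and
# the error count.

.as_word_set <- function(lexicon) {
  if (inherits(lexicon, "toy_lexicon")) return(lexicon$words)
  if (is.character(lexicon)) return(lexicon)
  if (is.data.frame(lexicon)) {
    if (all(c("pinyin", "is_word") %in% names(lexicon))) {
      return(lexicon$pinyin[lexicon$is_word])
    }
    if ("pinyin" %in% names(lexicon)) return(lexicon$pinyin)
  }
  stop("lexicon must be a character vector of tonal pinyin words, ",
       "a data frame with columns pinyin/is_word, or a toy_lexicon",
       call. = FALSE)
}

.check_response_cols <- function(responses) {
  need <- c("participant_id", "trial_id", "stimulus", "response")
  miss <- setdiff(need, names(responses))
  if (length(miss)) {
    stop("responses table is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
}

#' Classify productions as correct, nonword, or repetition
#'
#' Flags every production in a response stream. A production is a *word* if
#' its tonal pinyin string is in the lexicon; a *repetition* if the same
#' tonal syllable was produced earlier in the same trial (first occurrences
#' are never repetitions; a repeat of a tone variant is not a repetition,
#' since tone variants are distinct legitimate responses); and *correct* if
#' it is a word and not a repetition. The three response types
#' (correct / nonword / repetition) are mutually exclusive, with repetition
#' taking precedence over nonword, so their counts sum to the number of
#' productions.
#'
#' @param responses A data frame with one production per row and columns
#'   `participant_id`, `trial_id`, `stimulus` (tonal pinyin), `response`
#'   (tonal pinyin), and optionally `response_index` (production order within
#'   the trial; row order is used when absent).
#' @param lexicon The word list: a character vector of tonal pinyin words, a
#'   data frame with columns `pinyin` and `is_word`, or a [toy_lexicon()].
#' @return The input as a tibble, ordered within trial, with added columns
#'   `response_index`, `is_word`, `is_repetition`, `is_correct`, and
#'   `response_type` (`"correct"`, `"nonword"`, `"repetition"`).
#' @examples
#' resp <- tibble::tibble(participant_id = "p1", trial_id = "t1",
#'                        stimulus = "ma1", response = c("ma3", "ma3", "ma2"))
#' classify_productions(resp, lexicon = c("ma1", "ma3"))
#' @export
classify_productions <- function(responses, lexicon) {
  .check_response_cols(responses)
  words <- .as_word_set(lexicon)
  out <- tibble::as_tibble(responses)
  if (!"response_index" %in% names(out)) {
    out <- out |>
      dplyr::group_by(.data$participant_id, .data$trial_id) |>
      dplyr::mutate(response_index = dplyr::row_number()) |>
      dplyr::ungroup()
  }
  out |>
    dplyr::arrange(.data$participant_id, .data$trial_id,
                   .data$response_index) |>
    dplyr::group_by(.data$participant_id, .data$trial_id) |>
    dplyr::mutate(
      is_word = .data$response %in% words,
      is_repetition = duplicated(.data$response),
      is_correct = .data$is_word & !.data$is_repetition,
      response_type = dplyr::case_when(
        .data$is_repetition ~ "repetition",
        !.data$is_word ~ "nonword",
        TRUE ~ "correct"
      )
    ) |>
    dplyr::ungroup()
}

#' Score fluency measures for every trial
#'
#' Computes the per-trial fluency and error measures from a classified
#' response stream:
#'
#' * **WE** (weighted edit): the sum of graded weights [edit_weight()]
#'   between the stimulus and each *correct* production — a fluency score in
#'   which a response's value decays with its edit distance from the
#'   stimulus.
#' * **RE** (running edit): the mean of [edit_weight()] over consecutive
#'   production pairs, errors included — 1 means every production was an
#'   immediate neighbour of the one before it; low values mean repeated
#'   mental jumps away from successive similarity.
#' * **SN**: the proportion of consecutive pairs that are syllable
#'   neighbours (same atonal base), errors included — the signature of
#'   tone-family enumeration during search.
#' * **Error**: the number of nonword plus repetition productions.
#'
#' RE and SN are undefined (`NA`) on trials with fewer than two productions,
#' rather than 0, so downstream outlier screens are not distorted.
#'
#' @param classified A classified response table from
#'   [classify_productions()].
#' @param mapping A slot mapping from [pinyin_mapping()] covering every
#'   stimulus and response string.
#' @return A tibble with one row per (participant, trial): `n_productions`,
#'   `n_correct`, `n_nonword`, `n_repetition`, `WE`, `RE`, `SN`, `Error`.
#' @export
score_trials <- function(classified, mapping = pinyin_mapping()) {
  need <- c("is_correct", "response_type", "response_index")
  if (!all(need %in% names(classified))) {
    stop("run classify_productions() first", call. = FALSE)
  }
  strings <- unique(c(classified$stimulus, classified$response))
  bad <- !stringr::str_detect(strings, "^.+[1-5]$") |
    !(stringr::str_sub(strings, 1, -2) %in% mapping$pinyin)
  if (any(bad)) {
    ctx <- classified |>
      dplyr::filter(.data$response %in% strings[bad] |
                      .data$stimulus %in% strings[bad]) |>
      dplyr::distinct(.data$participant_id, .data$trial_id)
    stop("unparseable syllable(s) ",
         paste(strings[bad], collapse = ", "), " in trial(s) ",
         paste(paste0(ctx$participant_id, "/", ctx$trial_id),
               collapse = ", "), call. = FALSE)
  }
  parsed <- parse_pinyin(strings, mapping)
  look <- function(x) parsed[match(x, parsed$pinyin), ]

  classified |>
    dplyr::arrange(.data$participant_id, .data$trial_id,
                   .data$response_index) |>
    dplyr::group_by(.data$participant_id, .data$trial_id,
                    .data$stimulus) |>
    dplyr::group_modify(function(d, key) {
      syl <- look(d$response)
      stim <- look(key$stimulus)
      n <- nrow(d)
      corr <- syl[d$is_correct, , drop = FALSE]
      we <- if (nrow(corr)) sum(edit_weight(stim, corr)) else 0
      if (n >= 2L) {
        a <- syl[-n, , drop = FALSE]
        b <- syl[-1L, , drop = FALSE]
        re <- mean(edit_weight(a, b))
        sn <- mean(is_syllable_neighbor(a, b))
      } else {
        re <- NA_real_
        sn <- NA_real_
      }
      tibble::tibble(
        n_productions = n,
        n_correct = sum(d$response_type == "correct"),
        n_nonword = sum(d$response_type == "nonword"),
        n_repetition = sum(d$response_type == "repetition"),
        WE = we, RE = re, SN = sn,
        Error = sum(d$response_type != "correct")
      )
    }) |>
    dplyr::ungroup()
}
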