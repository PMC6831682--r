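# Synthetic cohorts with known ground truth. The generator emulates
# one-minute phonological fluency streams as a per-step mixture of two search
# moves observed in real trials: a *syllable move* that enumerates the
# remaining tone variants of the current atonal base (tone-family runs,
# nonwords included), and a *segment move* that mutates a single slot of the
# previous production (an immediate-neighbour chain). Jumps abandon local
# similarity at family boundaries, either returning to the stimulus
# neighbourhood or restarting from a random word. Repetition slips re-emit a
# recently produced item. Participant covariates shift the move mixture and
# error rates through logit-linear links, giving every generated trial a
# known ground-truth strategy parameterisation.

#' Build a toy lexicon over a small slot inventory
#'
#' Crosses small per-slot alphabets (onset C, glide G, nucleus V, coda X —
#' empty C/G/X allowed, V always filled) with tones 1-4 into a full syllable
#' inventory, and marks each tonal syllable as a real word with probability
#' `word_probability`; the rest are pronounceable nonwords, mimicking
#' syllables with no corresponding character. Atonal labels are the
#' concatenated slot symbols, which parse unambiguously because the alphabets
#' are disjoint.
#'
#' @param onsets,glides,nuclei,codas Character alphabets per slot; `""`
#'   marks the empty option (not allowed for `nuclei`).
#' @param tones Integer tone categories (default 1:4).
#' @param word_probability Probability a tonal syllable is a word.
#' @param seed Integer seed; the lexicon is reproducible given the seed.
#' @return A `toy_lexicon`: list with `mapping` (atonal slot table usable as
#'   the `mapping` argument everywhere), `syllables` (tonal inventory with
#'   `is_word`), and `words` (character vector of tonal word strings).
#' @examples
#' lex <- toy_lexicon(seed = 1)
#' head(lex$syllables)
#' @export
toy_lexicon <- function(onsets = c("", "p", "t", "k", "s", "m", "l"),
                        glides = c("", "i", "u"),
                        nuclei = c("a", "e", "o"),
                        codas = c("", "n", "r"),
                        tones = 1:4,
                        word_probability = 0.7,
                        seed = 1) {
  if (any(nuclei == "")) stop("the nucleus slot cannot be empty", call. = FALSE)
  grid <- expand.grid(C = onsets, G = glides, V = nuclei, X = codas,
                      KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  if (nrow(grid) < 2L) stop("degenerate inventory: fewer than 2 syllables",
                            call. = FALSE)
  sym <- c(onsets, glides, nuclei, codas)
  sym <- sym[sym != ""]
  if (anyDuplicated(sym)) {
    stop("slot alphabets must be disjoint so atonal labels are unambiguous",
         call. = FALSE)
  }
  atonal <- paste0(grid$C, grid$G, grid$V, grid$X)
  mapping <- tibble::tibble(
    pinyin = atonal,
    C = dplyr::na_if(grid$C, ""),
    G = dplyr::na_if(grid$G, ""),
    V = grid$V,
    X = dplyr::na_if(grid$X, "")
  )
  syllables <- tidyr::crossing(mapping, T = as.integer(tones)) |>
    dplyr::rename(atonal = "pinyin") |>
    dplyr::mutate(pinyin = paste0(.data$atonal, .data$T), .before = 1)
  syllables$is_word <- withr::with_seed(
    seed, stats::rbinom(nrow(syllables), 1, word_probability) == 1
  )
  if (!any(syllables$is_word)) stop("lexicon has no words", call. = FALSE)
  structure(
    list(mapping = mapping, syllables = syllables,
         words = syllables$pinyin[syllables$is_word],
         word_probability = word_probability, seed = seed),
    class = "toy_lexicon"
  )
}

#' @export
print.toy_lexicon <- function(x, ...) {
  cat("<toy_lexicon> ", nrow(x$syllables), " tonal syllables (",
      length(x$words), " words, p_word = ", x$word_probability, ")\n",
      sep = "")
  invisible(x)
}

#' Strategy parameters for trial generation
#'
#' The tunable knobs of the mental-search generator, all per production step:
#'
#' * `p_syllable` — probability a step continues/starts tone-family
#'   enumeration (the syllable-driven signature) rather than single-slot
#'   mutation (the segment-driven signature).
#' * `p_jump` — probability, at steps that do not continue a tone family, of
#'   abandoning successive similarity entirely.
#' * `p_anchor` — fraction of jumps that return to the stimulus
#'   neighbourhood (an unproduced immediate word neighbour of the stimulus)
#'   rather than restarting from a random word.
#' * `error_nonword_rate` — probability a segment move lands on a nonword
#'   (tone-family enumeration produces nonwords naturally, whatever this
#'   rate).
#' * `error_repetition_rate` — probability a step re-emits one of the last
#'   three productions (a working-memory slip).
#' * `mean_length`, `dispersion` — negative-binomial parameters of the
#'   production count per one-minute trial, bounded to `[2, 30]`.
#'
#' @param p_syllable,p_jump,p_anchor,error_nonword_rate,error_repetition_rate
#'   Probabilities in `[0, 1]`.
#' @param mean_length Mean productions per trial.
#' @param dispersion Negative-binomial size parameter.
#' @return A `strategy_params` list.
#' @export
strategy_params <- function(p_syllable = 0.35, p_jump = 0.10,
                            p_anchor = 0.5,
                            error_nonword_rate = 0.08,
                            error_repetition_rate = 0.05,
                            mean_length = 14, dispersion = 8) {
  p <- list(p_syllable = p_syllable, p_jump = p_jump, p_anchor = p_anchor,
            error_nonword_rate = error_nonword_rate,
            error_repetition_rate = error_repetition_rate,
            mean_length = mean_length, dispersion = dispersion)
  probs <- unlist(p[1:5])
  if (any(probs < 0 | probs > 1)) {
    stop("strategy probabilities must lie in [0, 1]", call. = FALSE)
  }
  structure(p, class = "strategy_params")
}

# rows of lexicon$syllables at slot-wise edit distance 1 from row `cur`
.edit1_rows <- function(cur, syllables, include_tone = TRUE) {
  cols <- if (include_tone) c(.slot_cols, "T") else .slot_cols
  d <- rep(0L, nrow(syllables))
  extra <- if (include_tone) 0L else
    as.integer(.slot_differs(syllables$T, cur$T))
  for (s in cols) d <- d + .slot_differs(syllables[[s]], cur[[s]])
  which(d == 1L & extra == 0L)
}

#' Generate one synthetic fluency trial
#'
#' Simulates an ordered production stream for one stimulus under a
#' [strategy_params()] setting (see that help page for the move model).
#' Generation is reproducible given `seed`. If local search dead-ends (no
#' unproduced candidate for a move), the trial is truncated and a
#' `truncated` attribute is set.
#'
#' @param stimulus Tonal pinyin string; must be in the lexicon.
#' @param strategy A [strategy_params()] object.
#' @param lexicon A [toy_lexicon()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `response_index` and `response`.
#' @examples
#' lex <- toy_lexicon(seed = 1)
#' generate_trial(lex$words[1], strategy_params(), lex, seed = 7)
#' @export
generate_trial <- function(stimulus, strategy, lexicon, seed = NULL) {
  if (!is.null(seed)) {
    return(withr::with_seed(seed,
                            generate_trial(stimulus, strategy, lexicon)))
  }
  syls <- lexicon$syllables
  si <- match(stimulus, syls$pinyin)
  if (is.na(si)) stop("stimulus not in lexicon: ", stimulus, call. = FALSE)
  n <- stats::rnbinom(1, size = strategy$dispersion, mu = strategy$mean_length)
  n <- max(2L, min(30L, n))

  stim_neighbors <- .edit1_rows(syls[si, ], syls)
  stim_word_neighbors <- stim_neighbors[syls$is_word[stim_neighbors]]

  produced <- character(0)
  cur <- si  # row index of current item
  truncated <- FALSE

  pick <- function(idx) if (length(idx) == 1L) idx else sample(idx, 1L)

  segment_move <- function(cur) {
    cand <- .edit1_rows(syls[cur, ], syls)
    cand <- cand[!(syls$pinyin[cand] %in% produced)]
    if (!length(cand)) return(NA_integer_)
    words <- cand[syls$is_word[cand]]
    nonwords <- cand[!syls$is_word[cand]]
    if (length(nonwords) &&
        (stats::runif(1) < strategy$error_nonword_rate || !length(words))) {
      pick(nonwords)
    } else {
      pick(words)
    }
  }

  for (step in seq_len(n)) {
    nxt <- NA_integer_
    if (length(produced) &&
        stats::runif(1) < strategy$error_repetition_rate) {
      rep_str <- sample(utils::tail(produced, 3), 1L)
      nxt <- match(rep_str, syls$pinyin)
      produced <- c(produced, syls$pinyin[nxt])
      cur <- nxt
      next
    }
    syllable_move <- stats::runif(1) < strategy$p_syllable
    if (syllable_move) {
      fam <- which(syls$atonal == syls$atonal[cur] & syls$T != syls$T[cur])
      fam <- fam[!(syls$pinyin[fam] %in% produced)]
      fam <- fam[order(syls$T[fam])]
      if (length(fam)) nxt <- fam[1L]
    }
    if (is.na(nxt)) {
      # family exhausted or segment mode: maybe jump, else mutate one slot
      if (stats::runif(1) < strategy$p_jump) {
        if (stats::runif(1) < strategy$p_anchor) {
          back <- stim_word_neighbors[
            !(syls$pinyin[stim_word_neighbors] %in% produced)]
          if (length(back)) nxt <- pick(back)
        }
        if (is.na(nxt)) {
          far <- which(syls$is_word & !(syls$pinyin %in% produced))
          far <- setdiff(far, cur)
          if (length(far)) nxt <- pick(far)
        }
      } else {
        nxt <- segment_move(cur)
      }
    }
    if (is.na(nxt)) nxt <- segment_move(cur)  # fall back before giving up
    if (is.na(nxt)) { truncated <- TRUE; break }
    produced <- c(produced, syls$pinyin[nxt])
    cur <- nxt
  }
  out <- tibble::tibble(response_index = seq_along(produced),
                        response = produced)
  attr(out, "truncated") <- truncated
  out
}

#' Covariate effect configuration for cohort generation
#'
#' Effect coefficients linking participant covariates to strategy parameters
#' on the logit scale, in the directions reported for real cohorts: higher
#' English proficiency lowers tone-family reliance (hence SN) and error
#' rates; more Chinese languages/dialects lowers tone-family reliance while
#' raising the jump rate (hence lower successive similarity RE and more
#' fragmented networks, higher NC); multilingual status lowers error rates.
#' Covariates are centred before the linear predictor is formed, and each
#' participant receives an independent normal perturbation (`participant_sd`)
#' on every logit, so parameters vary within covariate cells. Logit links
#' keep every probability in (0, 1) by construction.
#'
#' @param base A [strategy_params()] with the population-centre values.
#' @param english_on_p_syllable,numchinese_on_p_syllable Effects (per
#'   centred covariate unit) on the tone-family move logit.
#' @param numchinese_on_p_jump Effect on the jump logit.
#' @param english_on_nonword,english_on_repetition Effects on error logits.
#' @param multilingual_on_error Effect of multilingual status (0/1) on both
#'   error logits.
#' @param participant_sd SD of the per-participant logit perturbations.
#' @param length_sd SD of the per-participant log trial-length multiplier.
#' @return A `cohort_effects` list.
#' @export
cohort_effects <- function(base = strategy_params(),
                           english_on_p_syllable = -0.35,
                           numchinese_on_p_syllable = -0.25,
                           numchinese_on_p_jump = 0.45,
                           english_on_nonword = -0.30,
                           english_on_repetition = -0.20,
                           multilingual_on_error = -0.25,
                           participant_sd = 0.6,
                           length_sd = 0.20) {
  structure(
    list(base = base,
         english_on_p_syllable = english_on_p_syllable,
         numchinese_on_p_syllable = numchinese_on_p_syllable,
         numchinese_on_p_jump = numchinese_on_p_jump,
         english_on_nonword = english_on_nonword,
         english_on_repetition = english_on_repetition,
         multilingual_on_error = multilingual_on_error,
         participant_sd = participant_sd,
         length_sd = length_sd),
    class = "cohort_effects"
  )
}

#' Choose high-neighbourhood stimuli from a lexicon
#'
#' Picks `n` word syllables with the highest immediate word-neighbour
#' counts, one per atonal base, mirroring a stimulus set chosen to be dense
#' in single-edit neighbours without tone-family overlap.
#'
#' @param lexicon A [toy_lexicon()].
#' @param n Number of stimuli.
#' @return Character vector of tonal pinyin stimuli.
#' @export
pick_stimuli <- function(lexicon, n = 6) {
  syls <- lexicon$syllables
  wi <- which(syls$is_word)
  deg <- vapply(wi, function(i) {
    nb <- .edit1_rows(syls[i, ], syls)
    sum(syls$is_word[nb])
  }, numeric(1))
  ord <- wi[order(-deg)]
  out <- integer(0)
  for (i in ord) {
    if (!(syls$atonal[i] %in% syls$atonal[out])) out <- c(out, i)
    if (length(out) == n) break
  }
  if (length(out) < n) stop("lexicon too small for ", n, " stimuli",
                            call. = FALSE)
  syls$pinyin[out]
}

#' Generate a synthetic fluency cohort
#'
#' Samples participants with the covariate structure of a university Mandarin
#' cohort — self-rated English proficiency on levels 5-8, number of Chinese
#' languages/dialects 1-3, and a roughly even monolingual/multilingual split
#' — maps covariates to per-participant strategy parameters through
#' [cohort_effects()], and generates every participant's trials for a shared
#' stimulus set. The per-participant parameters are returned as ground truth
#' for recovery tests.
#'
#' @param n_participants Number of participants (default 95).
#' @param lexicon A [toy_lexicon()]; default `toy_lexicon(seed = seed)`.
#' @param effects A [cohort_effects()] configuration.
#' @param n_trials Number of stimuli/trials per participant (default 6).
#' @param seed Integer seed; the whole cohort is reproducible given it.
#' @return A `synthetic_cohort`: list with `participants` (covariates +
#'   ground-truth parameters), `responses` (one production per row, the
#'   format [classify_productions()] reads), `stimuli`, and `lexicon`.
#' @examples
#' coh <- generate_cohort(n_participants = 5, seed = 42)
#' coh$participants
#' @export
generate_cohort <- function(n_participants = 95, lexicon = NULL,
                            effects = cohort_effects(), n_trials = 6,
                            seed = 1) {
  if (is.null(lexicon)) lexicon <- toy_lexicon(seed = seed)
  withr::with_seed(seed, {
    base <- effects$base
    english <- sample(5:8, n_participants, replace = TRUE,
                      prob = c(0.12, 0.30, 0.38, 0.20))
    num_chinese <- sample(1:3, n_participants, replace = TRUE,
                          prob = c(0.25, 0.55, 0.20))
    multilingual <- stats::rbinom(n_participants, 1, 0.5)
    e_c <- english - mean(5:8)
    n_c <- num_chinese - 2
    noise <- function() stats::rnorm(n_participants, 0, effects$participant_sd)
    participants <- tibble::tibble(
      participant_id = sprintf("p%03d", seq_len(n_participants)),
      english = english,
      num_chinese = num_chinese,
      multilingual = multilingual,
      p_syllable = stats::plogis(
        stats::qlogis(base$p_syllable) +
          effects$english_on_p_syllable * e_c +
          effects$numchinese_on_p_syllable * n_c + noise()),
      p_jump = stats::plogis(
        stats::qlogis(base$p_jump) +
          effects$numchinese_on_p_jump * n_c + noise()),
      error_nonword_rate = stats::plogis(
        stats::qlogis(base$error_nonword_rate) +
          effects$english_on_nonword * e_c +
          effects$multilingual_on_error * multilingual + noise()),
      error_repetition_rate = stats::plogis(
        stats::qlogis(base$error_repetition_rate) +
          effects$english_on_repetition * e_c +
          effects$multilingual_on_error * multilingual + noise()),
      mean_length = pmin(24, pmax(
        4, base$mean_length *
          exp(stats::rnorm(n_participants, 0, effects$length_sd))))
    )
    stimuli <- pick_stimuli(lexicon, n_trials)
    responses <- purrr::pmap(participants, function(participant_id,
                                                    p_syllable, p_jump,
                                                    error_nonword_rate,
                                                    error_repetition_rate,
                                                    mean_length, ...) {
      strat <- strategy_params(
        p_syllable = p_syllable, p_jump = p_jump,
        p_anchor = effects$base$p_anchor,
        error_nonword_rate = error_nonword_rate,
        error_repetition_rate = error_repetition_rate,
        mean_length = mean_length, dispersion = effects$base$dispersion)
      purrr::imap(stats::setNames(stimuli,
                                  paste0("t", seq_along(stimuli))),
                  function(stim, tid) {
                    generate_trial(stim, strat, lexicon) |>
                      dplyr::mutate(participant_id = participant_id,
                                    trial_id = tid, stimulus = stim,
                                    .before = 1)
                  }) |> dplyr::bind_rows()
    }) |> dplyr::bind_rows()
    structure(
      list(participants = participants, responses = responses,
           stimuli = stimuli, lexicon = lexicon, seed = seed),
      class = "synthetic_cohort"
    )
  })
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort> ", nrow(x$participants), " participants, ",
      length(x$stimuli), " trials each, ",
      nrow(x$responses), " productions\n", sep = "")
  invisible(x)
}

#' Simulate a cohort and write it to disk
#'
#' Convenience wrapper around [generate_cohort()] that writes the response
#' table in the format the scoring pipeline reads (`responses.csv`), the
#' lexicon word list (`lexicon.csv`), the slot mapping (`mapping.tsv`), and a
#' ground-truth sidecar with the per-participant covariates and strategy
#' parameters (`ground_truth.csv`).
#'
#' @param out_dir Output directory (created if needed).
#' @param config Optional list (or path to a YAML file) with elements
#'   `n_participants`, `n_trials`, `seed`, and any [cohort_effects()]
#'   arguments.
#' @inheritParams generate_cohort
#' @return The `synthetic_cohort`, invisibly.
#' @export
simulate_cohort <- function(out_dir, config = NULL, seed = 1) {
  if (is.character(config)) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the yaml package", call. = FALSE)
    }
    config <- yaml::read_yaml(config)
  }
  config <- config %||% list()
  eff_args <- config[intersect(names(config),
                               names(formals(cohort_effects)))]
  if (!is.null(config$base)) {
    eff_args$base <- do.call(strategy_params, config$base)
  }
  coh <- generate_cohort(
    n_participants = config$n_participants %||% 95,
    n_trials = config$n_trials %||% 6,
    effects = do.call(cohort_effects, eff_args),
    seed = config$seed %||% seed
  )
  if (!dir.exists(out_dir)) dir.create(out_dir, recursive = TRUE)
  readr::write_csv(coh$responses, file.path(out_dir, "responses.csv"))
  readr::write_csv(tibble::tibble(pinyin = coh$lexicon$syllables$pinyin,
                                  is_word = coh$lexicon$syllables$is_word),
                   file.path(out_dir, "lexicon.csv"))
  readr::write_tsv(
    tibble::tibble(
      pinyin = coh$lexicon$mapping$pinyin,
      slots = paste(dplyr::coalesce(coh$lexicon$mapping$C, "-"),
                    dplyr::coalesce(coh$lexicon$mapping$G, "-"),
                    coh$lexicon$mapping$V,
                    dplyr::coalesce(coh$lexicon$mapping$X, "-"), sep = "|")),
    file.path(out_dir, "mapping.tsv"))
  readr::write_csv(coh$participants, file.path(out_dir, "ground_truth.csv"))
  invisible(coh)
}
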