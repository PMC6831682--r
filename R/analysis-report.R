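# Cohort-level descriptive analysis: variable summaries, the correlation
# table, response-type and hop breakdowns, the syllable-driven strategy
# split, and export of the analysis-ready table for external statistical
# modelling (the multivariate regression stage is deliberately not
# reimplemented here).

#' Score a whole cohort end to end
#'
#' Classifies every production, computes the per-trial fluency scores and
#' network measures, and joins them into one row per (participant, trial).
#' This is the main entry point: `generate_cohort() |> score_cohort()` (or a
#' read-in response table) yields the table every reporting function
#' consumes.
#'
#' @param responses A response table (columns `participant_id`, `trial_id`,
#'   `stimulus`, `response`, optional `response_index`) or a
#'   `synthetic_cohort`, whose responses, lexicon and mapping are then used.
#' @param lexicon Word list; see [classify_productions()]. Ignored when
#'   `responses` is a `synthetic_cohort`.
#' @param mapping Slot mapping; see [pinyin_mapping()]. A `toy_lexicon`
#'   passed as `lexicon` supplies its own mapping when this is left `NULL`.
#' @param include_stimulus Passed to [network_scores()].
#' @return A tibble, one row per trial, with fluency scores (`WE`, `RE`,
#'   `SN`, `Error`, counts) and network measures (`NC`, `CC_bar`, `M`, hop
#'   counts).
#' @export
score_cohort <- function(responses, lexicon = NULL, mapping = NULL,
                         include_stimulus = FALSE) {
  if (inherits(responses, "synthetic_cohort")) {
    lexicon <- responses$lexicon
    responses <- responses$responses
  }
  if (is.null(mapping)) {
    mapping <- if (inherits(lexicon, "toy_lexicon")) lexicon$mapping
               else pinyin_mapping()
  }
  cls <- classify_productions(responses, lexicon)
  dplyr::full_join(
    score_trials(cls, mapping),
    network_scores(cls, mapping, include_stimulus = include_stimulus),
    by = c("participant_id", "trial_id", "stimulus")
  )
}

.default_vars <- c("WE", "RE", "SN", "Error", "CC_bar", "M", "NC")

#' Distributional summary of the score variables
#'
#' Min, max, mean and SD per variable, the descriptive half of a cohort
#' summary table.
#'
#' @param score_table A per-trial score table (e.g. from [score_cohort()]).
#' @param vars Variables to summarise (default: the seven dependent
#'   variables WE, RE, SN, Error, CC_bar, M, NC).
#' @return A tibble with columns `variable`, `n`, `min`, `max`, `mean`,
#'   `sd`.
#' @export
fluency_descriptives <- function(score_table,
                                 vars = intersect(.default_vars,
                                                  names(score_table))) {
  if (!nrow(score_table)) stop("empty score table", call. = FALSE)
  if (!length(vars)) stop("no score variables found", call. = FALSE)
  score_table |>
    dplyr::select(dplyr::all_of(vars)) |>
    tidyr::pivot_longer(dplyr::everything(), names_to = "variable") |>
    dplyr::group_by(.data$variable) |>
    dplyr::summarise(
      n = sum(!is.na(.data$value)),
      min = min(.data$value, na.rm = TRUE),
      max = max(.data$value, na.rm = TRUE),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::arrange(match(.data$variable, vars))
}

#' Pairwise correlations between score variables
#'
#' Product-moment (or rank) correlations with pairwise-complete handling of
#' missing values. Variables with zero variance get `NA` correlations.
#'
#' @inheritParams fluency_descriptives
#' @param method `"pearson"` (default) or `"spearman"`.
#' @param by_participant If `TRUE`, trials are averaged within participant
#'   before correlating (participant-level rather than trial-level
#'   correlations).
#' @return A symmetric correlation matrix with unit diagonal.
#' @export
correlation_table <- function(score_table,
                              vars = intersect(.default_vars,
                                               names(score_table)),
                              method = c("pearson", "spearman"),
                              by_participant = FALSE) {
  method <- match.arg(method)
  tab <- score_table
  if (by_participant) {
    tab <- tab |>
      dplyr::group_by(.data$participant_id) |>
      dplyr::summarise(dplyr::across(dplyr::all_of(vars),
                                     ~mean(.x, na.rm = TRUE)),
                       .groups = "drop")
  }
  m <- suppressWarnings(
    stats::cor(as.matrix(tab[, vars]), use = "pairwise.complete.obs",
               method = method)
  )
  diag(m) <- 1
  m
}

#' Response-type and hop breakdown
#'
#' The proportions of correct, nonword and repetition productions across a
#' classified cohort, and (when a network score table is supplied) the
#' proportions of correct responses by hop distance from the stimulus, with
#' responses sharing no path to the stimulus binned as `"disconnected"`.
#' Each breakdown sums to 1.
#'
#' @param classified Output of [classify_productions()].
#' @param net_scores Optional output of [network_scores()] (or
#'   [score_cohort()]) carrying the `hops` list column.
#' @return A list with tibbles `types` (`response_type`, `n`, `prop`) and,
#'   when available, `hops` (`hop`, `n`, `prop`).
#' @export
response_type_breakdown <- function(classified, net_scores = NULL) {
  types <- classified |>
    dplyr::count(.data$response_type) |>
    dplyr::mutate(prop = .data$n / sum(.data$n))
  out <- list(types = types)
  if (!is.null(net_scores) && "hops" %in% names(net_scores)) {
    hops <- dplyr::bind_rows(net_scores$hops) |>
      dplyr::group_by(.data$hop) |>
      dplyr::summarise(n = sum(.data$n), .groups = "drop") |>
      dplyr::mutate(prop = .data$n / sum(.data$n))
    num <- suppressWarnings(as.numeric(hops$hop))
    out$hops <- hops[order(is.na(num), num), ]
  }
  out
}

#' Proportion of syllable-driven trials
#'
#' The fraction of trials whose syllable-neighbour proportion SN strictly
#' exceeds the threshold — the split separating predominantly syllable-driven
#' search (successive tone-family enumeration) from segment-driven search.
#'
#' @inheritParams fluency_descriptives
#' @param threshold Split point (default 0.50).
#' @return A single proportion.
#' @export
strategy_split <- function(score_table, threshold = 0.50) {
  sn <- score_table$SN
  mean(sn[!is.na(sn)] > threshold)
}

#' Export the analysis-ready model table
#'
#' Joins per-trial scores with participant covariates into the one-row-per-
#' trial table consumed by external statistical modelling (multivariate
#' regressions over the seven dependent variables). Rows with missing
#' covariates are flagged, not dropped.
#'
#' @inheritParams fluency_descriptives
#' @param participants A data frame with `participant_id` and covariate
#'   columns (e.g. `english`, `num_chinese`, `multilingual`).
#' @param path Optional CSV path to write the table to.
#' @return The joined tibble with a `covariates_missing` flag column.
#' @export
export_model_table <- function(score_table, participants, path = NULL) {
  cov_cols <- setdiff(names(participants), "participant_id")
  out <- dplyr::left_join(tibble::as_tibble(score_table),
                          tibble::as_tibble(participants),
                          by = "participant_id")
  out$covariates_missing <- !stats::complete.cases(out[, cov_cols])
  if (any(out$covariates_missing)) {
    warning(sum(out$covariates_missing),
            " row(s) have missing covariates (flagged, not dropped)")
  }
  if (!is.null(path)) readr::write_csv(out, path)
  out
}

#' Code multilingual status from self-rated proficiencies
#'
#' A participant is multilingual when more than one language is self-rated at
#' native-like level (9-10 on a 1-10 scale), monolingual otherwise.
#'
#' @param ratings A numeric matrix or data frame, one row per participant and
#'   one column per language, of self-rated spoken proficiencies (1-10).
#' @return Integer vector: 1 = multilingual, 0 = monolingual.
#' @examples
#' code_multilingual(rbind(c(10, 9, 4), c(10, 6, 5)))  # 1, 0
#' @export
code_multilingual <- function(ratings) {
  m <- as.matrix(ratings)
  as.integer(rowSums(m >= 9 & m <= 10, na.rm = TRUE) > 1)
}

#' Read a response table from disk
#'
#' Reads a UTF-8 delimited response table (one production per row) with
#' columns `participant_id`, `trial_id`, `stimulus`, `response` and optional
#' `response_index`. The delimiter is inferred from the file extension
#' (`.tsv` = tab, otherwise comma).
#'
#' @param path File path.
#' @return A tibble.
#' @export
read_responses <- function(path) {
  reader <- if (grepl("\\.tsv$", path)) readr::read_tsv else readr::read_csv
  out <- reader(path, show_col_types = FALSE, progress = FALSE)
  .check_response_cols(out)
  out
}
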