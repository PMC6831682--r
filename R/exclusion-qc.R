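# Outlier exclusion procedures: a participant-level screen on error counts,
# per-variable trial-level screens (one-sided SD rules and a Tukey boxplot
# rule), and a minimum-cell-count filter for sparse covariate levels.
# Thresholds are computed once on the full pre-exclusion distribution (a
# single pass, never re-iterated), so the screens are idempotent.

#' Participant-level exclusion on excessive error rates
#'
#' Flags participants whose total nonword or repetition production count lies
#' more than `sd_mult` standard deviations above the group mean of that
#' count. Both screens are one-sided (above only) and computed on the full
#' pre-exclusion distribution.
#'
#' @param error_table A data frame with one row per participant and columns
#'   `participant_id`, `n_nonword`, `n_repetition` (e.g. aggregated from
#'   [score_trials()] output).
#' @param sd_mult SD multiplier for the threshold (default 2.5).
#' @return The input tibble with added columns `excluded` (logical) and
#'   `reason` (`"nonwords"`, `"repetitions"`, `"nonwords+repetitions"`, or
#'   `NA`). Thresholds are attached as attribute `"thresholds"`.
#' @export
exclude_participants <- function(error_table, sd_mult = 2.5) {
  need <- c("participant_id", "n_nonword", "n_repetition")
  if (!all(need %in% names(error_table))) {
    stop("error_table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  out <- tibble::as_tibble(error_table)
  if (nrow(out) < 3L) {
    warning("fewer than 3 participants: SD threshold unreliable, ",
            "no exclusions made")
    out$excluded <- FALSE
    out$reason <- NA_character_
    return(out)
  }
  thr_nw <- mean(out$n_nonword) + sd_mult * stats::sd(out$n_nonword)
  thr_rep <- mean(out$n_repetition) + sd_mult * stats::sd(out$n_repetition)
  over_nw <- out$n_nonword > thr_nw
  over_rep <- out$n_repetition > thr_rep
  out$excluded <- over_nw | over_rep
  out$reason <- dplyr::case_when(
    over_nw & over_rep ~ "nonwords+repetitions",
    over_nw ~ "nonwords",
    over_rep ~ "repetitions",
    TRUE ~ NA_character_
  )
  attr(out, "thresholds") <- c(nonwords = thr_nw, repetitions = thr_rep)
  out
}

#' Default trial-level exclusion rules
#'
#' The per-variable screens applied to trial scores: WE and SN are screened
#' above the mean only (high outliers), RE below the mean only (low
#' outliers), and assortativity `M` with a two-sided Tukey boxplot rule
#' (outside the quartiles by more than `iqr_mult` interquartile ranges).
#'
#' @param sd_mult SD multiplier for the one-sided rules (default 2.5).
#' @param iqr_mult IQR multiplier for the boxplot rule (default 1.5, the
#'   Tukey fence).
#' @return A named list of rules usable with [exclude_trials()].
#' @export
fluency_exclusion_rules <- function(sd_mult = 2.5, iqr_mult = 1.5) {
  list(
    WE = list(rule = "sd_above", k = sd_mult),
    SN = list(rule = "sd_above", k = sd_mult),
    RE = list(rule = "sd_below", k = sd_mult),
    M = list(rule = "boxplot", k = iqr_mult)
  )
}

.rule_bounds <- function(x, rule, k) {
  switch(rule,
    sd_above = c(-Inf, mean(x, na.rm = TRUE) + k * stats::sd(x, na.rm = TRUE)),
    sd_below = c(mean(x, na.rm = TRUE) - k * stats::sd(x, na.rm = TRUE), Inf),
    boxplot = {
      q <- stats::quantile(x, c(0.25, 0.75), na.rm = TRUE, names = FALSE)
      c(q[1] - k * (q[2] - q[1]), q[2] + k * (q[2] - q[1]))
    },
    stop("unknown exclusion rule: ", rule, call. = FALSE)
  )
}

#' Trial-level outlier exclusion
#'
#' Applies per-variable outlier screens to a trial score table. Each rule's
#' bounds are computed once, on the full table; a trial is excluded if any
#' screened variable falls outside its bounds. Missing values never trigger
#' exclusion.
#'
#' @param score_table A data frame of per-trial scores (e.g. the join of
#'   [score_trials()] and [network_scores()]).
#' @param rules A named list mapping a column name to
#'   `list(rule = , k = )` with rule one of `"sd_above"`, `"sd_below"`,
#'   `"boxplot"`; see [fluency_exclusion_rules()].
#' @return The input tibble with columns `excluded` and `excluded_by`
#'   (comma-separated rule names). The attribute `"exclusion_summary"` holds
#'   a tibble of per-rule counts and bounds plus the overall excluded
#'   proportion as attribute `"prop_excluded"`.
#' @export
exclude_trials <- function(score_table, rules = fluency_exclusion_rules()) {
  out <- tibble::as_tibble(score_table)
  miss <- setdiff(names(rules), names(out))
  if (length(miss)) {
    stop("score_table has no column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  flags <- matrix(FALSE, nrow(out), length(rules),
                  dimnames = list(NULL, names(rules)))
  summ <- purrr::imap(rules, function(r, v) {
    b <- .rule_bounds(out[[v]], r$rule, r$k)
    hit <- !is.na(out[[v]]) & (out[[v]] < b[1] | out[[v]] > b[2])
    flags[, v] <<- hit
    tibble::tibble(variable = v, rule = r$rule, k = r$k,
                   lower = b[1], upper = b[2], n_excluded = sum(hit))
  }) |> dplyr::bind_rows()
  out$excluded <- rowSums(flags) > 0
  out$excluded_by <- apply(flags, 1, function(f) {
    if (!any(f)) NA_character_ else paste(names(rules)[f], collapse = ",")
  })
  attr(summ, "prop_excluded") <- mean(out$excluded)
  attr(out, "exclusion_summary") <- summ
  out
}

#' Exclude participants in sparse covariate cells
#'
#' Drops participants who occupy a covariate level shared by fewer than
#' `min_n` participants (e.g. the sole speaker at an extreme proficiency
#' level), so that every retained level supports a between-participant
#' contrast.
#'
#' @param participants A data frame with a `participant_id` column.
#' @param vars Character vector of covariate column names to screen.
#' @param min_n Minimum participants per level (default 2).
#' @return The input tibble with columns `excluded` and `reason`.
#' @export
exclude_sparse_levels <- function(participants, vars, min_n = 2) {
  out <- tibble::as_tibble(participants)
  out$excluded <- FALSE
  out$reason <- NA_character_
  for (v in vars) {
    counts <- table(out[[v]])
    sparse <- names(counts)[counts < min_n]
    hit <- as.character(out[[v]]) %in% sparse
    out$reason <- ifelse(hit & !out$excluded, paste0("sparse ", v),
                         out$reason)
    out$excluded <- out$excluded | hit
  }
  out
}

#' Write a QC report of exclusions
#'
#' Writes the per-trial exclusion table as CSV and the per-rule summary
#' (bounds, counts, overall excluded proportion) as JSON.
#'
#' @param excluded_table Output of [exclude_trials()].
#' @param dir Output directory (created if needed).
#' @return The directory, invisibly.
#' @export
write_qc_report <- function(excluded_table, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  readr::write_csv(excluded_table, file.path(dir, "trial_exclusions.csv"))
  summ <- attr(excluded_table, "exclusion_summary")
  if (!is.null(summ) && requireNamespace("jsonlite", quietly = TRUE)) {
    jsonlite::write_json(
      list(rules = summ,
           prop_excluded = attr(summ, "prop_excluded")),
      file.path(dir, "exclusion_summary.json"),
      auto_unbox = TRUE, digits = NA
    )
  }
  invisible(dir)
}
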