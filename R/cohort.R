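#' Encode diagnostic status from a DSM-5 ADHD presentation label
#'
#' ADHD is recorded clinically as one of three presentations (Inattentive,
#' Hyperactive-Impulsive, Combined). For modeling, presentations are re-coded
#' as two binary *status* flags, with Combined positive on both, so that the
#' inattentive and hyperactive domains can carry separate regression effects.
#' Participants with ADHD other/unspecified do not meet criteria for a specific
#' presentation and are excluded from every downstream model.
#'
#' @param presentation Character vector with values among
#'   `"Inattentive"`, `"Hyperactive"`, `"Combined"`, `"OtherUnspecified"`,
#'   `"None"`.
#' @return A tibble with one row per input element and integer columns
#'   `adhd_inatt`, `adhd_hyper`, `excluded` (0/1).
#' @examples
#' code_diagnosis_status(c("Combined", "None", "OtherUnspecified"))
#' @export
code_diagnosis_status <- function(presentation) {
  valid <- c("Inattentive", "Hyperactive", "Combined", "OtherUnspecified", "None")
  bad <- setdiff(unique(presentation), valid)
  if (length(bad) > 0) {
    abort(paste0(
      "Unknown presentation label(s): ",
      paste0("'", bad, "'", collapse = ", "),
      ". Must be one of: ", paste(valid, collapse = ", "), "."
    ))
  }
  tibble::tibble(
    adhd_inatt = as.integer(presentation %in% c("Inattentive", "Combined")),
    adhd_hyper = as.integer(presentation %in% c("Hyperactive", "Combined")),
    excluded   = as.integer(presentation == "OtherUnspecified")
  )
}

#' Add diagnostic status flags to a participant table
#'
#' Convenience wrapper applying [code_diagnosis_status()] to the
#' `presentation` column of a participant table.
#'
#' @param participants Data frame with a `presentation` column.
#' @return The input as a tibble with `adhd_inatt`, `adhd_hyper`, `excluded`
#'   columns added (overwritten if present).
#' @export
add_diagnosis_status <- function(participants) {
  stopifnot("presentation" %in% names(participants))
  status <- code_diagnosis_status(participants$presentation)
  participants <- tibble::as_tibble(participants)
  participants$adhd_inatt <- status$adhd_inatt
  participants$adhd_hyper <- status$adhd_hyper
  participants$excluded <- status$excluded
  participants
}

# Round half away from zero, the convention used for printed percentages
# (e.g. 60/349 = 17.19% -> 17; 12.5% -> 13, not 12).
round_half_up <- function(x) sign(x) * floor(abs(x) + 0.5)

#' Default diagnostic group definitions for cohort summaries
#'
#' One predicate per column of a demographics table: ADHD-Inattentive and
#' ADHD-Hyperactive status groups both include the Combined presentation by
#' construction of the status flags; the Typically Developing group requires
#' the explicit all-negative indicator `td`.
#'
#' @return Named list of one-sided formulas, each a predicate over the
#'   participant table.
#' @export
cohort_groups <- function() {
  list(
    "ADHD-Inattentive"     = ~ .data$adhd_inatt == 1,
    "ADHD-Hyperactive"     = ~ .data$adhd_hyper == 1,
    "ASD"                  = ~ .data$asd == 1,
    "Typically Developing" = ~ .data$td == 1,
    "Full Sample"          = ~TRUE
  )
}

#' Descriptive cohort summary by diagnostic group
#'
#' Produces a demographics/clinical table in the conventional layout: per
#' group, n; mean (SD) of continuous characteristics over non-missing values
#' (pairwise, not listwise); count and integer-rounded percentage for binary
#' characteristics. Overlapping groups (Inattentive, Hyperactive) double-count
#' Combined-presentation members by construction.
#'
#' @param participants Participant table with diagnostic status flags (see
#'   [add_diagnosis_status()]). Excluded records are retained here (they are
#'   part of the described sample) unless already filtered by the caller.
#' @param groups Named list of one-sided formulas over the table, as in
#'   [cohort_groups()].
#' @param continuous Character vector of continuous columns to summarize as
#'   mean (SD); defaults to the standard demographic/clinical set, intersected
#'   with available columns.
#' @param binary Character vector of binary columns to summarize as count (%).
#' @return A tidy tibble with columns `group`, `n`, `characteristic`,
#'   `stat` (`"mean_sd"` or `"count_pct"`), `value1` (mean or count),
#'   `value2` (sd or integer percent). Empty groups yield `n = 0` and missing
#'   statistics.
#' @seealso [format_cohort_table()] for the wide printed layout.
#' @export
summarize_cohort <- function(participants,
                             groups = cohort_groups(),
                             continuous = NULL,
                             binary = NULL) {
  participants <- tibble::as_tibble(participants)
  default_cont <- c("age", "swan_inatt", "swan_hyper", "assq", "mfq", "scared",
                    "cbcl_ext", "cbcl_int", "iq_full", "iq_verbal",
                    "interview_minutes")
  default_bin <- c("sex", "adhd_inatt", "adhd_hyper", "asd")
  continuous <- continuous %||% intersect(default_cont, names(participants))
  binary <- binary %||% intersect(default_bin, names(participants))

  purrr::imap_dfr(groups, function(pred, group_name) {
    keep <- rlang::eval_tidy(rlang::f_rhs(pred), data = participants)
    keep <- rep_len(keep, nrow(participants))
    keep[is.na(keep)] <- FALSE
    sub <- participants[keep, , drop = FALSE]
    n <- nrow(sub)
    cont <- purrr::map_dfr(continuous, function(col) {
      x <- sub[[col]]
      x <- x[!is.na(x)]
      tibble::tibble(
        characteristic = col, stat = "mean_sd",
        value1 = if (length(x) > 0) mean(x) else NA_real_,
        value2 = if (length(x) > 1) sd(x) else if (length(x) == 1) 0 else NA_real_
      )
    })
    bin <- purrr::map_dfr(binary, function(col) {
      x <- sub[[col]]
      cnt <- sum(x == 1, na.rm = TRUE)
      tibble::tibble(
        characteristic = col, stat = "count_pct",
        value1 = if (n > 0) as.numeric(cnt) else NA_real_,
        value2 = if (n > 0) round_half_up(100 * cnt / n) else NA_real_
      )
    })
    dplyr::bind_rows(cont, bin) |>
      dplyr::mutate(group = group_name, n = n, .before = 1)
  })
}

#' Format a cohort summary as a printed-style character table
#'
#' Renders the output of [summarize_cohort()] into the familiar wide layout
#' with cells `"mean (sd)"` for continuous rows and `"count (pct)"` for binary
#' rows, one column per group.
#'
#' @param summary Output of [summarize_cohort()].
#' @param digits Digits for means/SDs (default 1).
#' @return A tibble with a `characteristic` column and one character column
#'   per group; the first row holds group sizes.
#' @export
format_cohort_table <- function(summary, digits = 1) {
  fmt <- summary |>
    dplyr::mutate(cell = dplyr::case_when(
      is.na(.data$value1) ~ NA_character_,
      .data$stat == "mean_sd" ~ sprintf(
        paste0("%.", digits, "f (%.", max(digits, 2) - 1, "f)"),
        .data$value1, .data$value2
      ),
      TRUE ~ sprintf("%d (%d)", as.integer(.data$value1), as.integer(.data$value2))
    )) |>
    dplyr::select("group", "characteristic", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  sizes <- summary |>
    dplyr::distinct(.data$group, .data$n) |>
    dplyr::mutate(cell = sprintf("N=%d", .data$n), characteristic = "n") |>
    dplyr::select("group", "characteristic", "cell") |>
    tidyr::pivot_wider(names_from = "group", values_from = "cell")
  dplyr::bind_rows(sizes, fmt)
}

#' Male-to-female ratio of a cohort
#'
#' @param participants Participant table with a binary `sex` column coded
#'   female = 1, male = 0.
#' @return The ratio (males / females) rounded to two decimals.
#' @examples
#' sex_ratio(tibble::tibble(sex = rep(c(0, 1), c(1556, 785)))) # 1.98
#' @export
sex_ratio <- function(participants) {
  males <- sum(participants$sex == 0, na.rm = TRUE)
  females <- sum(participants$sex == 1, na.rm = TRUE)
  if (females == 0) abort("undefined ratio: no females in cohort")
  round(males / females, 2)
}
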