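#' Identify the embedding columns of an answer-embedding table
#'
#' Embedding tables are wide: one row per participant x question, with the
#' D-dimensional vector spread over columns `v0 ... v{D-1}`.
#'
#' @param embeddings Embedding tibble.
#' @return Character vector of embedding column names, in dimension order.
#' @export
embedding_cols <- function(embeddings) {
  cols <- grep("^v[0-9]+$", names(embeddings), value = TRUE)
  if (length(cols) == 0) abort("no embedding columns (v0, v1, ...) found")
  cols[order(as.integer(sub("^v", "", cols)))]
}

#' Build the typically-developing reference set of median embeddings
#'
#' The normative semantic baseline is the component-wise median embedding for
#' each interview question, over all non-missing answers from typically
#' developing participants inside the reference age band (by default the
#' older TD participants, 14-22 years). Raw embeddings are medianed without
#' unit-normalization; cosine similarity handles scale at scoring time.
#'
#' @param embeddings Wide embedding table: `participant_id`, `question_id`,
#'   `missing` (0/1), `v0 ... v{D-1}`.
#' @param participants Participant table with `participant_id`, `age` and a
#'   `td` indicator (1 = confirmed negative in all diagnostic categories).
#' @param age_band Numeric length-2 inclusive age band, default `c(14, 22)`.
#' @return Tibble with `question_id`, `n_contributors`, and the median vector
#'   in columns `v0 ...`; one row per question appearing in `embeddings`.
#' @export
build_reference <- function(embeddings, participants, age_band = c(14, 22)) {
  stopifnot("td" %in% names(participants), "age" %in% names(participants))
  vcols <- embedding_cols(embeddings)
  td_ids <- participants$participant_id[
    participants$td == 1 & !is.na(participants$age) &
      participants$age >= age_band[1] & participants$age <= age_band[2]
  ]
  contrib <- embeddings |>
    dplyr::filter(.data$participant_id %in% td_ids, .data$missing == 0)
  questions <- sort(unique(embeddings$question_id))
  empty <- setdiff(questions, unique(contrib$question_id))
  if (length(empty) > 0) {
    abort(paste0("no typically-developing reference answers for question(s): ",
                 paste(empty, collapse = ", ")))
  }
  contrib |>
    dplyr::group_by(question_id = .data$question_id) |>
    dplyr::summarise(
      n_contributors = dplyr::n(),
      dplyr::across(dplyr::all_of(vcols), median),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$question_id)
}

#' Semantic typicality: cosine similarity to the TD median embedding
#'
#' Scores how semantically "typical" each answer is, as the cosine similarity
#' between its embedding and the reference median embedding for the same
#' question. Missing answers get a missing score; a zero-norm answer vector
#' yields a missing score with a warning. Scores are invariant to positive
#' rescaling of either vector.
#'
#' @param embeddings Wide embedding table (see [build_reference()]).
#' @param reference Reference set from [build_reference()].
#' @return Tibble `participant_id`, `question_id`, `similarity` in `[-1, 1]`
#'   or `NA`.
#' @export
typicality <- function(embeddings, reference) {
  vcols <- embedding_cols(embeddings)
  stopifnot(all(vcols %in% names(reference)))
  unknown <- setdiff(unique(embeddings$question_id), reference$question_id)
  if (length(unknown) > 0) {
    abort(paste0("no reference embedding for question(s): ",
                 paste(unknown, collapse = ", ")))
  }
  A <- as.matrix(embeddings[vcols])
  R <- as.matrix(reference[vcols])[
    match(embeddings$question_id, reference$question_id), , drop = FALSE]
  rnorm2 <- sqrt(rowSums(R^2))
  if (any(rnorm2 == 0)) abort("reference embedding with zero norm")
  anorm <- sqrt(rowSums(A^2))
  sim <- rowSums(A * R) / (anorm * rnorm2)
  sim[embeddings$missing == 1] <- NA_real_
  zero <- embeddings$missing == 0 & !is.na(anorm) & anorm == 0
  if (any(zero)) {
    warn("zero-norm answer vector(s); typicality set to missing")
    sim[zero] <- NA_real_
  }
  tibble::tibble(
    participant_id = embeddings$participant_id,
    question_id = embeddings$question_id,
    similarity = sim
  )
}

#' Fisher-Z transform of similarity scores
#'
#' The inverse hyperbolic tangent (artanh), applied to cosine similarities
#' prior to regression to approximate normality. Inputs are clipped to
#' `[-1 + eps, 1 - eps]` so that scores of exactly +/-1 map to large finite
#' values (bounding leverage in downstream regression) rather than infinity.
#'
#' @param s Numeric vector of similarities in `[-1, 1]` (NA passed through).
#' @param eps Clipping margin, default `1e-7` (caps `|z|` at about 8.4).
#' @return `artanh(clip(s))`, same length as `s`.
#' @examples
#' fisher_z(0.5) # 0.5 * log(3) = 0.549306
#' @export
fisher_z <- function(s, eps = 1e-7) {
  out_of_range <- !is.na(s) & abs(s) > 1 + 1e-9
  if (any(out_of_range)) {
    abort(paste0("similarity outside [-1, 1]: ",
                 paste(format(s[out_of_range]), collapse = ", ")))
  }
  atanh(pmin(pmax(s, -1 + eps), 1 - eps))
}

#' Default question-to-domain map
#'
#' Groups the 23 interview questions into conceptually meaningful domains.
#' Only the self-emotion domain's membership (questions 14, 17, 20, 23) is
#' attested; the remaining assignments are a plausible placeholder partition
#' and should be overridden with the study-specific map when available.
#'
#' @return Named list of integer question-id vectors.
#' @export
default_domains <- function() {
  list(
    narrative_detail       = 1:5,
    factual_memory         = 6:9,
    thematic_understanding = 10:13,
    self_emotion           = c(14L, 17L, 20L, 23L),
    character_emotion      = c(15L, 16L, 18L),
    preferences_positive   = c(19L, 21L),
    preferences_negative   = 22L
  )
}

#' Domain-level semantic typicality scores
#'
#' Averages per-question typicality scores into domains (mean of the
#' available, non-missing questions; a domain with all questions missing is
#' missing), then applies the Fisher-Z transform to the domain mean for use
#' as a regression outcome.
#'
#' @param similarities Long score table from [typicality()].
#' @param domains Named list mapping domain names to question ids, as
#'   [default_domains()].
#' @return Tibble `participant_id`, `domain`, `score` (mean similarity),
#'   `z` (Fisher-Z of the mean).
#' @export
domain_score <- function(similarities, domains = default_domains()) {
  qs <- unlist(domains, use.names = FALSE)
  bad <- qs[qs < 1 | qs > 23 | qs != as.integer(qs)]
  if (length(bad) > 0) {
    abort(paste0("domain map references unknown question(s): ",
                 paste(unique(bad), collapse = ", ")))
  }
  map <- tibble::tibble(
    domain = rep(names(domains), lengths(domains)),
    question_id = as.integer(qs)
  )
  similarities |>
    dplyr::inner_join(map, by = "question_id", relationship = "many-to-many") |>
    dplyr::group_by(.data$participant_id, .data$domain) |>
    dplyr::summarise(
      score = if (all(is.na(.data$similarity))) NA_real_ else
        mean(.data$similarity, na.rm = TRUE),
      .groups = "drop"
    ) |>
    dplyr::mutate(z = fisher_z(.data$score))
}

#' Select the most typical answer for a question
#'
#' Returns the participant whose (non-missing) answer is semantically closest
#' to the reference median embedding, i.e. the argmax of cosine similarity.
#' Ties are broken deterministically by the smallest participant id.
#'
#' @param embeddings Wide embedding table.
#' @param reference Reference set from [build_reference()].
#' @param question Question id to search.
#' @return A one-row tibble `participant_id`, `question_id`, `similarity`.
#' @export
select_typical_answer <- function(embeddings, reference, question) {
  cand <- dplyr::filter(embeddings, .data$question_id == question,
                        .data$missing == 0)
  if (nrow(cand) == 0) {
    abort(paste0("no answers available for question ", question))
  }
  scores <- typicality(cand, reference) |>
    dplyr::filter(!is.na(.data$similarity)) |>
    dplyr::arrange(dplyr::desc(.data$similarity), .data$participant_id)
  if (nrow(scores) == 0) {
    abort(paste0("no scorable answers for question ", question))
  }
  scores[1, ]
}
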