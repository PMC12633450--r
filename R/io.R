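#' Read a participant table from CSV
#'
#' Expects columns `participant_id`, `age`, `sex`, `iq_full`, `iq_verbal`,
#' `presentation`, `asd`, plus optional clinical scale columns; missing
#' values as empty cells. Diagnostic status flags are derived from the
#' presentation label on read.
#'
#' @param path CSV path.
#' @return Participant tibble with `adhd_inatt`, `adhd_hyper`, `excluded`
#'   added.
#' @export
read_participants <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("participant_id", "age", "sex", "presentation", "asd")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("participants file '", path, "' lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  add_diagnosis_status(df)
}

#' Read a long-format landmark table from CSV
#'
#' Expects columns `participant_id`, `frame`, `landmark_id`,
#' `landmark_class`, `region`, `x`, `y`, `z`, `present`.
#'
#' @param path CSV path.
#' @return Long landmark tibble.
#' @export
read_landmarks <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  check_landmark_cols(df, c("participant_id", "frame", "landmark_id",
                            "landmark_class", "region", "x", "y", "z",
                            "present"))
  df
}

#' Read an answer-embedding table from CSV
#'
#' Expects columns `participant_id`, `question_id`, `missing`, and the
#' embedding dimensions `v0 ... v{D-1}`.
#'
#' @param path CSV path.
#' @return Wide embedding tibble.
#' @export
read_embeddings <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  required <- c("participant_id", "question_id", "missing")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols) > 0) {
    abort(paste0("embeddings file '", path, "' lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
  embedding_cols(df) # errors if no v* columns
  df
}
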