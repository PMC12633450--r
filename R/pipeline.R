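#' Assemble the participant-by-feature analysis table
#'
#' Joins the participant table with (any of) a precomputed behavioral feature
#' table, movement features computed from landmark series, and Fisher-Z
#' domain typicality scores computed from answer embeddings (building the TD
#' reference from the participants inside the reference age band).
#'
#' @param participants Participant table with status flags and a `td`
#'   indicator.
#' @param features Optional wide feature table keyed by `participant_id`.
#' @param landmarks Optional long landmark table (see [movement_features()]).
#' @param embeddings Optional wide embedding table (see [typicality()]).
#' @param qc,fps,template,shoulders Movement-chain settings.
#' @param domains Question-to-domain map for semantic scores.
#' @param reference_age_band TD reference age band.
#' @return The participant tibble with one added column per feature;
#'   semantic domain outcomes are named `semantic_<domain>_z`.
#' @export
assemble_features <- function(participants, features = NULL,
                              landmarks = NULL, embeddings = NULL,
                              qc = qc_config(), fps = 30,
                              template = canonical_face_template(),
                              shoulders = c("left_shoulder", "right_shoulder"),
                              domains = default_domains(),
                              reference_age_band = c(14, 22)) {
  out <- tibble::as_tibble(participants)
  if (!is.null(features)) {
    out <- dplyr::left_join(out, features, by = "participant_id")
  }
  if (!is.null(landmarks)) {
    mv <- movement_features(landmarks, qc = qc, fps = fps,
                            template = template, shoulders = shoulders)
    out <- dplyr::left_join(out, mv, by = "participant_id")
  }
  if (!is.null(embeddings)) {
    ref <- build_reference(embeddings, participants,
                           age_band = reference_age_band)
    dom <- typicality(embeddings, ref) |>
      domain_score(domains) |>
      dplyr::select("participant_id", "domain", "z") |>
      tidyr::pivot_wider(names_from = "domain", values_from = "z",
                         names_glue = "semantic_{domain}_z")
    out <- dplyr::left_join(out, dom, by = "participant_id")
  }
  out
}

#' Run the end-to-end phenotyping analysis
#'
#' Assembles the analysis table, fits the multivariate robust model for every
#' outcome of every analysis block, applies the Bonferroni correction within
#' each block (family size = number of models in the block unless
#' overridden), and collects per-block effect-size matrices. Cells that do
#' not reach the corrected significance cut-off are flagged, never dropped,
#' mirroring the masking convention of effect-size heatmaps. A model that
#' fails (e.g. underdetermined after listwise deletion) is recorded in the
#' report and the run continues.
#'
#' @inheritParams assemble_features
#' @param blocks Named list of outcome-column vectors, one element per
#'   analysis block (e.g. language, semantic, prosody, movement). Outcomes
#'   must exist in the assembled table.
#' @param family_sizes Optional named list/vector overriding the Bonferroni
#'   family size per block.
#' @param alpha Significance cut-off on adjusted p-values (default 0.01).
#' @param predictors Model predictors, default [eq1_predictors()].
#' @return A `pheno_run` object: list with `effects` (long tibble of every
#'   (outcome, predictor) fit result incl. `p_adj`, `significant`),
#'   `matrices` (per block, wide outcome x predictor effect-size tibble),
#'   `significance` (matching logical masks), and `report`.
#' @export
run_pipeline <- function(participants, features = NULL, landmarks = NULL,
                         embeddings = NULL, blocks, family_sizes = NULL,
                         alpha = 0.01, predictors = eq1_predictors(),
                         qc = qc_config(), fps = 30,
                         template = canonical_face_template(),
                         shoulders = c("left_shoulder", "right_shoulder"),
                         domains = default_domains(),
                         reference_age_band = c(14, 22)) {
  stopifnot(is.list(blocks), length(blocks) > 0, !is.null(names(blocks)))
  tab <- assemble_features(
    participants, features = features, landmarks = landmarks,
    embeddings = embeddings, qc = qc, fps = fps, template = template,
    shoulders = shoulders, domains = domains,
    reference_age_band = reference_age_band
  )
  missing_outcomes <- setdiff(unlist(blocks), names(tab))
  if (length(missing_outcomes) > 0) {
    abort(paste0("block outcome(s) not in assembled table: ",
                 paste(missing_outcomes, collapse = ", ")))
  }

  errors <- list()
  effects <- purrr::imap_dfr(blocks, function(outcomes, block) {
    m <- if (!is.null(family_sizes) && block %in% names(family_sizes)) {
      as.numeric(family_sizes[[block]])
    } else {
      length(outcomes)
    }
    block_effects <- purrr::map_dfr(outcomes, function(oc) {
      fit <- tryCatch(
        fit_phenotype_model(tab, oc, predictors = predictors),
        error = function(e) {
          errors[[paste(block, oc, sep = "/")]] <<- conditionMessage(e)
          NULL
        }
      )
      if (is.null(fit)) return(tibble::tibble())
      tidy(fit) |>
        dplyr::filter(.data$term != "(Intercept)") |>
        dplyr::mutate(outcome = oc, n_used = fit$n_used,
                      converged = fit$converged, .before = 1)
    })
    if (nrow(block_effects) == 0) return(block_effects)
    # correction is across the block's m models, applied per predictor
    block_effects |>
      dplyr::mutate(block = block, family_size = m) |>
      dplyr::group_by(.data$term) |>
      dplyr::mutate(
        p_adj = bonferroni_flag(.data$p_value, m, alpha)$p_adj,
        significant = bonferroni_flag(.data$p_value, m, alpha)$significant
      ) |>
      dplyr::ungroup()
  })

  matrices <- list(); significance <- list()
  for (block in unique(effects$block)) {
    be <- dplyr::filter(effects, .data$block == !!block)
    matrices[[block]] <- be |>
      dplyr::select("outcome", "term", "effect_size") |>
      tidyr::pivot_wider(names_from = "term", values_from = "effect_size")
    significance[[block]] <- be |>
      dplyr::select("outcome", "term", "significant") |>
      tidyr::pivot_wider(names_from = "term", values_from = "significant")
  }

  structure(
    list(
      effects = effects, matrices = matrices, significance = significance,
      report = list(
        alpha = alpha,
        blocks = blocks,
        family_sizes = purrr::imap(blocks, function(o, b) {
          if (!is.null(family_sizes) && b %in% names(family_sizes))
            as.numeric(family_sizes[[b]]) else length(o)
        }),
        n_used = setNames(
          as.list(effects$n_used[!duplicated(effects$outcome)]),
          effects$outcome[!duplicated(effects$outcome)]
        ),
        converged = setNames(
          as.list(effects$converged[!duplicated(effects$outcome)]),
          effects$outcome[!duplicated(effects$outcome)]
        ),
        model_errors = errors,
        predictors = predictors,
        package_version = as.character(utils::packageVersion("phenokit"))
      )
    ),
    class = "pheno_run"
  )
}

#' @export
print.pheno_run <- function(x, ...) {
  cat("<pheno_run> ", length(x$report$blocks), " block(s), ",
      nrow(x$effects), " (outcome, predictor) effects, alpha=",
      x$report$alpha, "\n", sep = "")
  for (b in names(x$matrices)) {
    cat("\nBlock '", b, "' effect sizes:\n", sep = "")
    print(x$matrices[[b]])
  }
  invisible(x)
}

#' Tidy the effects of a pipeline run
#'
#' @param x A `pheno_run`.
#' @param ... Unused.
#' @return The long effects tibble (one row per outcome and predictor).
#' @exportS3Method generics::tidy
tidy.pheno_run <- function(x, ...) x$effects

#' One-row-per-model summary of a pipeline run
#'
#' @param x A `pheno_run`.
#' @param ... Unused.
#' @return Tibble `block`, `outcome`, `n_used`, `converged`, `family_size`.
#' @exportS3Method generics::glance
glance.pheno_run <- function(x, ...) {
  x$effects |>
    dplyr::distinct(.data$block, .data$outcome, .data$n_used,
                    .data$converged, .data$family_size)
}

#' Write pipeline outputs to disk
#'
#' Exports the canonical CSV/JSON artifacts of a run: the long effects table,
#' one effect-size matrix CSV per block (with the matching significance
#' mask columns), and a JSON run report.
#'
#' @param run A `pheno_run`.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_run <- function(run, dir) {
  stopifnot(inherits(run, "pheno_run"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- file.path(dir, "effects.csv")
  readr::write_csv(run$effects, paths)
  for (block in names(run$matrices)) {
    sig <- run$significance[[block]]
    names(sig)[-1] <- paste0("significant_", names(sig)[-1])
    p <- file.path(dir, paste0("effects_matrix_", block, ".csv"))
    readr::write_csv(
      dplyr::left_join(run$matrices[[block]], sig, by = "outcome"), p
    )
    paths <- c(paths, p)
  }
  rp <- file.path(dir, "report.json")
  jsonlite::write_json(run$report, rp, auto_unbox = TRUE, pretty = TRUE,
                       force = TRUE)
  invisible(c(paths, rp))
}
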