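#' Simulation configuration for synthetic cohorts
#'
#' Defaults reproduce the study conditions of a large community
#' developmental cohort: 2,341 participants aged 5-22 (truncated normal,
#' mean 10.1, SD 3.39), about one third female, ADHD-Hyperactive prevalence
#' decreasing with age (OR 0.83 per year), Inattentive status drawn
#' conditionally on Hyperactive so the Combined overlap matches the observed
#' presentation counts, and ASD generated through a logistic link on the two
#' ADHD status flags with odds ratios 2.3 (Inattentive) and 1.6
#' (Hyperactive); the ASD and Hyperactive intercepts are calibrated so the
#' configured marginal prevalences hold exactly in the generative model.
#'
#' @param age_mean,age_sd,age_range Truncated-normal age distribution (years).
#' @param female_frac Probability of `sex = 1` (female).
#' @param p_hyper Marginal prevalence of ADHD-Hyperactive status.
#' @param or_age_hyper Odds ratio on Hyperactive status per year of age.
#' @param p_inatt_given_hyper,p_inatt_given_nothyper Conditional prevalence
#'   of Inattentive status given Hyperactive status (encodes the Combined
#'   overlap).
#' @param p_asd Marginal ASD prevalence.
#' @param or_inatt_asd,or_hyper_asd Comorbidity odds ratios of each ADHD
#'   status on ASD.
#' @param p_other_given_none Probability that a participant with neither
#'   status flag carries an ADHD other/unspecified label (excluded from
#'   analysis).
#' @param p_td_given_eligible Probability that a participant negative on
#'   every diagnosis is confirmed typically developing (the remainder carry
#'   other clinical diagnoses).
#' @param iq_mean,iq_sd,iq_shift_asd,iq_shift_td,iq_missing_rate Full-scale
#'   IQ distribution, group shifts, and per-field missingness.
#' @param scale_missing_rate Missingness rate for clinical scale scores.
#' @param interview_minutes_mean,interview_minutes_sd Interview length.
#' @return A list of class `"sim_config"`.
#' @export
sim_config <- function(age_mean = 10.1, age_sd = 3.39, age_range = c(5, 22),
                       female_frac = 785 / 2341,
                       p_hyper = 718 / 2341, or_age_hyper = 0.83,
                       p_inatt_given_hyper = 625 / 718,
                       p_inatt_given_nothyper = 653 / 1623,
                       p_asd = 349 / 2341,
                       or_inatt_asd = 2.3, or_hyper_asd = 1.6,
                       p_other_given_none = 84 / 970,
                       p_td_given_eligible = 168 / 815,
                       iq_mean = 99.4, iq_sd = 16.6,
                       iq_shift_asd = -2.7, iq_shift_td = 7.1,
                       iq_missing_rate = 1 - 2186 / 2341,
                       scale_missing_rate = 0.06,
                       interview_minutes_mean = 4.5,
                       interview_minutes_sd = 1.54) {
  cfg <- list(
    age_mean = age_mean, age_sd = age_sd, age_range = age_range,
    female_frac = female_frac,
    p_hyper = p_hyper, or_age_hyper = or_age_hyper,
    p_inatt_given_hyper = p_inatt_given_hyper,
    p_inatt_given_nothyper = p_inatt_given_nothyper,
    p_asd = p_asd, or_inatt_asd = or_inatt_asd, or_hyper_asd = or_hyper_asd,
    p_other_given_none = p_other_given_none,
    p_td_given_eligible = p_td_given_eligible,
    iq_mean = iq_mean, iq_sd = iq_sd, iq_shift_asd = iq_shift_asd,
    iq_shift_td = iq_shift_td, iq_missing_rate = iq_missing_rate,
    scale_missing_rate = scale_missing_rate,
    interview_minutes_mean = interview_minutes_mean,
    interview_minutes_sd = interview_minutes_sd
  )
  probs <- unlist(cfg[c("female_frac", "p_hyper", "p_inatt_given_hyper",
                        "p_inatt_given_nothyper", "p_asd",
                        "p_other_given_none", "p_td_given_eligible",
                        "iq_missing_rate", "scale_missing_rate")])
  if (any(probs < 0 | probs > 1)) {
    abort("impossible configuration: probabilities must lie in [0, 1]")
  }
  stopifnot(age_sd > 0, iq_sd > 0, or_age_hyper > 0,
            or_inatt_asd > 0, or_hyper_asd > 0)
  structure(cfg, class = "sim_config")
}

rtruncnorm <- function(n, mean, sd, lower, upper) {
  lo <- pnorm(lower, mean, sd)
  hi <- pnorm(upper, mean, sd)
  qnorm(runif(n, lo, hi), mean, sd)
}

# Solve for the logistic intercept making mean(plogis(b0 + offset)) == target.
calibrate_intercept <- function(offset, target) {
  f <- function(b0) mean(plogis(b0 + offset)) - target
  sol <- tryCatch(uniroot(f, c(-30, 30))$root, error = function(e) NULL)
  if (is.null(sol)) {
    abort("impossible prevalence/odds-ratio combination: no admissible intercept")
  }
  sol
}

#' Simulate a diagnostically comorbid developmental cohort
#'
#' Draws ages, sex, diagnostic status flags with the configured comorbidity
#' log-odds structure, presentation labels (Combined when both flags are
#' positive; a fraction of no-status participants labeled other/unspecified
#' and marked excluded), a typically-developing indicator, IQ, clinical scale
#' scores, and interview lengths. Fully deterministic given `(config, seed)`.
#'
#' @param n Number of participants (default 2341).
#' @param config A [sim_config()].
#' @param seed Integer seed.
#' @return Participant tibble; the generative parameters (calibrated
#'   intercepts, config, seed) are stored in `attr(, "groundtruth")`.
#' @export
simulate_cohort <- function(n = 2341, config = sim_config(), seed = 1) {
  stopifnot(inherits(config, "sim_config"), n >= 1)
  set.seed(seed)
  age <- rtruncnorm(n, config$age_mean, config$age_sd,
                    config$age_range[1], config$age_range[2])
  sex <- rbinom(n, 1, config$female_frac)

  if (config$p_hyper > 0) {
    hyper_offset <- log(config$or_age_hyper) * (age - config$age_mean)
    b0_hyper <- calibrate_intercept(hyper_offset, config$p_hyper)
    adhd_hyper <- rbinom(n, 1, plogis(b0_hyper + hyper_offset))
  } else {
    b0_hyper <- -Inf
    adhd_hyper <- rep(0L, n)
  }
  p_inatt <- ifelse(adhd_hyper == 1, config$p_inatt_given_hyper,
                    config$p_inatt_given_nothyper)
  adhd_inatt <- rbinom(n, 1, p_inatt)

  if (config$p_asd > 0) {
    asd_offset <- log(config$or_inatt_asd) * adhd_inatt +
      log(config$or_hyper_asd) * adhd_hyper
    b0_asd <- calibrate_intercept(asd_offset, config$p_asd)
    asd <- rbinom(n, 1, plogis(b0_asd + asd_offset))
  } else {
    b0_asd <- -Inf
    asd <- rep(0L, n)
  }

  presentation <- dplyr::case_when(
    adhd_inatt == 1 & adhd_hyper == 1 ~ "Combined",
    adhd_inatt == 1 ~ "Inattentive",
    adhd_hyper == 1 ~ "Hyperactive",
    TRUE ~ "None"
  )
  none <- presentation == "None"
  other <- none & rbinom(n, 1, config$p_other_given_none) == 1
  presentation[other] <- "OtherUnspecified"
  status <- code_diagnosis_status(presentation)

  eligible <- asd == 0 & status$adhd_inatt == 0 & status$adhd_hyper == 0 &
    status$excluded == 0
  td <- integer(n)
  td[eligible] <- rbinom(sum(eligible), 1, config$p_td_given_eligible)

  iq_full <- rnorm(n, config$iq_mean + config$iq_shift_asd * asd +
                     config$iq_shift_td * td, config$iq_sd)
  iq_verbal <- iq_full + rnorm(n, 3.8, 6)
  iq_full[rbinom(n, 1, config$iq_missing_rate) == 1] <- NA
  iq_verbal[rbinom(n, 1, config$iq_missing_rate) == 1] <- NA

  inatt <- status$adhd_inatt; hyper <- status$adhd_hyper
  any_dx <- pmax(inatt, hyper, asd)
  scales <- tibble::tibble(
    swan_inatt = -0.3 + 1.5 * inatt + 0.2 * asd + rnorm(n, 0, 0.9),
    swan_hyper = -0.2 + 1.5 * hyper + 0.3 * inatt -
      0.09 * (age - config$age_mean) + rnorm(n, 0, 0.9),
    assq = pmax(0, 2.5 + 3 * inatt + 2 * hyper + 11 * asd + rnorm(n, 0, 6)),
    mfq = pmax(0, 4.7 + 4.5 * any_dx + rnorm(n, 0, 6)),
    scared = pmax(0, 9.4 + 5 * any_dx + rnorm(n, 0, 9)),
    cbcl_ext = pmax(0, 6 + 4 * inatt + 4 * hyper + 2 * asd + rnorm(n, 0, 7)),
    cbcl_int = pmax(0, 5.3 + 4 * inatt + 2 * hyper + 3 * asd + rnorm(n, 0, 6))
  )
  for (col in names(scales)) {
    scales[[col]][rbinom(n, 1, config$scale_missing_rate) == 1] <- NA
  }

  out <- tibble::tibble(
    participant_id = sprintf("P%05d", seq_len(n)),
    age = age, sex = sex,
    iq_full = iq_full, iq_verbal = iq_verbal,
    presentation = presentation,
    adhd_inatt = status$adhd_inatt,
    adhd_hyper = status$adhd_hyper,
    excluded = status$excluded,
    asd = as.integer(asd), td = td
  )
  out <- dplyr::bind_cols(out, scales)
  out$interview_minutes <- pmax(
    1, rnorm(n, config$interview_minutes_mean, config$interview_minutes_sd)
  )
  attr(out, "groundtruth") <- list(
    seed = seed, config = config, b0_hyper = b0_hyper, b0_asd = b0_asd
  )
  out
}

#' Simulate behavioral features with known effect-size structure
#'
#' Generates one column per feature as a linear combination of the
#' standardized model predictors plus Gaussian noise:
#' `y = sum_k b_k x_k(std) + e`, `e ~ N(0, noise_sd)`. With `noise_sd = 1`
#' and nearly orthogonal predictors, the generative coefficient `b_k` is (up
#' to the usual partial-correlation attenuation) the effect size
#' `t / sqrt(dfe)` the model-fitting stage recovers, making the table a
#' round-trip oracle for effect-size recovery.
#'
#' @param records Participant table (from [simulate_cohort()] or real data).
#' @param effects Named list: one element per feature, each a named numeric
#'   vector of standardized coefficients over (a subset of)
#'   [eq1_predictors()].
#' @param noise_sd Residual standard deviation (scalar or per-feature).
#' @param seed Integer seed.
#' @return Tibble `participant_id` plus one numeric column per feature; rows
#'   whose predictors are missing get missing features (exercising listwise
#'   deletion downstream). Ground truth (coefficients, standardization
#'   constants) in `attr(, "groundtruth")`.
#' @export
simulate_feature_table <- function(records, effects, noise_sd = 1, seed = 1) {
  stopifnot(is.list(effects), length(effects) > 0, !is.null(names(effects)))
  set.seed(seed)
  n <- nrow(records)
  noise_sd <- rep_len(noise_sd, length(effects))
  std <- list()
  out <- tibble::tibble(participant_id = records$participant_id)
  for (i in seq_along(effects)) {
    feat <- names(effects)[i]
    b <- effects[[i]]
    unknown <- setdiff(names(b), names(records))
    if (length(unknown) > 0) {
      abort(paste0("unknown predictor(s) in effects for '", feat, "': ",
                   paste(unknown, collapse = ", ")))
    }
    y <- rep(0, n)
    for (pred in names(b)) {
      x <- as.numeric(records[[pred]])
      mu <- mean(x, na.rm = TRUE)
      sdx <- sd(x, na.rm = TRUE)
      if (is.na(sdx) || sdx == 0) sdx <- 1
      std[[feat]][[pred]] <- c(mean = mu, sd = sdx)
      y <- y + b[[pred]] * (x - mu) / sdx
    }
    out[[feat]] <- y + rnorm(n, 0, noise_sd[i])
  }
  attr(out, "groundtruth") <- list(
    seed = seed, effects = effects, noise_sd = noise_sd,
    standardization = std
  )
  out
}

#' Configuration for synthetic landmark series
#'
#' Parameters of the generative motion model: each landmark follows a
#' mean-reverting (AR-1) trajectory around its rest position, with per-frame
#' innovation SD `step * exp(age_slope (age - age_ref) + hyper_step hyper +
#' u)`, `u` a per-participant lognormal variability term - so log mean
#' displacement is, by construction, linear in age and hyperactive status.
#' Missing runs and high-variance jitter bursts are injected at configured
#' rates with their locations recorded as ground truth. Defaults reflect the
#' study's recording conditions (30 fps, 4.5-minute interviews,
#' image-normalized coordinates).
#'
#' @param fps Frames per second.
#' @param duration_seconds Series length in seconds.
#' @param face_step,pose_step Baseline innovation SD per frame and coordinate
#'   (normalized units), per landmark class.
#' @param age_slope Log-linear age effect on the innovation SD (per year).
#' @param hyper_step Log increment for ADHD-Hyperactive status.
#' @param age_ref Centering age for the slope.
#' @param participant_sd SD of the per-participant log variability term.
#' @param ar_phi AR(1) mean-reversion coefficient.
#' @param head_motion_step Innovation SD of the global head-pose translation
#'   shared by all face landmarks (removed by affine alignment).
#' @param missing_runs_per_minute,missing_run_frames Rate and mean length of
#'   injected missing runs per landmark.
#' @param jitter_bursts_per_minute,jitter_sd,jitter_burst_frames Rate,
#'   x-noise SD, and length of injected jitter bursts per landmark.
#' @param n_face_landmarks Number of template face landmarks to simulate
#'   (first rows of [canonical_face_template()]; at least 4).
#' @return A list of class `"landmark_config"`.
#' @export
landmark_config <- function(fps = 30, duration_seconds = 270,
                            face_step = 0.004, pose_step = 0.0015,
                            age_slope = -0.03, hyper_step = 0.12,
                            age_ref = 10, participant_sd = 0.3,
                            ar_phi = 0.98, head_motion_step = 0.002,
                            missing_runs_per_minute = 1,
                            missing_run_frames = 45,
                            jitter_bursts_per_minute = 0.5,
                            jitter_sd = 0.5, jitter_burst_frames = 10,
                            n_face_landmarks = 13) {
  stopifnot(fps > 0, duration_seconds > 0, face_step >= 0, pose_step >= 0,
            ar_phi >= 0, ar_phi < 1, n_face_landmarks >= 4,
            n_face_landmarks <= nrow(canonical_face_template()))
  structure(as.list(environment()), class = "landmark_config")
}

# AR(1) deviations: nf frames x k series, innovation sd per series recycled.
ou_deviations <- function(nf, k, step_sd, phi) {
  z <- matrix(rnorm(nf * k), nf, k) * rep(step_sd, each = nf)
  matrix(as.numeric(stats::filter(z, phi, method = "recursive")), nf, k)
}

sample_artifact_frames <- function(nf, rate_per_minute, mean_len, fps) {
  n_runs <- rpois(1, rate_per_minute * nf / (fps * 60))
  if (n_runs == 0) return(integer(0))
  starts <- sample.int(nf, n_runs, replace = TRUE)
  lens <- pmax(1, rpois(n_runs, mean_len))
  unique(unlist(purrr::map2(starts, lens, ~ seq.int(.x, min(.x + .y - 1, nf)))))
}

#' Simulate landmark time-series for a cohort
#'
#' Generates face and pose landmark trajectories per participant under the
#' motion model of [landmark_config()]: face landmarks move around the
#' canonical template positions and additionally share a global head-pose
#' translation; pose landmarks (shoulders, wrists) move around fixed rest
#' positions. Injected missing runs (`present = 0`) and jitter bursts
#' (x-noise added) are recorded per participant and landmark in
#' `attr(, "groundtruth")`.
#'
#' @param records Participant table with `participant_id`, `age`,
#'   `adhd_hyper`.
#' @param config A [landmark_config()].
#' @param seed Integer seed.
#' @return Long landmark tibble: `participant_id`, `frame`, `landmark_id`,
#'   `landmark_class`, `region`, `x`, `y`, `z`, `present`.
#' @export
simulate_landmarks <- function(records, config = landmark_config(), seed = 1) {
  stopifnot(inherits(config, "landmark_config"))
  set.seed(seed)
  nf <- as.integer(round(config$fps * config$duration_seconds))
  tpl <- canonical_face_template()[seq_len(config$n_face_landmarks), ]
  pose <- tibble::tribble(
    ~landmark_id,     ~region, ~x,   ~y,   ~z,
    "left_shoulder",  "body",  0.35, 0.50, 0,
    "right_shoulder", "body",  0.65, 0.50, 0,
    "left_wrist",     "body",  0.30, 0.75, 0,
    "right_wrist",    "body",  0.70, 0.75, 0
  )
  lmk <- dplyr::bind_rows(
    dplyr::mutate(tpl, landmark_class = "face"),
    dplyr::mutate(pose, landmark_class = "pose")
  )
  nl <- nrow(lmk)
  rest <- as.matrix(lmk[, c("x", "y", "z")])
  artifacts <- list()

  per_participant <- purrr::pmap(
    list(records$participant_id, records$age, records$adhd_hyper),
    function(pid, age, hyper) {
      u <- rnorm(1, 0, config$participant_sd)
      scale_fac <- exp(config$age_slope * (age - config$age_ref) +
                         config$hyper_step * hyper + u)
      step <- ifelse(lmk$landmark_class == "face",
                     config$face_step, config$pose_step) * scale_fac
      dev <- ou_deviations(nf, nl * 3, rep(step, 3), config$ar_phi)
      coords <- dev + rep(rest, each = nf)
      dim(coords) <- c(nf, nl, 3)
      head_dev <- ou_deviations(nf, 3, config$head_motion_step, config$ar_phi)
      face_idx <- which(lmk$landmark_class == "face")
      for (d in 1:3) {
        coords[, face_idx, d] <- coords[, face_idx, d] + head_dev[, d]
      }
      present <- matrix(1L, nf, nl)
      miss <- vector("list", nl)
      jit <- vector("list", nl)
      for (j in seq_len(nl)) {
        mf <- sample_artifact_frames(nf, config$missing_runs_per_minute,
                                     config$missing_run_frames, config$fps)
        present[mf, j] <- 0L
        miss[[j]] <- mf
        jf <- sample_artifact_frames(nf, config$jitter_bursts_per_minute,
                                     config$jitter_burst_frames, config$fps)
        if (length(jf) > 0) {
          coords[jf, j, 1] <- coords[jf, j, 1] +
            rnorm(length(jf), 0, config$jitter_sd)
        }
        jit[[j]] <- jf
      }
      artifacts[[pid]] <<- list(
        missing = setNames(miss, lmk$landmark_id),
        jitter = setNames(jit, lmk$landmark_id),
        step_scale = scale_fac
      )
      tibble::tibble(
        participant_id = pid,
        frame = rep(seq_len(nf), nl),
        landmark_id = rep(lmk$landmark_id, each = nf),
        landmark_class = rep(lmk$landmark_class, each = nf),
        region = rep(lmk$region, each = nf),
        x = as.vector(coords[, , 1]),
        y = as.vector(coords[, , 2]),
        z = as.vector(coords[, , 3]),
        present = as.integer(present)
      )
    }
  )
  out <- dplyr::bind_rows(per_participant)
  attr(out, "groundtruth") <- list(
    seed = seed, config = config, artifacts = artifacts
  )
  out
}

#' Configuration for synthetic answer embeddings
#'
#' Each question has a fixed prototype vector (the semantic location of the
#' typical answer); a participant's answer is the prototype plus isotropic
#' Gaussian noise whose scale decreases with age and, for narrative-type
#' questions, increases with ASD status - so semantic typicality (cosine
#' similarity to the TD median) falls with the noise scale by construction.
#'
#' @param dim Embedding dimension (default 768; at least 2).
#' @param n_questions Number of interview questions (default 23).
#' @param base_sigma Baseline noise scale.
#' @param age_slope Log-linear age effect on the noise scale (negative:
#'   older participants answer more typically).
#' @param age_ref Centering age.
#' @param asd_shift Log increment of the noise scale under ASD for narrative
#'   questions.
#' @param narrative_questions Question ids subject to the ASD shift.
#' @param missing_rate Probability an answer is missing.
#' @param prototype_sd Component SD of the prototype vectors.
#' @return A list of class `"embedding_config"`.
#' @export
embedding_config <- function(dim = 768, n_questions = 23, base_sigma = 0.5,
                             age_slope = -0.02, age_ref = 10,
                             asd_shift = 0.3, narrative_questions = 1:13,
                             missing_rate = 0.08, prototype_sd = 1) {
  if (dim < 2) abort("embedding dimension must be at least 2")
  stopifnot(n_questions >= 1, base_sigma >= 0, missing_rate >= 0,
            missing_rate <= 1, prototype_sd > 0)
  structure(as.list(environment()), class = "embedding_config")
}

#' Simulate answer embeddings for a cohort
#'
#' @param records Participant table with `participant_id`, `age`, `asd`.
#' @param config An [embedding_config()].
#' @param seed Integer seed.
#' @return Wide embedding tibble (`participant_id`, `question_id`, `missing`,
#'   `v0 ... v{D-1}`); prototypes and per-row noise scales in
#'   `attr(, "groundtruth")`.
#' @export
simulate_embeddings <- function(records, config = embedding_config(), seed = 1) {
  stopifnot(inherits(config, "embedding_config"))
  set.seed(seed)
  D <- config$dim
  nq <- config$n_questions
  prototypes <- matrix(rnorm(nq * D, 0, config$prototype_sd), nq, D)
  grid <- tidyr::expand_grid(
    participant_id = records$participant_id,
    question_id = seq_len(nq)
  ) |>
    dplyr::left_join(
      dplyr::select(records, "participant_id", "age", "asd"),
      by = "participant_id"
    )
  narrative <- grid$question_id %in% config$narrative_questions
  sigma <- config$base_sigma * exp(
    config$age_slope * (grid$age - config$age_ref) +
      config$asd_shift * grid$asd * narrative
  )
  nr <- nrow(grid)
  vec <- prototypes[grid$question_id, , drop = FALSE] +
    matrix(rnorm(nr * D), nr, D) * sigma
  missing <- rbinom(nr, 1, config$missing_rate)
  vec[missing == 1, ] <- NA_real_
  colnames(vec) <- paste0("v", seq_len(D) - 1)
  out <- dplyr::bind_cols(
    tibble::tibble(
      participant_id = grid$participant_id,
      question_id = grid$question_id,
      missing = missing
    ),
    tibble::as_tibble(vec)
  )
  attr(out, "groundtruth") <- list(
    seed = seed, config = config, prototypes = prototypes, sigma = sigma
  )
  out
}
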