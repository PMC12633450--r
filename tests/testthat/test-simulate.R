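test_that("simulation is fully deterministic under (config, seed)", {
  a <- simulate_cohort(n = 300, seed = 9)
  b <- simulate_cohort(n = 300, seed = 9)
  attr(a, "groundtruth") <- attr(b, "groundtruth") <- NULL
  expect_identical(a, b)
  expect_false(identical(a$age, simulate_cohort(n = 300, seed = 10)$age))
  la <- simulate_landmarks(a[1:2, ], landmark_config(duration_seconds = 2), 4)
  lb <- simulate_landmarks(a[1:2, ], landmark_config(duration_seconds = 2), 4)
  attr(la, "groundtruth") <- attr(lb, "groundtruth") <- NULL
  expect_identical(la, lb)
  ea <- simulate_embeddings(a[1:5, ], embedding_config(dim = 8), 4)
  eb <- simulate_embeddings(a[1:5, ], embedding_config(dim = 8), 4)
  attr(ea, "groundtruth") <- attr(eb, "groundtruth") <- NULL
  expect_identical(ea, eb)
})

test_that("zero prevalences produce zero positive diagnoses", {
  cfg <- sim_config(p_hyper = 0, p_inatt_given_hyper = 0,
                    p_inatt_given_nothyper = 0, p_asd = 0,
                    p_other_given_none = 0)
  co <- simulate_cohort(n = 200, config = cfg, seed = 2)
  expect_equal(sum(co$adhd_inatt + co$adhd_hyper + co$asd + co$excluded), 0)
  expect_true(all(co$presentation == "None"))
  expect_error(sim_config(p_asd = 1.4), "\\[0, 1\\]")
})

test_that("cohort marginals match the configured study conditions", {
  co <- simulate_cohort(n = 8000, seed = 3)
  expect_true(all(co$age >= 5 & co$age <= 22))
  expect_equal(mean(co$age), 10.1, tolerance = 0.05)
  expect_equal(mean(co$sex), 785 / 2341, tolerance = 0.1)
  expect_equal(mean(co$adhd_hyper), 718 / 2341, tolerance = 0.1)
  expect_equal(mean(co$adhd_inatt), 1278 / 2341, tolerance = 0.1)
  expect_equal(mean(co$asd), 349 / 2341, tolerance = 0.1)
  # age -> hyperactive: negative association by construction
  expect_lt(spearman_rho(co$age, co$adhd_hyper)$rho, 0)
})

test_that("configured comorbidity odds ratio is recovered by refitting", {
  co <- simulate_cohort(n = 8000, seed = 5)
  fit <- fit_phenotype_model(
    dplyr::filter(co, excluded == 0), "asd", family = "logistic",
    predictors = c("age", "iq_full", "sex", "adhd_inatt", "adhd_hyper")
  )
  or_inatt <- dplyr::filter(tidy(fit), term == "adhd_inatt")$odds_ratio
  expect_equal(or_inatt, 2.3, tolerance = 0.2)
})

test_that("feature table is the configured linear model plus noise", {
  co <- simulate_cohort(n = 400, seed = 7)
  # zero effects, zero noise: constant column
  f0 <- simulate_feature_table(co, list(flat = c(age = 0)), noise_sd = 0,
                               seed = 1)
  expect_true(all(f0$flat == 0))
  expect_error(
    simulate_feature_table(co, list(f = c(not_a_predictor = 1))),
    "unknown predictor"
  )
  # negative age effect implies negative rank correlation with age
  co2 <- simulate_cohort(n = 2000, seed = 8)
  fneg <- simulate_feature_table(co2, list(f = c(age = -0.4)), seed = 2)
  expect_lt(spearman_rho(co2$age, fneg$f)$rho, 0)
})

test_that("landmark generator exposes its ground truth to the QC masks", {
  co <- simulate_cohort(n = 2, seed = 13)
  # no motion, no artifacts: all displacement zero -> log missing
  still <- simulate_landmarks(
    co, landmark_config(duration_seconds = 2, face_step = 0, pose_step = 0,
                        head_motion_step = 0, participant_sd = 0,
                        missing_runs_per_minute = 0,
                        jitter_bursts_per_minute = 0), seed = 1
  )
  expect_warning(s <- region_displacement_summary(still), "zero mean")
  expect_true(all(s$mean_displacement == 0))
  expect_true(all(is.na(s$log_mean_displacement)))
  # injected jitter bursts are caught by the jitter mask at their locations
  jit <- simulate_landmarks(
    co, landmark_config(duration_seconds = 4, missing_runs_per_minute = 0,
                        jitter_bursts_per_minute = 8, jitter_sd = 0.5),
    seed = 3
  )
  gt <- attr(jit, "groundtruth")$artifacts
  m <- mask_jitter(jit) |>
    dplyr::arrange(participant_id, landmark_id, frame)
  hit <- FALSE
  for (pid in names(gt)) {
    for (lid in names(gt[[pid]]$jitter)) {
      frames <- gt[[pid]]$jitter[[lid]]
      if (length(frames) == 0) next
      hit <- TRUE
      sel <- m$participant_id == pid & m$landmark_id == lid & m$frame %in% frames
      expect_false(any(m$valid[sel]))
    }
  }
  expect_true(hit) # the fixture actually injected bursts
  # injected missing runs invalidate their frames under the missingness mask
  mis <- simulate_landmarks(
    co, landmark_config(duration_seconds = 4, missing_runs_per_minute = 10,
                        missing_run_frames = 30, jitter_bursts_per_minute = 0),
    seed = 4
  )
  gtm <- attr(mis, "groundtruth")$artifacts
  mm <- mask_missing_windows(mis) |>
    dplyr::arrange(participant_id, landmark_id, frame)
  run_hit <- FALSE
  for (pid in names(gtm)) {
    for (lid in names(gtm[[pid]]$missing)) {
      frames <- gtm[[pid]]$missing[[lid]]
      if (length(frames) < 20) next # long runs always violate the 10% rule
      run_hit <- TRUE
      sel <- mm$participant_id == pid & mm$landmark_id == lid &
        mm$frame %in% frames
      expect_false(any(mm$valid[sel]))
    }
  }
  expect_true(run_hit)
})

test_that("hyperactive status raises simulated movement as configured", {
  base <- simulate_cohort(n = 60, seed = 17)
  lo <- dplyr::mutate(base, adhd_hyper = 0)
  hi <- dplyr::mutate(base, adhd_hyper = 1)
  cfg <- landmark_config(duration_seconds = 4, hyper_step = 0.3,
                         participant_sd = 0,
                         missing_runs_per_minute = 0,
                         jitter_bursts_per_minute = 0)
  flo <- movement_features(simulate_landmarks(lo, cfg, seed = 18))
  fhi <- movement_features(simulate_landmarks(hi, cfg, seed = 18))
  expect_gt(mean(fhi$log_disp_body) - mean(flo$log_disp_body), 0.1)
  expect_gt(mean(fhi$log_disp_face) - mean(flo$log_disp_face), 0.1)
})

test_that("embedding generator links noise scale to typicality as configured", {
  co <- simulate_cohort(n = 300, seed = 19)
  pool <- dplyr::mutate(co, td = 1)
  # sigma = 0: every answer equals its prototype, typicality 1
  e0 <- simulate_embeddings(
    co[1:50, ], embedding_config(dim = 8, n_questions = 3, base_sigma = 0,
                                 missing_rate = 0), seed = 20
  )
  r0 <- build_reference(e0, pool, age_band = c(5, 22))
  expect_equal(typicality(e0, r0)$similarity, rep(1, nrow(e0)),
               tolerance = 1e-12)
  # ASD-shifted noise lowers mean typicality on narrative questions
  co$asd <- rep(c(0, 1), length.out = nrow(co))
  e1 <- simulate_embeddings(
    co, embedding_config(dim = 16, n_questions = 4, narrative_questions = 1:4,
                         asd_shift = 0.5, missing_rate = 0), seed = 21
  )
  r1 <- build_reference(e1, pool, age_band = c(5, 22))
  t1 <- typicality(e1, r1) |>
    dplyr::left_join(dplyr::select(co, participant_id, asd), by = "participant_id")
  expect_lt(mean(t1$similarity[t1$asd == 1]), mean(t1$similarity[t1$asd == 0]))
  # full missingness propagates to all scores
  e2 <- simulate_embeddings(
    co[1:20, ], embedding_config(dim = 8, n_questions = 2, missing_rate = 1),
    seed = 22
  )
  expect_true(all(e2$missing == 1))
  expect_true(all(is.na(typicality(e2, r0[r0$question_id %in% 1:2, ])$similarity)))
  expect_error(embedding_config(dim = 1), "at least 2")
})
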