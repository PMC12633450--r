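test_that("missingness mask matches the brute-force all-windows scan", {
  w <- 60; fmax <- 0.10
  # always present -> all valid
  s0 <- one_landmark_series(x = rep(0.5, 600))
  expect_true(all(mask_missing_windows(s0, fps = 30)$valid))
  # contiguous run of 31 missing in 600 frames: > 10% in covering windows
  pres <- rep(1, 600); pres[100:130] <- 0
  m <- mask_missing_windows(one_landmark_series(x = rep(0.5, 600), present = pres),
                            fps = 30)
  expect_equal(m$valid, oracle_mask_missing(pres, w, fmax))
  expect_false(any(m$valid[100:130]))
  expect_true(all(m$valid[300:600]))
  # boundary: exactly 6 missing per 60-frame window (6/60 = 10%, not > 10%)
  pres2 <- rep(1, 600); pres2[seq(10, 590, by = 10)] <- 0
  m2 <- mask_missing_windows(one_landmark_series(rep(0.5, 600), present = pres2),
                             fps = 30)
  expect_true(all(m2$valid[pres2 == 1]))
  expect_equal(m2$valid, oracle_mask_missing(pres2, w, fmax))
  # random patterns, series shorter than the window included
  set.seed(7)
  for (n in c(20, 59, 200)) {
    pres <- rbinom(n, 1, 0.9)
    got <- mask_missing_windows(one_landmark_series(runif(n), present = pres),
                                fps = 30)$valid
    expect_equal(got, oracle_mask_missing(pres, w, fmax))
  }
})

test_that("jitter mask applies class thresholds and matches brute force", {
  # constant x: zero variance, all valid
  expect_true(all(mask_jitter(one_landmark_series(rep(0.3, 50)))$valid))
  # face landmark alternating 0/0.3: sd ~ 0.158 > 0.1 -> invalid
  alt <- one_landmark_series(rep(c(0, 0.3), 25), landmark_class = "face")
  expect_false(any(mask_jitter(alt)$valid))
  # same series as pose: 0.158 > 0.01 too; but small pose noise passes
  set.seed(3)
  xp <- 0.5 + rnorm(200, 0, 0.002) # windowed sample sd well under 0.01
  calm <- one_landmark_series(xp, landmark_class = "pose", region = "body")
  got <- mask_jitter(calm)$valid
  expect_equal(got, oracle_mask_jitter(xp, rep(1, 200), 10, 0.01))
  # windows with < 2 present frames impose no exclusion
  pres <- rep(0, 40); pres[c(5, 25)] <- 1
  spiky <- one_landmark_series(c(rep(0, 4), 10, rep(0, 19), -10, rep(0, 14)),
                               present = pres)
  expect_true(all(mask_jitter(spiky)$valid))
  # random fuzz against the oracle, both classes
  set.seed(11)
  for (cls in c("face", "pose")) {
    x <- runif(150); pres <- rbinom(150, 1, 0.8)
    thr <- if (cls == "face") 0.1 else 0.01
    got <- mask_jitter(one_landmark_series(x, present = pres,
                                           landmark_class = cls))$valid
    expect_equal(got, oracle_mask_jitter(x, pres, 10, thr))
  }
})

test_that("combined validity is the elementwise AND and rejects misaligned masks", {
  s <- one_landmark_series(runif(30))
  m1 <- mask_missing_windows(s); m2 <- mask_jitter(s)
  set.seed(2)
  m1$valid <- rbinom(30, 1, 0.5) == 1
  m2$valid <- rbinom(30, 1, 0.5) == 1
  expect_equal(combine_validity(m1, m2)$valid, m1$valid & m2$valid)
  expect_error(combine_validity(m1, m2[-1, ]), "mismatch")
})

test_that("tightening QC thresholds never enlarges the valid set", {
  set.seed(5)
  x <- cumsum(rnorm(200, 0, 0.03))
  pres <- rbinom(200, 1, 0.85)
  s <- one_landmark_series(x, present = pres)
  loose <- combine_validity(
    mask_missing_windows(s, qc_config(missing_fraction_max = 0.2)),
    mask_jitter(s, qc_config(jitter_threshold_face = 0.2))
  )
  tight <- combine_validity(
    mask_missing_windows(s, qc_config(missing_fraction_max = 0.1)),
    mask_jitter(s, qc_config(jitter_threshold_face = 0.05))
  )
  expect_true(all(loose$valid[tight$valid]))
})

test_that("affine alignment recovers the canonical face exactly", {
  tpl <- dplyr::arrange(canonical_face_template(), landmark_id)
  tpl_xyz <- as.matrix(tpl[, c("x", "y", "z")])
  # identity: already canonical
  a <- align_face_affine(template_series()) |> dplyr::arrange(landmark_id)
  expect_equal(as.matrix(a[, c("x", "y", "z")]), tpl_xyz,
               ignore_attr = TRUE, tolerance = 1e-10)
  # rotation 30 degrees + translation + scale x1.7: affine family is closed
  th <- pi / 6
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  distort <- function(M) 1.7 * M %*% t(R) + rep(c(0.2, -0.1, 0.05), each = nrow(M))
  a2 <- align_face_affine(template_series(transform = distort)) |>
    dplyr::arrange(landmark_id)
  expect_lt(max(abs(as.matrix(a2[, c("x", "y", "z")]) - tpl_xyz)), 1e-8)
  # arbitrary invertible affine distortion
  set.seed(8)
  A <- diag(3) + matrix(rnorm(9, 0, 0.2), 3, 3)
  distort3 <- function(M) M %*% t(A) + rep(c(0.3, 0.1, -0.2), each = nrow(M))
  a3 <- align_face_affine(template_series(transform = distort3)) |>
    dplyr::arrange(landmark_id)
  expect_lt(max(abs(as.matrix(a3[, c("x", "y", "z")]) - tpl_xyz)), 1e-8)
})

test_that("degenerate face configurations are marked invalid, not crashed", {
  # only 3 present landmarks: cannot fit an affine map
  s <- template_series()
  s$present[4:nrow(s)] <- 0
  a <- align_face_affine(s)
  expect_true(all(a$present == 0))
  # 4+ present but coplanar AND collinear-degenerate: rank-deficient design
  s2 <- template_series()
  s2$x <- seq(0, 1, length.out = nrow(s2)); s2$y <- 2 * s2$x; s2$z <- 0
  a2 <- align_face_affine(s2)
  expect_true(all(a2$present == 0))
})

test_that("inter-shoulder normalization is exact and scale invariant", {
  mk <- function(k = 1) tibble::tibble(
    participant_id = "P1", frame = 1,
    landmark_id = c("left_shoulder", "right_shoulder", "pt"),
    landmark_class = "pose", region = "body",
    x = k * c(0, 2, 1), y = k * c(0, 0, 1), z = 0, present = 1
  )
  n1 <- normalize_body_scale(mk())
  expect_equal(n1$x[n1$landmark_id == "pt"], 0.5)
  expect_equal(n1$y[n1$landmark_id == "pt"], 0.5)
  expect_equal(n1$z[n1$landmark_id == "pt"], 0)
  # uniform frame scaling leaves normalized coordinates unchanged
  n2 <- normalize_body_scale(mk(k = 3.7))
  expect_equal(n1[, c("x", "y", "z")], n2[, c("x", "y", "z")], tolerance = 1e-12)
  # coincident shoulders: frame invalid
  bad <- mk(); bad$x[2] <- 0; bad$y[2] <- 0
  nb <- normalize_body_scale(bad)
  expect_true(all(nb$present == 0))
})

test_that("displacement summaries average time first, then landmarks", {
  # single landmark moving (v, 0, 0) per frame
  v <- 0.02
  s <- one_landmark_series(x = seq(0, by = v, length.out = 50))
  out <- region_displacement_summary(s)
  expect_equal(out$mean_displacement, v, tolerance = 1e-12)
  expect_equal(out$log_mean_displacement, log(v), tolerance = 1e-12)
  expect_equal(out$n_valid_frame_pairs, 49L)
  # two-landmark region with per-landmark means a and b -> (a + b) / 2
  a <- 0.01; b <- 0.05
  s2 <- dplyr::bind_rows(
    one_landmark_series(seq(0, by = a, length.out = 50), landmark_id = "l1"),
    one_landmark_series(seq(0, by = b, length.out = 50), landmark_id = "l2")
  )
  out2 <- region_displacement_summary(s2)
  expect_equal(out2$mean_displacement, (a + b) / 2, tolerance = 1e-12)
  # static landmarks: zero displacement, log flagged missing with a warning
  s3 <- one_landmark_series(rep(0.4, 30))
  expect_warning(out3 <- region_displacement_summary(s3), "zero mean")
  expect_equal(out3$mean_displacement, 0)
  expect_true(is.na(out3$log_mean_displacement))
  # masked-out region: missing summary
  s4 <- one_landmark_series(runif(30))
  mk <- mask_missing_windows(s4); mk$valid <- FALSE
  out4 <- region_displacement_summary(s4, mk)
  expect_true(is.na(out4$mean_displacement))
  expect_equal(out4$n_valid_frame_pairs, 0L)
})

test_that("gaps in validity are skipped, never interpolated", {
  x <- seq(0, by = 0.01, length.out = 10)
  pres <- rep(1, 10); pres[5] <- 0
  s <- one_landmark_series(x, present = pres)
  out <- region_displacement_summary(s)
  # pairs (4,5) and (5,6) dropped: 7 valid pairs, all with displacement 0.01
  expect_equal(out$n_valid_frame_pairs, 7L)
  expect_equal(out$mean_displacement, 0.01, tolerance = 1e-12)
})

test_that("body movement summaries are invariant to global scale", {
  set.seed(21)
  co <- simulate_cohort(n = 4, seed = 21)
  lms <- simulate_landmarks(co, landmark_config(duration_seconds = 4), seed = 22)
  pose <- dplyr::filter(lms, landmark_class == "pose")
  f1 <- region_displacement_summary(normalize_body_scale(pose))
  scaled <- dplyr::mutate(pose, x = 5.3 * x, y = 5.3 * y, z = 5.3 * z)
  f2 <- region_displacement_summary(normalize_body_scale(scaled))
  expect_lt(max(abs(f1$mean_displacement - f2$mean_displacement)), 1e-10)
  expect_lt(max(abs(f1$log_mean_displacement - f2$log_mean_displacement)), 1e-10)
})

test_that("face movement after alignment is invariant to rigid motion", {
  set.seed(31)
  co <- simulate_cohort(n = 3, seed = 31)
  lms <- simulate_landmarks(
    co, landmark_config(duration_seconds = 4, head_motion_step = 0,
                        missing_runs_per_minute = 0,
                        jitter_bursts_per_minute = 0), seed = 32
  )
  face <- dplyr::filter(lms, landmark_class == "face")
  th <- 0.4
  R <- matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
  moved <- face
  XYZ <- as.matrix(face[, c("x", "y", "z")]) %*% t(R)
  moved$x <- XYZ[, 1] + 0.1; moved$y <- XYZ[, 2] - 0.2; moved$z <- XYZ[, 3] + 0.05
  f1 <- region_displacement_summary(align_face_affine(face))
  f2 <- region_displacement_summary(align_face_affine(moved))
  expect_lt(max(abs(f1$mean_displacement - f2$mean_displacement)), 1e-8)
})
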