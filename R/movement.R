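#' Quality-control configuration for landmark time-series
#'
#' Thresholds for the two sliding-window quality checks applied to raw
#' landmark trajectories before movement is quantified: a missingness check
#' (segments with more than `missing_fraction_max` missing values inside any
#' covering window of `missing_window_seconds` are excluded) and a jitter
#' check (windows of `jitter_window_frames` frames whose x-coordinate sample
#' standard deviation exceeds a class-specific threshold are excluded,
#' 0.1 for face landmarks and 0.01 for pose landmarks, in image-normalized
#' coordinate units).
#'
#' @param missing_window_seconds Window length for the missingness check, in
#'   seconds (default 2).
#' @param missing_fraction_max Maximum tolerated missing fraction per window
#'   (default 0.10; the rule is strict: a window violates only if the
#'   fraction *exceeds* this value).
#' @param jitter_window_frames Window length for the jitter check, in frames
#'   (default 10).
#' @param jitter_threshold_face,jitter_threshold_pose Jitter thresholds on the
#'   sample SD of x, per landmark class.
#' @param distance_epsilon Minimum inter-shoulder distance (normalized units)
#'   below which a frame is treated as degenerate in
#'   [normalize_body_scale()].
#' @return A list of class `"qc_config"`.
#' @export
qc_config <- function(missing_window_seconds = 2,
                      missing_fraction_max = 0.10,
                      jitter_window_frames = 10,
                      jitter_threshold_face = 0.1,
                      jitter_threshold_pose = 0.01,
                      distance_epsilon = 1e-9) {
  stopifnot(
    missing_window_seconds > 0, missing_fraction_max > 0,
    jitter_window_frames >= 1, jitter_threshold_face > 0,
    jitter_threshold_pose > 0, distance_epsilon > 0
  )
  structure(
    list(
      missing_window_seconds = missing_window_seconds,
      missing_fraction_max = missing_fraction_max,
      jitter_window_frames = jitter_window_frames,
      jitter_threshold_face = jitter_threshold_face,
      jitter_threshold_pose = jitter_threshold_pose,
      distance_epsilon = distance_epsilon
    ),
    class = "qc_config"
  )
}

# All sliding windows of nominal length w overlapping frames 1..n, stepping by
# one frame and truncated at both series edges to their actual length.
# Returns parallel integer vectors of window start/end frames.
window_bounds <- function(n, w) {
  if (n < 1) return(list(a = integer(0), b = integer(0)))
  s <- seq.int(2L - w, n)
  a <- pmax(1L, s)
  b <- pmin(s + w - 1L, n)
  keep <- b >= a & !duplicated(a * (n + 1) + b)
  list(a = a[keep], b = b[keep])
}

# Mark frames covered by any window [a_i, b_i] with bad_i TRUE (difference
# array + cumulative sum, O(n + windows)).
covered_by_bad <- function(n, a, b, bad) {
  a <- a[bad]; b <- b[bad]
  if (length(a) == 0) return(rep(FALSE, n))
  d <- tabulate(a, nbins = n + 1L) - tabulate(b + 1L, nbins = n + 1L)
  cumsum(d)[seq_len(n)] > 0
}

mask_missing_vec <- function(present, w, fmax) {
  n <- length(present)
  if (n == 0) return(logical(0))
  miss <- as.numeric(is.na(present) | present == 0)
  cs <- c(0, cumsum(miss))
  wb <- window_bounds(n, w)
  cnt <- cs[wb$b + 1L] - cs[wb$a]
  len <- wb$b - wb$a + 1L
  !covered_by_bad(n, wb$a, wb$b, cnt / len > fmax)
}

mask_jitter_vec <- function(x, present, w, thr) {
  n <- length(present)
  if (n == 0) return(logical(0))
  p <- as.numeric(!is.na(present) & present == 1)
  xm <- ifelse(p == 1 & !is.na(x), x, 0)
  csp <- c(0, cumsum(p))
  cs1 <- c(0, cumsum(xm))
  cs2 <- c(0, cumsum(xm^2))
  wb <- window_bounds(n, w)
  np <- csp[wb$b + 1L] - csp[wb$a]
  s1 <- cs1[wb$b + 1L] - cs1[wb$a]
  s2 <- cs2[wb$b + 1L] - cs2[wb$a]
  # sample SD (ddof = 1); windows with < 2 present frames impose no exclusion
  v <- (s2 - s1^2 / pmax(np, 1)) / pmax(np - 1, 1)
  sdv <- sqrt(pmax(v, 0))
  bad <- np >= 2 & sdv > thr
  !covered_by_bad(n, wb$a, wb$b, bad)
}

check_landmark_cols <- function(landmarks, cols) {
  missing_cols <- setdiff(cols, names(landmarks))
  if (length(missing_cols) > 0) {
    abort(paste0("landmark table lacks column(s): ",
                 paste(missing_cols, collapse = ", ")))
  }
}

#' Missing-data validity mask for landmark series
#'
#' A frame is invalid for a landmark if any sliding window (step one frame,
#' nominal length `fps * missing_window_seconds`, truncated at the series
#' edges) containing it has a missing fraction exceeding
#' `missing_fraction_max` for that landmark.
#'
#' @param landmarks Long landmark table with columns `participant_id`,
#'   `landmark_id`, `frame`, `present` (and `landmark_class`, `x` for the
#'   companion [mask_jitter()]).
#' @param qc A [qc_config()].
#' @param fps Sampling rate in frames per second (default 30).
#' @return Tibble `participant_id`, `landmark_id`, `frame`, `valid` (logical),
#'   ordered by participant, landmark, frame.
#' @export
mask_missing_windows <- function(landmarks, qc = qc_config(), fps = 30) {
  check_landmark_cols(landmarks, c("participant_id", "landmark_id", "frame", "present"))
  w <- as.integer(round(fps * qc$missing_window_seconds))
  stopifnot(w >= 1)
  landmarks |>
    dplyr::arrange(.data$participant_id, .data$landmark_id, .data$frame) |>
    dplyr::group_by(.data$participant_id, .data$landmark_id) |>
    dplyr::mutate(valid = mask_missing_vec(.data$present, w, qc$missing_fraction_max)) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "landmark_id", "frame", "valid")
}

#' Jitter validity mask for landmark series
#'
#' A frame is invalid for a landmark if any covering 10-frame sliding window
#' has a sample standard deviation of the x-coordinate (over present frames in
#' the window) exceeding the class threshold (face vs pose). Windows with
#' fewer than two present frames impose no exclusion.
#'
#' @inheritParams mask_missing_windows
#' @return Tibble `participant_id`, `landmark_id`, `frame`, `valid`.
#' @export
mask_jitter <- function(landmarks, qc = qc_config()) {
  check_landmark_cols(landmarks, c("participant_id", "landmark_id", "frame",
                                   "present", "landmark_class", "x"))
  landmarks |>
    dplyr::arrange(.data$participant_id, .data$landmark_id, .data$frame) |>
    dplyr::group_by(.data$participant_id, .data$landmark_id) |>
    dplyr::mutate(valid = mask_jitter_vec(
      .data$x, .data$present, qc$jitter_window_frames,
      if (.data$landmark_class[1] == "face") qc$jitter_threshold_face else qc$jitter_threshold_pose
    )) |>
    dplyr::ungroup() |>
    dplyr::select("participant_id", "landmark_id", "frame", "valid")
}

#' Combine two validity masks
#'
#' A landmark-frame is valid only if it passed both quality checks: the
#' result is the elementwise logical AND of aligned masks.
#'
#' @param m1,m2 Mask tibbles as returned by [mask_missing_windows()] /
#'   [mask_jitter()], over the same landmark-frames.
#' @return Mask tibble with `valid = m1$valid & m2$valid`.
#' @export
combine_validity <- function(m1, m2) {
  key <- c("participant_id", "landmark_id", "frame")
  m1 <- dplyr::arrange(m1, .data$participant_id, .data$landmark_id, .data$frame)
  m2 <- dplyr::arrange(m2, .data$participant_id, .data$landmark_id, .data$frame)
  if (nrow(m1) != nrow(m2) ||
      !identical(as.data.frame(m1[key]), as.data.frame(m2[key]))) {
    abort("mask shape mismatch: masks cover different landmark-frames")
  }
  dplyr::mutate(m1, valid = .data$valid & m2$valid)
}

#' Canonical face template
#'
#' A synthetic 13-point face template in image-normalized coordinates used as
#' the target of per-frame affine alignment. It is a configuration asset, not
#' a claim about any particular detector's canonical model: any template with
#' at least four non-coplanar points (in the affine sense) works, and users
#' with a detector-specific canonical face should supply their own.
#'
#' @return Tibble `landmark_id`, `region`, `x`, `y`, `z`.
#' @export
canonical_face_template <- function() {
  tibble::tribble(
    ~landmark_id,      ~region,  ~x,   ~y,   ~z,
    "nose_tip",        "face",  0.50, 0.45, 0.060,
    "left_cheek",      "face",  0.42, 0.50, 0.030,
    "right_cheek",     "face",  0.58, 0.50, 0.030,
    "forehead",        "head",  0.50, 0.28, 0.025,
    "chin",            "head",  0.50, 0.62, 0.020,
    "left_eye_outer",  "eyes",  0.41, 0.38, 0.000,
    "left_eye_inner",  "eyes",  0.46, 0.38, 0.018,
    "right_eye_inner", "eyes",  0.54, 0.38, 0.018,
    "right_eye_outer", "eyes",  0.59, 0.38, 0.000,
    "mouth_left",      "mouth", 0.45, 0.55, 0.030,
    "mouth_right",     "mouth", 0.55, 0.55, 0.030,
    "mouth_top",       "mouth", 0.50, 0.53, 0.042,
    "mouth_bottom",    "mouth", 0.50, 0.57, 0.040
  )
}

#' Align face landmarks to a canonical template by per-frame affine fit
#'
#' For each frame, fits the least-squares affine map `A p + b` from the
#' present face landmarks to their canonical template positions, and applies
#' the fitted map to all face landmarks in the frame. This removes head
#' rotation, translation, scale, and shear, so residual displacement reflects
#' facial motion rather than head pose. Frames with fewer than four present
#' face landmarks, or an affinely degenerate (rank-deficient) configuration,
#' are marked invalid by setting `present = 0` for their face landmarks.
#'
#' @param landmarks Long landmark table; rows with `landmark_class == "face"`
#'   and a `landmark_id` found in the template are aligned, all other rows
#'   pass through untouched.
#' @param template Canonical coordinates, as [canonical_face_template()].
#' @return The landmark table with face coordinates replaced by aligned
#'   coordinates, same row set (re-ordered by participant, landmark, frame).
#' @export
align_face_affine <- function(landmarks, template = canonical_face_template()) {
  check_landmark_cols(landmarks, c("participant_id", "landmark_id", "frame",
                                   "landmark_class", "x", "y", "z", "present"))
  landmarks <- dplyr::arrange(tibble::as_tibble(landmarks),
                              .data$participant_id, .data$landmark_id, .data$frame)
  is_face <- landmarks$landmark_class == "face" &
    landmarks$landmark_id %in% template$landmark_id
  if (!any(is_face)) return(landmarks)
  face <- landmarks[is_face, ]

  out <- face |>
    dplyr::group_by(.data$participant_id) |>
    dplyr::group_modify(~ align_one_participant(.x, template)) |>
    dplyr::ungroup()

  landmarks[is_face, c("x", "y", "z", "present")] <-
    out[, c("x", "y", "z", "present")]
  landmarks
}

# face: one participant's face landmarks, arranged by (landmark_id, frame),
# assumed a complete frame x landmark grid (checked).
align_one_participant <- function(face, template) {
  lids <- unique(face$landmark_id)
  frames <- sort(unique(face$frame))
  nf <- length(frames)
  nl <- length(lids)
  if (nrow(face) != nf * nl) {
    abort("face landmark series is not a complete frame x landmark grid")
  }
  # column-major fill: rows arranged landmark-major, frame fastest
  X <- matrix(face$x, nf, nl)
  Y <- matrix(face$y, nf, nl)
  Z <- matrix(face$z, nf, nl)
  P <- matrix(face$present, nf, nl)
  tpl <- as.matrix(template[match(lids, template$landmark_id), c("x", "y", "z")])
  ones <- rep(1, nl)
  for (i in seq_len(nf)) {
    idx <- which(P[i, ] == 1)
    ok <- FALSE
    if (length(idx) >= 4) {
      D <- cbind(X[i, idx], Y[i, idx], Z[i, idx], 1)
      qd <- qr(D)
      if (qd$rank == 4) {
        B <- qr.coef(qd, tpl[idx, , drop = FALSE])
        new <- cbind(X[i, ], Y[i, ], Z[i, ], ones) %*% B
        X[i, ] <- new[, 1]; Y[i, ] <- new[, 2]; Z[i, ] <- new[, 3]
        ok <- TRUE
      }
    }
    if (!ok) P[i, ] <- 0
  }
  face$x <- as.vector(X)
  face$y <- as.vector(Y)
  face$z <- as.vector(Z)
  face$present <- as.vector(P)
  face
}

#' Normalize body landmarks by inter-shoulder distance
#'
#' Divides every pose-landmark coordinate by the frame's Euclidean
#' shoulder-to-shoulder distance, rendering body movement invariant to body
#' size and distance from the camera. Frames where either shoulder is absent,
#' or the shoulders are (numerically) coincident, are marked invalid by
#' setting `present = 0` for their pose landmarks.
#'
#' @param landmarks Long landmark table; rows with `landmark_class == "pose"`
#'   are normalized.
#' @param shoulders Length-2 character vector of shoulder `landmark_id`s.
#' @param distance_epsilon Minimum admissible inter-shoulder distance.
#' @return The landmark table with pose coordinates normalized.
#' @export
normalize_body_scale <- function(landmarks,
                                 shoulders = c("left_shoulder", "right_shoulder"),
                                 distance_epsilon = qc_config()$distance_epsilon) {
  check_landmark_cols(landmarks, c("participant_id", "landmark_id", "frame",
                                   "landmark_class", "x", "y", "z", "present"))
  landmarks <- tibble::as_tibble(landmarks)
  sh <- landmarks |>
    dplyr::filter(.data$landmark_id %in% shoulders, .data$present == 1) |>
    dplyr::select("participant_id", "frame", "landmark_id", "x", "y", "z") |>
    tidyr::pivot_wider(names_from = "landmark_id",
                       values_from = c("x", "y", "z"))
  need <- as.vector(outer(c("x_", "y_", "z_"), shoulders, paste0))
  dist_tbl <- if (all(need %in% names(sh)) && nrow(sh) > 0) {
    sh$shoulder_dist <- sqrt(
      (sh[[paste0("x_", shoulders[1])]] - sh[[paste0("x_", shoulders[2])]])^2 +
      (sh[[paste0("y_", shoulders[1])]] - sh[[paste0("y_", shoulders[2])]])^2 +
      (sh[[paste0("z_", shoulders[1])]] - sh[[paste0("z_", shoulders[2])]])^2
    )
    dplyr::select(sh, "participant_id", "frame", "shoulder_dist")
  } else {
    tibble::tibble(participant_id = landmarks$participant_id[0],
                   frame = landmarks$frame[0], shoulder_dist = numeric(0))
  }
  landmarks <- dplyr::left_join(landmarks, dist_tbl,
                                by = c("participant_id", "frame"))
  is_pose <- landmarks$landmark_class == "pose"
  bad <- is_pose & (is.na(landmarks$shoulder_dist) |
                      landmarks$shoulder_dist <= distance_epsilon)
  good <- is_pose & !bad
  for (col in c("x", "y", "z")) {
    landmarks[[col]][good] <- landmarks[[col]][good] / landmarks$shoulder_dist[good]
  }
  landmarks$present[bad] <- 0
  dplyr::select(landmarks, -"shoulder_dist")
}

#' Per-region framewise displacement summary
#'
#' Movement is quantified per landmark as the frame-to-frame 3D Euclidean
#' displacement over consecutive valid frame pairs (both endpoints present,
#' passing the supplied validity mask, and one frame apart); gaps are skipped,
#' never interpolated. Displacements are first averaged over time within each
#' landmark, then across the landmarks of each anatomical region, yielding a
#' single mean movement score per region, together with its natural log.
#'
#' @param landmarks Long landmark table (aligned/normalized as appropriate).
#' @param mask Optional validity mask from [combine_validity()]; if `NULL`,
#'   all frames are treated as passing QC (presence still applies).
#' @return Tibble `participant_id`, `region`, `mean_displacement`,
#'   `log_mean_displacement`, `n_valid_frame_pairs`. Regions with no valid
#'   frame pairs get missing summaries; a region whose mean displacement is
#'   exactly zero gets a missing log with a warning.
#' @export
region_displacement_summary <- function(landmarks, mask = NULL) {
  check_landmark_cols(landmarks, c("participant_id", "landmark_id", "frame",
                                   "region", "x", "y", "z", "present"))
  landmarks <- dplyr::arrange(tibble::as_tibble(landmarks),
                              .data$participant_id, .data$landmark_id, .data$frame)
  if (!is.null(mask)) {
    landmarks <- dplyr::left_join(
      landmarks, mask, by = c("participant_id", "landmark_id", "frame")
    )
    if (anyNA(landmarks$valid)) abort("mask does not cover all landmark-frames")
  } else {
    landmarks$valid <- TRUE
  }
  per_landmark <- landmarks |>
    dplyr::mutate(ok = .data$present == 1 & .data$valid) |>
    dplyr::group_by(.data$participant_id, .data$landmark_id, .data$region) |>
    dplyr::mutate(
      pair_ok = .data$ok & dplyr::lead(.data$ok, default = FALSE) &
        !is.na(dplyr::lead(.data$frame)) &
        dplyr::lead(.data$frame) == .data$frame + 1,
      disp = sqrt((dplyr::lead(.data$x) - .data$x)^2 +
                    (dplyr::lead(.data$y) - .data$y)^2 +
                    (dplyr::lead(.data$z) - .data$z)^2)
    ) |>
    dplyr::summarise(
      disp_sum = sum(.data$disp[.data$pair_ok]),
      n_pairs = sum(.data$pair_ok),
      .groups = "drop"
    )
  out <- per_landmark |>
    dplyr::group_by(.data$participant_id, .data$region) |>
    dplyr::summarise(
      mean_displacement = if (any(.data$n_pairs > 0)) {
        mean((.data$disp_sum / .data$n_pairs)[.data$n_pairs > 0])
      } else NA_real_,
      n_valid_frame_pairs = sum(.data$n_pairs),
      .groups = "drop"
    )
  if (any(!is.na(out$mean_displacement) & out$mean_displacement == 0)) {
    warn("some regions have zero mean displacement; log summary set to missing")
  }
  out$log_mean_displacement <- ifelse(
    !is.na(out$mean_displacement) & out$mean_displacement > 0,
    log(out$mean_displacement), NA_real_
  )
  dplyr::select(out, "participant_id", "region", "mean_displacement",
                "log_mean_displacement", "n_valid_frame_pairs")
}

#' Full movement feature extraction from landmark series
#'
#' Runs the complete movement chain: QC masking (missingness and jitter),
#' affine face alignment to a canonical template, inter-shoulder body
#' normalization, and per-region framewise displacement, returning one row
#' per participant with a log mean displacement column per region.
#'
#' @inheritParams mask_missing_windows
#' @param template Canonical face template for alignment (`NULL` to skip).
#' @param shoulders Shoulder landmark ids for body normalization (`NULL` to
#'   skip).
#' @return Wide tibble: `participant_id`, `log_disp_<region>` and
#'   `n_pairs_<region>` columns.
#' @export
movement_features <- function(landmarks, qc = qc_config(), fps = 30,
                              template = canonical_face_template(),
                              shoulders = c("left_shoulder", "right_shoulder")) {
  mask <- combine_validity(
    mask_missing_windows(landmarks, qc, fps),
    mask_jitter(landmarks, qc)
  )
  if (!is.null(template) && any(landmarks$landmark_class == "face")) {
    landmarks <- align_face_affine(landmarks, template)
  }
  if (!is.null(shoulders) && any(landmarks$landmark_class == "pose")) {
    landmarks <- normalize_body_scale(landmarks, shoulders,
                                      distance_epsilon = qc$distance_epsilon)
  }
  wide <- region_displacement_summary(landmarks, mask) |>
    tidyr::pivot_wider(
      id_cols = "participant_id",
      names_from = "region",
      values_from = c("log_mean_displacement", "n_valid_frame_pairs")
    )
  names(wide) <- sub("^log_mean_displacement_", "log_disp_", names(wide))
  names(wide) <- sub("^n_valid_frame_pairs_", "n_pairs_", names(wide))
  wide
}
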