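# Independent brute-force oracles and small fixture builders.
# Oracles deliberately use naive loops, not the package's vectorized path.

# Enumerate every sliding window of nominal length w overlapping 1..n
# (truncated at the edges) and scan it directly.
oracle_windows <- function(n, w) {
  out <- list()
  for (s in (2 - w):n) {
    a <- max(1, s); b <- min(s + w - 1, n)
    if (b >= a) out[[length(out) + 1]] <- c(a, b)
  }
  unique(out)
}

oracle_mask_missing <- function(present, w, fmax) {
  n <- length(present)
  valid <- rep(TRUE, n)
  for (win in oracle_windows(n, w)) {
    fr <- win[1]:win[2]
    if (mean(present[fr] == 0) > fmax) valid[fr] <- FALSE
  }
  valid
}

oracle_mask_jitter <- function(x, present, w, thr) {
  n <- length(present)
  valid <- rep(TRUE, n)
  for (win in oracle_windows(n, w)) {
    fr <- win[1]:win[2]
    xs <- x[fr][present[fr] == 1]
    if (length(xs) >= 2 && sd(xs) > thr) valid[fr] <- FALSE
  }
  valid
}

# Single-landmark series builder
one_landmark_series <- function(x, y = 0, z = 0, present = 1,
                                landmark_id = "lm1", landmark_class = "face",
                                region = "face", participant_id = "P1") {
  n <- length(x)
  tibble::tibble(
    participant_id = participant_id,
    frame = seq_len(n),
    landmark_id = landmark_id,
    landmark_class = landmark_class,
    region = region,
    x = x, y = rep_len(y, n), z = rep_len(z, n),
    present = rep_len(present, n)
  )
}

# A full-face single-frame (or multi-frame static) series from the template
template_series <- function(n_frames = 1, participant_id = "P1",
                            transform = identity) {
  tpl <- canonical_face_template()
  purrr::map_dfr(seq_len(n_frames), function(f) {
    coords <- transform(as.matrix(tpl[, c("x", "y", "z")]))
    tibble::tibble(
      participant_id = participant_id, frame = f,
      landmark_id = tpl$landmark_id, landmark_class = "face",
      region = tpl$region,
      x = coords[, 1], y = coords[, 2], z = coords[, 3], present = 1
    )
  })
}

# OLS via normal equations (closed form, independent of lm/qr fitting path)
ols_normal_equations <- function(y, X) {
  solve(t(X) %*% X, t(X) %*% y)[, 1]
}

eq1_effects_vector <- function() {
  c(age = 0.40, iq_full = 0.27, sex = 0.08,
    adhd_inatt = 0.00, adhd_hyper = 0.12, asd = 0.13)
}
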