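#' Standard predictor set for the multivariate phenotype model
#'
#' Every behavioral metric is modeled as
#' `metric ~ age + iq_full + sex + adhd_inatt + adhd_hyper + asd`,
#' isolating the unique contribution of each diagnostic status while
#' controlling for development, cognitive ability and sex.
#'
#' @return Character vector of predictor column names.
#' @export
eq1_predictors <- function() {
  c("age", "iq_full", "sex", "adhd_inatt", "adhd_hyper", "asd")
}

#' Assemble the design matrix for one outcome
#'
#' Drops excluded records (ADHD other/unspecified), then applies listwise
#' deletion per model: any row missing the outcome or any predictor is
#' removed, so the number of observations can vary across outcomes.
#'
#' @param data Participant-level table containing the outcome and predictor
#'   columns (and optionally `excluded`).
#' @param outcome Name of the outcome column.
#' @param predictors Predictor column names (default [eq1_predictors()]).
#' @param interaction Optional name of a binary disorder flag; adds an
#'   `age:<flag>` interaction column to the design.
#' @return List with `y` (numeric vector), `X` (matrix with intercept),
#'   `n_used`.
#' @export
build_design <- function(data, outcome, predictors = eq1_predictors(),
                         interaction = NULL) {
  cols <- c(outcome, predictors)
  missing_cols <- setdiff(cols, names(data))
  if (length(missing_cols) > 0) {
    abort(paste0("column(s) not found: ", paste(missing_cols, collapse = ", ")))
  }
  if (anyDuplicated(predictors)) abort("predictors must be distinct")
  if (!is.null(interaction) && !interaction %in% predictors) {
    abort("interaction flag must be one of the included predictors")
  }
  if ("excluded" %in% names(data)) {
    data <- data[is.na(data$excluded) | data$excluded != 1, , drop = FALSE]
  }
  sub <- data[cols]
  keep <- complete.cases(sub)
  sub <- sub[keep, , drop = FALSE]
  if (nrow(sub) <= length(predictors) + 1 + !is.null(interaction)) {
    abort(paste0("underdetermined: ", nrow(sub), " usable rows for ",
                 length(predictors) + 1 + !is.null(interaction),
                 " parameters in model for '", outcome, "'"))
  }
  X <- cbind(`(Intercept)` = 1, as.matrix(sub[predictors]))
  if (!is.null(interaction)) {
    ix <- sub[["age"]] * sub[[interaction]]
    X <- cbind(X, ix)
    colnames(X)[ncol(X)] <- paste0("age:", interaction)
  }
  n_used <- nrow(X)
  if (n_used <= ncol(X)) {
    abort(paste0("underdetermined: ", n_used, " usable rows for ",
                 ncol(X), " parameters in model for '", outcome, "'"))
  }
  list(y = as.numeric(sub[[outcome]]), X = X, n_used = n_used)
}

new_pheno_fit <- function(coefficients, dfe, n_used, converged, family,
                          outcome = NA_character_, sigma = NA_real_) {
  structure(
    list(coefficients = coefficients, dfe = dfe, n_used = n_used,
         converged = converged, family = family, outcome = outcome,
         sigma = sigma),
    class = "pheno_fit"
  )
}

# t-statistic with guarded zero-SE cases (exact fits): 0/0 -> 0, x/0 -> Inf.
safe_t <- function(beta, se) {
  t <- beta / se
  t[se == 0 & beta == 0] <- 0
  t[se == 0 & beta != 0] <- sign(beta[se == 0 & beta != 0]) * Inf
  t
}

#' Robust linear regression with Tukey bisquare weights
#'
#' Iteratively reweighted least squares with the Tukey bisquare psi:
#' `w(u) = (1 - (u/c)^2)^2` for `|u| <= c`, else 0, where `u` is the residual
#' divided by the MAD-based robust scale `median(|r|) / 0.6745`. Gross
#' outliers receive zero weight, so a handful of extreme observations cannot
#' drive the coefficient estimates. Standard errors use the M-estimation
#' (Huber) covariance with a small-sample correction, as in the standard
#' robust-fitting implementations; p-values use the t reference distribution
#' with `dfe = n - p` error degrees of freedom, and the effect size of each
#' predictor is `t / sqrt(dfe)` (see [effect_size()]).
#'
#' @param y Numeric outcome vector.
#' @param X Design matrix including the intercept (see [build_design()]).
#' @param tuning Bisquare tuning constant, default 4.685 (95% Gaussian
#'   efficiency).
#' @param tol Convergence tolerance on the max coefficient change.
#' @param max_iter Maximum IRLS iterations; non-convergence is reported via
#'   `converged = 0` with a warning, never an error.
#' @return A `pheno_fit` object; see [tidy.pheno_fit()] and
#'   [glance.pheno_fit()].
#' @export
fit_robust_linear <- function(y, X, tuning = 4.685, tol = 1e-8,
                              max_iter = 200) {
  X <- as.matrix(X)
  n <- nrow(X); p <- ncol(X)
  stopifnot(length(y) == n, n > p)
  qx <- qr(X)
  if (qx$rank < p) abort("design matrix is rank deficient")
  beta <- qr.coef(qx, y)
  w <- rep(1, n)
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    r <- y - drop(X %*% beta)
    s <- median(abs(r)) / 0.6745
    if (s < 1e-12 * max(1, median(abs(y)))) {
      # (near-)exact fit: all weights 1, already converged
      w <- rep(1, n)
      converged <- TRUE
      break
    }
    u <- r / s
    w <- ifelse(abs(u) <= tuning, (1 - (u / tuning)^2)^2, 0)
    fit <- stats::lm.wfit(X, y, w)
    new_beta <- fit$coefficients
    if (max(abs(new_beta - beta)) < tol * max(1, max(abs(new_beta)))) {
      beta <- new_beta
      converged <- TRUE
      break
    }
    beta <- new_beta
  }
  if (!converged) {
    warn(paste0("bisquare IRLS did not converge in ", max_iter, " iterations"))
  }
  r <- y - drop(X %*% beta)
  dfe <- n - p
  s <- median(abs(r)) / 0.6745
  if (s < 1e-12 * max(1, median(abs(y)))) {
    # exact fit: zero residual variance
    se <- rep(0, p)
  } else {
    # M-estimation covariance (Huber, with small-sample correction):
    # psi(u) = u (1-(u/c)^2)^2, cov = K^2 s^2 [sum psi^2/(n-p)] / m^2 (X'X)^-1
    u <- r / s
    inb <- abs(u) <= tuning
    psi <- ifelse(inb, u * (1 - (u / tuning)^2)^2, 0)
    dpsi <- ifelse(inb, (1 - (u / tuning)^2) * (1 - 5 * (u / tuning)^2), 0)
    m1 <- mean(dpsi)
    if (m1 <= 0) {
      # pathological weighting; fall back to the weighted-fit covariance
      sigma2 <- sum(w * r^2) / dfe
      cov_beta <- sigma2 * chol2inv(chol(crossprod(X * sqrt(w))))
    } else {
      K <- 1 + (p / n) * var(dpsi) / m1^2
      cov_beta <- K^2 * s^2 * (sum(psi^2) / dfe) / m1^2 *
        chol2inv(chol(crossprod(X)))
    }
    se <- sqrt(pmax(diag(cov_beta), 0))
  }
  t <- safe_t(beta, se)
  pval <- 2 * pt(-abs(t), dfe)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(t),
    dfe = dfe,
    effect_size = unname(effect_size(t, dfe)),
    p_value = unname(pval)
  )
  new_pheno_fit(coefs, dfe = dfe, n_used = n,
                converged = as.integer(converged),
                family = "robust_linear", sigma = s)
}

#' Effect size from a t-statistic and error degrees of freedom
#'
#' `ES = t / sqrt(dfe)`, a normalization that makes effects comparable across
#' models with different numbers of usable observations. For a binary
#' predictor with positive fraction p it approaches
#' `d * sqrt(p (1 - p) (1 - R2))` (d the Cohen's d of the group contrast, R2
#' the predictor's collinearity with the rest of the design); for continuous
#' predictors it is the coefficient estimate over the standard deviation of
#' its sampling distribution.
#'
#' @param t t-statistic(s).
#' @param dfe Error degrees of freedom (`n_used - n_parameters`), `>= 1`.
#' @return `t / sqrt(dfe)`.
#' @examples
#' effect_size(3, 900) # 0.1
#' @export
effect_size <- function(t, dfe) {
  if (any(dfe < 1)) abort("dfe must be >= 1")
  t / sqrt(dfe)
}

#' Logistic regression with odds ratios
#'
#' Maximum-likelihood logistic fit for binary outcomes (e.g. diagnosis
#' status), reporting odds ratios as the exponentiated coefficients: the
#' multiplicative change in odds per unit change of the predictor (one year
#' for age, one group contrast for binary predictors).
#'
#' @param y01 Binary outcome vector (0/1).
#' @param X Design matrix including the intercept.
#' @return A `pheno_fit` with an `odds_ratio` column in its coefficients.
#' @export
fit_logistic <- function(y01, X) {
  X <- as.matrix(X)
  stopifnot(all(y01 %in% c(0, 1)), nrow(X) == length(y01))
  fit <- suppressWarnings(
    stats::glm.fit(X, y01, family = stats::binomial())
  )
  beta <- fit$coefficients
  if (!fit$converged || any(!is.finite(beta)) || any(abs(beta) > 15)) {
    abort(paste0(
      "logistic fit suggests (quasi-)complete separation; ",
      "penalized estimation is out of scope"
    ))
  }
  wls <- fit$weights
  cov_beta <- chol2inv(chol(crossprod(X * sqrt(wls))))
  se <- sqrt(diag(cov_beta))
  z <- safe_t(beta, se)
  dfe <- nrow(X) - ncol(X)
  coefs <- tibble::tibble(
    term = colnames(X),
    estimate = unname(beta),
    std_error = unname(se),
    statistic = unname(z),
    dfe = dfe,
    effect_size = unname(effect_size(z, dfe)),
    odds_ratio = unname(exp(beta)),
    p_value = unname(2 * pnorm(-abs(z)))
  )
  new_pheno_fit(coefs, dfe = dfe, n_used = nrow(X), converged = 1L,
                family = "logistic")
}

#' Fit the multivariate phenotype model for one outcome
#'
#' Data-frame-first wrapper around [build_design()] plus
#' [fit_robust_linear()] or [fit_logistic()].
#'
#' @inheritParams build_design
#' @param family `"robust_linear"` (continuous metrics) or `"logistic"`
#'   (binary diagnosis outcomes, reported as odds ratios).
#' @param ... Passed on to the fitting function.
#' @return A `pheno_fit`.
#' @examples
#' cohort <- simulate_cohort(n = 400, seed = 7)
#' fit <- fit_phenotype_model(
#'   dplyr::mutate(cohort, outcome = rnorm(dplyr::n())), "outcome"
#' )
#' tidy(fit)
#' @export
fit_phenotype_model <- function(data, outcome,
                                family = c("robust_linear", "logistic"),
                                predictors = eq1_predictors(),
                                interaction = NULL, ...) {
  family <- match.arg(family)
  d <- build_design(data, outcome, predictors, interaction)
  fit <- switch(family,
    robust_linear = fit_robust_linear(d$y, d$X, ...),
    logistic = fit_logistic(d$y, d$X)
  )
  fit$outcome <- outcome
  fit
}

#' Post-hoc age-by-disorder interaction model
#'
#' Refits the standard multivariate model with an added `age x disorder`
#' interaction column, used as a follow-up wherever a disorder and age both
#' showed significant main effects. The interaction p-value is reported
#' uncorrected.
#'
#' @inheritParams build_design
#' @param disorder_flag One of `"asd"`, `"adhd_inatt"`, `"adhd_hyper"`.
#' @return A `pheno_fit` whose last term is the interaction.
#' @export
fit_interaction <- function(data, outcome,
                            disorder_flag = c("asd", "adhd_inatt", "adhd_hyper")) {
  disorder_flag <- match.arg(disorder_flag)
  fit_phenotype_model(data, outcome, family = "robust_linear",
                      interaction = disorder_flag)
}

#' Bonferroni correction and significance flags
#'
#' Adjusts p-values for a family of `family_size` models
#' (`p_adj = min(1, m p)`) and flags those below the significance cut-off
#' (default 0.01, the convention used for effect-size matrices).
#'
#' @param pvals Numeric vector of p-values.
#' @param family_size Number of models in the family (`m`), at least the
#'   number of p-values supplied.
#' @param alpha Significance cut-off on the adjusted p-value.
#' @return Tibble `p`, `p_adj`, `significant`.
#' @examples
#' bonferroni_flag(c(0.0005, 0.002), family_size = 9)
#' @export
bonferroni_flag <- function(pvals, family_size, alpha = 0.01) {
  if (family_size < 1) abort("family_size must be >= 1")
  if (family_size < length(pvals)) {
    abort("family_size is smaller than the number of tests supplied")
  }
  p_adj <- pmin(1, family_size * pvals)
  tibble::tibble(p = pvals, p_adj = p_adj, significant = p_adj < alpha)
}

#' Spearman rank correlation with t-approximation p-value
#'
#' Pearson correlation of mid-ranks over pairwise-complete observations, with
#' a two-sided p-value from the t approximation
#' `t = rho sqrt((n-2) / (1-rho^2))`. The degrees of freedom `n - 2` follow
#' the reporting convention `rho(df)`.
#'
#' @param x,y Numeric vectors of equal length.
#' @return Tibble `rho`, `p`, `n`, `df`; `rho` is `NA` with a warning when
#'   either input is constant.
#' @export
spearman_rho <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) abort("need at least 3 pairwise-complete observations")
  if (length(unique(x)) < 2 || length(unique(y)) < 2) {
    warn("constant input: Spearman correlation undefined")
    return(tibble::tibble(rho = NA_real_, p = NA_real_, n = n, df = n - 2))
  }
  rho <- stats::cor(rank(x), rank(y))
  if (abs(rho) >= 1) {
    p <- 0
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * pt(-abs(tstat), n - 2)
  }
  tibble::tibble(rho = rho, p = p, n = n, df = n - 2)
}

#' @export
print.pheno_fit <- function(x, ...) {
  cat("<pheno_fit> ", x$family,
      if (!is.na(x$outcome)) paste0(" for '", x$outcome, "'"),
      "  n_used=", x$n_used, "  dfe=", x$dfe,
      "  converged=", x$converged, "\n", sep = "")
  print(x$coefficients)
  invisible(x)
}

#' Tidy a phenotype model fit
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return One row per model term: `term`, `estimate`, `std_error`,
#'   `statistic`, `dfe`, `effect_size`, `p_value` (plus `odds_ratio` for
#'   logistic fits).
#' @exportS3Method generics::tidy
tidy.pheno_fit <- function(x, ...) {
  x$coefficients
}

#' One-row model summary for a phenotype fit
#'
#' @param x A `pheno_fit`.
#' @param ... Unused.
#' @return Tibble with `outcome`, `family`, `n_used`, `dfe`, `converged`,
#'   `sigma`.
#' @exportS3Method generics::glance
glance.pheno_fit <- function(x, ...) {
  tibble::tibble(
    outcome = x$outcome, family = x$family, n_used = x$n_used,
    dfe = x$dfe, converged = x$converged, sigma = x$sigma
  )
}
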