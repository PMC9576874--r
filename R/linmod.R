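# Shared linear-model engine: covariate design construction, OLS with
# classical inference, empirical-Bayes variance moderation for the mQTL
# scan, and Bonferroni family-wise control.

#' Build a covariate design matrix
#'
#' Intercept, numeric covariates, dummy-coded categoricals (reference =
#' first declared level) and six of the seven cell-proportion columns --
#' granulocytes, the dominant cord-blood fraction, is dropped to break the
#' sum-to-one collinearity -- plus any extra terms. The result must be of
#' full column rank; otherwise the linearly dependent columns are named in
#' the error.
#'
#' @param covariates covariate data frame, or `NULL` for an
#'   intercept-only design.
#' @param extra optional named list/data frame/matrix of extra columns
#'   (e.g. a coded SNP).
#' @param drop_cell cell column removed to break collinearity (default
#'   `"cell_Gran"`).
#' @return Numeric design matrix with an `"(Intercept)"` column and
#'   attribute `rank`.
#' @export
build_design <- function(covariates = NULL, extra = NULL,
                         drop_cell = "cell_Gran") {
  E <- if (!is.null(extra)) as.matrix(as.data.frame(extra)) else NULL
  if (is.null(covariates)) {
    if (is.null(E)) stop("need covariates or extra terms to size the design")
    X <- matrix(1, nrow(E), 1, dimnames = list(NULL, "(Intercept)"))
  } else {
    covs <- covariates[, setdiff(names(covariates), drop_cell), drop = FALSE]
    if (anyNA(covs)) stop("missing covariate values")
    X <- stats::model.matrix(~ ., data = covs)
  }
  if (!is.null(E)) {
    stopifnot(nrow(E) == nrow(X))
    X <- cbind(X, E)
  }
  qx <- qr(X)
  if (qx$rank < ncol(X)) {
    dep <- colnames(X)[qx$pivot[(qx$rank + 1):ncol(X)]]
    stop("design matrix is rank-deficient; dependent column(s): ",
         paste(dep, collapse = ", "))
  }
  attr(X, "rank") <- qx$rank
  X
}

#' Ordinary least squares with classical inference
#'
#' QR-based least squares; standard errors from `s^2 (X'X)^{-1}`, t
#' statistics and two-sided p-values from the t distribution with
#' `n - rank` residual degrees of freedom.
#'
#' @param X full-rank design matrix.
#' @param y response vector, no missing values.
#' @return An object of class `ols_fit`: coefficients, `se`, `t`, `p`,
#'   residual variance `s2`, residual degrees of freedom `df`, `n`.
#' @export
fit_ols <- function(X, y) {
  stopifnot(!anyNA(X), !anyNA(y), nrow(X) == length(y))
  n <- nrow(X); p <- ncol(X)
  qx <- qr(X)
  if (qx$rank < p) stop("design matrix is rank-deficient")
  if (n <= p) stop("need more observations than parameters")
  beta <- qr.coef(qx, y)
  res <- y - drop(X %*% beta)
  df <- n - p
  s2 <- sum(res^2) / df
  xtx_inv <- chol2inv(qr.R(qx))
  o <- order(qx$pivot)
  xtx_inv <- xtx_inv[o, o, drop = FALSE]
  se <- sqrt(pmax(diag(xtx_inv), 0) * s2)
  tval <- beta / se
  pval <- 2 * pt(-abs(tval), df = df)
  structure(list(coefficients = beta, se = se, t = tval, p = pval,
                 s2 = s2, df = df, n = n, cov_unscaled = xtx_inv),
            class = "ols_fit")
}

#' @export
print.ols_fit <- function(x, ...) {
  cat("ols_fit: n =", x$n, ", residual df =", x$df, "\n")
  print(data.frame(beta = x$coefficients, se = x$se, t = x$t, p = x$p))
  invisible(x)
}

# Newton inversion of the trigamma function (psi'(x) = y), used by the
# moderation hyperparameter fit.
.trigamma_inverse <- function(y) {
  vapply(y, function(yi) {
    if (!is.finite(yi) || yi <= 0) return(Inf)
    if (yi > 1e7) return(1 / sqrt(yi))
    x <- 0.5 + 1 / yi
    for (it in seq_len(50)) {
      tri <- trigamma(x)
      dif <- tri * (1 - tri / yi) / psigamma(x, deriv = 2)
      x <- x + dif
      if (abs(dif) / x < 1e-8) break
    }
    x
  }, numeric(1))
}

#' Empirical-Bayes moderation of residual variances
#'
#' Fits the scaled inverse-chi-square prior `s0^2, d0` to a set of
#' residual variances by the method of moments on log variances (the
#' trigamma equation solved by Newton iteration, tolerance 1e-8), and
#' shrinks each variance to `s~^2 = (d0 s0^2 + df s^2) / (d0 + df)`.
#' Moderated t statistics use `s~` with `df + d0` degrees of freedom.
#' When the observed log-variance dispersion does not exceed the
#' chi-square sampling noise `trigamma(df/2)`, the prior is degenerate:
#' `d0 = Inf` and every moderated variance equals `s0^2`.
#'
#' @param s2 vector of positive residual variances (>= 10).
#' @param df common residual degrees of freedom of the fits. A vector is
#'   accepted when fits have differing df (e.g. complete-case fits);
#'   hyperparameters are then estimated from the modal-df subset.
#' @return List with `d0`, `s0_sq`, `s2_post` (moderated variances) and
#'   `df_total` (`df + d0`).
#' @export
ebayes_moderate <- function(s2, df) {
  stopifnot(length(s2) >= 10, all(s2 > 0), all(df > 0))
  if (length(df) == 1) df <- rep(df, length(s2))
  df_mode <- as.numeric(names(which.max(table(df))))
  use <- df == df_mode
  e <- log(s2[use])
  emean <- mean(e)
  evar <- var(e)
  noise <- trigamma(df_mode / 2)
  if (evar <= noise) {
    # no excess dispersion: degenerate prior at the geometric-mean
    # variance, so equal observed variances pass through unchanged and
    # the moderated t reduces exactly to the ordinary t
    d0 <- Inf
    s0_sq <- exp(emean)
    s2_post <- rep(s0_sq, length(s2))
  } else {
    d0 <- 2 * .trigamma_inverse(evar - noise)
    s0_sq <- exp(emean - digamma(df_mode / 2) + log(df_mode / 2) +
                   digamma(d0 / 2) - log(d0 / 2))
    s2_post <- (d0 * s0_sq + df * s2) / (d0 + df)
  }
  list(d0 = d0, s0_sq = s0_sq, s2_post = s2_post, df_total = df + d0)
}

#' Bonferroni family-wise control
#'
#' Flags p-values at or below `alpha / m` (ties at the threshold are
#' significant).
#'
#' @param p vector of p-values.
#' @param alpha family-wise level (default 0.05).
#' @param m number of tests (default `length(p)`).
#' @return List with logical `flags`, the `threshold` `alpha/m`, and `m`.
#' @examples
#' bonferroni(c(1e-7, 0.02), alpha = 0.05, m = 12194)$threshold
#' @export
bonferroni <- function(p, alpha = 0.05, m = length(p)) {
  stopifnot(m >= 1)
  thr <- alpha / m
  list(flags = !is.na(p) & p <= thr, threshold = thr, m = m)
}
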