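#' Clustered logistic regression via generalized estimating equations
#'
#' Fits a marginal logistic model for a binary outcome with clustering on a
#' grouping key (here: repeated alerts within a PCP), using the classic
#' iterative scheme: Fisher scoring for the regression coefficients given a
#' working correlation, moment estimation of the exchangeable correlation
#' parameter from Pearson residuals, and robust (sandwich) standard errors
#' that keep inference valid even when the working correlation is wrong.
#' With every cluster of size one the estimates coincide with ordinary
#' logistic regression.
#'
#' @param data A data frame of analysis rows.
#' @param outcome Name of a logical/0-1 outcome column; rows with `NA`
#'   outcome are dropped (with a message).
#' @param covariates Character vector of covariate column names; character
#'   columns become unordered factors. Covariate levels with zero rows are
#'   dropped with a warning.
#' @param cluster Name of the cluster-key column.
#' @param ref_levels Optional named list/character vector giving the
#'   reference level per covariate (e.g.
#'   `c(alert_type = "information_only")`).
#' @param corstr Working correlation: `"exchangeable"` (default) or
#'   `"independence"`.
#' @param maxit,tol Scoring iteration controls.
#' @return An object of class `alertlog_gee`: coefficients, robust SEs and
#'   vcov, the working-correlation estimate `alpha`, scale `phi`,
#'   `converged`, sample sizes, and factor reference metadata. Use
#'   [or_table()] for odds ratios with 95% confidence intervals.
#' @export
fit_clustered_logit <- function(data, outcome, covariates, cluster,
                                ref_levels = NULL,
                                corstr = c("exchangeable", "independence"),
                                maxit = 50L, tol = 1e-8) {
  corstr <- match.arg(corstr)
  y <- data[[outcome]]
  if (is.logical(y)) y <- as.numeric(y)
  keep <- !is.na(y)
  for (v in covariates) keep <- keep & !is.na(data[[v]])
  if (sum(!keep) > 0) {
    message(sprintf("dropping %d rows with missing outcome/covariates",
                    sum(!keep)))
  }
  y <- y[keep]
  if (length(y) == 0 || length(unique(y)) < 2) {
    rlang::abort(sprintf("outcome '%s' is constant or empty; cannot fit",
                         outcome),
                 class = "alertlog_degenerate_outcome")
  }
  covdf <- data[keep, covariates, drop = FALSE]
  refs <- list()
  for (v in covariates) {
    x <- covdf[[v]]
    if (is.character(x) || is.logical(x)) x <- factor(x)
    if (is.factor(x)) {
      empty <- setdiff(levels(x), unique(as.character(x)))
      if (length(empty) > 0) {
        rlang::warn(sprintf("covariate '%s': dropping empty level(s) %s", v,
                            paste(empty, collapse = ", ")))
        x <- droplevels(x)
      }
      if (!is.null(ref_levels) && !is.null(ref_levels[[v]])) {
        x <- stats::relevel(x, ref = ref_levels[[v]])
      }
      refs[[v]] <- levels(x)[1]
    }
    covdf[[v]] <- x
  }
  X <- stats::model.matrix(~ ., data = covdf)
  cl <- as.character(data[[cluster]][keep])
  if (length(unique(cl)) < 2) {
    rlang::abort("need at least 2 clusters", class = "alertlog_parameter_error")
  }
  fit <- gee_logit_engine(y, X, cl, corstr, maxit, tol)
  structure(
    c(fit,
      list(outcome = outcome, covariates = covariates, cluster = cluster,
           reference_levels = refs, n_rows = length(y),
           n_clusters = length(unique(cl)))),
    class = "alertlog_gee")
}

# Liang-Zeger scoring, vectorized over clusters with rowsum().
# For exchangeable R(alpha): R^-1 = [I - (alpha/(1+(n-1)alpha)) J] / (1-alpha),
# so cluster sums suffice and no per-cluster matrix inversion is needed.
gee_logit_engine <- function(y, X, cl, corstr, maxit, tol) {
  p <- ncol(X)
  cl <- factor(cl)
  csize <- as.numeric(table(cl)[levels(cl)])
  idx <- as.integer(cl)
  beta <- suppressWarnings(
    stats::glm.fit(X, y, family = stats::binomial())$coefficients)
  alpha <- 0
  converged <- FALSE
  phi <- 1
  for (it in seq_len(maxit)) {
    eta <- drop(X %*% beta)
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
    e <- (y - mu) / sqrt(w)                       # Pearson residuals
    n_tot <- length(y)
    phi <- sum(e^2) / (n_tot - p)
    if (corstr == "exchangeable") {
      se <- drop(rowsum(e, idx))
      se2 <- drop(rowsum(e^2, idx))
      npairs <- sum(csize * (csize - 1) / 2)
      alpha <- if (npairs > p) {
        sum((se^2 - se2) / 2) / ((npairs - p) * phi)
      } else 0
      alpha <- max(min(alpha, 0.99),
                   -1 / (max(csize) - 1 + 1e-8) + 1e-6)
    } else {
      alpha <- 0
    }
    cfac <- alpha / (1 + (csize - 1) * alpha)     # per cluster
    U <- X * sqrt(w)
    r <- e
    SU <- rowsum(U, idx)                          # cluster sums of U rows
    sr <- drop(rowsum(r, idx))
    # B = sum_i U_i' Rinv U_i ; score = sum_i U_i' Rinv r_i   (phi cancels)
    B <- (crossprod(U) - crossprod(SU, SU * cfac)) / (1 - alpha)
    score <- (crossprod(U, r) - crossprod(SU, cfac * sr)) / (1 - alpha)
    delta <- solve(B, score)
    beta <- beta + drop(delta)
    if (max(abs(delta)) < tol) {
      converged <- TRUE
      break
    }
  }
  # sandwich: per-cluster score contributions m_i = U_i' Rinv r_i
  eta <- drop(X %*% beta)
  mu <- stats::plogis(eta)
  w <- mu * (1 - mu)
  e <- (y - mu) / sqrt(w)
  U <- X * sqrt(w)
  SU <- rowsum(U, idx)
  sr <- drop(rowsum(e, idx))
  cfac <- alpha / (1 + (csize - 1) * alpha)
  M <- (rowsum(U * e, idx) - (cfac * sr) * SU) / (1 - alpha)
  B <- (crossprod(U) - crossprod(SU, SU * cfac)) / (1 - alpha)
  Binv <- solve(B)
  vcov <- Binv %*% crossprod(M) %*% Binv
  dimnames(vcov) <- list(colnames(X), colnames(X))
  names(beta) <- colnames(X)
  if (!converged) {
    rlang::warn("GEE scoring did not converge; estimates reported as-is")
  }
  list(coefficients = beta, vcov = vcov,
       robust_se = sqrt(diag(vcov)), alpha = alpha, phi = phi,
       converged = converged, n_iter = it)
}

#' @export
print.alertlog_gee <- function(x, ...) {
  cat(sprintf(
    "Clustered logistic GEE fit: outcome '%s', %d rows in %d clusters\n",
    x$outcome, x$n_rows, x$n_clusters))
  cat(sprintf("exchangeable correlation alpha = %.4f, converged: %s\n",
              x$alpha, x$converged))
  print(or_table(x), ...)
  invisible(x)
}

#' Odds ratios with robust 95 percent confidence intervals
#'
#' Exponentiates the non-intercept coefficients of a clustered logistic fit;
#' Wald intervals are formed on the log-odds scale with the robust standard
#' errors, then exponentiated. Reference levels (odds ratio fixed at 1) are
#' recorded per covariate.
#'
#' @param fit An `alertlog_gee` object.
#' @return A tibble with `term`, `reference`, `log_odds`, `robust_se`,
#'   `odds_ratio`, `ci_low`, `ci_high`.
#' @export
or_table <- function(fit) {
  stopifnot(inherits(fit, "alertlog_gee"))
  keep <- names(fit$coefficients) != "(Intercept)"
  est <- fit$coefficients[keep]
  se <- fit$robust_se[keep]
  term <- names(est)
  ref <- rep(NA_character_, length(term))
  for (v in names(fit$reference_levels)) {
    ref[startsWith(term, v)] <- fit$reference_levels[[v]]
  }
  z <- stats::qnorm(0.975)
  tibble::tibble(
    term = term, reference = ref, log_odds = unname(est),
    robust_se = unname(se), odds_ratio = exp(unname(est)),
    ci_low = exp(unname(est) - z * se), ci_high = exp(unname(est) + z * se))
}
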