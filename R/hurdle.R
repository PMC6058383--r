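# zero-truncated negative binomial log-likelihood (log link), parameters
# c(beta, log_theta); stable via log1p(-exp(log_p0))
.ztnb_nll <- function(par, y, Xd) {
  p <- ncol(Xd)
  beta <- par[seq_len(p)]
  theta <- exp(par[p + 1L])
  eta <- as.vector(Xd %*% beta)
  eta <- pmin(eta, 30)  # guard against overflow in exp
  mu <- exp(eta)
  log_p0 <- theta * (log(theta) - log(theta + mu))
  ll <- dnbinom(y, size = theta, mu = mu, log = TRUE) - log1p(-exp(log_p0))
  if (!all(is.finite(ll))) return(1e10)
  -sum(ll)
}

.fit_ztnb <- function(y, Xd) {
  p <- ncol(Xd)
  # deterministic restarts: Poisson-GLM start, intercept-only start,
  # method-of-moments dispersion start
  starts <- list()
  pois <- tryCatch(
    suppressWarnings(glm.fit(Xd, y, family = poisson())$coefficients),
    error = function(e) NULL)
  if (!is.null(pois) && all(is.finite(pois))) starts[[1L]] <- c(pois, 0)
  starts[[length(starts) + 1L]] <- c(log(mean(y)), rep(0, p - 1L), 0)
  v <- var(y); m <- mean(y)
  th_mom <- if (v > m) m^2 / (v - m) else 10
  starts[[length(starts) + 1L]] <- c(log(m), rep(0, p - 1L), log(max(th_mom, 1e-2)))
  best <- NULL
  for (s in starts) {
    fit <- tryCatch(
      optim(s, .ztnb_nll, y = y, Xd = Xd, method = "BFGS",
            control = list(maxit = 500, reltol = 1e-12)),
      error = function(e) NULL)
    if (is.null(fit)) next
    if (is.null(best) || fit$value < best$value) best <- fit
  }
  if (is.null(best)) .stopf("zero-truncated NB fit failed from every start")
  hess <- tryCatch(optimHess(best$par, .ztnb_nll, y = y, Xd = Xd),
                   error = function(e) NULL)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  se <- if (!is.null(vc) && all(diag(vc) > 0)) sqrt(diag(vc)) else rep(NA_real_, p + 1L)
  list(par = best$par, se = se, nll = best$value,
       converged = best$convergence == 0L && all(is.finite(se)))
}

.coef_table <- function(est, se, terms) {
  z <- est / se
  data.frame(term = terms, estimate = est, se = se, z = z,
             p = 2 * pnorm(-abs(z)), row.names = NULL, stringsAsFactors = FALSE)
}

#' Hurdle regression of counts on methylation covariates
#'
#' Two-part maximum-likelihood model for zero-inflated count responses: a
#' logistic regression for crossing the hurdle (probability that the count
#' is positive) and a zero-truncated negative binomial with log link for the
#' positive counts. Coefficient p-values are asymptotic Wald tests. The
#' truncated-NB likelihood is maximized by BFGS from three deterministic
#' starts (Poisson-GLM coefficients, intercept-only, method-of-moments
#' dispersion); non-convergence is reported in the `converged` flag, never
#' silently.
#'
#' @param y non-negative integer counts with at least one zero and one
#'   positive value.
#' @param X covariate matrix (no intercept column; one is added).
#' @return an object of class `hurdle_fit`: `zero` and `count` coefficient
#'   tables (`term, estimate, se, z, p`), `dispersion` (theta), `logLik`,
#'   `converged`, `n`.
#' @seealso [fit_negbin()] for responses without excess zeros,
#'   [q2_cross_validate()] for predictive assessment.
#' @export
fit_hurdle <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!.is_count(y)) .stopf("response must be non-negative integers")
  if (!all(is.finite(X))) .stopf("non-finite covariates")
  pos <- y > 0L
  if (!any(pos) || all(pos)) .stopf("hurdle model needs both zero and positive responses")
  terms <- c("(Intercept)", colnames(X))
  zfit <- suppressWarnings(glm(pos ~ X, family = binomial()))
  zsum <- summary(zfit)$coefficients
  zero_tab <- .coef_table(zsum[, 1L], zsum[, 2L], terms)
  Xd <- cbind(1, X[pos, , drop = FALSE])
  cfit <- .fit_ztnb(y[pos], Xd)
  p <- length(terms)
  count_tab <- .coef_table(cfit$par[seq_len(p)], cfit$se[seq_len(p)], terms)
  out <- list(
    zero = zero_tab, count = count_tab,
    dispersion = exp(cfit$par[p + 1L]),
    logLik = as.numeric(logLik(zfit)) - cfit$nll,
    converged = cfit$converged && zfit$converged,
    n = length(y), n_positive = sum(pos), kind = "hurdle"
  )
  class(out) <- c("hurdle_fit", "methkit_fit")
  out
}

#' Negative-binomial regression of counts on methylation covariates
#'
#' A log-link negative binomial fit (no hurdle), for responses in which
#' zeros are not over-represented. Thin wrapper over the standard
#' maximum-likelihood NB GLM, reported in the same coefficient-table shape
#' as [fit_hurdle()].
#'
#' @inheritParams fit_hurdle
#' @return an object of class `negbin_fit`: `count` coefficient table,
#'   `dispersion` (theta), `logLik`, `converged`, `n`.
#' @export
fit_negbin <- function(y, X) {
  X <- as.matrix(X)
  if (is.null(colnames(X))) colnames(X) <- paste0("x", seq_len(ncol(X)))
  if (!.is_count(y)) .stopf("response must be non-negative integers")
  df <- data.frame(.y = y, X, check.names = FALSE)
  form <- stats::as.formula(paste(".y ~", paste(sprintf("`%s`", colnames(X)), collapse = " + ")))
  fit <- tryCatch(suppressWarnings(MASS::glm.nb(form, data = df)),
                  error = function(e) NULL)
  if (is.null(fit)) {
    # dispersion estimation can diverge on equi- or under-dispersed counts;
    # the theta -> Inf limit of the NB is the Poisson GLM
    fit <- suppressWarnings(glm(form, data = df, family = poisson()))
    theta <- Inf
  } else {
    theta <- fit$theta
  }
  sm <- summary(fit)$coefficients
  out <- list(
    count = .coef_table(sm[, 1L], sm[, 2L], c("(Intercept)", colnames(X))),
    dispersion = theta,
    logLik = as.numeric(logLik(fit)),
    converged = isTRUE(fit$converged %||% TRUE),
    n = length(y), kind = "negbin"
  )
  class(out) <- c("negbin_fit", "methkit_fit")
  out
}

#' @export
coef.methkit_fit <- function(object, part = c("count", "zero"), ...) {
  part <- match.arg(part)
  if (part == "zero" && is.null(object$zero)) .stopf("no zero part in a %s fit", object$kind)
  setNames(object[[part]]$estimate, object[[part]]$term)
}

#' @export
logLik.methkit_fit <- function(object, ...) {
  structure(object$logLik, class = "logLik",
            df = nrow(object$count) + 1L + if (!is.null(object$zero)) nrow(object$zero) else 0L)
}

#' @export
print.methkit_fit <- function(x, ...) {
  cat(sprintf("%s fit (n = %d%s), logLik = %.2f, theta = %.3f%s\n",
              if (x$kind == "hurdle") "Hurdle (logit + zero-truncated NB)" else "Negative binomial",
              x$n,
              if (!is.null(x$n_positive)) sprintf(", %d positive", x$n_positive) else "",
              x$logLik, x$dispersion,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  if (!is.null(x$zero)) {
    cat("Zero part (logit, P[count > 0]):\n")
    print(x$zero, digits = 4)
  }
  cat("Count part (log link):\n")
  print(x$count, digits = 4)
  invisible(x)
}

#' @export
summary.methkit_fit <- function(object, ...) object

#' Predicted mean response
#'
#' For a hurdle fit, `P(count > 0) * E[count | count > 0]` with the
#' truncated-NB conditional mean `mu / (1 - P0)`; for a plain NB fit,
#' `exp(X beta)`.
#'
#' @param object a `hurdle_fit` or `negbin_fit`.
#' @param newdata covariate matrix with the columns used in fitting.
#' @param ... unused.
#' @return numeric vector of expected counts.
#' @export
predict.methkit_fit <- function(object, newdata, ...) {
  X <- cbind(1, as.matrix(newdata))
  mu <- exp(pmin(as.vector(X %*% object$count$estimate), 30))
  if (object$kind == "negbin") return(mu)
  p_pos <- plogis(as.vector(X %*% object$zero$estimate))
  theta <- object$dispersion
  p0 <- (theta / (theta + mu))^theta
  p_pos * mu / (1 - p0)
}
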