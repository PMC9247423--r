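#' Maximum-likelihood logistic regression by IRLS
#'
#' Fits a binary-outcome logistic model by iteratively reweighted least
#' squares. Convergence is declared when the largest absolute score
#' (gradient of the log-likelihood) falls below `tol_score` or the relative
#' change in deviance falls below `tol_dev`. If the fit diverges — complete
#' or quasi-complete separation, detected as exploding coefficients or
#' fitted probabilities pinned at 0/1 — the model is refitted with a small
#' ridge penalty (`ridge_lambda`, default 1e-6) and this is reported in the
#' result, never applied silently.
#'
#' @param x Numeric design matrix including an intercept column.
#' @param y 0/1 outcome vector with at least one success and one failure.
#' @param ridge Ridge penalty applied from the start (0 = plain ML).
#' @param ridge_lambda Penalty used by the separation fallback.
#' @param max_iter Maximum IRLS iterations.
#' @param tol_score,tol_dev Convergence tolerances.
#' @param stratum Optional label (e.g. `c(country = "AU", sex = "male")`)
#'   carried into the result.
#' @return A `certification_fit`: list with `coefficients`, `se`, `vcov`,
#'   `converged`, `iterations`, `deviance`, `ridge` (penalty actually
#'   used), `separation` flag, `fitted`, `stratum`, and the `design`
#'   metadata when fitted via [fit_certification()].
#' @export
fit_logistic <- function(x, y, ridge = 0, ridge_lambda = 1e-6,
                         max_iter = 100, tol_score = 1e-8, tol_dev = 1e-10,
                         stratum = NULL) {
  x_full <- as.matrix(x)
  y <- as.numeric(y)
  stopifnot(nrow(x_full) == length(y), all(y %in% c(0, 1)))
  if (sum(y) == 0 || sum(y) == length(y)) {
    stop("outcome must contain at least one success and one failure", call. = FALSE)
  }
  # indicators never observed in this cohort are aliased: drop from the fit,
  # report NA coefficients (glm-style)
  observed <- apply(x_full != 0, 2, any)
  x <- x_full[, observed, drop = FALSE]

  run_irls <- function(lambda) {
    p <- ncol(x)
    beta <- numeric(p)
    int <- which(colnames(x) == "(Intercept)")
    if (length(int) == 1) beta[int] <- qlogis(mean(y))
    dev_old <- Inf
    trace <- numeric(0)
    pen <- diag(lambda, p)
    if (length(int) == 1 && lambda > 0) pen[int, int] <- 0  # intercept unpenalized
    for (it in seq_len(max_iter)) {
      eta <- drop(x %*% beta)
      mu <- plogis(eta)
      w <- pmax(mu * (1 - mu), 1e-12)
      score <- drop(crossprod(x, y - mu)) - drop(pen %*% beta)
      info <- crossprod(x, x * w) + pen
      step <- tryCatch(solve(info, score), error = function(e) {
        solve(info + diag(1e-10, p), score)
      })
      beta <- beta + step
      eta <- drop(x %*% beta)
      mu_new <- plogis(pmin(pmax(eta, -30), 30))
      dev <- -2 * sum(y * log(pmax(mu_new, 1e-300)) +
                      (1 - y) * log(pmax(1 - mu_new, 1e-300)))
      trace <- c(trace, dev)
      rel <- abs(dev - dev_old) / (abs(dev) + 0.1)
      score_new <- drop(crossprod(x, y - plogis(drop(x %*% beta)))) -
        drop(pen %*% beta)
      if (max(abs(score_new)) < tol_score || rel < tol_dev) {
        return(list(beta = beta, converged = TRUE, iterations = it,
                    deviance = dev, trace = trace, pen = pen))
      }
      dev_old <- dev
      if (any(abs(beta) > 1e3)) {
        return(list(beta = beta, converged = FALSE, iterations = it,
                    deviance = dev, trace = trace, pen = pen,
                    diverged = TRUE))
      }
    }
    list(beta = beta, converged = FALSE, iterations = max_iter,
         deviance = dev_old, trace = trace, pen = pen)
  }

  lambda_used <- ridge
  res <- run_irls(ridge)
  separation <- FALSE
  # separation lets IRLS "converge" by score while coefficients run away
  looks_separated <- isTRUE(res$diverged) || any(abs(res$beta) > 25)
  if (looks_separated && ridge == 0) {
    separation <- TRUE
    lambda_used <- ridge_lambda
    res <- run_irls(ridge_lambda)
  }
  if (!res$converged) {
    stop("IRLS did not converge in ", max_iter, " iterations; deviance trace: ",
         paste(format(tail(res$trace, 5), digits = 8), collapse = ", "),
         call. = FALSE)
  }
  eta <- drop(x %*% res$beta)
  mu <- plogis(eta)
  w <- pmax(mu * (1 - mu), 1e-12)
  info <- crossprod(x, x * w) + res$pen
  vc <- tryCatch(solve(info), error = function(e) {
    matrix(NA_real_, ncol(x), ncol(x))
  })
  beta <- setNames(rep(NA_real_, ncol(x_full)), colnames(x_full))
  beta[observed] <- drop(res$beta)
  se <- setNames(rep(NA_real_, ncol(x_full)), colnames(x_full))
  se[observed] <- sqrt(pmax(diag(vc), 0))
  structure(list(
    coefficients = beta,
    se = se,
    vcov = vc,
    aliased = setNames(!observed, colnames(x_full)),
    converged = res$converged,
    iterations = res$iterations,
    deviance = res$deviance,
    ridge = lambda_used,
    separation = separation,
    fitted = mu,
    n = length(y),
    stratum = stratum
  ), class = "certification_fit")
}

#' @export
print.certification_fit <- function(x, ...) {
  cat("<certification_fit> ", length(x$coefficients), " terms, n = ", x$n,
      ", deviance = ", format(x$deviance, digits = 8), "\n", sep = "")
  if (!is.null(x$stratum)) {
    cat("  stratum: ", paste(names(x$stratum), x$stratum, sep = "=",
                             collapse = ", "), "\n", sep = "")
  }
  if (x$separation) cat("  separation detected; ridge penalty ", x$ridge,
                        " applied\n", sep = "")
  cat("  converged in ", x$iterations, " IRLS iterations\n", sep = "")
  invisible(x)
}

#' Coefficient table of a certification fit
#'
#' @param fit A `certification_fit`.
#' @return Tibble `term,estimate,se`.
#' @export
coef_table <- function(fit) {
  stopifnot(inherits(fit, "certification_fit"))
  tibble::tibble(term = names(fit$coefficients),
                 estimate = unname(fit$coefficients),
                 se = unname(fit$se))
}
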