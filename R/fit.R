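#' Specification of a binary-choice model
#'
#' @param outcome name of the binary outcome column.
#' @param regressors character vector of regressor column names, in display
#'   order; an intercept is always included first.
#' @param link `"logit"` or `"probit"`.
#' @param subset optional filter: a named list `list(column, value)` keeping
#'   rows where `column == value`, or NULL for the full sample.
#' @param label optional display label for rendered tables.
#' @return object of class `model_spec`.
#' @export
model_spec <- function(outcome, regressors, link = c("logit", "probit"),
                       subset = NULL, label = NULL) {
  link <- match.arg(link)
  structure(list(outcome = outcome, regressors = regressors, link = link,
                 subset = subset,
                 label = if (is.null(label)) outcome else label),
            class = "model_spec")
}

#' Maximum-likelihood fit of a binary logit or probit model
#'
#' Newton--Raphson on the full log-likelihood with analytic gradient and
#' observed-information Hessian; standard errors from the inverse observed
#' information at the optimum. Rows with a missing value in the outcome or
#' any regressor are dropped (listwise deletion). Logit fits additionally
#' report odds ratios `exp(coef)`; the pseudo-R-squared is McFadden's,
#' with the adjusted variant `1 - (LL - k)/LL0` penalising the parameter
#' count k.
#'
#' @param data data frame holding outcome and regressors.
#' @param spec a [model_spec()].
#' @param tol convergence tolerance on the score norm.
#' @param max_iter Newton iteration cap; non-convergence is flagged, not an
#'   error.
#' @return object of class `binary_fit` with coefficients, standard errors,
#'   z statistics, p-values, odds ratios (logit), log-likelihoods, McFadden
#'   and adjusted McFadden pseudo-R-squared, `n_used`, convergence metadata.
#' @export
fit_binary <- function(data, spec, tol = 1e-8, max_iter = 100L) {
  stopifnot(inherits(spec, "model_spec"))
  missing_cols <- setdiff(c(spec$outcome, spec$regressors), names(data))
  if (length(missing_cols) > 0)
    stop("columns not found: ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (!is.null(spec$subset)) {
    col <- spec$subset[[1]]
    val <- spec$subset[[2]]
    if (length(unique(stats::na.omit(data[[col]]))) < 2)
      stop("subgroup split on a constant column: ", col, call. = FALSE)
    data <- data[!is.na(data[[col]]) & data[[col]] == val, , drop = FALSE]
  }
  use <- stats::complete.cases(data[, c(spec$outcome, spec$regressors),
                                    drop = FALSE])
  d <- data[use, , drop = FALSE]
  y <- d[[spec$outcome]]
  if (!all(y %in% c(0, 1)))
    stop("outcome '", spec$outcome, "' must be coded 0/1", call. = FALSE)
  if (length(unique(y)) < 2)
    stop("outcome '", spec$outcome, "' has a single class after listwise ",
         "deletion", call. = FALSE)
  X <- cbind(`(Intercept)` = 1,
             as.matrix(d[, spec$regressors, drop = FALSE]))
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    drop_idx <- qrX$pivot[(qrX$rank + 1):ncol(X)]
    stop("design matrix is rank deficient; collinear columns: ",
         paste(colnames(X)[drop_idx], collapse = ", "), call. = FALSE)
  }

  nr <- newton_binary(X, y, spec$link, tol, max_iter)

  # separation shows up as coefficients diverging on the standardised scale
  sx <- apply(X, 2, stats::sd)
  sx[sx == 0] <- 1                     # intercept
  if (any(abs(nr$beta * sx) > 20))
    stop("perfect (or quasi-) separation detected: coefficient for ",
         paste(colnames(X)[abs(nr$beta * sx) > 20], collapse = ", "),
         " diverges", call. = FALSE)

  se <- sqrt(diag(nr$vcov))
  z <- nr$beta / se
  p <- 2 * stats::pnorm(-abs(z))
  k <- ncol(X)
  ll0 <- ll_intercept_only(y)
  mcfadden <- 1 - nr$ll / ll0
  mcfadden_adj <- 1 - (nr$ll - k) / ll0

  structure(list(
    spec = spec,
    coefficients = stats::setNames(nr$beta, colnames(X)),
    se = stats::setNames(se, colnames(X)),
    z = stats::setNames(z, colnames(X)),
    p_values = stats::setNames(p, colnames(X)),
    odds_ratios = if (spec$link == "logit")
      stats::setNames(exp(nr$beta), colnames(X)) else NULL,
    vcov = nr$vcov,
    log_lik = nr$ll, log_lik_null = ll0,
    pseudo_r2 = mcfadden, pseudo_r2_adj = mcfadden_adj,
    n_used = length(y), n_input = nrow(data),
    converged = nr$converged, iterations = nr$iterations,
    score_norm = nr$score_norm
  ), class = "binary_fit")
}

newton_binary <- function(X, y, link, tol, max_iter) {
  beta <- numeric(ncol(X))
  converged <- FALSE
  polish_done <- FALSE
  iter <- 0L
  score_norm <- Inf
  repeat {
    eta <- drop(X %*% beta)
    if (link == "logit") {
      mu <- stats::plogis(eta)
      u <- y - mu                        # d ll / d eta
      w <- mu * (1 - mu)                 # -d2 ll / d eta2 (observed = expected)
    } else {
      phi <- stats::dnorm(eta)
      Phi <- stats::pnorm(eta)
      Phi <- pmin(pmax(Phi, 1e-12), 1 - 1e-12)
      lam1 <- phi / Phi                  # inverse Mills, y = 1
      lam0 <- phi / (1 - Phi)            # y = 0
      u <- ifelse(y == 1, lam1, -lam0)
      w <- ifelse(y == 1, lam1 * (lam1 + eta), lam0 * (lam0 - eta))
      w <- pmax(w, 1e-12)
    }
    score <- drop(crossprod(X, u))
    score_norm <- sqrt(sum(score^2))
    if (score_norm <= tol) converged <- TRUE
    if (converged && polish_done) break
    if (converged) polish_done <- TRUE   # one last step: quadratic cleanup
    if (iter >= max_iter) break
    H <- crossprod(X * w, X)             # observed information
    step <- tryCatch(solve(H, score), error = function(e) {
      # a singular information matrix during iteration is the usual footprint
      # of (quasi-)separation: some coefficient is running off to infinity
      sx <- apply(X, 2, stats::sd); sx[sx == 0] <- 1
      big <- abs(beta * sx) > 5
      if (any(big))
        stop("perfect (or quasi-) separation detected: coefficient for ",
             paste(colnames(X)[big], collapse = ", "), " diverges",
             call. = FALSE)
      stop("numerical error: information matrix singular (",
           conditionMessage(e), ")", call. = FALSE)
    })
    # dampen overshooting steps far from the optimum
    if (max(abs(step)) > 10) step <- step * 10 / max(abs(step))
    beta <- beta + step
    iter <- iter + 1L
  }
  eta <- drop(X %*% beta)
  ll <- binary_loglik(y, eta, link)
  if (link == "logit") {
    mu <- stats::plogis(eta)
    w <- mu * (1 - mu)
  } else {
    phi <- stats::dnorm(eta)
    Phi <- pmin(pmax(stats::pnorm(eta), 1e-12), 1 - 1e-12)
    lam1 <- phi / Phi
    lam0 <- phi / (1 - Phi)
    w <- ifelse(y == 1, lam1 * (lam1 + eta), lam0 * (lam0 - eta))
    w <- pmax(w, 1e-12)
  }
  H <- crossprod(X * w, X)
  vc <- tryCatch(solve(H), error = function(e) matrix(NA_real_, ncol(X), ncol(X)))
  list(beta = beta, vcov = vc, ll = ll, converged = converged,
       iterations = iter, score_norm = score_norm)
}

binary_loglik <- function(y, eta, link) {
  if (link == "logit") {
    sum(y * eta - log1p(exp(pmin(eta, 700))))
  } else {
    Phi <- pmin(pmax(stats::pnorm(eta), 1e-300), 1 - 1e-16)
    sum(y * log(Phi) + (1 - y) * log1p(-Phi))
  }
}

ll_intercept_only <- function(y) {
  p <- mean(y)
  sum(y) * log(p) + sum(1 - y) * log(1 - p)
}

significance_stars <- function(p) {
  ifelse(p < 0.01, "***", ifelse(p < 0.05, "**", ifelse(p < 0.1, "*", "")))
}

#' @export
print.binary_fit <- function(x, digits = 4, ...) {
  cat(sprintf("Binary %s fit: %s ~ %s\n", x$spec$link, x$spec$outcome,
              paste(x$spec$regressors, collapse = " + ")))
  eff <- if (x$spec$link == "logit") x$odds_ratios else x$coefficients
  eff_name <- if (x$spec$link == "logit") "odds_ratio" else "coef"
  tab <- data.frame(
    round(eff, digits),
    z = round(x$z, 2),
    p = signif(x$p_values, 3),
    sig = significance_stars(x$p_values)
  )
  names(tab)[1] <- eff_name
  print(tab)
  cat(sprintf("n = %d, log-lik = %.3f, McFadden adj. R2 = %.4f%s\n",
              x$n_used, x$log_lik, x$pseudo_r2_adj,
              if (x$converged) "" else "  [NOT CONVERGED]"))
  invisible(x)
}

#' Tidy one-row-per-term summary of a fit
#' @param fit a `binary_fit`.
#' @return data frame with term, estimate, odds ratio (NA for probit),
#'   standard error, z, p and significance stars.
#' @export
fit_summary <- function(fit) {
  data.frame(
    term = names(fit$coefficients),
    estimate = unname(fit$coefficients),
    odds_ratio = if (is.null(fit$odds_ratios)) NA_real_
                 else unname(fit$odds_ratios),
    se = unname(fit$se),
    z = unname(fit$z),
    p = unname(fit$p_values),
    stars = significance_stars(unname(fit$p_values)),
    row.names = NULL
  )
}
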