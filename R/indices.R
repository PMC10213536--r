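#' Kinship index: log of total economic transfers
#'
#' Collapses the five give/receive transfer pairs (parents, children,
#' siblings, and two further relative categories) into a single intensity
#' measure, `log(1 + total)`. The `1 +` offset keeps respondents with no
#' recorded transfers at exactly 0, matching the observed minimum of the
#' index in survey data.
#'
#' @param give numeric matrix or data frame (n x 5) of amounts given, or a
#'   numeric vector for a single respondent.
#' @param receive same shape as `give`, amounts received.
#' @return numeric vector of index values, one per respondent; always >= 0.
#' @examples
#' kinship_index(rep(0, 5), rep(0, 5))           # 0
#' kinship_index(c(exp(1) - 1, 0, 0, 0, 0), rep(0, 5))  # 1
#' @export
kinship_index <- function(give, receive) {
  give <- as_amount_matrix(give, "give")
  receive <- as_amount_matrix(receive, "receive")
  if (nrow(give) != nrow(receive))
    stop("'give' and 'receive' must cover the same respondents", call. = FALSE)
  total <- rowSums(give) + rowSums(receive)
  log1p(total)
}

as_amount_matrix <- function(x, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) x <- matrix(x, nrow = 1)
  storage.mode(x) <- "double"
  bad <- !is.na(x) & x < 0
  if (any(bad))
    stop(sprintf("negative transfer amount in '%s'", what), call. = FALSE)
  x
}

#' Binary kinship indicator for robustness refits
#'
#' Recodes the transfer block to 1 when any economic transaction took place
#' and 0 otherwise (the "clan" replacement regressor).
#'
#' @inheritParams kinship_index
#' @return integer vector of 0/1.
#' @export
clan_indicator <- function(give, receive) {
  give <- as_amount_matrix(give, "give")
  receive <- as_amount_matrix(receive, "receive")
  as.integer(rowSums(give) + rowSums(receive) > 0)
}

#' Validated social-contact frequency (robustness friendship regressor)
#'
#' Pass-through for the 0--6 monthly contact-frequency item; values outside
#' the questionnaire's scale are an error rather than silently clipped.
#'
#' @param contact_freq integer vector.
#' @return the validated integer vector.
#' @export
friend_frequency <- function(contact_freq) {
  x <- contact_freq
  ok <- is.na(x) | (x >= 0 & x <= 6 & x == round(x))
  if (!all(ok))
    stop("contact_freq must be an integer in [0, 6]", call. = FALSE)
  as.integer(round(x))
}

#' Kaiser-Meyer-Olkin measure of sampling adequacy
#'
#' Overall and per-item MSA computed from the correlation matrix:
#' squared off-diagonal correlations over squared correlations plus squared
#' partial correlations, the latter obtained from the inverse correlation
#' matrix (anti-image approach).
#'
#' @param x numeric data matrix/data frame with >= 3 columns and more rows
#'   than columns, or an already-computed correlation matrix (square,
#'   symmetric, unit diagonal).
#' @return list with `kmo_overall` and named `kmo_per_item`.
#' @details With all off-diagonal correlations zero both sums vanish; the
#'   0/0 ratio is reported as 0 with a warning (there is no shared variance
#'   for a component analysis to summarise).
#' @export
kmo <- function(x) {
  R <- correlation_of(x)
  p <- ncol(R)
  Ri <- tryCatch(solve(R), error = function(e)
    stop("correlation matrix is singular; KMO undefined: ", conditionMessage(e),
         call. = FALSE))
  d <- 1 / sqrt(diag(Ri))
  P <- -Ri * tcrossprod(d)           # partial correlations, unit diagonal up to sign
  diag(P) <- 0
  Q <- R
  diag(Q) <- 0
  r2 <- Q^2
  p2 <- P^2
  num <- sum(r2)
  den <- num + sum(p2)
  if (den == 0) {
    warning("all off-diagonal correlations are zero; reporting KMO = 0")
    overall <- 0
    per_item <- rep(0, p)
  } else {
    overall <- num / den
    per_num <- rowSums(r2)
    per_den <- per_num + rowSums(p2)
    per_item <- ifelse(per_den == 0, 0, per_num / per_den)
  }
  names(per_item) <- colnames(R)
  list(kmo_overall = overall, kmo_per_item = per_item)
}

correlation_of <- function(x) {
  if (is.matrix(x) && nrow(x) == ncol(x) &&
      isTRUE(all.equal(unname(diag(x)), rep(1, ncol(x)))) &&
      isTRUE(all.equal(x, t(x)))) {
    if (is.null(colnames(x))) colnames(x) <- rownames(x) <- paste0("x", seq_len(ncol(x)))
    return(x)
  }
  if (is.data.frame(x)) x <- as.matrix(x)
  if (!is.numeric(x)) stop("'x' must be numeric", call. = FALSE)
  if (ncol(x) < 3) stop("need at least 3 indicator columns", call. = FALSE)
  if (nrow(x) <= ncol(x)) stop("need more rows than columns", call. = FALSE)
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator column: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)
  if (is.null(colnames(x))) colnames(x) <- paste0("x", seq_len(ncol(x)))
  stats::cor(x)
}

#' Friendship index: first principal component of social-interaction items
#'
#' Standardises the three friendship indicators (ceremonial/social spending,
#' guest meals last week, social activities last month), eigendecomposes
#' their correlation matrix, retains components with eigenvalue >= 1 (at
#' least one), and scores respondents on the first retained component. The
#' component sign is oriented so the spending item loads positively; scores
#' are exactly mean-centred by construction.
#'
#' @param x numeric matrix/data frame with 3 indicator columns, complete
#'   cases only.
#' @return list with `scores` (length n, mean 0) and `diagnostics`, an object
#'   of class `pca_diagnostics` carrying KMO results, eigenvalues, variance
#'   proportions, loadings and the retention count.
#' @export
friendship_index <- function(x) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (ncol(x) != 3)
    stop("friendship index expects exactly 3 indicator columns", call. = FALSE)
  if (anyNA(x))
    stop("friendship index requires complete cases; filter missing rows first",
         call. = FALSE)
  if (nrow(x) < 3) stop("need at least 3 usable rows", call. = FALSE)
  if (is.null(colnames(x)))
    colnames(x) <- c("social_spend", "guest_meals", "social_activity")
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0))
    stop("constant indicator column: ",
         paste(colnames(x)[sds == 0], collapse = ", "), call. = FALSE)

  z <- scale(x)                       # mean 0, sd 1 per column
  R <- stats::cor(x)
  eig <- eigen(R, symmetric = TRUE)
  ev <- eig$values
  loadings <- eig$vectors             # columns = components
  rownames(loadings) <- colnames(x)
  colnames(loadings) <- paste0("PC", seq_len(ncol(loadings)))
  n_retained <- max(1L, sum(ev >= 1))
  v1 <- loadings[, 1]
  if (v1[1] < 0) {                    # orient: spending item loads positively
    v1 <- -v1
    loadings[, 1] <- v1
  }
  scores <- drop(z %*% v1)

  km <- kmo(R)
  diagnostics <- structure(list(
    kmo_overall = km$kmo_overall,
    kmo_per_item = km$kmo_per_item,
    eigenvalues = ev,
    proportions = ev / sum(ev),
    cumulative = cumsum(ev / sum(ev)),
    loadings = t(loadings),           # components x indicators
    n_retained = n_retained
  ), class = "pca_diagnostics")
  list(scores = scores, diagnostics = diagnostics)
}

#' @export
print.pca_diagnostics <- function(x, digits = 4, ...) {
  cat("Principal-component diagnostics (correlation matrix)\n")
  cat(sprintf("  Overall KMO: %.*f\n", digits, x$kmo_overall))
  cat("  Per-item MSA:\n")
  for (nm in names(x$kmo_per_item))
    cat(sprintf("    %-16s %.*f\n", nm, digits, x$kmo_per_item[[nm]]))
  tab <- data.frame(
    eigenvalue = round(x$eigenvalues, digits + 1),
    proportion = round(x$proportions, digits),
    cumulative = round(x$cumulative, digits)
  )
  rownames(tab) <- paste0("Comp", seq_along(x$eigenvalues))
  print(tab)
  cat(sprintf("  Components retained (eigenvalue >= 1): %d\n", x$n_retained))
  invisible(x)
}

#' Attach all tie-strength indices to a respondent table
#'
#' Computes `hosnet_R` (kinship log-sum), `hosnet_F` (friendship first-PC
#' score), `clan` and `friend` and binds them as columns. `hosnet_F` is
#' computed on rows with complete friendship indicators; other rows get NA.
#'
#' @param data respondent table as produced by [generate_population()].
#' @return list with `data` (the table plus index columns) and `diagnostics`
#'   (the [friendship_index()] PCA/KMO diagnostics).
#' @export
add_indices <- function(data) {
  gv <- data[, paste0("transfers_give", 1:5), drop = FALSE]
  rc <- data[, paste0("transfers_receive", 1:5), drop = FALSE]
  data$hosnet_R <- kinship_index(gv, rc)
  data$clan <- clan_indicator(gv, rc)
  data$friend <- friend_frequency(data$contact_freq)

  ind <- as.matrix(data[, c("social_spend", "guest_meals", "social_activity")])
  cc <- stats::complete.cases(ind)
  fi <- friendship_index(ind[cc, , drop = FALSE])
  data$hosnet_F <- NA_real_
  data$hosnet_F[cc] <- fi$scores
  list(data = data, diagnostics = fi$diagnostics)
}
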