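#' Configuration for the synthetic survey-microdata generator
#'
#' Bundles every knob of the data-generating process: sample size, seed,
#' covariate distribution parameters (calibrated to the descriptive first
#' moments of the CHARLS-2018-style variable set), the zero-inflated
#' log-normal transfer model behind the kinship index, the friendship
#' indicator distributions, the true logit coefficients of the care-choice
#' outcome, and the mediation coefficients of the supplementary-medical-
#' insurance channel.
#'
#' Coefficients are on the log-odds scale. Defaults reproduce the headline
#' odds ratios of the care-choice model (kinship index 1.091, friendship
#' index 1.128, age 1.036, insurance 1.736, east-province 1.318, medical
#' 1.8, ...) with baseline formal-care prevalence of about 0.1975, kinship
#' index mean about 1.50 with minimum 0, and an any-transfer share of about
#' 0.546.
#'
#' @param n sample size (positive integer).
#' @param seed RNG seed, or NULL to leave the RNG state untouched.
#' @param covariate_params named list of distribution parameters, see
#'   defaults in the source.
#' @param transfer_params list with `p_zero` (per-category probability of no
#'   transfer, 10 give/receive categories), `meanlog`, `sdlog` of the
#'   log-normal amount for non-zero cells.
#' @param friendship_params distributions of the three friendship
#'   indicators (zero-inflated log-normal spending, zero-inflated Poisson
#'   guest meals, Poisson activity count).
#' @param contact_probs length-7 probability vector over contact-frequency
#'   values 0..6.
#' @param true_logit_coefs named numeric vector: intercept plus one
#'   coefficient per care-choice regressor, in the order
#'   `intercept, hosnet_R, hosnet_F, medical, age, gender, edu, married,
#'   health, insurance, l_expen, family, urban, province`.
#' @param mediation_coefs named numeric vector `intercept, hosnet_R,
#'   hosnet_F` of the supplementary-medical-insurance logit.
#' @param hosnet_R_or_by_urban optional length-2 vector `c(rural, urban)` of
#'   odds ratios replacing the kinship coefficient per stratum, for
#'   heterogeneity power studies; NULL for a homogeneous effect.
#' @param missing_rate probability, per field and respondent, of an
#'   independently missing value (0 disables missingness).
#' @return object of class `generator_config`.
#' @export
generator_config <- function(n = 10000,
                             seed = NULL,
                             covariate_params = list(),
                             transfer_params = list(),
                             friendship_params = list(),
                             contact_probs = NULL,
                             true_logit_coefs = NULL,
                             mediation_coefs = NULL,
                             hosnet_R_or_by_urban = NULL,
                             missing_rate = 0) {
  if (!is.numeric(n) || length(n) != 1 || is.na(n) || n <= 0 || n != round(n))
    stop("configuration error: 'n' must be a positive integer", call. = FALSE)

  cov_def <- list(
    age_mean = 64.8572, age_sd = 10.2065, age_min = 45,
    gender = 0.4730, edu = 0.1269, married = 0.8508, health = 0.2501,
    insurance = 0.9697,
    l_expen_mean = 7.1346, l_expen_sd = 1.0272,
    family_mean = 3.07, family_sd = 1.8437, family_max = 20,
    urban = 0.2888, province = 0.3090
  )
  tr_def <- list(p_zero = 0.9240715, meanlog = 1.873, sdlog = 2.3)
  fr_def <- list(spend_p_zero = 0.45, spend_meanlog = 6.2, spend_sdlog = 1.4,
                 meals_p_zero = 0.70, meals_lambda = 4,
                 activity_lambda = 0.8, latent_rho = 0.08)
  cp_def <- c(0.65, 0.17, 0.08, 0.045, 0.025, 0.02, 0.01)
  lc_def <- c(intercept = -4.9041,
              hosnet_R = log(1.091), hosnet_F = log(1.128),
              medical = log(1.8),
              age = log(1.036), gender = log(1.048), edu = log(0.914),
              married = log(0.881), health = log(1.069),
              insurance = log(1.736), l_expen = log(1.032),
              family = log(1.010), urban = log(1.007),
              province = log(1.318))
  mc_def <- c(intercept = stats::qlogis(0.30),
              hosnet_R = log(1.004), hosnet_F = log(1.082))

  cfg <- list(
    n = as.integer(n),
    seed = seed,
    covariate_params = utils::modifyList(cov_def, covariate_params),
    transfer_params = utils::modifyList(tr_def, transfer_params),
    friendship_params = utils::modifyList(fr_def, friendship_params),
    contact_probs = if (is.null(contact_probs)) cp_def else contact_probs,
    true_logit_coefs = if (is.null(true_logit_coefs)) lc_def else true_logit_coefs,
    mediation_coefs = if (is.null(mediation_coefs)) mc_def else mediation_coefs,
    hosnet_R_or_by_urban = hosnet_R_or_by_urban,
    missing_rate = missing_rate
  )

  if (length(cfg$true_logit_coefs) != length(lc_def) ||
      !identical(names(cfg$true_logit_coefs), names(lc_def)))
    stop("configuration error: 'true_logit_coefs' must be named and match ",
         "the regressor count of the care-choice model (",
         length(lc_def), " entries: ",
         paste(names(lc_def), collapse = ", "), ")", call. = FALSE)
  if (length(cfg$mediation_coefs) != 3)
    stop("configuration error: 'mediation_coefs' needs intercept, hosnet_R, ",
         "hosnet_F", call. = FALSE)
  if (length(cfg$contact_probs) != 7 || any(cfg$contact_probs < 0) ||
      abs(sum(cfg$contact_probs) - 1) > 1e-8)
    stop("configuration error: 'contact_probs' must be 7 probabilities ",
         "summing to 1", call. = FALSE)
  if (!is.null(cfg$hosnet_R_or_by_urban) &&
      (length(cfg$hosnet_R_or_by_urban) != 2 ||
       any(cfg$hosnet_R_or_by_urban <= 0)))
    stop("configuration error: 'hosnet_R_or_by_urban' must be two positive ",
         "odds ratios c(rural, urban)", call. = FALSE)
  if (cfg$missing_rate < 0 || cfg$missing_rate >= 1)
    stop("configuration error: 'missing_rate' must be in [0, 1)", call. = FALSE)
  pz <- cfg$transfer_params$p_zero
  if (pz < 0 || pz > 1)
    stop("configuration error: transfer 'p_zero' must be in [0, 1]",
         call. = FALSE)
  class(cfg) <- "generator_config"
  cfg
}

#' Column order of a respondent table
#' @return character vector of the documented column names, in file order.
#' @export
respondent_columns <- function() {
  c("id", "age", "gender", "edu", "married", "health", "insurance",
    "l_expen", "family", "urban", "province",
    paste0("transfers_give", 1:5), paste0("transfers_receive", 1:5),
    "social_spend", "guest_meals", "social_activity", "contact_freq",
    "medical", "care_all")
}

#' Generate a synthetic respondent table with a known data-generating process
#'
#' Draws covariates, the transfer block, friendship indicators and contact
#' frequency; derives the kinship and friendship indices with the same
#' functions used downstream; then draws the supplementary-medical-insurance
#' indicator from its mediation logit and finally the formal-care choice
#' from the full logit whose coefficients are `config$true_logit_coefs`.
#' Because the outcome depends on the data only through the derived indices,
#' re-deriving the indices and refitting the same logit exactly inverts the
#' process, which is what the parameter-recovery tests exploit.
#'
#' @param config a [generator_config()].
#' @return data frame, one row per respondent, columns as in
#'   [respondent_columns()].
#' @export
generate_population <- function(config = generator_config()) {
  if (!inherits(config, "generator_config"))
    config <- do.call(generator_config, config)
  if (!is.null(config$seed)) set.seed(config$seed)
  n <- config$n
  cv <- config$covariate_params

  age <- round(rtruncnorm_left(n, cv$age_mean, cv$age_sd, cv$age_min))
  gender <- stats::rbinom(n, 1, cv$gender)
  edu <- stats::rbinom(n, 1, cv$edu)
  married <- stats::rbinom(n, 1, cv$married)
  health <- stats::rbinom(n, 1, cv$health)
  insurance <- stats::rbinom(n, 1, cv$insurance)
  l_expen <- stats::rnorm(n, cv$l_expen_mean, cv$l_expen_sd)
  family <- pmin(cv$family_max, round(rtruncnorm_left(n, cv$family_mean,
                                                      cv$family_sd, 0)))
  urban <- stats::rbinom(n, 1, cv$urban)
  province <- stats::rbinom(n, 1, cv$province)

  tp <- config$transfer_params
  transfers <- matrix(0, n, 10)
  nz <- matrix(stats::runif(n * 10) >= tp$p_zero, n, 10)
  k <- sum(nz)
  if (k > 0)
    transfers[nz] <- stats::rlnorm(k, tp$meanlog, tp$sdlog)
  give <- transfers[, 1:5, drop = FALSE]
  receive <- transfers[, 6:10, drop = FALSE]

  # Friendship indicators share a latent sociability factor via a Gaussian
  # copula (equicorrelation latent_rho), giving the weak positive pairwise
  # correlations such interaction items show in survey data.
  fp <- config$friendship_params
  rho <- fp$latent_rho
  z0 <- stats::rnorm(n)
  U <- stats::pnorm(sqrt(rho) * z0 +
                    sqrt(1 - rho) * matrix(stats::rnorm(n * 3), n, 3))
  zi_quantile <- function(u, p_zero, qfun, ...) {
    out <- numeric(length(u))
    pos <- u >= p_zero
    out[pos] <- qfun((u[pos] - p_zero) / (1 - p_zero), ...)
    out
  }
  social_spend <- zi_quantile(U[, 1], fp$spend_p_zero, stats::qlnorm,
                              fp$spend_meanlog, fp$spend_sdlog)
  guest_meals <- zi_quantile(U[, 2], fp$meals_p_zero, stats::qpois,
                             fp$meals_lambda)
  social_activity <- stats::qpois(U[, 3], fp$activity_lambda)
  contact_freq <- sample(0:6, n, replace = TRUE, prob = config$contact_probs)

  hosnet_R <- kinship_index(give, receive)
  hosnet_F <- friendship_index(cbind(social_spend = social_spend,
                                     guest_meals = guest_meals,
                                     social_activity = social_activity))$scores

  mc <- config$mediation_coefs
  medical <- stats::rbinom(n, 1, stats::plogis(
    mc[[1]] + mc[[2]] * hosnet_R + mc[[3]] * hosnet_F))

  b <- config$true_logit_coefs
  b_R <- rep(b[["hosnet_R"]], n)
  if (!is.null(config$hosnet_R_or_by_urban))
    b_R <- log(config$hosnet_R_or_by_urban)[urban + 1L]
  lp <- b[["intercept"]] + b_R * hosnet_R + b[["hosnet_F"]] * hosnet_F +
    b[["medical"]] * medical + b[["age"]] * age + b[["gender"]] * gender +
    b[["edu"]] * edu + b[["married"]] * married + b[["health"]] * health +
    b[["insurance"]] * insurance + b[["l_expen"]] * l_expen +
    b[["family"]] * family + b[["urban"]] * urban +
    b[["province"]] * province
  care_all <- stats::rbinom(n, 1, stats::plogis(lp))

  out <- data.frame(
    id = seq_len(n), age = age, gender = gender, edu = edu,
    married = married, health = health, insurance = insurance,
    l_expen = l_expen, family = family, urban = urban, province = province,
    give, receive,
    social_spend = social_spend, guest_meals = guest_meals,
    social_activity = social_activity, contact_freq = contact_freq,
    medical = medical, care_all = care_all
  )
  names(out)[12:21] <- c(paste0("transfers_give", 1:5),
                         paste0("transfers_receive", 1:5))

  if (config$missing_rate > 0) {
    for (col in setdiff(names(out), "id")) {
      miss <- stats::runif(n) < config$missing_rate
      out[[col]][miss] <- NA
    }
  }
  out[] <- lapply(out, as.numeric)  # uniform storage; CSV round-trip exact
  out[, respondent_columns()]
}

# Left-truncated normal draw by inverse-CDF; exact and vectorised.
rtruncnorm_left <- function(n, mean, sd, lower) {
  p_lo <- stats::pnorm(lower, mean, sd)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mean, sd)
}
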