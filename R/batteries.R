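#' Control-variable set of the care-choice models
#'
#' Ten controls spanning personal characteristics (age, gender, education,
#' marital status, health, social security), family characteristics (log
#' household expenditure, household size) and regional characteristics
#' (urban and east-province dummies).
#' @return character vector of column names.
#' @export
care_controls <- function() {
  c("age", "gender", "edu", "married", "health", "insurance",
    "l_expen", "family", "urban", "province")
}

battery <- function(fits) structure(fits, class = "fit_battery")

#' Baseline care-choice regressions
#'
#' Four logit fits: the kinship index alone and with all controls, then the
#' friendship index alone and with all controls. Fitting the core regressor
#' with and without controls shows whether its estimate is stable to
#' conditioning, the usual informal check against omitted-variable artefacts.
#'
#' @param data respondent table with index columns (see [add_indices()]).
#' @return named list of class `fit_battery` with elements
#'   `kinship_core`, `kinship_full`, `friendship_core`, `friendship_full`.
#' @export
baseline_battery <- function(data) {
  ctl <- care_controls()
  battery(list(
    kinship_core = fit_binary(data, model_spec("care_all", "hosnet_R",
                                               label = "Kinship (1)")),
    kinship_full = fit_binary(data, model_spec("care_all",
                                               c("hosnet_R", ctl),
                                               label = "Kinship (2)")),
    friendship_core = fit_binary(data, model_spec("care_all", "hosnet_F",
                                                  label = "Friendship (1)")),
    friendship_full = fit_binary(data, model_spec("care_all",
                                                  c("hosnet_F", ctl),
                                                  label = "Friendship (2)"))
  ))
}

#' Robustness refits: replacement regressors and probit link
#'
#' Two logit fits replacing the indices with their cruder counterparts (the
#' binary any-transfer indicator `clan`, the 0--6 contact frequency
#' `friend`) and two probit re-estimations of the original indices. Probit
#' fits report coefficients rather than odds ratios.
#'
#' @inheritParams baseline_battery
#' @return `fit_battery` with elements `clan_logit`, `friend_logit`,
#'   `kinship_probit`, `friendship_probit`.
#' @export
robustness_battery <- function(data) {
  ctl <- care_controls()
  battery(list(
    clan_logit = fit_binary(data, model_spec("care_all", c("clan", ctl),
                                             label = "Logit (1)")),
    friend_logit = fit_binary(data, model_spec("care_all", c("friend", ctl),
                                               label = "Logit (2)")),
    kinship_probit = fit_binary(data, model_spec("care_all",
                                                 c("hosnet_R", ctl),
                                                 link = "probit",
                                                 label = "Probit (1)")),
    friendship_probit = fit_binary(data, model_spec("care_all",
                                                    c("hosnet_F", ctl),
                                                    link = "probit",
                                                    label = "Probit (2)"))
  ))
}

#' Heterogeneity analysis: province and urban/rural subgroups
#'
#' Eight logit fits: each index re-estimated on the east-province,
#' mid-west, urban and rural subsamples. The splitting dummy is dropped
#' from the control set within its own split (it is constant there).
#'
#' @inheritParams baseline_battery
#' @return `fit_battery` with elements named `<index>_<subgroup>` for
#'   subgroups `east`, `midwest`, `urban`, `rural`.
#' @export
heterogeneity_battery <- function(data) {
  ctl <- care_controls()
  splits <- list(east = list("province", 1), midwest = list("province", 0),
                 urban = list("urban", 1), rural = list("urban", 0))
  fits <- list()
  for (index in c("hosnet_R", "hosnet_F")) {
    for (sg in names(splits)) {
      drop_col <- splits[[sg]][[1]]
      fits[[paste0(index, "_", sg)]] <- fit_binary(
        data, model_spec("care_all", c(index, setdiff(ctl, drop_col)),
                         subset = splits[[sg]],
                         label = paste(index, sg)))
    }
  }
  battery(fits)
}

#' Mechanism regressions: the medical-insurance channel
#'
#' For each index, three logit fits tracing the information channel from
#' tie strength to formal-care demand: (1) supplementary medical insurance
#' on the index and controls, (2) care choice on medical plus the index and
#' controls, (3) the same model restricted to healthy respondents --- if
#' tie-transmitted risk information (not own health shocks) drives demand,
#' the medical effect should persist there.
#'
#' @inheritParams baseline_battery
#' @return `fit_battery` with elements `<index>_medical`, `<index>_care`,
#'   `<index>_care_healthy` for each of `hosnet_R`, `hosnet_F`.
#' @export
mechanism_battery <- function(data) {
  ctl <- care_controls()
  fits <- list()
  for (index in c("hosnet_R", "hosnet_F")) {
    fits[[paste0(index, "_medical")]] <- fit_binary(
      data, model_spec("medical", c(index, ctl),
                       label = paste(index, "medical (1)")))
    fits[[paste0(index, "_care")]] <- fit_binary(
      data, model_spec("care_all", c("medical", index, ctl),
                       label = paste(index, "care_all (2)")))
    fits[[paste0(index, "_care_healthy")]] <- fit_binary(
      data, model_spec("care_all", c("medical", index, setdiff(ctl, "health")),
                       subset = list("health", 1),
                       label = paste(index, "care_all (3), healthy")))
  }
  battery(fits)
}

#' Flatten a battery into one long summary table
#' @param fits a `fit_battery`.
#' @return data frame with one row per model term, including model label,
#'   link, n and adjusted pseudo-R-squared.
#' @export
battery_summary <- function(fits) {
  do.call(rbind, lapply(names(fits), function(nm) {
    f <- fits[[nm]]
    s <- fit_summary(f)
    cbind(model = nm, label = f$spec$label, link = f$spec$link, s,
          n = f$n_used, pseudo_r2_adj = f$pseudo_r2_adj)
  }))
}

#' @export
print.fit_battery <- function(x, ...) {
  cat(render_battery(x), sep = "\n")
  invisible(x)
}

#' Render a battery as an aligned plain-text regression table
#'
#' One column per model; effect sizes (odds ratios for logit, coefficients
#' for probit) with z statistics in parentheses; significance stars at the
#' 10/5/1% levels; sample size and adjusted pseudo-R-squared rows.
#'
#' @param fits a `fit_battery`.
#' @return character vector of lines.
#' @export
render_battery <- function(fits) {
  terms <- unique(unlist(lapply(fits, function(f)
    setdiff(names(f$coefficients), "(Intercept)"))))
  header <- c("Variable", vapply(fits, function(f) f$spec$label, ""))
  rows <- lapply(terms, function(tm) {
    cells <- vapply(fits, function(f) {
      if (!tm %in% names(f$coefficients)) return("-")
      eff <- if (f$spec$link == "logit") f$odds_ratios[[tm]]
             else f$coefficients[[tm]]
      sprintf("%.3f%s (%.2f)", eff,
              significance_stars(f$p_values[[tm]]), f$z[[tm]])
    }, "")
    c(tm, cells)
  })
  rows <- c(rows,
            list(c("Sample size",
                   vapply(fits, function(f) format(f$n_used), ""))),
            list(c("Adjusted R-squared",
                   vapply(fits, function(f) sprintf("%.4f", f$pseudo_r2_adj),
                          ""))))
  tab <- do.call(rbind, c(list(header), rows))
  widths <- apply(nchar(tab), 2, max)
  apply(tab, 1, function(r)
    paste(mapply(formatC, r, width = widths, flag = "-"), collapse = "  "))
}
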