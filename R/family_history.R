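#' Parental dyslipidemia exposure
#'
#' For each offspring with at least one parent of known disease status,
#' counts affected parents (among parents with known status) and assigns
#' the exposure category `no_affected_parent`, `at_least_one` or `both`.
#' Offspring with no parent of known status are omitted with a message.
#'
#' @param ped A `pedigree`.
#' @param statuses Table with `person_id` and logical `status`
#'   (e.g. from [dyslipidemia_status()]).
#' @return Tibble with `person_id`, `outcome` (own status, `NA` if
#'   unknown), `exposure`, `n_affected_parents`, `n_known_parents`.
#' @export
parental_exposure <- function(ped, statuses) {
  stopifnot(inherits(ped, "pedigree"))
  st <- stats::setNames(statuses$status, statuses$person_id)
  off <- ped[!is.na(ped$father_id) | !is.na(ped$mother_id), ]
  if (nrow(off) == 0) {
    return(tibble::tibble(person_id = character(), outcome = logical(),
                          exposure = character(),
                          n_affected_parents = integer(),
                          n_known_parents = integer()))
  }
  pstat <- cbind(st[off$father_id], st[off$mother_id])
  n_known <- rowSums(!is.na(pstat))
  n_aff <- rowSums(pstat, na.rm = TRUE)
  keep <- n_known > 0
  if (any(!keep)) {
    rlang::inform(paste0(sum(!keep),
                         " offspring with no parent of known status omitted"))
  }
  tibble::tibble(
    person_id = off$individual_id[keep],
    outcome = unname(st[off$individual_id[keep]]),
    exposure = dplyr::case_when(
      n_aff[keep] == 0 ~ "no_affected_parent",
      n_aff[keep] == n_known[keep] & n_known[keep] == 2 ~ "both",
      TRUE ~ "at_least_one"),
    n_affected_parents = as.integer(n_aff[keep]),
    n_known_parents = as.integer(n_known[keep]))
}

#' Family-history odds ratio from a logistic model
#'
#' Fits a maximum-likelihood logistic regression (iteratively reweighted
#' least squares via [stats::glm()], coefficient tolerance 1e-8, at most
#' 100 iterations) of the outcome on a binary family-history exposure
#' contrast, adjusted for the requested covariates, and returns the
#' exposure odds ratio with its Wald 95\% confidence interval from the
#' observed information.
#'
#' When `both` is pooled into the exposed group (the default contrast
#' `"at_least_one"`), the comparison is >= 1 affected parent versus none;
#' the `"both"` contrast compares both-affected versus none, dropping the
#' one-affected category.
#'
#' @param records Tibble from [parental_exposure()] joined with `age` and
#'   `sex` columns; `outcome` must be logical with both classes present.
#' @param contrast `"at_least_one"` (pools `both`) or `"both"`.
#' @param covariates Covariate column names (default `c("age", "sex")`);
#'   constant columns are dropped with a message (e.g. `sex` within a
#'   single-sex stratum).
#' @param stratum Label stored in the result (default `"total"`).
#' @param trait Optional trait label stored in the result.
#' @return One-row tibble: `trait`, `stratum`, `contrast`, `odds_ratio`,
#'   `ci_low`, `ci_high`, `n`, `n_cases`.
#' @export
fit_logistic_or <- function(records, contrast = c("at_least_one", "both"),
                            covariates = c("age", "sex"),
                            stratum = "total", trait = "dyslipidemia") {
  contrast <- match.arg(contrast)
  df <- tibble::as_tibble(records)
  df <- df[!is.na(df$outcome) & !is.na(df$exposure), ]
  if (contrast == "at_least_one") {
    df$exposed <- df$exposure %in% c("at_least_one", "both")
  } else {
    df <- df[df$exposure %in% c("no_affected_parent", "both"), ]
    df$exposed <- df$exposure == "both"
  }
  for (lev in c(TRUE, FALSE)) {
    sub <- df$outcome[df$exposed == lev]
    if (sum(sub) == 0 || sum(!sub) == 0) {
      stop("fit_logistic_or: need at least one case and one control in ",
           "each exposure level")
    }
  }
  covariates <- intersect(covariates, names(df))
  keep <- vapply(covariates, function(v)
    length(unique(stats::na.omit(df[[v]]))) > 1, logical(1))
  if (any(!keep)) {
    rlang::inform(paste0("dropping constant covariate(s): ",
                         paste(covariates[!keep], collapse = ", ")))
  }
  covariates <- covariates[keep]
  fml <- stats::reformulate(c("exposed", covariates), response = "outcome")
  fit <- stats::glm(fml, data = df, family = stats::binomial(),
                    control = stats::glm.control(epsilon = 1e-8, maxit = 100))
  if (!fit$converged) stop("fit_logistic_or: IRLS did not converge")
  mu <- stats::fitted(fit)
  if (any(mu < 1e-10) || any(mu > 1 - 1e-10) ||
      abs(stats::coef(fit)[["exposedTRUE"]]) > 15) {
    stop("fit_logistic_or: (quasi-)perfect separation detected; ",
         "the exposure effect is not identifiable")
  }
  beta <- stats::coef(fit)[["exposedTRUE"]]
  se <- sqrt(diag(stats::vcov(fit)))[["exposedTRUE"]]
  tibble::tibble(trait = trait, stratum = stratum, contrast = contrast,
                 odds_ratio = exp(beta),
                 ci_low = exp(beta - 1.96 * se),
                 ci_high = exp(beta + 1.96 * se),
                 n = nrow(df), n_cases = sum(df$outcome))
}

#' Family-history odds-ratio table
#'
#' Runs [fit_logistic_or()] for both exposure contrasts in the three
#' strata (total, males, females), mirroring a family-history
#' forest-plot layout. Strata or contrasts that cannot be fitted (no
#' cases, separation) are skipped with a message.
#'
#' @param records Output of [parental_exposure()] joined with `age` and
#'   `sex`.
#' @inheritParams fit_logistic_or
#' @return Tibble of OR rows.
#' @export
family_history_or <- function(records, covariates = c("age", "sex"),
                              trait = "dyslipidemia") {
  strata <- list(total = rep(TRUE, nrow(records)),
                 males = records$sex == "male",
                 females = records$sex == "female")
  grid <- tidyr::expand_grid(stratum = names(strata),
                             contrast = c("at_least_one", "both"))
  empty <- tibble::tibble(trait = character(), stratum = character(),
                          contrast = character(), odds_ratio = double(),
                          ci_low = double(), ci_high = double(),
                          n = integer(), n_cases = integer())
  dplyr::bind_rows(empty, purrr::pmap_dfr(grid, function(stratum, contrast) {
    sub <- records[strata[[stratum]], ]
    tryCatch(
      fit_logistic_or(sub, contrast = contrast, covariates = covariates,
                      stratum = stratum, trait = trait),
      error = function(e) {
        rlang::inform(paste0("skipping ", stratum, "/", contrast, ": ",
                             conditionMessage(e)))
        NULL
      })
  }))
}

#' Forest plot of family-history odds ratios
#'
#' @param or_table Tibble from [family_history_or()].
#' @return A ggplot.
#' @export
plot_or <- function(or_table) {
  ggplot2::ggplot(or_table,
                  ggplot2::aes(x = .data$odds_ratio, y = .data$stratum,
                               colour = .data$contrast)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 1, linetype = 2) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(~trait) +
    ggplot2::labs(x = "odds ratio (95% CI)", y = NULL,
                  title = "Offspring dyslipidemia risk by parental history")
}
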