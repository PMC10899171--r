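#' Friedewald LDL-C
#'
#' Derived low-density lipoprotein cholesterol from total cholesterol,
#' HDL-C and triglycerides: `ldl = tc - hdl - tg / 5` (all mg/dL). The
#' formula is invalid at high triglycerides; values with `tg >= 400` are
#' returned as `NA`.
#'
#' @param tc,hdl,tg Numeric vectors, mg/dL, all positive.
#' @param tg_max Upper triglyceride validity bound (default 400 mg/dL).
#' @param formula Optional replacement `function(tc, hdl, tg)` for the
#'   LDL derivation; when supplied, `tg_max` masking still applies.
#' @return Numeric vector of LDL-C (mg/dL), `NA` where invalid.
#' @export
#' @examples
#' friedewald_ldl(200, 50, 100)  # 130
friedewald_ldl <- function(tc, hdl, tg, tg_max = 400, formula = NULL) {
  ok <- !is.na(tc) & !is.na(hdl) & !is.na(tg)
  if (any(ok & (tc <= 0 | hdl <= 0 | tg <= 0))) {
    stop("friedewald_ldl: tc, hdl and tg must be positive")
  }
  ldl <- if (is.null(formula)) tc - hdl - tg / 5 else formula(tc, hdl, tg)
  ldl[!ok | tg >= tg_max] <- NA_real_
  ldl
}

#' Adjust total cholesterol for lipid-lowering medication
#'
#' Measured TC under lipid-lowering treatment underestimates the
#' untreated level; treated values are divided by 0.8.
#'
#' @param tc Numeric vector, mg/dL, positive.
#' @param drug Logical vector: on lipid-lowering medication.
#' @param divisor Adjustment divisor (default 0.8).
#' @return Adjusted TC vector.
#' @export
adjust_tc_for_medication <- function(tc, drug, divisor = 0.8) {
  if (any(tc <= 0, na.rm = TRUE)) stop("tc must be positive")
  drug <- !is.na(drug) & drug
  ifelse(drug, tc / divisor, tc)
}

#' ATP III lipid flags
#'
#' Adds the four ATP III dyslipidemia indicator columns to a measurement
#' table: high TC (>= 200 mg/dL), high TG (>= 200 mg/dL), high LDL-C
#' (>= 160 mg/dL), and low HDL-C (< 40 mg/dL for men, < 50 mg/dL for
#' women).
#'
#' @param data Data frame with columns `sex` (`"male"`/`"female"`) and any
#'   of `tc`, `tg`, `hdl`, `ldl` (mg/dL; `NA` allowed).
#' @param thresholds Named list overriding the cut-points
#'   (`tc`, `tg`, `ldl`, `hdl_male`, `hdl_female`).
#' @return `data` as a tibble with logical columns `high_tc`, `high_tg`,
#'   `low_hdl`, `high_ldl` appended (`NA` where the measurement is
#'   missing).
#' @export
classify_lipid_flags <- function(data, thresholds = list()) {
  th <- utils::modifyList(
    list(tc = 200, tg = 200, ldl = 160, hdl_male = 40, hdl_female = 50),
    thresholds)
  data <- tibble::as_tibble(data)
  has <- function(col) col %in% names(data)
  if (has("hdl") && (!has("sex") || anyNA(data$sex[!is.na(data$hdl)]))) {
    stop("classify_lipid_flags: sex is required to flag HDL-C")
  }
  dplyr::mutate(
    data,
    high_tc = if (has("tc")) .data$tc >= th$tc else NA,
    high_tg = if (has("tg")) .data$tg >= th$tg else NA,
    low_hdl = if (has("hdl")) {
      .data$hdl < ifelse(.data$sex == "male", th$hdl_male, th$hdl_female)
    } else NA,
    high_ldl = if (has("ldl")) .data$ldl >= th$ldl else NA
  )
}

# shared eligibility filter for the FM/AM scenario builders
eligible_phases <- function(data, min_age) {
  data <- tibble::as_tibble(data)
  stopifnot(all(c("person_id", "phase", "age") %in% names(data)))
  data <- dplyr::arrange(data, .data$person_id, .data$phase)
  elig <- dplyr::filter(data, .data$age >= min_age)
  dropped <- setdiff(unique(data$person_id), unique(elig$person_id))
  if (length(dropped) > 0) {
    rlang::inform(paste0(length(dropped),
                         " person(s) never reach age ", min_age,
                         " and are dropped from the scenario table"))
  }
  elig
}

#' First-measurement (FM) scenario table
#'
#' One row per person: the earliest phase at which the person is at least
#' `min_age` years old. Persons never reaching `min_age` are dropped with
#' a message.
#'
#' @param data Longitudinal phenotype table with `person_id`, `phase`,
#'   `age`, `sex` and trait columns.
#' @param traits Trait columns to carry (default the lipid four).
#' @param min_age Eligibility age in years (default 18).
#' @return Tibble with `scenario = "FM"`, one row per eligible person.
#' @export
first_measurement <- function(data, traits = c("tc", "tg", "hdl", "ldl"),
                              min_age = 18) {
  traits <- intersect(traits, names(data))
  elig <- eligible_phases(data, min_age)
  out <- dplyr::slice_min(dplyr::group_by(elig, .data$person_id),
                          .data$phase, n = 1, with_ties = FALSE)
  out <- dplyr::ungroup(out)
  dplyr::select(dplyr::mutate(out, scenario = "FM"),
                "person_id", "scenario", "phase", "age", "sex",
                dplyr::all_of(traits))
}

#' Average-measurement (AM) scenario table
#'
#' One row per person: the arithmetic mean of each trait over that
#' person's eligible (`age >= min_age`) phases with a non-missing value,
#' together with the per-trait phase count (`n_<trait>`). Availability may
#' differ by trait.
#'
#' @inheritParams first_measurement
#' @return Tibble with `scenario = "AM"`, one row per eligible person.
#' @export
average_measurement <- function(data, traits = c("tc", "tg", "hdl", "ldl"),
                                min_age = 18) {
  traits <- intersect(traits, names(data))
  elig <- eligible_phases(data, min_age)
  out <- dplyr::summarise(
    dplyr::group_by(elig, .data$person_id),
    age = mean(.data$age),
    sex = .data$sex[1],
    dplyr::across(dplyr::all_of(traits),
                  list(mean = ~ ifelse(all(is.na(.x)), NA_real_,
                                       mean(.x, na.rm = TRUE)),
                       n = ~ sum(!is.na(.x)))),
    .groups = "drop")
  names(out) <- sub("_mean$", "", names(out))
  names(out) <- sub("^(tc|tg|hdl|ldl)_n$", "n_\\1", names(out))
  dplyr::select(dplyr::mutate(out, scenario = "AM"),
                "person_id", "scenario", "age", "sex",
                dplyr::all_of(traits), dplyr::starts_with("n_"))
}

#' Residualize a trait on age and sex
#'
#' Ordinary least-squares adjustment: the trait (optionally on the log
#' scale) is regressed on an intercept, age and a sex indicator, and the
#' residuals are returned. A degenerate design column (constant age or a
#' single sex) is dropped with a warning.
#'
#' @param values Numeric trait vector.
#' @param age Numeric vector of ages.
#' @param sex Character or factor vector (`"male"`/`"female"`).
#' @param log_scale Take `log(values)` before fitting (use for TG, HDL-C
#'   and LDL-C; not TC).
#' @return Numeric vector of residuals (mean zero); `NA` propagated.
#' @export
residualize <- function(values, age, sex, log_scale = FALSE) {
  stopifnot(length(age) == length(values), length(sex) == length(values))
  y <- if (log_scale) log(values) else values
  df <- data.frame(y = y, age = age, sex = as.character(sex))
  terms <- c()
  if (length(unique(stats::na.omit(df$age))) > 1) {
    terms <- c(terms, "age")
  } else {
    warning("residualize: age is constant; dropping the age term")
  }
  if (length(unique(stats::na.omit(df$sex))) > 1) {
    terms <- c(terms, "sex")
  } else {
    warning("residualize: single-sex data; dropping the sex term")
  }
  fml <- stats::reformulate(if (length(terms)) terms else "1", response = "y")
  fit <- stats::lm(fml, data = df, na.action = stats::na.exclude)
  unname(stats::residuals(fit))
}

#' Rank-based inverse normal transformation
#'
#' Maps values to normal scores
#' `qnorm((rank - offset) / (n - 2 * offset + 1))` using midranks for
#' ties; the default offset 3/8 gives Blom scores. Missing values are
#' preserved; `n` counts non-missing values.
#'
#' @param values Numeric vector with at least 2 distinct non-missing
#'   values.
#' @param offset Rank offset constant (default 3/8).
#' @return Numeric vector of normal scores in the input order.
#' @export
#' @examples
#' inverse_normal_transform(c(3, 1, 2))
inverse_normal_transform <- function(values, offset = 3 / 8) {
  obs <- !is.na(values)
  x <- values[obs]
  n <- length(x)
  if (n < 2) stop("inverse_normal_transform: need at least 2 values")
  if (length(unique(x)) == 1) {
    stop("inverse_normal_transform: all values identical; ranks degenerate")
  }
  r <- rank(x, ties.method = "average")
  scores <- stats::qnorm((r - offset) / (n - 2 * offset + 1))
  out <- rep(NA_real_, length(values))
  out[obs] <- scores
  out
}

#' Adjust and normalize scenario traits
#'
#' Convenience wrapper applying [residualize()] (log scale for all traits
#' except TC) followed by [inverse_normal_transform()] to each trait
#' column of an FM/AM scenario table or a single-phase table.
#'
#' @param data Table with `age`, `sex` and trait columns.
#' @param traits Trait columns to transform.
#' @param log_traits Traits adjusted on the log scale (default TG, HDL-C,
#'   LDL-C).
#' @param offset Passed to [inverse_normal_transform()].
#' @return `data` with the trait columns replaced by normal scores.
#' @export
adjust_traits <- function(data, traits = c("tc", "tg", "hdl", "ldl"),
                          log_traits = c("tg", "hdl", "ldl"),
                          offset = 3 / 8) {
  traits <- intersect(traits, names(data))
  for (tr in traits) {
    res <- residualize(data[[tr]], data$age, data$sex,
                       log_scale = tr %in% log_traits)
    data[[tr]] <- inverse_normal_transform(res, offset = offset)
  }
  data
}
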