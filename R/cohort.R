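#' Apply inclusion and exclusion criteria
#'
#' Screens a longitudinal phenotype table person by person and reports,
#' for each person, whether they are retained and which rules fired.
#' Rules applied (all configurable through `config`):
#'
#' * `under18`: the person never reaches the inclusion age (default 18).
#' * `extreme_lipids`: any record with a robust z-score (median/MAD on the
#'   log scale, computed per trait over all records) exceeding `zmax`
#'   (default 5), or outside configured absolute bounds.
#' * `fh_screen`: simplified familial-hypercholesterolemia screen: TC
#'   above `fh_tc` (default 290) or LDL-C above `fh_ldl` (default 190) at
#'   any phase; if the table has a logical `fh_flag` column (positive
#'   family history of premature disease) the screen additionally requires
#'   it. This is a configurable stand-in, not a full clinical FH
#'   work-up.
#' * `under40_drug`: lipid-lowering medication at any phase with age < 40.
#' * `over40_drug_or_cvd`: age > 40 at a phase with medication or positive
#'   cardiovascular status.
#'
#' @param data Phenotype table with `person_id`, `phase`, `age` and
#'   optionally `tc`, `tg`, `hdl`, `ldl`, `drug`, `cvd`, `fh_flag`.
#' @param config Named list of overrides: `min_age`, `zmax`,
#'   `absolute_bounds` (named list of `c(lo, hi)` per trait, replaces the
#'   robust-z rule), `fh_tc`, `fh_ldl`, and logical switches
#'   `extreme_rule`, `fh_rule`, `drug_rules`.
#' @return Tibble with one row per person: `person_id`, `included`, and
#'   `exclusion_reasons` (comma-separated; empty when included).
#' @export
apply_exclusions <- function(data, config = list()) {
  cfg <- utils::modifyList(
    list(min_age = 18, zmax = 5, absolute_bounds = NULL,
         fh_tc = 290, fh_ldl = 190,
         extreme_rule = TRUE, fh_rule = TRUE, drug_rules = TRUE),
    config)
  data <- tibble::as_tibble(data)
  traits <- intersect(c("tc", "tg", "hdl", "ldl"), names(data))
  has <- function(col) col %in% names(data)

  extreme <- rep(FALSE, nrow(data))
  if (cfg$extreme_rule) {
    for (tr in traits) {
      x <- data[[tr]]
      if (!is.null(cfg$absolute_bounds) && tr %in% names(cfg$absolute_bounds)) {
        b <- cfg$absolute_bounds[[tr]]
        extreme <- extreme | (!is.na(x) & (x < b[1] | x > b[2]))
      } else {
        lx <- log(x)
        med <- stats::median(lx, na.rm = TRUE)
        mad_ <- stats::mad(lx, na.rm = TRUE)
        if (is.finite(mad_) && mad_ > 0) {
          extreme <- extreme | (!is.na(lx) & abs(lx - med) / mad_ > cfg$zmax)
        }
      }
    }
  }

  fh <- rep(FALSE, nrow(data))
  if (cfg$fh_rule) {
    if (has("tc")) fh <- fh | (!is.na(data$tc) & data$tc > cfg$fh_tc)
    if (has("ldl")) fh <- fh | (!is.na(data$ldl) & data$ldl > cfg$fh_ldl)
    if (has("fh_flag")) fh <- fh & (!is.na(data$fh_flag) & data$fh_flag)
  }

  drug <- if (has("drug")) !is.na(data$drug) & data$drug else rep(FALSE, nrow(data))
  cvd <- if (has("cvd")) !is.na(data$cvd) & data$cvd else rep(FALSE, nrow(data))
  u40 <- cfg$drug_rules & drug & data$age < 40
  o40 <- cfg$drug_rules & (drug | cvd) & data$age > 40

  per_rec <- tibble::tibble(person_id = data$person_id, age = data$age,
                            extreme = extreme, fh = fh, u40 = u40, o40 = o40)
  rep_ <- dplyr::summarise(
    dplyr::group_by(per_rec, .data$person_id),
    under18 = all(.data$age < cfg$min_age),
    extreme_lipids = any(.data$extreme),
    fh_screen = any(.data$fh),
    under40_drug = any(.data$u40),
    over40_drug_or_cvd = any(.data$o40),
    .groups = "drop")

  reasons <- c("under18", "extreme_lipids", "fh_screen", "under40_drug",
               "over40_drug_or_cvd")
  mat <- as.matrix(rep_[reasons])
  rep_$exclusion_reasons <- apply(mat, 1, function(r)
    paste(reasons[r], collapse = ","))
  rep_$included <- !apply(mat, 1, any)
  dplyr::select(rep_, "person_id", "included", "exclusion_reasons")
}

#' Longitudinal dyslipidemia status
#'
#' A person is dyslipidemic if they have a positive lipid-lowering drug
#' history at any phase, or meet at least one ATP III threshold in at
#' least two phases. `first_positive_phase` is the first drug-positive
#' phase (drug basis) or the second flag-positive phase (threshold basis).
#'
#' @param flags Per-phase table with `person_id`, `phase`, the flag
#'   columns `high_tc`, `high_tg`, `low_hdl`, `high_ldl` (any subset) and
#'   optionally `drug` and `age`.
#' @param min_flag_phases Number of flag-positive phases required
#'   (default 2).
#' @param drug_rule `"any"` (default): any drug history counts;
#'   `"over40"`: a strict variant requiring age > 40 at a drug-positive
#'   phase.
#' @return Tibble with `person_id`, `status`, `first_positive_phase`,
#'   `basis` (`"drug_history"`, `"threshold_two_phases"` or `NA`).
#' @export
dyslipidemia_status <- function(flags, min_flag_phases = 2,
                                drug_rule = c("any", "over40")) {
  drug_rule <- match.arg(drug_rule)
  flags <- tibble::as_tibble(flags)
  if (nrow(flags) == 0) stop("dyslipidemia_status: no observed phases")
  flag_cols <- intersect(c("high_tc", "high_tg", "low_hdl", "high_ldl"),
                         names(flags))
  if (length(flag_cols) == 0) stop("dyslipidemia_status: no flag columns")
  fm <- as.matrix(flags[flag_cols])
  any_flag <- rowSums(fm, na.rm = TRUE) > 0
  drug <- if ("drug" %in% names(flags)) !is.na(flags$drug) & flags$drug
          else rep(FALSE, nrow(flags))
  if (drug_rule == "over40") {
    stopifnot("age" %in% names(flags))
    drug <- drug & flags$age > 40
  }
  df <- tibble::tibble(person_id = flags$person_id, phase = flags$phase,
                       any_flag = any_flag, drug = drug)
  df <- dplyr::arrange(df, .data$person_id, .data$phase)
  dplyr::summarise(
    dplyr::group_by(df, .data$person_id),
    status = any(.data$drug) || sum(.data$any_flag) >= min_flag_phases,
    basis = dplyr::if_else(any(.data$drug), "drug_history",
                           dplyr::if_else(sum(.data$any_flag) >= min_flag_phases,
                                          "threshold_two_phases",
                                          NA_character_)),
    first_positive_phase = dplyr::case_when(
      any(.data$drug) ~ .data$phase[.data$drug][1],
      sum(.data$any_flag) >= min_flag_phases ~
        .data$phase[.data$any_flag][min_flag_phases],
      TRUE ~ NA_real_),
    .groups = "drop")
}

#' Point prevalence at the baseline phase
#'
#' Proportion of persons observed at the baseline phase whose dyslipidemia
#' status is already positive there (`first_positive_phase <=
#' baseline_phase`).
#'
#' @param statuses Output of [dyslipidemia_status()].
#' @param observations Table with `person_id`, `phase` giving observed
#'   phases (the phenotype table works).
#' @param baseline_phase Baseline phase (default 2).
#' @return One-row tibble: `prevalence`, `n_positive`, `n`.
#' @export
point_prevalence <- function(statuses, observations, baseline_phase = 2) {
  at_base <- unique(observations$person_id[observations$phase == baseline_phase])
  if (length(at_base) == 0) {
    stop("point_prevalence: no persons observed at the baseline phase")
  }
  st <- statuses[statuses$person_id %in% at_base, ]
  pos <- if ("first_positive_phase" %in% names(st)) {
    # longitudinal statuses: positive at baseline means the rule was
    # already met there
    sum(st$status & !is.na(st$first_positive_phase) &
          st$first_positive_phase <= baseline_phase)
  } else {
    sum(st$status)  # cross-sectional statuses
  }
  tibble::tibble(prevalence = pos / length(at_base),
                 n_positive = pos, n = length(at_base))
}

#' Periodic prevalence over the follow-up
#'
#' Baseline point-prevalent cases plus persons first turning positive in
#' later phases, over all persons ever observed; each person counted once.
#'
#' @inheritParams point_prevalence
#' @return One-row tibble: `prevalence`, `n_positive`, `n`.
#' @export
periodic_prevalence <- function(statuses, observations, baseline_phase = 2) {
  everyone <- unique(observations$person_id)
  st <- statuses[statuses$person_id %in% everyone, ]
  pos <- sum(st$status)
  tibble::tibble(prevalence = pos / length(everyone),
                 n_positive = pos, n = length(everyone))
}
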