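#' Simulation configuration
#'
#' Assembles the parameter set for the cohort generator. Per-trait means
#' and SDs by sex default to the baseline characteristics of a large urban
#' Iranian family cohort (first-measurement scenario); per-trait
#' heritabilities default to that cohort's likelihood-based estimates.
#' Triglycerides are simulated log-normally. Variance shares are of the
#' single-phase phenotypic variance: additive genetic (`h2`), shared
#' household (`household_share`), phase-level measurement error
#' (`phase_error_share`), remainder permanent environment.
#'
#' @param n_families Number of families.
#' @param generations Offspring generations (1 = nuclear families;
#'   consanguineous matches require >= 3).
#' @param sibship Integer range `c(min, max)` for sibship size (uniform),
#'   or a probability vector over sizes `1..length`.
#' @param marry_prob Probability a non-final-generation child marries and
#'   reproduces.
#' @param consanguinity_rate Target fraction of non-founder marriages that
#'   are between blood relatives.
#' @param phases Phase numbers (default `2:6`, 3-year spacing).
#' @param traits Named list of per-trait parameter lists with elements
#'   `mean_male`, `mean_female`, `sd_male`, `sd_female`, `h2`,
#'   `household_share`, `phase_error_share`, `age_effect`, `log_scale`.
#' @param missing_rate Per-record missingness after the first phase.
#' @param disease List with `liability_h2` and `prevalence` for the
#'   liability-threshold dyslipidemia status.
#' @param seed Integer seed.
#' @return A `simulation_config` list.
#' @export
simulation_config <- function(n_families = 500, generations = 2,
                              sibship = c(2, 4), marry_prob = 0.6,
                              consanguinity_rate = 0, phases = 2:6,
                              traits = NULL, missing_rate = 0.1,
                              disease = list(liability_h2 = 0.41,
                                             prevalence = 0.40),
                              seed = 1) {
  default_traits <- list(
    tc  = list(mean_male = 194.43, mean_female = 182.56,
               sd_male = 45.60, sd_female = 80.30, h2 = 0.4258,
               household_share = 0.10, phase_error_share = 0.20,
               age_effect = 0.7, log_scale = FALSE),
    tg  = list(mean_male = 169.86, mean_female = 132.68,
               sd_male = 122.97, sd_female = 109.50, h2 = 0.3364,
               household_share = 0.10, phase_error_share = 0.20,
               age_effect = 0.006, log_scale = TRUE),
    hdl = list(mean_male = 38.80, mean_female = 40.11,
               sd_male = 9.66, sd_female = 19.30, h2 = 0.4050,
               household_share = 0.10, phase_error_share = 0.20,
               age_effect = 0.05, log_scale = FALSE),
    ldl = list(mean_male = 133.32, mean_female = 106.16,
               sd_male = 39.37, sd_female = 57.24, h2 = 0.4110,
               household_share = 0.10, phase_error_share = 0.20,
               age_effect = 0.6, log_scale = FALSE))
  if (!is.null(traits)) {
    for (tr in names(traits)) {
      default_traits[[tr]] <- utils::modifyList(
        default_traits[[tr]] %||% traits[[tr]], traits[[tr]])
    }
  }
  for (tr in names(default_traits)) {
    p <- default_traits[[tr]]
    if (p$h2 + p$household_share + p$phase_error_share > 1) {
      stop("simulation_config: variance shares for ", tr, " exceed 1")
    }
  }
  stopifnot(consanguinity_rate >= 0, consanguinity_rate <= 1,
            missing_rate >= 0, missing_rate < 1,
            marry_prob >= 0, marry_prob <= 1)
  structure(list(n_families = n_families, generations = generations,
                 sibship = sibship, marry_prob = marry_prob,
                 consanguinity_rate = consanguinity_rate, phases = phases,
                 traits = default_traits, missing_rate = missing_rate,
                 disease = disease, seed = seed),
            class = "simulation_config")
}

# length-2 integer vectors are a (min, max) range; anything else is a
# probability vector over sizes 1..length(sibship)
draw_sibship <- function(sibship, n) {
  if (length(sibship) == 2 && all(sibship == round(sibship)) &&
      sibship[2] >= sibship[1] && sibship[1] >= 1) {
    sizes <- seq(sibship[1], sibship[2])
    sizes[sample.int(length(sizes), n, replace = TRUE)]
  } else {
    sample(seq_along(sibship), n, replace = TRUE, prob = sibship)
  }
}

#' Simulate a multi-generation pedigree cohort
#'
#' Each family starts from a founder couple; each couple draws a sibship
#' from the configured distribution; children of non-final generations
#' marry with probability `marry_prob`, either a new founder or a blood
#' relative: an unmarried opposite-sex family member with kinship in
#' (0, 0.2] (typically a first cousin). Such relatives first exist from
#' the grandchild generation on, so `consanguinity_rate` is enforced among
#' marriages of generation two onward: a consanguineous match is attempted
#' whenever the achieved count lags the target fraction of eligible
#' couples, and a shortfall (no candidate available) falls back to a
#' founder spouse. Bookkeeping is recorded in the `consanguinity`
#' attribute.
#'
#' @param cfg A [simulation_config()] (or arguments to build one).
#' @param seed Overrides `cfg$seed`.
#' @return A `pedigree` tibble with an extra `generation` column and a
#'   `consanguinity` attribute (`requested`, `achieved` counts).
#' @export
simulate_pedigree <- function(cfg = simulation_config(), seed = NULL) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  set.seed(seed %||% cfg$seed)
  requested <- 0L; achieved <- 0L; eligible_couples <- 0L
  fam_list <- vector("list", cfg$n_families)
  for (f in seq_len(cfg$n_families)) {
    fid <- paste0("F", f)
    nid <- 0L
    new_id <- function() {
      nid <<- nid + 1L
      paste0(fid, "_", nid)
    }
    rows <- list()
    add <- function(sex, father = NA_character_, mother = NA_character_,
                    gen = 0L) {
      id <- new_id()
      rows[[length(rows) + 1L]] <<- list(individual_id = id, father_id = father,
                                         mother_id = mother, sex = sex,
                                         generation = gen)
      id
    }
    pa <- add("male"); ma <- add("female")
    couples <- list(c(pa, ma))
    spoused <- c(pa, ma)
    for (t in seq_len(cfg$generations)) {
      kids <- character(0)
      for (cp in couples) {
        k <- draw_sibship(cfg$sibship, 1)
        for (s in seq_len(k)) {
          kids <- c(kids, add(sample(c("male", "female"), 1),
                              father = cp[1], mother = cp[2], gen = t))
        }
      }
      couples <- list()
      if (t < cfg$generations && length(kids) > 0) {
        df <- dplyr::bind_rows(rows)
        sex_of <- stats::setNames(df$sex, df$individual_id)
        pool <- kids[stats::runif(length(kids)) < cfg$marry_prob]
        pool <- sample(pool)
        # Consanguineous matches need marriageable relatives, which first
        # exist for grandchildren (t >= 2): unmarried opposite-sex family
        # members with kinship in (0, 0.2] (first cousins, unmarried
        # aunts/uncles, ...). A consanguineous match is attempted whenever
        # the achieved count falls below target * eligible couples, so the
        # realized rate converges on the configured one.
        try_consang <- t >= 2 && cfg$consanguinity_rate > 0
        phi <- if (try_consang) kinship_block(df) else NULL
        while (length(pool) > 0) {
          w <- pool[1]
          pool <- pool[-1]
          partner <- NULL
          if (try_consang &&
              achieved < cfg$consanguinity_rate * (eligible_couples + 1)) {
            requested <- requested + 1L
            cand <- setdiff(df$individual_id[sex_of[df$individual_id] !=
                                               sex_of[w]], spoused)
            kw <- phi[w, cand]
            cand <- cand[kw > 0 & kw <= 0.2]
            if (length(cand) > 0) {
              partner <- if (length(cand) == 1) cand else sample(cand, 1)
              pool <- setdiff(pool, partner)
              achieved <- achieved + 1L
            }
          }
          if (is.null(partner)) {
            partner <- add(if (sex_of[w] == "male") "female" else "male",
                           gen = t)
            sex_of[partner] <- if (sex_of[w] == "male") "female" else "male"
          }
          if (try_consang) eligible_couples <- eligible_couples + 1L
          spoused <- c(spoused, w, partner)
          cp <- if (sex_of[w] == "male") c(w, partner) else c(partner, w)
          couples[[length(couples) + 1L]] <- cp
        }
      }
    }
    fam <- dplyr::bind_rows(rows)
    fam$family_id <- fid
    fam_list[[f]] <- fam
  }
  all_rows <- dplyr::bind_rows(fam_list)
  gen <- stats::setNames(all_rows$generation, all_rows$individual_id)
  ped <- pedigree(all_rows[c("family_id", "individual_id", "father_id",
                             "mother_id", "sex")],
                  missing_code = NA_character_)
  ped$generation <- unname(gen[ped$individual_id])
  attr(ped, "consanguinity") <- c(requested = requested, achieved = achieved,
                                  eligible_couples = eligible_couples)
  ped
}

#' Simulate additive breeding values
#'
#' Draws `g ~ N(0, sigma_g2 * A)` via a per-family Cholesky factorization
#' of the relationship matrix; a numerically singular block gets a 1e-8
#' diagonal jitter (with a message).
#'
#' @param kin A `kinship_matrix` (or `pedigree`).
#' @param sigma_g2 Additive genetic variance.
#' @param seed Optional seed.
#' @return Named numeric vector of breeding values (all individuals).
#' @export
simulate_breeding_values <- function(kin, sigma_g2, seed = NULL) {
  if (inherits(kin, "pedigree")) kin <- kinship_matrix(kin)
  if (!is.null(seed)) set.seed(seed)
  if (sigma_g2 == 0) {
    return(stats::setNames(rep(0, length(kin$ids)), kin$ids))
  }
  fams <- split(kin$ids, factor(kin$family_id, levels = unique(kin$family_id)))
  g <- unlist(lapply(fams, function(members) {
    a <- 2 * as.matrix(kin$phi[members, members, drop = FALSE])
    r <- tryCatch(chol(a), error = function(e) {
      rlang::inform("singular relationship block: adding 1e-8 jitter")
      chol(a + diag(1e-8, nrow(a)))
    })
    drop(crossprod(r, stats::rnorm(length(members)))) * sqrt(sigma_g2)
  }), use.names = FALSE)
  stats::setNames(g, unlist(fams, use.names = FALSE))
}

# lognormal parameters matching a target mean and sd on the raw scale
lognormal_params <- function(mean, sd) {
  s2 <- log(1 + (sd / mean)^2)
  list(mu = log(mean) - s2 / 2, sigma = sqrt(s2))
}

#' Simulate longitudinal lipid phenotypes
#'
#' Generates per-phase lipid records on a simulated pedigree under an
#' additive-genetic + household + permanent-environment + phase-error
#' variance structure. On the working scale (log for log-scale traits)
#' each record is
#' `mu_sex + age_effect * (age - 40) + g_i + c_f + p_i + e_ip`; ages
#' advance 3 years per phase; lipid-lowering medication and CVD flags
#' persist once acquired; records after a person's first phase drop out at
#' the configured missingness rate.
#'
#' @param ped Pedigree from [simulate_pedigree()] (needs the `generation`
#'   column; it is reconstructed if absent).
#' @param cfg A [simulation_config()].
#' @param seed Overrides `cfg$seed`.
#' @return Tibble: `person_id`, `family_id`, `phase`, `age`, `sex`, `tc`,
#'   `tg`, `hdl`, `ldl` (mg/dL), `drug`, `cvd`.
#' @export
simulate_longitudinal_lipids <- function(ped, cfg = simulation_config(),
                                         seed = NULL) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  set.seed(seed %||% (cfg$seed + 1L))
  if (is.null(ped$generation)) {
    gen <- stats::setNames(rep(0L, nrow(ped)), ped$individual_id)
    for (i in seq_len(nrow(ped))) {  # rows are parents-first
      pg <- gen[stats::na.omit(c(ped$father_id[i], ped$mother_id[i]))]
      if (length(pg) > 0) gen[ped$individual_id[i]] <- max(pg) + 1L
    }
    ped$generation <- unname(gen[ped$individual_id])
  }
  n <- nrow(ped)
  kin <- kinship_matrix(ped)
  ord <- match(kin$ids, ped$individual_id)
  base_age <- pmax(stats::rnorm(n, 58 - 26 * ped$generation, 5), 1)

  phases <- cfg$phases
  long <- tidyr::expand_grid(i = seq_len(n), phase = phases)
  long$person_id <- ped$individual_id[long$i]
  long$family_id <- ped$family_id[long$i]
  long$sex <- ped$sex[long$i]
  long$age <- round(base_age[long$i] + 3 * (long$phase - phases[1]), 1)

  fam_idx <- match(long$family_id, unique(ped$family_id))
  for (tr in names(cfg$traits)) {
    p <- cfg$traits[[tr]]
    if (p$log_scale) {
      lm_ <- lognormal_params(p$mean_male, p$sd_male)
      lf_ <- lognormal_params(p$mean_female, p$sd_female)
      mu <- ifelse(long$sex == "male", lm_$mu, lf_$mu)
      s2 <- mean(c(lm_$sigma^2, lf_$sigma^2))
    } else {
      mu <- ifelse(long$sex == "male", p$mean_male, p$mean_female)
      s2 <- mean(c(p$sd_male^2, p$sd_female^2))
    }
    g <- simulate_breeding_values(kin, p$h2 * s2)[ped$individual_id]
    hh <- stats::rnorm(length(unique(ped$family_id)),
                       0, sqrt(p$household_share * s2))
    perm_share <- 1 - p$h2 - p$household_share - p$phase_error_share
    pe <- stats::rnorm(n, 0, sqrt(perm_share * s2))
    eps <- stats::rnorm(nrow(long), 0, sqrt(p$phase_error_share * s2))
    val <- mu + p$age_effect * (long$age - 40) +
      g[long$i] + hh[fam_idx] + pe[long$i] + eps
    long[[tr]] <- if (p$log_scale) exp(val) else pmax(val, 1)
  }

  # medication and CVD: onset probabilities, persistent once acquired
  p_drug <- stats::plogis((long$tc - 320) / 15) * (long$age > 40)
  long$drug <- stats::runif(nrow(long)) < p_drug
  p_cvd <- 0.002 + 0.01 * (long$age > 55)
  long$cvd <- stats::runif(nrow(long)) < p_cvd
  long <- dplyr::arrange(long, .data$i, .data$phase)
  long <- dplyr::mutate(dplyr::group_by(long, .data$i),
                        drug = cumsum(.data$drug) > 0,
                        cvd = cumsum(.data$cvd) > 0,
                        keep = dplyr::row_number() == 1 |
                          stats::runif(dplyr::n()) >= cfg$missing_rate)
  long <- dplyr::ungroup(long)
  long <- long[long$keep, ]
  dplyr::select(long, "person_id", "family_id", "phase", "age", "sex",
                "tc", "tg", "hdl", "ldl", "drug", "cvd")
}

#' Simulate liability-threshold disease statuses
#'
#' Liability is `g + e` with variances `(h2, 1 - h2)`; status is liability
#' above `qnorm(1 - prevalence)`, so the population prevalence matches the
#' target up to Monte-Carlo error.
#'
#' @param kin A `kinship_matrix` (or `pedigree`).
#' @param liability_h2 Liability-scale heritability in \[0, 1\].
#' @param prevalence Target population prevalence in (0, 1).
#' @param seed Optional seed.
#' @return Tibble: `person_id`, `liability`, `status`.
#' @export
simulate_disease_status <- function(kin, liability_h2 = 0.41,
                                    prevalence = 0.40, seed = NULL) {
  if (inherits(kin, "pedigree")) kin <- kinship_matrix(kin)
  if (!is.null(seed)) set.seed(seed)
  stopifnot(liability_h2 >= 0, liability_h2 <= 1,
            prevalence > 0, prevalence < 1)
  g <- simulate_breeding_values(kin, liability_h2)
  e <- stats::rnorm(length(g), 0, sqrt(1 - liability_h2))
  liab <- unname(g) + e
  tibble::tibble(person_id = kin$ids, liability = liab,
                 status = liab > stats::qnorm(1 - prevalence))
}

#' Simulate a complete cohort
#'
#' Pedigree, longitudinal lipid phenotypes and liability-threshold
#' dyslipidemia statuses in one call; stage seeds are derived from the
#' configured seed.
#'
#' @param cfg A [simulation_config()].
#' @return List with `pedigree`, `phenotypes`, `statuses`, `config`.
#' @export
simulate_cohort <- function(cfg = simulation_config()) {
  if (!inherits(cfg, "simulation_config")) cfg <- do.call(simulation_config, cfg)
  ped <- simulate_pedigree(cfg, seed = cfg$seed)
  pheno <- simulate_longitudinal_lipids(ped, cfg, seed = cfg$seed + 1L)
  statuses <- simulate_disease_status(kinship_matrix(ped),
                                      cfg$disease$liability_h2,
                                      cfg$disease$prevalence,
                                      seed = cfg$seed + 2L)
  list(pedigree = ped, phenotypes = pheno, statuses = statuses, config = cfg)
}
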