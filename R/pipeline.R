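#' Run the family-based dyslipidemia pipeline
#'
#' Orchestrates the analysis stages over a simulated or supplied cohort
#' and writes each stage's artifacts (TSV/JSON) into `out_dir`, plus a
#' JSON run manifest (package version, seed, configuration hash, stages
#' run). Later stages read the artifacts of earlier ones, so a stage whose
#' upstream artifact is missing fails with an error naming the stage to
#' run first.
#'
#' Stages: `simulate` (pedigree + phenotypes + statuses), `kinship`,
#' `pairs`, `prevalence`, `icc`, `history`, `h2-ml`, `h2-bayes`, `report`,
#' or `all`.
#'
#' @param stages Character vector of stages, or `"all"`.
#' @param config A [simulation_config()], a YAML file path of its
#'   arguments, or a list with elements `pedigree_file` and
#'   `phenotype_file` pointing at existing inputs.
#' @param out_dir Output directory (created if needed).
#' @param seed Run seed; every stage derives its randomness from it.
#' @param scenario `"both"` (default), `"fm"` or `"am"`.
#' @param mcmc An [mcmc_config()] for the Bayesian stage.
#' @param n_boot Bootstrap resamples for the ICC stage.
#' @return Invisibly, the manifest list.
#' @export
run_pipeline <- function(stages = "all", config = simulation_config(),
                         out_dir = tempfile("famlipid_run_"), seed = 1,
                         scenario = c("both", "fm", "am"),
                         mcmc = mcmc_config(n_iter = 4000, burn_in = 2000,
                                            thin = 2, seed = seed),
                         n_boot = 500) {
  scenario <- match.arg(scenario)
  all_stages <- c("simulate", "kinship", "pairs", "prevalence", "icc",
                  "history", "h2-ml", "h2-bayes", "report")
  if (identical(stages, "all")) stages <- all_stages
  stopifnot(all(stages %in% all_stages))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  art <- function(name) file.path(out_dir, name)
  need <- function(name, producer) {
    if (!file.exists(art(name))) {
      stop("missing artifact '", name, "': run stage `", producer, "` first")
    }
  }

  if (is.character(config)) config <- yaml::read_yaml(config)
  external <- is.list(config) && !inherits(config, "simulation_config") &&
    !is.null(config$pedigree_file)
  if (!external && !inherits(config, "simulation_config")) {
    config <- do.call(simulation_config, config)
  }

  scenarios <- switch(scenario, both = c("FM", "AM"), fm = "FM", am = "AM")

  if ("simulate" %in% stages) {
    if (external) {
      ped <- read_pedigree(config$pedigree_file)
      pheno <- readr::read_tsv(config$phenotype_file, show_col_types = FALSE)
      statuses <- NULL
    } else {
      config$seed <- as.integer(seed)
      sim <- simulate_cohort(config)
      ped <- sim$pedigree
      pheno <- sim$phenotypes
      statuses <- sim$statuses
    }
    readr::write_tsv(as.data.frame(ped), art("pedigree.tsv"))
    readr::write_tsv(pheno, art("phenotypes.tsv"))
    if (!is.null(statuses)) {
      readr::write_tsv(statuses, art("liability_statuses.tsv"))
    }
  }

  load_ped <- function() {
    need("pedigree.tsv", "simulate")
    df <- readr::read_tsv(art("pedigree.tsv"), show_col_types = FALSE,
                          col_types = readr::cols(.default = "c"))
    pedigree(df, missing_code = c("0", "NA"))
  }
  load_pheno <- function() {
    need("phenotypes.tsv", "simulate")
    readr::read_tsv(art("phenotypes.tsv"), show_col_types = FALSE)
  }

  if ("kinship" %in% stages) {
    write_kinship_tsv(kinship_matrix(load_ped()), art("kinship.tsv"))
  }

  if ("pairs" %in% stages) {
    readr::write_tsv(pedigree_pairs(load_ped()), art("pairs.tsv"))
  }

  make_scenarios <- function(pheno) {
    flags <- classify_lipid_flags(
      dplyr::mutate(pheno, tc = adjust_tc_for_medication(.data$tc, .data$drug)))
    statuses <- dyslipidemia_status(flags)
    tabs <- list()
    if ("FM" %in% scenarios) tabs$FM <- first_measurement(pheno)
    if ("AM" %in% scenarios) tabs$AM <- average_measurement(pheno)
    list(flags = flags, statuses = statuses,
         tabs = lapply(tabs, adjust_traits))
  }

  if (any(c("prevalence", "icc", "history", "h2-ml", "h2-bayes") %in% stages)) {
    pheno <- load_pheno()
    elig <- apply_exclusions(pheno)
    readr::write_tsv(elig, art("eligibility.tsv"))
    pheno <- pheno[pheno$person_id %in% elig$person_id[elig$included], ]
    sc <- make_scenarios(pheno)
    readr::write_tsv(sc$statuses, art("statuses.tsv"))
  }

  if ("prevalence" %in% stages) {
    pt <- point_prevalence(sc$statuses, pheno)
    pd <- periodic_prevalence(sc$statuses, pheno)
    jsonlite::write_json(list(point = pt$prevalence, periodic = pd$prevalence,
                              n_baseline = pt$n, n = pd$n,
                              denominator = "all ever-observed persons"),
                         art("prevalence.json"), auto_unbox = TRUE)
  }

  if ("icc" %in% stages) {
    need("pairs.tsv", "pairs")
    pairs <- readr::read_tsv(art("pairs.tsv"), show_col_types = FALSE,
                             col_types = readr::cols(.default = "c",
                                                     kinship = "d"))
    icc_tab <- purrr::imap_dfr(sc$tabs, function(tab, sc_name) {
      familial_correlation(pairs, dplyr::rename(tab, value = "tc"),
                           traits = "value", scenario = sc_name,
                           n_boot = n_boot, seed = seed)
    })
    st <- dplyr::rename(sc$statuses, value = "status")
    icc_bin <- familial_correlation(pairs, st, traits = "value",
                                    scenario = "status", binary = TRUE,
                                    n_boot = n_boot, seed = seed)
    readr::write_tsv(dplyr::bind_rows(icc_tab, icc_bin), art("icc.tsv"))
  }

  if ("history" %in% stages) {
    ped <- load_ped()
    exp_rec <- parental_exposure(ped, sc$statuses)
    covar <- dplyr::distinct(pheno, .data$person_id, .data$sex)
    age1 <- dplyr::summarise(dplyr::group_by(pheno, .data$person_id),
                             age = min(.data$age), .groups = "drop")
    exp_rec <- dplyr::inner_join(exp_rec, covar, by = "person_id")
    exp_rec <- dplyr::inner_join(exp_rec, age1, by = "person_id")
    readr::write_tsv(family_history_or(exp_rec), art("history_or.tsv"))
  }

  if (any(c("h2-ml", "h2-bayes") %in% stages)) {
    need("kinship.tsv", "kinship")
    ped <- load_ped()
    kin <- kinship_matrix(ped)
  }

  if ("h2-ml" %in% stages) {
    h2 <- purrr::imap_dfr(sc$tabs, function(tab, sc_name) {
      purrr::map_dfr(c("tc", "tg", "hdl", "ldl"), function(tr) {
        fit <- fit_polygenic_ml(tab, tr, kin)
        dplyr::mutate(glance(fit), scenario = sc_name, .before = 1)
      })
    })
    readr::write_tsv(h2, art("h2_ml.tsv"))
  }

  if ("h2-bayes" %in% stages) {
    h2b <- purrr::imap_dfr(sc$tabs, function(tab, sc_name) {
      fit <- gibbs_gaussian(tab, "tc", kin, config = mcmc)
      dplyr::mutate(glance(fit), scenario = sc_name, .before = 1)
    })
    st <- dplyr::inner_join(sc$statuses,
                            dplyr::distinct(pheno, .data$person_id),
                            by = "person_id")
    pb <- gibbs_probit(st, "status", kin, config = mcmc)
    h2b <- dplyr::bind_rows(h2b, dplyr::mutate(glance(pb), scenario = "status",
                                               .before = 1))
    readr::write_tsv(h2b, art("h2_bayes.tsv"))
  }

  if ("report" %in% stages) {
    need("pairs.tsv", "pairs")
    pairs <- readr::read_tsv(art("pairs.tsv"), show_col_types = FALSE)
    pair_counts <- dplyr::count(pairs, .data$category, .data$sex_label,
                                name = "n_pairs")
    readr::write_tsv(pair_counts, art("report_pairs.tsv"))
    pheno <- load_pheno()
    fm <- first_measurement(pheno)
    baseline <- tidyr::pivot_longer(fm, dplyr::any_of(c("age", "tc", "tg",
                                                        "hdl", "ldl")),
                                    names_to = "variable")
    baseline <- dplyr::summarise(
      dplyr::group_by(baseline, .data$variable, .data$sex),
      mean = mean(.data$value, na.rm = TRUE),
      sd = stats::sd(.data$value, na.rm = TRUE),
      n = sum(!is.na(.data$value)), .groups = "drop")
    readr::write_tsv(baseline, art("report_baseline.tsv"))
    if (file.exists(art("h2_ml.tsv"))) {
      h2 <- readr::read_tsv(art("h2_ml.tsv"), show_col_types = FALSE)
      readr::write_tsv(
        dplyr::select(h2, "scenario", "trait", "h2", "se_h2"),
        art("report_heritability.tsv"))
    }
  }

  manifest <- list(
    package = "famlipid",
    version = as.character(utils::packageVersion("famlipid")),
    seed = seed, scenario = scenario, stages = stages,
    config_hash = rlang::hash(config),
    artifacts = sort(list.files(out_dir)))
  jsonlite::write_json(manifest, art("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  invisible(manifest)
}
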