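test_that("the smallest config gives a nuclear family, deterministically", {
  cfg <- simulation_config(n_families = 1, generations = 1,
                           sibship = c(2, 2), seed = 3)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 4)
  expect_equal(length(founders(ped)), 2)
  pairs <- pedigree_pairs(ped)
  expect_equal(sum(pairs$category == "sibling"), 1)
  # same seed, identical pedigree
  expect_identical(as.data.frame(simulate_pedigree(cfg)),
                   as.data.frame(ped))
  # different seed, different pedigree (sex assignment at least)
  cfg2 <- simulation_config(n_families = 30, generations = 1, seed = 4)
  expect_false(identical(as.data.frame(simulate_pedigree(cfg2)),
                         as.data.frame(simulate_pedigree(
                           simulation_config(n_families = 30,
                                             generations = 1, seed = 5)))))
})

test_that("sibship sizes respect the configured range", {
  cfg <- simulation_config(n_families = 100, generations = 1,
                           sibship = c(2, 4), seed = 6)
  ped <- simulate_pedigree(cfg)
  kids_per_family <- table(ped$family_id[!is.na(ped$father_id)])
  expect_true(all(kids_per_family >= 2 & kids_per_family <= 4))
})

test_that("achieved consanguinity tracks the configured rate", {
  cfg <- simulation_config(n_families = 220, generations = 3,
                           sibship = c(2, 4), marry_prob = 0.8,
                           consanguinity_rate = 0.28, seed = 11)
  ped <- simulate_pedigree(cfg)
  sp <- dplyr::filter(pedigree_pairs(ped), category == "spouse")
  gen <- setNames(ped$generation, ped$individual_id)
  nonf <- setNames(!is.na(ped$father_id), ped$individual_id)
  eligible <- (gen[sp$id_a] >= 2 & nonf[sp$id_a]) |
    (gen[sp$id_b] >= 2 & nonf[sp$id_b])
  n <- sum(eligible)
  expect_gt(n, 800)
  rate <- mean(sp$kinship[eligible] > 0)
  half <- 1.96 * sqrt(0.28 * 0.72 / n)
  expect_lt(abs(rate - 0.28), half + 1e-9)
})

test_that("breeding values have the configured covariance structure", {
  # unrelated founders: i.i.d. with variance sigma_g2
  ped <- pedigree(data.frame(
    family_id = paste0("F", 1:4000), individual_id = paste0("I", 1:4000),
    father_id = "0", mother_id = "0", sex = rep(c("1", "2"), 2000)))
  kin <- kinship_matrix(ped)
  g <- simulate_breeding_values(kin, 2.5, seed = 12)
  expect_equal(var(unname(g)), 2.5, tolerance = 0.1)
  expect_equal(unname(simulate_breeding_values(kin, 0, seed = 12)),
               rep(0, 4000))
  # sib-pair covariance equals A_sib * sigma_g2 = 0.5 * sigma_g2
  cfg <- simulation_config(n_families = 5000, generations = 1,
                           sibship = c(2, 2), seed = 13)
  ped2 <- simulate_pedigree(cfg)
  kin2 <- kinship_matrix(ped2)
  g2 <- simulate_breeding_values(kin2, 1, seed = 14)
  sibs <- ped2[!is.na(ped2$father_id), ]
  first <- sibs$individual_id[!duplicated(sibs$family_id)]
  second <- sibs$individual_id[duplicated(sibs$family_id)]
  cv <- cov(g2[first], g2[second])
  expect_lt(abs(cv - 0.5), 3 * sqrt((1 + 0.25) / 5000))
})

test_that("longitudinal lipids carry the planted structure", {
  cfg <- simulation_config(n_families = 250, generations = 1,
                           missing_rate = 0, seed = 15)
  ph <- simulate_longitudinal_lipids(simulate_pedigree(cfg), cfg)
  # phases strictly increasing, ages advance 3 years per phase
  by_person <- dplyr::group_by(ph, person_id)
  chk <- dplyr::summarise(by_person,
                          inc = all(diff(phase) > 0),
                          age_step = all(abs(diff(age) - 3 * diff(phase))
                                         < 1e-9))
  expect_true(all(chk$inc))
  expect_true(all(chk$age_step))
  # planted male-female TC gap at the configured means (age-adjusted)
  fm <- suppressMessages(first_measurement(ph))
  res <- lm(tc ~ age + sex, data = fm)
  gap <- coef(res)[["sexmale"]]
  se <- summary(res)$coefficients["sexmale", 2]
  expect_lt(abs(gap - (194.43 - 182.56)), 4 * se)
  # all values positive; TG log-normal hence right-skewed
  expect_true(all(ph$tc > 0 & ph$tg > 0 & ph$hdl > 0 & ph$ldl > 0))
  tg_skew <- mean((ph$tg - mean(ph$tg))^3) / sd(ph$tg)^3
  expect_gt(tg_skew, 0.5)
})

test_that("zero error shares make phases identical up to the age trend", {
  cfg <- simulation_config(
    n_families = 20, generations = 1, missing_rate = 0, seed = 16,
    traits = list(tc = list(phase_error_share = 0, household_share = 0,
                            age_effect = 0)))
  ph <- simulate_longitudinal_lipids(simulate_pedigree(cfg), cfg)
  spread <- dplyr::summarise(dplyr::group_by(ph, person_id),
                             s = max(tc) - min(tc))
  expect_true(all(spread$s < 1e-9))
})

test_that("averaging phases shrinks the error share as expected", {
  cfg <- simulation_config(n_families = 400, generations = 1,
                           missing_rate = 0, seed = 17,
                           traits = list(tc = list(age_effect = 0)))
  ped <- simulate_pedigree(cfg)
  ph <- simulate_longitudinal_lipids(ped, cfg)
  wide <- tidyr::pivot_wider(ph[c("person_id", "phase", "tc")],
                             names_from = "phase", values_from = "tc")
  mat <- as.matrix(wide[-1])
  # within-person variance across phases estimates the phase-error share
  v_within <- mean(apply(mat, 1, var))
  v_total <- var(mat[, 1])
  expect_equal(v_within / v_total, 0.20, tolerance = 0.1)
  # the AM over the 5 phases has a visibly smaller residual spread than FM
  am <- rowMeans(mat)
  expect_lt(var(am), v_total)
})

test_that("disease statuses follow the liability-threshold model", {
  # h2 = 0: i.i.d. coin at the target prevalence
  ped <- pedigree(data.frame(
    family_id = paste0("F", 1:3000), individual_id = paste0("I", 1:3000),
    father_id = "0", mother_id = "0", sex = rep(c("1", "2"), 1500)))
  kin <- kinship_matrix(ped)
  st <- simulate_disease_status(kin, 0, 0.5, seed = 18)
  expect_lt(abs(mean(st$status) - 0.5), 3 * sqrt(0.25 / 3000))
  # parent-offspring concordance matches the bivariate-normal oracle
  cfg <- simulation_config(n_families = 4000, generations = 1,
                           sibship = c(1, 1), seed = 19)
  ped2 <- simulate_pedigree(cfg)
  st2 <- simulate_disease_status(kinship_matrix(ped2), 0.42, 0.40, seed = 20)
  status <- setNames(st2$status, st2$person_id)
  kid <- ped2$individual_id[!is.na(ped2$father_id)]
  dad <- ped2$father_id[!is.na(ped2$father_id)]
  both <- mean(status[kid] & status[dad])
  want <- bvn_exceedance(qnorm(0.6), 0.5 * 0.42)
  expect_lt(abs(both - want), 3 * sqrt(want * (1 - want) / length(kid)))
  # h2 = 1 with both parents affected: offspring risk above prevalence
  st3 <- simulate_disease_status(kinship_matrix(ped2), 1, 0.40, seed = 21)
  s3 <- setNames(st3$status, st3$person_id)
  mom <- ped2$mother_id[!is.na(ped2$father_id)]
  risk <- mean(s3[kid][s3[dad] & s3[mom]])
  expect_gt(risk, 0.40)
})

test_that("simulate_cohort is deterministic end to end", {
  cfg <- simulation_config(n_families = 25, generations = 1, seed = 22)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a$phenotypes, b$phenotypes)
  expect_identical(a$statuses, b$statuses)
  # generated tables satisfy the phenotype invariants
  expect_true(all(a$phenotypes$tc > 0))
  expect_true(all(a$phenotypes$phase %in% 2:6))
})
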