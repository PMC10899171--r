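# small Gaussian cohort used by several blocks
sim_gaussian_cohort <- function(n_families, h2, seed, generations = 1) {
  cfg <- simulation_config(n_families = n_families,
                           generations = generations, seed = seed)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  set.seed(seed + 1000)
  g <- simulate_breeding_values(kin, h2)
  y <- unname(g) + rnorm(length(g), 0, sqrt(1 - h2))
  list(kin = kin, data = tibble::tibble(person_id = kin$ids, y = y))
}

test_that("profile-likelihood fit equals the dense MVN density oracle", {
  sim <- sim_gaussian_cohort(8, 0.5, seed = 3)  # ~30 individuals
  expect_lte(nrow(sim$data), 50)
  fit <- fit_polygenic_ml(sim$data, "y", sim$kin, method = "ML")
  a <- as.matrix(relationship_matrix(sim$kin))[sim$data$person_id,
                                               sim$data$person_id]
  v <- fit$sigma_g2 * a + fit$sigma_e2 * diag(nrow(a))
  x <- matrix(1, nrow(a), 1)
  expect_equal(fit$loglik, dense_mvn_loglik(sim$data$y, x, v),
               tolerance = 1e-8)
  # and at a non-optimal parameter value the oracle is lower
  v2 <- 0.9 * fit$sigma_g2 * a + 1.1 * fit$sigma_e2 * diag(nrow(a))
  expect_lt(dense_mvn_loglik(sim$data$y, x, v2), fit$loglik)
})

test_that("unrelated individuals give a flat profile flagged at zero", {
  ped <- pedigree(data.frame(
    family_id = paste0("F", 1:120), individual_id = paste0("I", 1:120),
    father_id = "0", mother_id = "0", sex = rep(c("1", "2"), 60)))
  kin <- kinship_matrix(ped)
  set.seed(8)
  dat <- tibble::tibble(person_id = kin$ids, y = rnorm(120))
  fit <- fit_polygenic_ml(dat, "y", kin)
  expect_equal(fit$h2, 0)
  expect_true(fit$boundary)
  expect_true(is.na(fit$se_h2))
})

test_that("a noiseless polygenic trait drives h2 to one", {
  cfg <- simulation_config(n_families = 40, generations = 1, seed = 5)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  g <- simulate_breeding_values(kin, 1, seed = 6)
  dat <- tibble::tibble(person_id = kin$ids, y = unname(g))
  fit <- fit_polygenic_ml(dat, "y", kin)
  expect_gte(fit$h2, 0.99)
})

test_that("ML and REML agree on large cohorts and tidy methods work", {
  sim <- sim_gaussian_cohort(250, 0.4, seed = 11)
  ml <- fit_polygenic_ml(sim$data, "y", sim$kin, method = "ML")
  reml <- fit_polygenic_ml(sim$data, "y", sim$kin, method = "REML")
  expect_lt(abs(ml$h2 - reml$h2), 0.02)
  td <- tidy(ml)
  expect_setequal(td$term, c("h2", "sigma_g2", "sigma_e2"))
  expect_equal(td$estimate[td$term == "h2"], ml$h2)
  gl <- glance(ml)
  expect_equal(gl$h2, ml$h2)
  expect_false(gl$boundary)
  expect_gt(ml$se_h2, 0)
})

test_that("MCMC schedule bookkeeping matches its definition", {
  cfg <- mcmc_config(400000, 200000, 40)
  expect_equal(cfg$n_retained, 5000L)
  expect_equal(mcmc_config(50000, 25000, 25)$n_retained, 1000L)
  expect_equal(mcmc_config(1000, 300, 7)$n_retained, 100L)  # floor
  expect_error(mcmc_config(1000, 1000, 10), "burn_in")
})

test_that("a prior-only Gibbs run reproduces the prior moments", {
  empty <- tibble::tibble(person_id = character(), y = double())
  fit <- gibbs_gaussian(empty, "y",
                        config = mcmc_config(4000, 1000, 1, n_chains = 2,
                                             seed = 2),
                        prior = list(df = 5, scale_g = 2, scale_e = 3))
  s <- summarize_posterior(fit)
  # scaled inverse-chi-square mean df*s/(df-2)
  expect_equal(s$mean[s$parameter == "sigma_g2"], 5 * 2 / 3,
               tolerance = 0.15)
  expect_equal(s$mean[s$parameter == "sigma_e2"], 5 * 3 / 3,
               tolerance = 0.15)
  expect_error(gibbs_gaussian(empty, "y"), "prior scales")
})

test_that("Gaussian Gibbs recovers a planted h2 and is seed-reproducible", {
  sim <- sim_gaussian_cohort(200, 0.4, seed = 21)
  cfg <- mcmc_config(4000, 2000, 2, n_chains = 2, seed = 7)
  fit <- gibbs_gaussian(sim$data, "y", sim$kin, config = cfg)
  s <- summarize_posterior(fit)
  expect_lt(abs(s$mean[s$parameter == "h2"] - 0.4), 0.08)
  expect_true(all(s$ci_low <= s$mean & s$mean <= s$ci_high))
  # identical seed, identical samples
  fit2 <- gibbs_gaussian(sim$data, "y", sim$kin, config = cfg)
  expect_identical(fit$chains, fit2$chains)
  # h2 summary is the mean of per-sample ratios
  pooled <- do.call(rbind, fit$chains)
  expect_equal(s$mean[s$parameter == "h2"],
               mean(pooled[, "sigma_g2"] /
                      (pooled[, "sigma_g2"] + pooled[, "sigma_e2"])))
})

test_that("planted zero genetic variance concentrates the posterior at 0", {
  cfg <- simulation_config(n_families = 500, generations = 1, seed = 31)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  st <- simulate_disease_status(kin, 0, 0.4, seed = 32)
  expect_gte(nrow(st), 2000)
  fit <- gibbs_probit(st, "status", kin,
                      config = mcmc_config(4000, 1500, 2, n_chains = 2,
                                           seed = 5))
  s <- summarize_posterior(fit)
  expect_lt(s$ci_high[s$parameter == "h2"], 0.15)
})

test_that("probit Gibbs implies the simulated prevalence", {
  cfg <- simulation_config(n_families = 250, generations = 1, seed = 41)
  ped <- simulate_pedigree(cfg)
  kin <- kinship_matrix(ped)
  st <- simulate_disease_status(kin, 0.41, 0.40, seed = 42)
  fit <- gibbs_probit(st, "status", kin,
                      config = mcmc_config(3000, 1000, 2, n_chains = 2,
                                           seed = 6))
  s <- summarize_posterior(fit)
  mu <- s$mean[s$parameter == "(Intercept)"]
  sg <- s$mean[s$parameter == "sigma_g2"]
  implied <- pnorm(mu / sqrt(sg + 1))
  expect_lt(abs(implied - mean(st$status)), 0.05)
  expect_error(gibbs_probit(dplyr::mutate(st, status = TRUE), "status", kin),
               "both outcome classes")
})

test_that("Gelman-Rubin follows its closed forms", {
  x <- rnorm(50)
  # identical chains: B = 0, psrf = sqrt((n-1)/n)
  expect_equal(gelman_rubin(list(x, x)), sqrt(49 / 50))
  # same-distribution chains mix
  set.seed(9)
  ch <- replicate(3, rnorm(10000), simplify = FALSE)
  expect_lt(gelman_rubin(ch), 1.01)
  # disjoint chains diverge
  expect_gt(gelman_rubin(list(rnorm(100), rnorm(100, 10))), 1.1)
  expect_error(gelman_rubin(list(x)), "at least 2")
  expect_error(gelman_rubin(list(rep(1, 20), rep(1, 20))),
               "zero within-chain variance")
  expect_error(gelman_rubin(list(rnorm(5), rnorm(5))), "length >= 10")
  # matrix input: one column per chain
  expect_equal(gelman_rubin(cbind(x, x)), sqrt(49 / 50))
})

test_that("posterior summaries expose moments, intervals and traces", {
  fake <- structure(list(
    chains = list(cbind(h2 = rep(0.5, 100)), cbind(h2 = rep(0.5, 100))),
    config = mcmc_config(200, 100, 1, n_chains = 2, seed = 1),
    model = "gaussian", trait = "y", n = 0),
    class = "polygenic_mcmc")
  s <- summarize_posterior(fake)
  expect_equal(s$sd, 0)
  expect_equal(s$ci_low, s$ci_high)  # collapsed interval
  set.seed(10)
  fake2 <- structure(list(
    chains = list(cbind(h2 = rnorm(2500)), cbind(h2 = rnorm(2500))),
    config = mcmc_config(200, 100, 1, n_chains = 2, seed = 1),
    model = "gaussian", trait = "y", n = 0),
    class = "polygenic_mcmc")
  s2 <- summarize_posterior(fake2)
  expect_lt(abs(s2$mean), 3 / sqrt(5000))
  draws <- posterior_samples(fake2)
  expect_equal(nrow(draws), 5000)
  expect_setequal(unique(draws$chain), 1:2)
  p <- autoplot(fake2)
  expect_s3_class(p, "ggplot")
})
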