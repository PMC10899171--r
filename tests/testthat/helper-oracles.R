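# Independent oracles used across the suite. These deliberately take
# different computational routes from the package implementation.

# Monte-Carlo kinship by gene dropping: founders get unique allele labels,
# every descendant inherits one random allele from each parent; phi_ij is
# the probability a random allele from i matches (is identical by descent
# to) a random allele from j, averaged over the four allele comparisons.
# Vectorized over drops. Returns list(phi, se) of matrices.
gene_drop_kinship <- function(ped, n_drops = 2e5) {
  ids <- ped$individual_id
  n <- length(ids)
  idx <- setNames(seq_len(n), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  a1 <- matrix(0L, n_drops, n)
  a2 <- matrix(0L, n_drops, n)
  lab <- 0L
  for (i in seq_len(n)) {  # pedigree rows are parents-first
    if (is.na(fa[i])) {
      a1[, i] <- lab + 1L
      lab <- lab + 2L
      a2[, i] <- lab
    } else {
      pick <- runif(n_drops) < 0.5
      a1[, i] <- ifelse(pick, a1[, fa[i]], a2[, fa[i]])
    }
    if (!is.na(mo[i])) {
      pick <- runif(n_drops) < 0.5
      a2[, i] <- ifelse(pick, a1[, mo[i]], a2[, mo[i]])
    } else if (is.na(fa[i]) && is.na(mo[i])) {
      # both labels already assigned above
    } else if (is.na(mo[i])) {
      lab <- lab + 1L
      a2[, i] <- lab
    }
    if (is.na(fa[i]) && !is.na(mo[i])) {
      lab <- lab + 1L
      a1[, i] <- lab
    }
  }
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  se <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n)) {
    for (j in i:n) {
      ind <- ((a1[, i] == a1[, j]) + (a1[, i] == a2[, j]) +
                (a2[, i] == a1[, j]) + (a2[, i] == a2[, j])) / 4
      phi[i, j] <- phi[j, i] <- mean(ind)
      se[i, j] <- se[j, i] <- sd(ind) / sqrt(n_drops)
    }
  }
  list(phi = phi, se = se)
}

# Brute-force relative-pair classifier: explicit ancestor-path logic over
# every unordered pair, no precomputation shared with the package.
brute_pair_classify <- function(ped) {
  fa <- setNames(ped$father_id, ped$individual_id)
  mo <- setNames(ped$mother_id, ped$individual_id)
  fam <- setNames(ped$family_id, ped$individual_id)
  par_of <- function(i) na.omit(c(fa[[i]], mo[[i]]))
  fullsib <- function(i, j) {
    !is.na(fa[[i]]) && !is.na(mo[[i]]) &&
      isTRUE(fa[[i]] == fa[[j]]) && isTRUE(mo[[i]] == mo[[j]])
  }
  halfsib <- function(i, j) {
    s <- sum(isTRUE(fa[[i]] == fa[[j]]) && !is.na(fa[[i]]),
             isTRUE(mo[[i]] == mo[[j]]) && !is.na(mo[[i]]))
    s == 1
  }
  classify <- function(i, j) {
    if (i %in% par_of(j) || j %in% par_of(i)) return("parent_offspring")
    if (fullsib(i, j)) return("sibling")
    gp_i <- unique(unlist(lapply(par_of(i), par_of)))
    gp_j <- unique(unlist(lapply(par_of(j), par_of)))
    if (i %in% gp_j || j %in% gp_i) return("grandparental")
    if (any(sapply(par_of(j), function(p) fullsib(i, p))) ||
        any(sapply(par_of(i), function(p) fullsib(j, p)))) {
      return("avuncular")
    }
    if (halfsib(i, j)) return("half_sibling")
    for (pi in par_of(i)) {
      for (pj in par_of(j)) if (fullsib(pi, pj)) return("cousin")
    }
    NA_character_
  }
  ids <- ped$individual_id
  out <- list()
  for (a in seq_along(ids)) {
    for (b in seq_along(ids)) {
      if (b <= a) next
      if (fam[[ids[a]]] != fam[[ids[b]]]) next
      cl <- classify(ids[a], ids[b])
      if (!is.na(cl)) out[[length(out) + 1]] <- cl
    }
  }
  table(unlist(out))
}

# Dense multivariate-normal log-likelihood with GLS fixed effects, for
# checking the profile-likelihood fit on small pedigrees.
dense_mvn_loglik <- function(y, x, v) {
  n <- length(y)
  vi <- solve(v)
  beta <- solve(t(x) %*% vi %*% x, t(x) %*% vi %*% y)
  r <- y - x %*% beta
  -0.5 * (n * log(2 * pi) + determinant(v, logarithm = TRUE)$modulus[1] +
            drop(t(r) %*% vi %*% r))
}

# One-way random-effects ANOVA ICC on balanced pairs, method-of-moments
# (divide-by-n) mean squares, via aov's sums of squares.
anova_icc <- function(x, y) {
  n <- length(x)
  v <- c(x, y)
  g <- factor(rep(seq_len(n), 2))
  ss <- anova(aov(v ~ g))$"Sum Sq"
  msb <- ss[1] / n
  msw <- ss[2] / n
  (msb - msw) / (msb + msw)
}

# Closed-form 2x2 odds ratio.
or_2x2 <- function(a, b, c, d) (a * d) / (b * c)

# P(X > t, Y > t) for standard bivariate normal with correlation rho,
# by 1-D numeric integration; used for liability-model concordance and
# the tetrachoric-to-observed conversion.
bvn_exceedance <- function(t, rho) {
  integrate(function(x) {
    dnorm(x) * pnorm((t - rho * x) / sqrt(1 - rho^2), lower.tail = FALSE)
  }, t, Inf, rel.tol = 1e-10)$value
}

# Observed-scale correlation of threshold indicators given liability
# correlation rho and prevalence p.
observed_scale_corr <- function(rho, prevalence) {
  t <- qnorm(1 - prevalence)
  p11 <- bvn_exceedance(t, rho)
  (p11 - prevalence^2) / (prevalence * (1 - prevalence))
}

# Random valid pedigree for property tests: founder couples plus a few
# offspring generations with random mates, guaranteed acyclic.
random_pedigree <- function(n_members = 12, n_families = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  fams <- lapply(seq_len(n_families), function(f) {
    fid <- paste0("R", f)
    id <- function(k) paste0(fid, "_", k)
    rows <- data.frame(family_id = fid, individual_id = id(1:2),
                       father_id = NA_character_, mother_id = NA_character_,
                       sex = c("male", "female"))
    k <- 2
    while (k < n_members) {
      males <- rows$individual_id[rows$sex == "male"]
      females <- rows$individual_id[rows$sex == "female"]
      pa <- sample(males, 1)
      ma <- sample(females, 1)
      # avoid parent-child matings to keep things plausible (not required)
      k <- k + 1
      rows <- rbind(rows, data.frame(
        family_id = fid, individual_id = id(k), father_id = pa,
        mother_id = ma, sex = sample(c("male", "female"), 1)))
      # occasionally add a fresh founder to keep the mate pool mixed
      if (runif(1) < 0.3 && k < n_members) {
        k <- k + 1
        rows <- rbind(rows, data.frame(
          family_id = fid, individual_id = id(k), father_id = NA_character_,
          mother_id = NA_character_, sex = sample(c("male", "female"), 1)))
      }
    }
    rows
  })
  famlipid::pedigree(do.call(rbind, fams), missing_code = NA_character_)
}

# Small helper: nuclear-family pedigree used in several tests.
nuclear_family <- function() {
  famlipid::pedigree(data.frame(
    family_id = "N1",
    individual_id = c("dad", "mom", "s1", "s2", "d1"),
    father_id = c("0", "0", "dad", "dad", "dad"),
    mother_id = c("0", "0", "mom", "mom", "mom"),
    sex = c("1", "2", "1", "1", "2")))
}
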