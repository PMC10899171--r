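#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

# Per-family eigenstructure of the additive relationship matrix restricted
# to the phenotyped individuals. Families are independent blocks of A, so
# one small dense eigendecomposition per family gives U and d with
# A = U diag(d) U'; all model fitting then works in the rotated basis
# where the random effect has independent components.
polygenic_structure <- function(kin, ids) {
  stopifnot(inherits(kin, "kinship_matrix"))
  miss <- setdiff(ids, kin$ids)
  if (length(miss) > 0) {
    stop("ids absent from the kinship matrix: ",
         paste(utils::head(miss, 5), collapse = ", "))
  }
  fam <- kin$family_id[match(ids, kin$ids)]
  ord <- order(match(fam, unique(fam)))  # stable block order
  ids_b <- ids[ord]
  fam_b <- fam[ord]
  blocks <- split(ids_b, factor(fam_b, levels = unique(fam_b)))
  eig <- lapply(blocks, function(members) {
    a <- 2 * as.matrix(kin$phi[members, members, drop = FALSE])
    e <- eigen(a, symmetric = TRUE)
    list(u = e$vectors, d = pmax(e$values, 0))
  })
  u <- Matrix::bdiag(lapply(eig, `[[`, "u"))
  list(ids = ids_b, perm = ord, u = u,
       d = unlist(lapply(eig, `[[`, "d"), use.names = FALSE))
}

# model matrix: intercept plus requested covariates (sex -> indicator)
polygenic_design <- function(data, covariates) {
  n <- nrow(data)
  x <- matrix(1, n, 1, dimnames = list(NULL, "(Intercept)"))
  for (v in covariates) {
    col <- data[[v]]
    if (is.character(col) || is.factor(col)) {
      col <- as.numeric(factor(col) == levels(factor(col))[2])
    }
    if (length(unique(col)) > 1) {
      x <- cbind(x, col)
      colnames(x)[ncol(x)] <- v
    }
  }
  x
}

#' Polygenic mixed model by profile maximum likelihood
#'
#' Fits the Gaussian polygenic ("animal") model
#' `y = X beta + g + e`, `g ~ N(0, A sigma_g^2)`, `e ~ N(0, I sigma_e^2)`
#' with `A = 2 phi` the numerator relationship matrix, by maximizing the
#' (restricted) multivariate-normal likelihood. A one-time per-family
#' eigendecomposition of `A` reduces the problem to a 1-D profile
#' likelihood over `h2 = sigma_g^2 / (sigma_g^2 + sigma_e^2)` on \[0, 1\];
#' the total variance and fixed effects are profiled out analytically.
#' The standard error of `h2` comes from the numerical curvature of the
#' profile log-likelihood.
#'
#' @param data Tibble with `person_id`, the trait column, and any
#'   covariates.
#' @param trait Name of the (transformed) trait column.
#' @param kin A `kinship_matrix` covering the phenotyped individuals.
#' @param covariates Fixed-effect columns beyond the intercept (use
#'   `NULL`, the default, when the trait was pre-residualized on age and
#'   sex; pass `c("age", "sex")` for raw traits).
#' @param method `"ML"` (default) or `"REML"`.
#' @return An object of class `polygenic_fit` with components `h2`,
#'   `se_h2`, `sigma_g2`, `sigma_e2`, `loglik`, `beta`, `n`, `method`,
#'   `boundary` (TRUE when the optimum lies at h2 = 0 or 1) and `trait`.
#' @export
fit_polygenic_ml <- function(data, trait, kin, covariates = NULL,
                             method = c("ML", "REML")) {
  method <- match.arg(method)
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[trait]]), ]
  str <- polygenic_structure(kin, data$person_id)
  data <- data[str$perm, ]
  y <- data[[trait]]
  x <- polygenic_design(data, covariates)
  n <- length(y)
  p <- ncol(x)
  ys <- as.numeric(Matrix::crossprod(str$u, y))
  xs <- as.matrix(Matrix::crossprod(str$u, x))
  d <- str$d

  prof <- function(h2) {
    w <- pmax(h2 * d + (1 - h2), 1e-12)
    xw <- xs / w
    xtwx <- crossprod(xs, xw)
    beta <- solve(xtwx, crossprod(xw, ys))
    r <- ys - xs %*% beta
    q <- sum(r^2 / w)
    if (method == "ML") {
      s2 <- q / n
      ll <- -0.5 * (n * log(2 * pi * s2) + sum(log(w)) + n)
    } else {
      s2 <- q / (n - p)
      ll <- -0.5 * ((n - p) * log(2 * pi * s2) + sum(log(w)) +
                      determinant(xtwx, logarithm = TRUE)$modulus[1] + (n - p))
    }
    list(ll = ll, s2 = s2, beta = beta)
  }

  opt <- stats::optimize(function(h) prof(h)$ll, interval = c(0, 1),
                         maximum = TRUE, tol = 1e-8)
  h2 <- opt$maximum
  at <- prof(h2)
  # the optimizer never returns exact endpoints; re-check them
  for (edge in c(0, 1)) {
    pe <- prof(edge)
    if (pe$ll > at$ll) { h2 <- edge; at <- pe }
  }
  # a flat profile (e.g. A = identity: no familial resemblance information)
  # leaves h2 unidentified; report 0 and flag it
  if (at$ll - prof(0)$ll < 1e-8) {
    h2 <- 0
    at <- prof(0)
  }
  boundary <- h2 < 1e-4 || h2 > 1 - 1e-4
  eps <- 1e-4
  se_h2 <- if (!boundary) {
    d2 <- (prof(h2 + eps)$ll - 2 * at$ll + prof(h2 - eps)$ll) / eps^2
    if (d2 < 0) sqrt(-1 / d2) else NA_real_
  } else NA_real_

  structure(list(h2 = h2, se_h2 = se_h2,
                 sigma_g2 = h2 * at$s2, sigma_e2 = (1 - h2) * at$s2,
                 loglik = at$ll, beta = stats::setNames(as.numeric(at$beta),
                                                        colnames(x)),
                 n = n, method = method, boundary = boundary, trait = trait),
            class = "polygenic_fit")
}

#' @export
print.polygenic_fit <- function(x, ...) {
  cat("<polygenic_fit> trait:", x$trait, " method:", x$method, "\n",
      sprintf("  h2 = %.4f (SE %.4f)  sigma_g2 = %.4f  sigma_e2 = %.4f\n",
              x$h2, x$se_h2, x$sigma_g2, x$sigma_e2),
      if (x$boundary) "  note: estimate at the boundary of [0, 1]\n" else "",
      sep = "")
  invisible(x)
}

#' @rdname fit_polygenic_ml
#' @param x A `polygenic_fit`.
#' @param ... Unused.
#' @export
tidy.polygenic_fit <- function(x, ...) {
  tibble::tibble(term = c("h2", "sigma_g2", "sigma_e2"),
                 estimate = c(x$h2, x$sigma_g2, x$sigma_e2),
                 std.error = c(x$se_h2, NA, NA))
}

#' @rdname fit_polygenic_ml
#' @export
glance.polygenic_fit <- function(x, ...) {
  tibble::tibble(trait = x$trait, method = x$method, h2 = x$h2,
                 se_h2 = x$se_h2, sigma_g2 = x$sigma_g2,
                 sigma_e2 = x$sigma_e2, logLik = x$loglik, nobs = x$n,
                 boundary = x$boundary)
}

#' MCMC schedule
#'
#' @param n_iter Iterations per chain.
#' @param burn_in Burn-in iterations discarded (must be < `n_iter`).
#' @param thin Thinning interval (>= 1).
#' @param n_chains Number of chains (at least 1; convergence diagnostics need
#'   2 or more).
#' @param seed Integer RNG seed.
#' @return A `mcmc_config` list including `n_retained =
#'   floor((n_iter - burn_in) / thin)` per chain.
#' @export
#' @examples
#' mcmc_config(400000, 200000, 40)$n_retained  # 5000
mcmc_config <- function(n_iter = 50000, burn_in = 25000, thin = 25,
                        n_chains = 2, seed = 1) {
  stopifnot(burn_in < n_iter, thin >= 1, n_chains >= 1)
  structure(list(n_iter = as.integer(n_iter), burn_in = as.integer(burn_in),
                 thin = as.integer(thin), n_chains = as.integer(n_chains),
                 seed = as.integer(seed),
                 n_retained = as.integer((n_iter - burn_in) %/% thin)),
            class = "mcmc_config")
}

# scaled inverse chi-square draw: (df0*s0 + ss) / chisq(df0 + n)
riscaled_chisq <- function(df0, s0, ss = 0, n = 0) {
  (df0 * s0 + ss) / stats::rchisq(1, df0 + n)
}

#' Gibbs sampler for the Gaussian polygenic model
#'
#' Full-conditional Gibbs sampling of `y = X beta + g + e`,
#' `g ~ N(0, A sigma_g^2)`, `e ~ N(0, I sigma_e^2)`. The random effect is
#' rotated into the eigenbasis of `A` (computed once per family block)
#' where its components are independent, so every update is a vectorized
#' closed-form draw: normal for `beta` and the rotated effects, scaled
#' inverse-chi-square for the two variances (weakly informative prior,
#' default df 5 and scale half the trait variance each).
#'
#' @inheritParams fit_polygenic_ml
#' @param config An [mcmc_config()].
#' @param prior List with `df`, `scale_g`, `scale_e`; scales default to
#'   `var(y) / 2`. Must be given explicitly for a prior-only run
#'   (`data` with zero rows), which samples from the prior.
#' @return Object of class `polygenic_mcmc`: retained samples per chain
#'   (columns: fixed effects, `sigma_g2`, `sigma_e2`, `h2`), the config,
#'   and the model label.
#' @export
gibbs_gaussian <- function(data, trait, kin = NULL, covariates = NULL,
                           config = mcmc_config(), prior = list()) {
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[trait]]), ]
  n <- nrow(data)
  if (n > 0) {
    str <- polygenic_structure(kin, data$person_id)
    data <- data[str$perm, ]
    y <- data[[trait]]
    x <- polygenic_design(data, covariates)
    ys <- as.numeric(Matrix::crossprod(str$u, y))
    xs <- as.matrix(Matrix::crossprod(str$u, x))
    d <- str$d
    pos <- d > 1e-12
    xtx_r <- chol(crossprod(xs))
    p <- ncol(xs)
    vy <- stats::var(y)
  } else {
    p <- 0
    vy <- NULL
  }
  defaults <- list(df = 5,
                   scale_g = if (n > 0) vy / 2,
                   scale_e = if (n > 0) vy / 2)
  pr <- utils::modifyList(defaults, prior)
  if (is.null(pr$scale_g) || is.null(pr$scale_e)) {
    stop("gibbs_gaussian: prior scales must be supplied for a prior-only run")
  }

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    # overdispersed starting values
    sg2 <- pr$scale_g * exp(stats::runif(1, -1, 1))
    se2 <- pr$scale_e * exp(stats::runif(1, -1, 1))
    if (n > 0) {
      beta <- rep(0, p)
      a <- rep(0, n)
    }
    keep <- matrix(NA_real_, config$n_retained, p + 3)
    colnames(keep) <- c(if (n > 0) colnames(xs), "sigma_g2", "sigma_e2", "h2")
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      if (n > 0) {
        # rotated random effects: independent normal full conditionals
        r <- ys - drop(xs %*% beta)
        v <- 1 / (1 / se2 + 1 / (sg2 * d))
        a <- stats::rnorm(n, (r / se2) * v, sqrt(v))
        a[!pos] <- 0
        # fixed effects, flat prior
        bhat <- backsolve(xtx_r,
                          backsolve(xtx_r, crossprod(xs, ys - a),
                                    transpose = TRUE))
        beta <- drop(bhat) + sqrt(se2) *
          backsolve(xtx_r, stats::rnorm(p))
        ss_g <- sum(a[pos]^2 / d[pos])
        sg2 <- riscaled_chisq(pr$df, pr$scale_g, ss_g, sum(pos))
        e <- ys - drop(xs %*% beta) - a
        se2 <- riscaled_chisq(pr$df, pr$scale_e, sum(e^2), n)
      } else {
        sg2 <- riscaled_chisq(pr$df, pr$scale_g)
        se2 <- riscaled_chisq(pr$df, pr$scale_e)
      }
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        k <- k + 1L
        keep[k, ] <- c(if (n > 0) beta, sg2, se2, sg2 / (sg2 + se2))
      }
    }
    chains[[ch]] <- keep
  }
  structure(list(chains = chains, config = config, model = "gaussian",
                 trait = trait, n = n),
            class = "polygenic_mcmc")
}

#' Gibbs sampler for the probit liability (threshold) model
#'
#' Binary outcomes are modelled through an unobserved Gaussian liability
#' `l = X beta + g + e` with `e ~ N(0, 1)` (fixed for identifiability) and
#' `status = (l > 0)`; the probit link arises as
#' `P(status = 1) = Phi(eta)`. Sampling augments the data with the latent
#' liabilities (truncated-normal draws consistent with each observed
#' status) and then applies the Gaussian-model updates with the residual
#' variance fixed at 1. Liability-scale heritability
#' `h2 = sigma_g^2 / (sigma_g^2 + 1)` is recorded per retained sample.
#'
#' @inheritParams gibbs_gaussian
#' @param status Name of the logical/0-1 outcome column; both classes must
#'   be present.
#' @param prior List with `df` and `scale_g` (default df 5, scale half the
#'   variance of the observed 0/1 outcome).
#' @return Object of class `polygenic_mcmc` (columns: fixed effects,
#'   `sigma_g2`, `h2`).
#' @export
gibbs_probit <- function(data, status, kin, covariates = NULL,
                         config = mcmc_config(), prior = list()) {
  data <- tibble::as_tibble(data)
  data <- data[!is.na(data[[status]]), ]
  z <- as.logical(data[[status]])
  if (length(unique(z)) < 2) {
    stop("gibbs_probit: both outcome classes must be present")
  }
  str <- polygenic_structure(kin, data$person_id)
  data <- data[str$perm, ]
  z <- z[str$perm]
  x <- polygenic_design(data, covariates)
  n <- nrow(x)
  p <- ncol(x)
  u <- str$u
  d <- str$d
  pos <- d > 1e-12
  xtx_r <- chol(crossprod(x))
  pr <- utils::modifyList(list(df = 5, scale_g = stats::var(as.numeric(z)) / 2),
                          prior)

  set.seed(config$seed)
  chains <- vector("list", config$n_chains)
  for (ch in seq_len(config$n_chains)) {
    sg2 <- pr$scale_g * exp(stats::runif(1, -1, 1))
    beta <- rep(0, p)
    kvec <- rep(0, n)  # genetic effect in observation order
    keep <- matrix(NA_real_, config$n_retained, p + 2)
    colnames(keep) <- c(colnames(x), "sigma_g2", "h2")
    k <- 0L
    for (it in seq_len(config$n_iter)) {
      eta <- drop(x %*% beta) + kvec
      # truncated-normal latent liabilities (inverse-CDF, vectorized)
      p0 <- stats::pnorm(-eta)
      uu <- stats::runif(n)
      q <- ifelse(z, p0 + uu * (1 - p0), uu * p0)
      q <- pmin(pmax(q, 1e-12), 1 - 1e-12)
      l <- eta + stats::qnorm(q)
      # rotated residual for the random-effect update (se2 = 1)
      rs <- as.numeric(Matrix::crossprod(u, l - drop(x %*% beta)))
      v <- 1 / (1 + 1 / (sg2 * d))
      a <- stats::rnorm(n, rs * v, sqrt(v))
      a[!pos] <- 0
      kvec <- as.numeric(u %*% a)
      bhat <- backsolve(xtx_r,
                        backsolve(xtx_r, crossprod(x, l - kvec),
                                  transpose = TRUE))
      beta <- drop(bhat) + backsolve(xtx_r, stats::rnorm(p))
      ss_g <- sum(a[pos]^2 / d[pos])
      sg2 <- riscaled_chisq(pr$df, pr$scale_g, ss_g, sum(pos))
      if (it > config$burn_in && (it - config$burn_in) %% config$thin == 0) {
        k <- k + 1L
        keep[k, ] <- c(beta, sg2, sg2 / (sg2 + 1))
      }
    }
    chains[[ch]] <- keep
  }
  structure(list(chains = chains, config = config, model = "probit",
                 trait = status, n = n),
            class = "polygenic_mcmc")
}

#' Gelman-Rubin potential scale reduction factor
#'
#' `psrf = sqrt(((n - 1) / n * W + B / n) / W)` with `W` the mean
#' within-chain variance and `B` the between-chain variance of the chain
#' means times `n`. Values near 1 indicate the chains have mixed.
#'
#' @param chains A list of equal-length numeric vectors, or a matrix with
#'   one column per chain. At least 2 chains of length >= 10.
#' @return The PSRF (numeric scalar).
#' @export
gelman_rubin <- function(chains) {
  if (is.matrix(chains)) chains <- asplit(chains, 2)
  chains <- lapply(chains, as.numeric)
  m <- length(chains)
  if (m < 2) stop("gelman_rubin: need at least 2 chains")
  n <- unique(lengths(chains))
  if (length(n) != 1) stop("gelman_rubin: chains must have equal length")
  if (n < 10) stop("gelman_rubin: chains must have length >= 10")
  w <- mean(vapply(chains, stats::var, double(1)))
  if (w == 0) stop("gelman_rubin: zero within-chain variance")
  b <- n * stats::var(vapply(chains, mean, double(1)))
  sqrt(((n - 1) / n * w + b / n) / w)
}

#' Summarize a posterior sample
#'
#' Posterior mean, sd, equal-tailed 95\% credible interval and (for >= 2
#' chains) the Gelman-Rubin PSRF, per parameter. For `h2` the summary is
#' of the per-sample variance ratio, not a ratio of means.
#'
#' @param x A `polygenic_mcmc` object.
#' @param conf_level Credible level (default 0.95).
#' @param ... Unused.
#' @return Tibble: `parameter`, `mean`, `sd`, `ci_low`, `ci_high`, `psrf`.
#' @export
summarize_posterior <- function(x, conf_level = 0.95, ...) {
  UseMethod("summarize_posterior")
}

#' @export
summarize_posterior.polygenic_mcmc <- function(x, conf_level = 0.95, ...) {
  params <- colnames(x$chains[[1]])
  alpha <- (1 - conf_level) / 2
  purrr::map_dfr(params, function(pm) {
    per_chain <- lapply(x$chains, function(m) m[, pm])
    pooled <- unlist(per_chain, use.names = FALSE)
    psrf <- if (length(per_chain) >= 2 && stats::sd(pooled) > 0) {
      gelman_rubin(per_chain)
    } else {
      NA_real_
    }
    tibble::tibble(parameter = pm, mean = mean(pooled), sd = stats::sd(pooled),
                   ci_low = stats::quantile(pooled, alpha, names = FALSE),
                   ci_high = stats::quantile(pooled, 1 - alpha, names = FALSE),
                   psrf = psrf)
  })
}

#' Posterior samples in long form
#'
#' @param x A `polygenic_mcmc`.
#' @return Tibble: `chain`, `iteration`, `parameter`, `value` (retained
#'   samples only).
#' @export
posterior_samples <- function(x) {
  stopifnot(inherits(x, "polygenic_mcmc"))
  purrr::imap_dfr(x$chains, function(m, ch) {
    df <- tibble::as_tibble(as.data.frame(m))
    df$chain <- ch
    df$iteration <- seq_len(nrow(m))
    tidyr::pivot_longer(df, -c("chain", "iteration"),
                        names_to = "parameter", values_to = "value")
  })
}

#' @export
print.polygenic_mcmc <- function(x, ...) {
  cat("<polygenic_mcmc> model:", x$model, " trait:", x$trait, "\n",
      "  ", x$config$n_chains, " chain(s) x ", x$config$n_retained,
      " retained samples (", x$config$n_iter, " iterations, ",
      x$config$burn_in, " burn-in, thin ", x$config$thin, ")\n", sep = "")
  print(summarize_posterior(x))
  invisible(x)
}

#' @rdname summarize_posterior
#' @export
tidy.polygenic_mcmc <- function(x, conf_level = 0.95, ...) {
  summarize_posterior(x, conf_level = conf_level)
}

#' @rdname summarize_posterior
#' @export
glance.polygenic_mcmc <- function(x, ...) {
  s <- summarize_posterior(x)
  row_h2 <- s[s$parameter == "h2", ]
  row_sg <- s[s$parameter == "sigma_g2", ]
  tibble::tibble(model = x$model, trait = x$trait, h2 = row_h2$mean,
                 sd_h2 = row_h2$sd, psrf_sigma_g2 = row_sg$psrf, nobs = x$n,
                 n_retained = x$config$n_retained,
                 n_chains = x$config$n_chains)
}

#' Trace plot of retained posterior samples
#'
#' @param object A `polygenic_mcmc`.
#' @param parameters Parameters to show (default all).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.polygenic_mcmc <- function(object, parameters = NULL, ...) {
  df <- posterior_samples(object)
  if (!is.null(parameters)) df <- df[df$parameter %in% parameters, ]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$value,
                                   colour = factor(.data$chain))) +
    ggplot2::geom_line(alpha = 0.7) +
    ggplot2::facet_wrap(~parameter, scales = "free_y") +
    ggplot2::labs(colour = "chain", x = "retained iteration",
                  title = paste("Trace:", object$model, "model"))
}
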