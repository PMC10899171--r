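#' Pair up trait values for relative pairs
#'
#' Joins a typed pair table with a per-person trait table and returns one
#' row per pair with both members' values present. Exchangeable pair types
#' (same-sex sibling-like pairs and spouses) are marked for double entry;
#' ordered types (parent-offspring, grandparental, avuncular and mixed-sex
#' sibling-like pairs) keep the senior (or male) member in slot `x`.
#'
#' @param pairs Tibble from [pedigree_pairs()] (columns `family_id`,
#'   `id_a`, `id_b`, `category`, `sex_label`).
#' @param trait_table Tibble with `person_id` and the trait column.
#' @param trait Name of the trait column (default `"value"`).
#' @return Tibble with `family_id`, `category`, `sex_label`, `id_a`,
#'   `id_b`, `x`, `y`, `exchangeable`.
#' @export
build_pair_values <- function(pairs, trait_table, trait = "value") {
  val <- stats::setNames(trait_table[[trait]], trait_table$person_id)
  out <- tibble::as_tibble(pairs)
  out$x <- unname(val[out$id_a])
  out$y <- unname(val[out$id_b])
  out <- out[!is.na(out$x) & !is.na(out$y), ]
  same_sex_like <- out$category %in% c("sibling", "half_sibling", "cousin") &
    !grepl("brother-sister", out$sex_label, fixed = TRUE) &
    !grepl("male-female", out$sex_label, fixed = TRUE)
  out$exchangeable <- same_sex_like | out$category == "spouse"
  dplyr::select(out, "family_id", "category", "sex_label",
                "id_a", "id_b", "x", "y", "exchangeable")
}

# product-moment ICC point estimate on a pair-value tibble
icc_point <- function(x, y, exchangeable) {
  if (exchangeable) stats::cor(c(x, y), c(y, x)) else stats::cor(x, y)
}

#' Intraclass/interclass correlation for a relative-pair type
#'
#' Exchangeable pair types use the double-entry product-moment estimator
#' (each pair entered as (x, y) and (y, x)); ordered types use the plain
#' interclass product-moment correlation. The 95\% confidence interval is
#' a percentile cluster bootstrap resampling whole families, since pairs
#' within a family are not independent.
#'
#' @param pair_values Tibble from [build_pair_values()] (a single pair
#'   type).
#' @param exchangeable Override the `exchangeable` column (default: taken
#'   from the table, which must then be homogeneous).
#' @param n_boot Bootstrap resamples (default 2000).
#' @param conf_level Confidence level (default 0.95).
#' @param seed Optional RNG seed for the bootstrap.
#' @return One-row tibble: `icc`, `ci_low`, `ci_high`, `n_pairs`,
#'   `significant` (CI excludes 0).
#' @export
pair_icc <- function(pair_values, exchangeable = NULL, n_boot = 2000,
                     conf_level = 0.95, seed = NULL) {
  df <- tibble::as_tibble(pair_values)
  if (nrow(df) < 2) stop("pair_icc: need at least 2 pairs")
  if (is.null(exchangeable)) {
    stopifnot(length(unique(df$exchangeable)) == 1)
    exchangeable <- df$exchangeable[1]
  }
  if (stats::sd(df$x) == 0 || stats::sd(df$y) == 0) {
    if (!exchangeable || stats::sd(c(df$x, df$y)) == 0) {
      stop("pair_icc: zero variance in pair values")
    }
  }
  est <- icc_point(df$x, df$y, exchangeable)
  if (!is.null(seed)) {
    old <- globalenv()$.Random.seed
    on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv()))
    set.seed(seed)
  }
  fams <- split(seq_len(nrow(df)), df$family_id)
  boots <- vapply(seq_len(n_boot), function(b) {
    take <- unlist(fams[sample.int(length(fams), replace = TRUE)],
                   use.names = FALSE)
    x <- df$x[take]; y <- df$y[take]
    if (exchangeable) {
      if (stats::sd(c(x, y)) == 0) return(NA_real_)
    } else if (stats::sd(x) == 0 || stats::sd(y) == 0) {
      return(NA_real_)
    }
    icc_point(x, y, exchangeable)
  }, double(1))
  alpha <- (1 - conf_level) / 2
  ci <- stats::quantile(boots, c(alpha, 1 - alpha), na.rm = TRUE,
                        names = FALSE)
  tibble::tibble(icc = est, ci_low = ci[1], ci_high = ci[2],
                 n_pairs = nrow(df),
                 significant = ci[1] > 0 | ci[2] < 0)
}

#' Correlation of binary statuses within relative pairs
#'
#' Applies the same double-entry/interclass machinery to 0/1 disease
#' statuses (a phi-type correlation on the observed scale), with the
#' family cluster bootstrap CI.
#'
#' @inheritParams pair_icc
#' @return One-row tibble as in [pair_icc()].
#' @export
binary_icc <- function(pair_values, exchangeable = NULL, n_boot = 2000,
                       conf_level = 0.95, seed = NULL) {
  df <- tibble::as_tibble(pair_values)
  df$x <- as.numeric(df$x)
  df$y <- as.numeric(df$y)
  pair_icc(df, exchangeable = exchangeable, n_boot = n_boot,
           conf_level = conf_level, seed = seed)
}

#' Familial-correlation table across pair types
#'
#' Computes the ICC for every pair type and sex label present (plus a
#' pooled parent-offspring row), for one trait table. Pair types with
#' fewer than `min_pairs` complete pairs, or with degenerate variance,
#' are skipped.
#'
#' @param pairs Tibble from [pedigree_pairs()].
#' @param trait_table Tibble with `person_id` and trait columns.
#' @param traits Trait columns to analyze.
#' @param scenario Label stored in the output (e.g. `"FM"`).
#' @param binary Treat values as 0/1 statuses.
#' @param min_pairs Minimum pair count (default 10).
#' @inheritParams pair_icc
#' @return Tibble: `trait`, `scenario`, `category`, `sex_label`, `icc`,
#'   `ci_low`, `ci_high`, `n_pairs`, `significant`.
#' @export
familial_correlation <- function(pairs, trait_table, traits = "value",
                                 scenario = "FM", binary = FALSE,
                                 min_pairs = 10, n_boot = 2000, seed = NULL) {
  fn <- if (binary) binary_icc else pair_icc
  purrr::map_dfr(traits, function(tr) {
    pv <- build_pair_values(pairs, trait_table, trait = tr)
    groups <- dplyr::group_split(dplyr::group_by(pv, .data$category,
                                                 .data$sex_label))
    pooled <- pv[pv$category == "parent_offspring", ]
    if (nrow(pooled) > 0) {
      pooled$sex_label <- "pooled"
      groups <- c(groups, list(pooled))
    }
    purrr::map_dfr(groups, function(g) {
      if (nrow(g) < min_pairs) return(NULL)
      res <- tryCatch(fn(g, n_boot = n_boot, seed = seed),
                      error = function(e) NULL)
      if (is.null(res)) return(NULL)
      dplyr::bind_cols(tibble::tibble(trait = tr, scenario = scenario,
                                      category = g$category[1],
                                      sex_label = g$sex_label[1]), res)
    })
  })
}

#' Forest plot of familial correlations
#'
#' @param icc_table Tibble from [familial_correlation()].
#' @param significant_only Show only rows whose CI excludes zero.
#' @return A ggplot.
#' @export
plot_icc <- function(icc_table, significant_only = FALSE) {
  df <- if (significant_only) {
    dplyr::filter(icc_table, .data$significant)
  } else {
    icc_table
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$icc, y = .data$sex_label,
                                   colour = .data$scenario)) +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$ci_low, xmax = .data$ci_high),
      height = 0.2, position = ggplot2::position_dodge(width = 0.5)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2) +
    ggplot2::facet_grid(category ~ trait, scales = "free_y", space = "free_y") +
    ggplot2::labs(x = "intraclass correlation (95% CI)", y = NULL,
                  title = "Familial correlation by relative-pair type")
}
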