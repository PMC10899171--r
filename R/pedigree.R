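#' Read a PED-style pedigree file
#'
#' Parses a whitespace- or tab-delimited pedigree table with columns
#' family id, individual id, father id, mother id and sex, validates it,
#' and returns a pedigree tibble. Parents may appear after their children
#' in the file; the result is independent of row order up to row
#' arrangement.
#'
#' @param path Path to the pedigree file. No header is expected unless the
#'   first line matches the column names.
#' @param missing_code Code used for a missing parent (default `"0"`).
#' @param sex_codes Named character vector mapping file codes to sexes,
#'   default `c(male = "1", female = "2")`. Codes `"male"`/`"female"` are
#'   always accepted.
#' @return A `pedigree` tibble with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id` (`NA` when missing) and `sex`
#'   (`"male"`/`"female"`).
#' @export
#' @examples
#' ped_file <- tempfile()
#' writeLines(c("F1 P 0 0 1", "F1 M 0 0 2", "F1 C P M 1"), ped_file)
#' read_pedigree(ped_file)
read_pedigree <- function(path, missing_code = "0",
                          sex_codes = c(male = "1", female = "2")) {
  raw <- utils::read.table(path, header = FALSE, colClasses = "character",
                           col.names = c("family_id", "individual_id",
                                         "father_id", "mother_id", "sex"))
  if (nrow(raw) > 0 && identical(tolower(raw$family_id[1]), "family_id")) {
    raw <- raw[-1, , drop = FALSE]
  }
  pedigree(tibble::as_tibble(raw), missing_code = missing_code,
           sex_codes = sex_codes)
}

#' Construct and validate a pedigree
#'
#' Validates individual uniqueness, sex codes, parental sex consistency,
#' presence of referenced parents and acyclicity, and returns a classed
#' tibble used by the kinship and pair-enumeration functions.
#'
#' @param data Data frame with columns `family_id`, `individual_id`,
#'   `father_id`, `mother_id`, `sex`.
#' @inheritParams read_pedigree
#' @return A `pedigree` tibble.
#' @export
pedigree <- function(data, missing_code = "0",
                     sex_codes = c(male = "1", female = "2")) {
  cols <- c("family_id", "individual_id", "father_id", "mother_id", "sex")
  if (!all(cols %in% names(data))) {
    stop("pedigree data must have columns: ", paste(cols, collapse = ", "))
  }
  ped <- tibble::as_tibble(data[cols])
  ped <- dplyr::mutate(ped, dplyr::across(dplyr::everything(), as.character))

  dup <- ped$individual_id[duplicated(ped$individual_id)]
  if (length(dup) > 0) {
    stop("duplicated individual id(s): ", paste(unique(dup), collapse = ", "))
  }

  sex_map <- c(stats::setNames(names(sex_codes), sex_codes),
               male = "male", female = "female")
  sex <- unname(sex_map[ped$sex])
  if (anyNA(sex)) {
    bad <- unique(ped$sex[is.na(sex)])
    stop("unknown sex code(s): ", paste(bad, collapse = ", "))
  }
  ped$sex <- sex

  ped$father_id[ped$father_id %in% missing_code] <- NA_character_
  ped$mother_id[ped$mother_id %in% missing_code] <- NA_character_

  refs <- stats::na.omit(unique(c(ped$father_id, ped$mother_id)))
  absent <- setdiff(refs, ped$individual_id)
  if (length(absent) > 0) {
    stop("referenced parent(s) absent from pedigree: ",
         paste(absent, collapse = ", "))
  }

  sex_of <- stats::setNames(ped$sex, ped$individual_id)
  bad_father <- unique(stats::na.omit(ped$father_id[
    sex_of[ped$father_id] != "male"]))
  if (length(bad_father) > 0) {
    stop("father(s) recorded with sex=female: ",
         paste(bad_father, collapse = ", "))
  }
  bad_mother <- unique(stats::na.omit(ped$mother_id[
    sex_of[ped$mother_id] != "female"]))
  if (length(bad_mother) > 0) {
    stop("mother(s) recorded with sex=male: ",
         paste(bad_mother, collapse = ", "))
  }

  # acyclicity check via Kahn's algorithm, then a canonical order
  # (family, generation depth, id) so loading is row-order independent
  ord <- pedigree_order(ped)
  depth <- stats::setNames(integer(nrow(ped)), ord)
  fa <- stats::setNames(ped$father_id, ped$individual_id)
  mo <- stats::setNames(ped$mother_id, ped$individual_id)
  for (id in ord) {
    pg <- depth[stats::na.omit(c(fa[[id]], mo[[id]]))]
    depth[id] <- if (length(pg) > 0) max(pg) + 1L else 0L
  }
  ped <- ped[order(match(ped$family_id, unique(ped$family_id)),
                   depth[ped$individual_id], ped$individual_id), ]
  class(ped) <- c("pedigree", class(tibble::tibble()))
  ped
}

# Topological order (founders first); errors on cycles.
pedigree_order <- function(ped) {
  ids <- ped$individual_id
  idx <- stats::setNames(seq_along(ids), ids)
  fa <- idx[ped$father_id]
  mo <- idx[ped$mother_id]
  n <- length(ids)
  indeg <- (!is.na(fa)) + (!is.na(mo))
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(fa[i], mo[i])) {
      if (!is.na(p)) children[[p]] <- c(children[[p]], i)
    }
  }
  queue <- which(indeg == 0)
  out <- integer(0)
  while (length(queue) > 0) {
    i <- queue[1]; queue <- queue[-1]
    out <- c(out, i)
    for (ch in children[[i]]) {
      indeg[ch] <- indeg[ch] - 1L
      if (indeg[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (length(out) < n) {
    stop("pedigree contains a cycle involving: ",
         paste(ids[setdiff(seq_len(n), out)], collapse = ", "))
  }
  ids[out]
}

#' Founders of a pedigree
#'
#' @param ped A `pedigree`.
#' @return Character vector of individual ids with both parents missing.
#' @export
founders <- function(ped) {
  ped$individual_id[is.na(ped$father_id) & is.na(ped$mother_id)]
}

#' Kinship matrix of a pedigree
#'
#' Computes pairwise kinship coefficients phi by the recursive tabular
#' method: individuals are processed parents-first; for a non-founder j
#' with parents f and m, `phi[i, j] = (phi[i, f] + phi[i, m]) / 2` for any
#' earlier i, and `phi[j, j] = (1 + phi[f, m]) / 2`, so the diagonal is
#' `0.5 * (1 + F)` with `F` the inbreeding coefficient. Founders are
#' assumed unrelated and non-inbred; a missing parent contributes zero
#' kinship.
#'
#' Families are independent blocks, so the result is stored as a sparse
#' block-diagonal symmetric matrix.
#'
#' @param ped A `pedigree`.
#' @return An object of class `kinship_matrix`: a list with elements
#'   `ids` (ordering of rows/columns), `family_id` (family of each id) and
#'   `phi` (sparse symmetric matrix of kinship coefficients with dimnames).
#' @export
#' @examples
#' ped <- pedigree(data.frame(
#'   family_id = "F1", individual_id = c("P", "M", "C"),
#'   father_id = c("0", "0", "P"), mother_id = c("0", "0", "M"),
#'   sex = c("1", "2", "1")))
#' kinship_matrix(ped)$phi
kinship_matrix <- function(ped) {
  stopifnot(inherits(ped, "pedigree") || is.data.frame(ped))
  if (!inherits(ped, "pedigree")) ped <- pedigree(ped)
  fams <- split(seq_len(nrow(ped)), ped$family_id)
  # keep first-appearance order of families
  fams <- fams[unique(ped$family_id)]
  blocks <- lapply(fams, function(rows) {
    kinship_block(ped[rows, , drop = FALSE])
  })
  phi <- Matrix::bdiag(lapply(blocks, function(b) Matrix::Matrix(b)))
  ids <- unlist(lapply(blocks, rownames), use.names = FALSE)
  dimnames(phi) <- list(ids, ids)
  phi <- Matrix::forceSymmetric(phi)
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)[ids]
  structure(list(ids = ids, family_id = unname(fam_of), phi = phi),
            class = "kinship_matrix")
}

# Dense kinship for one family, rows already a valid pedigree subset.
kinship_block <- function(fam) {
  ids <- fam$individual_id  # already parents-first
  n <- length(ids)
  idx <- stats::setNames(seq_len(n), ids)
  fa <- idx[fam$father_id]
  mo <- idx[fam$mother_id]
  phi <- matrix(0, n, n, dimnames = list(ids, ids))
  for (j in seq_len(n)) {
    f <- fa[j]; m <- mo[j]
    if (j > 1) {
      prev <- seq_len(j - 1)
      v <- numeric(j - 1)
      if (!is.na(f)) v <- v + phi[prev, f]
      if (!is.na(m)) v <- v + phi[prev, m]
      v <- v / 2
      phi[prev, j] <- v
      phi[j, prev] <- v
    }
    phi[j, j] <- if (!is.na(f) && !is.na(m)) 0.5 * (1 + phi[f, m]) else 0.5
  }
  phi
}

#' @export
print.kinship_matrix <- function(x, ...) {
  cat("<kinship_matrix> ", length(x$ids), " individuals, ",
      length(unique(x$family_id)), " families\n", sep = "")
  invisible(x)
}

#' Additive (numerator) relationship matrix
#'
#' Returns `A = 2 * phi`, the covariance scaling of additive genetic
#' effects in the polygenic model: `diag(A) = 1 + F` and `A` is positive
#' semi-definite.
#'
#' @param kin A `kinship_matrix` (or a `pedigree`, which is converted).
#' @return Sparse symmetric matrix `A` with individual ids as dimnames.
#' @export
relationship_matrix <- function(kin) {
  if (inherits(kin, "pedigree") || (is.data.frame(kin) &&
      all(c("individual_id", "father_id") %in% names(kin)))) {
    kin <- kinship_matrix(kin)
  }
  stopifnot(inherits(kin, "kinship_matrix"))
  2 * kin$phi
}

#' Enumerate typed relative pairs
#'
#' Classifies every within-family unordered pair into at most one
#' first/second-degree category (parent-offspring, sibling, grandparental,
#' avuncular, half-sibling, first cousin; first-degree takes precedence
#' over second-degree for compound relationships in consanguineous
#' pedigrees) and, separately, enumerates spouse pairs (inferred from
#' shared offspring, plus an optional explicit list for childless
#' couples). A married pair of blood relatives therefore contributes one
#' row in its blood category and one spouse row.
#'
#' @param ped A `pedigree`.
#' @param spouses Optional data frame with columns `id_a`, `id_b` giving
#'   explicit spouse pairs (e.g. childless couples).
#' @param include_half_avuncular Count half-sib-of-parent pairs as
#'   avuncular (default `FALSE`: avuncular requires a full sibling of a
#'   parent).
#' @return Tibble with columns `family_id`, `id_a`, `id_b`, `category`,
#'   `sex_label`, `kinship`. For ordered categories the senior member
#'   (parent, grandparent, aunt/uncle) is `id_a`.
#' @export
pedigree_pairs <- function(ped, spouses = NULL,
                           include_half_avuncular = FALSE) {
  stopifnot(inherits(ped, "pedigree"))
  kin <- kinship_matrix(ped)
  phi <- kin$phi
  fams <- split(seq_len(nrow(ped)), ped$family_id)[unique(ped$family_id)]
  res <- purrr::map(fams, function(rows) {
    classify_family_pairs(ped[rows, , drop = FALSE],
                          include_half_avuncular = include_half_avuncular)
  })
  out <- dplyr::bind_rows(res)

  sp <- spouse_pairs(ped, spouses)
  if (nrow(sp) > 0) {
    sp$category <- "spouse"
    sex_of <- stats::setNames(ped$sex, ped$individual_id)
    # order male first for a stable label
    swap <- sex_of[sp$id_a] == "female" & sex_of[sp$id_b] == "male"
    tmp <- sp$id_a[swap]; sp$id_a[swap] <- sp$id_b[swap]; sp$id_b[swap] <- tmp
    sp$sex_label <- unname(ifelse(sex_of[sp$id_a] != sex_of[sp$id_b],
                                  "husband-wife",
                                  paste(sex_of[sp$id_a], sex_of[sp$id_b],
                                        sep = "-")))
    out <- dplyr::bind_rows(out, sp)
  }
  if (nrow(out) == 0) {
    return(tibble::tibble(family_id = character(), id_a = character(),
                          id_b = character(), category = character(),
                          sex_label = character(), kinship = double()))
  }
  out$kinship <- phi[cbind(match(out$id_a, kin$ids), match(out$id_b, kin$ids))]
  tibble::as_tibble(out[c("family_id", "id_a", "id_b", "category",
                          "sex_label", "kinship")])
}

# Spouse pairs from shared offspring plus an optional explicit list.
spouse_pairs <- function(ped, spouses = NULL) {
  fam_of <- stats::setNames(ped$family_id, ped$individual_id)
  kids <- ped[!is.na(ped$father_id) & !is.na(ped$mother_id), ]
  sp <- unique(tibble::tibble(id_a = kids$father_id, id_b = kids$mother_id))
  if (!is.null(spouses)) {
    stopifnot(all(c("id_a", "id_b") %in% names(spouses)))
    extra <- tibble::tibble(id_a = as.character(spouses$id_a),
                            id_b = as.character(spouses$id_b))
    missing_ids <- setdiff(c(extra$id_a, extra$id_b), ped$individual_id)
    if (length(missing_ids) > 0) {
      stop("spouse list references unknown id(s): ",
           paste(missing_ids, collapse = ", "))
    }
    sp <- rbind(sp, extra)
  }
  if (nrow(sp) == 0) return(sp)
  key <- apply(cbind(pmin(sp$id_a, sp$id_b), pmax(sp$id_a, sp$id_b)), 1,
               paste, collapse = "\r")
  sp <- sp[!duplicated(key), , drop = FALSE]
  sp$family_id <- unname(fam_of[sp$id_a])
  sp
}

# Blood-relationship classification for all unordered pairs in one family.
classify_family_pairs <- function(fam, include_half_avuncular = FALSE) {
  ids <- fam$individual_id
  n <- length(ids)
  if (n < 2) {
    return(tibble::tibble(family_id = character(), id_a = character(),
                          id_b = character(), category = character(),
                          sex_label = character()))
  }
  fa <- stats::setNames(fam$father_id, ids)
  mo <- stats::setNames(fam$mother_id, ids)
  sex <- stats::setNames(fam$sex, ids)

  parents <- function(i) stats::na.omit(c(fa[i], mo[i]))
  full_sib <- function(i, j) {
    !is.na(fa[i]) && !is.na(mo[i]) && identical(fa[[i]], fa[[j]]) &&
      identical(mo[[i]], mo[[j]])
  }
  half_sib <- function(i, j) {
    shared <- sum(c(!is.na(fa[i]) && identical(fa[[i]], fa[[j]]),
                    !is.na(mo[i]) && identical(mo[[i]], mo[[j]])))
    shared == 1
  }
  sib_for_avuncular <- function(i, j) {
    full_sib(i, j) || (include_half_avuncular && half_sib(i, j))
  }
  grandparents <- function(i) unique(unlist(lapply(parents(i), parents)))

  rows <- vector("list", n * (n - 1) / 2)
  r <- 0L
  for (a in seq_len(n - 1)) {
    for (b in seq((a + 1), n)) {
      i <- ids[a]; j <- ids[b]
      cat_ <- NA_character_; first <- i; second <- j
      if (i %in% parents(j)) {
        cat_ <- "parent_offspring"; first <- i; second <- j
      } else if (j %in% parents(i)) {
        cat_ <- "parent_offspring"; first <- j; second <- i
      } else if (full_sib(i, j)) {
        cat_ <- "sibling"
      } else if (i %in% grandparents(j)) {
        cat_ <- "grandparental"; first <- i; second <- j
      } else if (j %in% grandparents(i)) {
        cat_ <- "grandparental"; first <- j; second <- i
      } else if (any(vapply(parents(j), function(p) sib_for_avuncular(i, p),
                            logical(1)))) {
        cat_ <- "avuncular"; first <- i; second <- j
      } else if (any(vapply(parents(i), function(p) sib_for_avuncular(j, p),
                            logical(1)))) {
        cat_ <- "avuncular"; first <- j; second <- i
      } else if (half_sib(i, j)) {
        cat_ <- "half_sibling"
      } else if (any(outer(parents(i), parents(j),
                           Vectorize(full_sib)))) {
        cat_ <- "cousin"
      }
      if (!is.na(cat_)) {
        r <- r + 1L
        rows[[r]] <- list(id_a = first, id_b = second, category = cat_)
      }
    }
  }
  if (r == 0L) {
    return(tibble::tibble(family_id = character(), id_a = character(),
                          id_b = character(), category = character(),
                          sex_label = character()))
  }
  out <- dplyr::bind_rows(rows[seq_len(r)])
  # exchangeable categories: order by sex (male first), then id, for a
  # deterministic label
  exch <- out$category %in% c("sibling", "half_sibling", "cousin")
  swap <- exch & (sex[out$id_a] == "female" & sex[out$id_b] == "male" |
                    (sex[out$id_a] == sex[out$id_b] & out$id_a > out$id_b))
  tmp <- out$id_a[swap]; out$id_a[swap] <- out$id_b[swap]; out$id_b[swap] <- tmp
  out$sex_label <- unname(pair_sex_label(out$category,
                                         unname(sex[out$id_a]),
                                         unname(sex[out$id_b])))
  out$family_id <- fam$family_id[1]
  out
}

pair_sex_label <- function(category, sex_a, sex_b) {
  lab <- character(length(category))
  po <- category == "parent_offspring"
  lab[po] <- paste(ifelse(sex_a[po] == "male", "father", "mother"),
                   ifelse(sex_b[po] == "male", "son", "daughter"), sep = "-")
  si <- category == "sibling"
  lab[si] <- paste(ifelse(sex_a[si] == "male", "brother", "sister"),
                   ifelse(sex_b[si] == "male", "brother", "sister"), sep = "-")
  gp <- category == "grandparental"
  lab[gp] <- paste(ifelse(sex_a[gp] == "male", "grandfather", "grandmother"),
                   ifelse(sex_b[gp] == "male", "grandson", "granddaughter"),
                   sep = "-")
  av <- category == "avuncular"
  lab[av] <- paste(ifelse(sex_a[av] == "male", "uncle", "aunt"),
                   ifelse(sex_b[av] == "male", "nephew", "niece"), sep = "-")
  other <- !(po | si | gp | av)
  lab[other] <- paste(sex_a[other], sex_b[other], sep = "-")
  lab
}

#' Consanguineous-marriage rate
#'
#' Fraction of spouse pairs whose members are blood relatives
#' (kinship coefficient greater than zero).
#'
#' @inheritParams pedigree_pairs
#' @return One-row tibble with `n_spouse_pairs`, `n_consanguineous`, `rate`.
#' @export
consanguinity_rate <- function(ped, spouses = NULL) {
  pairs <- pedigree_pairs(ped, spouses = spouses)
  sp <- dplyr::filter(pairs, .data$category == "spouse")
  if (nrow(sp) == 0) {
    stop("no spouse pairs found: consanguinity rate undefined")
  }
  tibble::tibble(n_spouse_pairs = nrow(sp),
                 n_consanguineous = sum(sp$kinship > 0),
                 rate = sum(sp$kinship > 0) / nrow(sp))
}

#' Write a kinship matrix as TSV
#'
#' @param kin A `kinship_matrix`.
#' @param path Output path; a dense tab-separated matrix with an `id`
#'   header column.
#' @return `path`, invisibly.
#' @export
write_kinship_tsv <- function(kin, path) {
  m <- as.matrix(kin$phi)
  df <- data.frame(id = rownames(m), m, check.names = FALSE)
  readr::write_tsv(tibble::as_tibble(df), path)
  invisible(path)
}
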