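test_that("PED files load with validation, independent of row order", {
  f <- withr::local_tempfile()
  writeLines(c("F1 P 0 0 1", "F1 M 0 0 2", "F1 C P M 1"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_setequal(founders(ped), c("P", "M"))

  # child listed before its parents gives the identical pedigree
  f2 <- withr::local_tempfile()
  writeLines(c("F1 C P M 1", "F1 M 0 0 2", "F1 P 0 0 1"), f2)
  expect_equal(as.data.frame(read_pedigree(f2)), as.data.frame(ped))
})

test_that("structural violations are hard errors naming the offender", {
  base <- data.frame(family_id = "F1", individual_id = c("P", "M", "C"),
                     father_id = c("0", "0", "P"),
                     mother_id = c("0", "0", "M"), sex = c("1", "2", "1"))
  dup <- base; dup$individual_id[2] <- "P"
  expect_error(pedigree(dup), "duplicated.*P")
  badsex <- base; badsex$sex[3] <- "9"
  expect_error(pedigree(badsex), "unknown sex.*9")
  femdad <- base; femdad$father_id[3] <- "M"
  expect_error(pedigree(femdad), "father.*female.*M")
  orphan <- base; orphan$father_id[3] <- "GHOST"
  expect_error(pedigree(orphan), "absent.*GHOST")
  cyc <- data.frame(family_id = "F1", individual_id = c("A", "B", "X"),
                    father_id = c("B", "A", "0"),
                    mother_id = c("X", "X", "0"), sex = c("1", "1", "2"))
  expect_error(pedigree(cyc), "cycle")
})

test_that("kinship matches textbook values, including inbreeding", {
  # grandparents g1 x g2 -> sibs a, b; their children c1, c2 are first
  # cousins; x is the child of the cousin marriage
  ped <- pedigree(data.frame(
    family_id = "F",
    individual_id = c("g1", "g2", "a", "b", "aw", "bh", "c1", "c2", "x"),
    father_id = c("0", "0", "g1", "g1", "0", "0", "a", "bh", "c1"),
    mother_id = c("0", "0", "g2", "g2", "0", "0", "aw", "b", "c2"),
    sex = c("1", "2", "1", "2", "2", "1", "1", "2", "1")))
  kin <- kinship_matrix(ped)
  phi <- as.matrix(kin$phi)
  expect_equal(phi["g1", "a"], 0.25)        # parent-offspring
  expect_equal(phi["a", "b"], 0.25)         # full siblings
  expect_equal(phi["c1", "c2"], 0.0625)     # first cousins
  expect_equal(phi["x", "x"], 0.53125)      # F = 0.0625
  expect_equal(phi["g1", "g2"], 0)          # unrelated founders

  a <- as.matrix(relationship_matrix(kin))
  expect_equal(a["x", "x"], 1.0625)         # 1 + F
  expect_equal(a["g1", "c1"], 2 * phi["g1", "c1"])
  expect_gte(min(eigen(a, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("relationship matrix of an outbred trio and of founders", {
  trio <- pedigree(data.frame(
    family_id = "F1", individual_id = c("P", "M", "C"),
    father_id = c("0", "0", "P"), mother_id = c("0", "0", "M"),
    sex = c("1", "2", "1")))
  a <- as.matrix(relationship_matrix(trio))
  expect_equal(unname(diag(a)), rep(1, 3))
  expect_equal(a["P", "C"], 0.5)
  founders_only <- pedigree(data.frame(
    family_id = "U", individual_id = c("u1", "u2", "u3"),
    father_id = "0", mother_id = "0", sex = c("1", "2", "1")))
  expect_equal(as.matrix(relationship_matrix(founders_only)),
               diag(3), ignore_attr = TRUE)
})

test_that("kinship properties hold on random pedigrees", {
  for (seed in 1:5) {
    ped <- random_pedigree(n_members = 15, n_families = 2, seed = seed)
    kin <- kinship_matrix(ped)
    phi <- as.matrix(kin$phi)
    expect_equal(phi, t(phi))
    fo <- founders(ped)
    off <- phi[fo, fo]; diag(off) <- 0
    expect_true(all(off == 0))
    a <- 2 * phi
    # diag(A) = 1 + F with F the parents' kinship
    fa <- setNames(ped$father_id, ped$individual_id)
    mo <- setNames(ped$mother_id, ped$individual_id)
    for (id in ped$individual_id) {
      f_i <- if (is.na(fa[id]) || is.na(mo[id])) 0 else phi[fa[id], mo[id]]
      expect_equal(a[id, id], 1 + f_i)
    }
    expect_gte(min(eigen(a, symmetric = TRUE, only.values = TRUE)$values),
               -1e-8)
  }
})

test_that("kinship agrees with the gene-dropping Monte-Carlo oracle", {
  ped <- random_pedigree(n_members = 50, seed = 42)
  kin <- kinship_matrix(ped)
  phi <- as.matrix(kin$phi)[ped$individual_id, ped$individual_id]
  set.seed(99)
  mc <- gene_drop_kinship(ped, n_drops = 2e5)
  # family-wise bound across all pairs (Bonferroni at 1%)
  z <- qnorm(1 - 0.01 / (2 * length(phi)))
  expect_true(all(abs(phi - mc$phi) <= pmax(z * mc$se, 1e-12)))
  # and the bulk of pairs sit inside 3 MC SE
  inside3 <- abs(phi - mc$phi) <= pmax(3 * mc$se, 1e-12)
  expect_gte(mean(inside3), 0.99)
})

test_that("nuclear-family pairs are enumerated exhaustively", {
  ped <- nuclear_family()  # dad, mom, 2 sons, 1 daughter
  pairs <- pedigree_pairs(ped)
  po <- pairs[pairs$category == "parent_offspring", ]
  expect_equal(nrow(po), 6)
  po_tab <- table(po$sex_label)
  expect_equal(as.integer(po_tab[c("father-son", "father-daughter",
                                   "mother-son", "mother-daughter")]),
               c(2L, 1L, 2L, 1L))
  sib_tab <- table(pairs$sex_label[pairs$category == "sibling"])
  expect_equal(as.integer(sib_tab[c("brother-brother", "brother-sister")]),
               c(1L, 2L))
  expect_equal(sum(pairs$category == "spouse"), 1)
  expect_equal(pairs$sex_label[pairs$category == "spouse"], "husband-wife")
})

test_that("three-generation line yields grandparental pairs", {
  ped <- pedigree(data.frame(
    family_id = "L", individual_id = c("gf", "gm", "f", "m", "s"),
    father_id = c("0", "0", "gf", "0", "f"),
    mother_id = c("0", "0", "gm", "0", "m"),
    sex = c("1", "2", "1", "2", "1")))
  pairs <- pedigree_pairs(ped)
  expect_equal(sum(pairs$category == "parent_offspring"), 4)
  gp <- pairs[pairs$category == "grandparental", ]
  expect_equal(nrow(gp), 2)
  expect_setequal(gp$sex_label, c("grandfather-grandson",
                                  "grandmother-grandson"))
  # senior member first
  expect_true(all(gp$id_a %in% c("gf", "gm")))
})

test_that("pair counts match the brute-force classifier", {
  # exhaustive sweep over small random pedigrees
  compare_counts <- function(ped) {
    got <- pedigree_pairs(ped)
    got_tab <- table(got$category[got$category != "spouse"])
    want <- brute_pair_classify(ped)
    expect_setequal(names(got_tab), names(want))
    expect_equal(as.integer(got_tab[names(want)]), as.integer(want))
  }
  # exhaustive sweep over small random pedigrees
  for (seed in 1:6) compare_counts(random_pedigree(n_members = 12,
                                                   seed = seed))
  # one larger simulated cohort
  ped <- simulate_pedigree(simulation_config(n_families = 15,
                                             generations = 2, seed = 3))
  expect_gte(nrow(ped), 150)
  compare_counts(ped)
})

test_that("explicit spouse lists add childless couples", {
  ped <- nuclear_family()
  pairs <- pedigree_pairs(ped, spouses = data.frame(id_a = "s1", id_b = "d1"))
  # s1-d1 are siblings AND listed spouses: one row per applicable category
  sub <- pairs[(pairs$id_a == "s1" & pairs$id_b == "d1") |
                 (pairs$id_a == "d1" & pairs$id_b == "s1"), ]
  expect_setequal(sub$category, c("sibling", "spouse"))
  expect_error(pedigree_pairs(ped, spouses = data.frame(id_a = "s1",
                                                        id_b = "nope")),
               "unknown id")
})

test_that("consanguinity rate counts related spouse pairs", {
  # four marriages, one between first cousins
  ped <- pedigree(data.frame(
    family_id = "F",
    individual_id = c("g1", "g2", "a", "b", "aw", "bh", "c1", "c2",
                      "c1w", "x", "y"),
    father_id = c("0", "0", "g1", "g1", "0", "0", "a", "bh", "0", "c1", "a"),
    mother_id = c("0", "0", "g2", "g2", "0", "0", "aw", "b", "0", "c2", "aw"),
    sex = c("1", "2", "1", "2", "2", "1", "1", "2", "2", "1", "1")))
  # marriages: g1-g2, a-aw, bh-b (all unrelated), c1-c2 (cousins)
  res <- consanguinity_rate(ped)
  expect_equal(res$n_spouse_pairs, 4)
  expect_equal(res$rate, 0.25)

  trio <- pedigree(data.frame(
    family_id = "T", individual_id = c("P", "M", "C"),
    father_id = c("0", "0", "P"), mother_id = c("0", "0", "M"),
    sex = c("1", "2", "1")))
  expect_equal(consanguinity_rate(trio)$rate, 0)
  singles <- pedigree(data.frame(
    family_id = "S", individual_id = c("u", "v"), father_id = "0",
    mother_id = "0", sex = c("1", "2")))
  expect_error(consanguinity_rate(singles), "no spouse pairs")
})
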