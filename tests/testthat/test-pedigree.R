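# Pedigree construction, validation, ordering, relationship matrix.

test_that("read_pedigree parses, normalizes unknowns and auto-adds parents", {
  f <- withr_tempfile <- tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire,sex",
               "child,mother,father,",
               "mother,0,NA,F",
               "father,,0,M"), f)
  ped <- read_pedigree(f)
  expect_s3_class(ped, "pedigree")
  expect_equal(nrow(ped), 3)
  expect_equal(n_founders(ped), 2)
  expect_true(is.na(ped$dam[ped$id == "mother"]))

  # referenced-but-unlisted dam is auto-added as a founder
  f2 <- tempfile(fileext = ".csv")
  writeLines(c("id,dam,sire,sex", "kid,X,,"), f2)
  expect_message(ped2 <- read_pedigree(f2), "auto-adding")
  expect_true("X" %in% ped2$id)
  expect_equal(n_founders(ped2), 1)
  unlink(c(f, f2))
})

test_that("validation rejects cycles, duplicates and sex conflicts", {
  expect_error(pedigree(c("A", "B"), dam = c("B", "A")), "cycle")
  expect_error(pedigree(c("A", "A")), "duplicate")
  expect_error(
    pedigree(c("m", "kid"), dam = c(NA, "m"), sex = c("M", NA)),
    "dam recorded as male")
  expect_error(
    pedigree(c("p", "kid"), sire = c(NA, "p"), sex = c("F", NA)),
    "sire recorded as female")
})

test_that("topological order puts parents first, ties by input order", {
  # founders only: input order preserved
  ped <- pedigree(c("c", "a", "b"))
  expect_equal(topological_order(ped), c("c", "a", "b"))
  # reversed chain restored
  ped <- pedigree(c("kid", "par", "gp"), dam = c("par", "gp", NA))
  expect_equal(topological_order(ped), c("gp", "par", "kid"))
  # two independent families interleave deterministically
  ped <- pedigree(c("o1", "o2", "d1", "d2"), dam = c("d1", "d2", NA, NA))
  ord <- topological_order(ped)
  expect_true(which(ord == "d1") < which(ord == "o1"))
  expect_true(which(ord == "d2") < which(ord == "o2"))
  expect_equal(ord, topological_order(ped)) # deterministic
})

test_that("canonical relatedness values", {
  ped <- fam_pedigree(2)
  A <- additive_relationship_matrix(ped)
  expect_equal(A["d", "o1"], 0.5) # parent-offspring
  expect_equal(A["o1", "o2"], 0.5) # full sibs
  expect_equal(diag(A), c(d = 1, s = 1, o1 = 1, o2 = 1))
  expect_equal(A["d", "s"], 0)

  # half sibs
  hs <- pedigree(c("d1", "d2", "s", "x", "y"),
                 dam = c(NA, NA, NA, "d1", "d2"),
                 sire = c(NA, NA, NA, "s", "s"))
  expect_equal(additive_relationship_matrix(hs)["x", "y"], 0.25)

  # offspring of a full-sib mating: F = 0.25, diagonal 1.25
  ib <- pedigree(c("d", "s", "o1", "o2", "z"),
                 dam = c(NA, NA, "d", "d", "o1"),
                 sire = c(NA, NA, "s", "s", "o2"))
  A <- additive_relationship_matrix(ib)
  expect_equal(A["z", "z"], 1.25)
  expect_equal(inbreeding_coefficients(ib)[["z"]], 0.25)
  # parent-offspring mating also gives F = 0.25
  po <- pedigree(c("d", "s", "o", "z"),
                 dam = c(NA, NA, "d", "d"),
                 sire = c(NA, NA, "s", "o"))
  expect_equal(inbreeding_coefficients(po)[["z"]], 0.25)
  expect_equal(inbreeding_coefficients(fam_pedigree(1))[["d"]], 0)
})

test_that("tabular A equals the recursive kinship oracle on random pedigrees", {
  set.seed(42)
  for (r in 1:40) {
    ped <- random_pedigree(n = sample(6:15, 1), n_founders = sample(2:5, 1))
    A <- additive_relationship_matrix(ped)
    expect_equal(A, kinship_oracle(ped), tolerance = 1e-12)
  }
})

test_that("A matrix invariants hold on random pedigrees", {
  set.seed(7)
  for (r in 1:10) {
    ped <- random_pedigree(n = 15, n_founders = 4)
    A <- additive_relationship_matrix(ped)
    expect_equal(A, t(A))
    expect_true(all(A >= 0))
    expect_true(all(diag(A) >= 1 & diag(A) <= 2))
    ev <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
    expect_gt(min(ev), -1e-8)
    # Cauchy-Schwarz bound
    bound <- sqrt(outer(diag(A), diag(A)))
    expect_true(all(A <= bound + 1e-12))
    # founders: diagonal exactly 1, mutual relatedness 0
    fnd <- ped$id[is.na(ped$dam) & is.na(ped$sire)]
    expect_equal(unname(diag(A[fnd, fnd, drop = FALSE])),
                 rep(1, length(fnd)))
    off <- A[fnd, fnd]
    diag(off) <- 0
    expect_equal(sum(off), 0)
  }
})

test_that("dropping a childless individual leaves other entries unchanged", {
  set.seed(11)
  ped <- random_pedigree(n = 12, n_founders = 3)
  A <- additive_relationship_matrix(ped)
  parents <- unique(c(ped$dam, ped$sire))
  leaf <- setdiff(ped$id, parents)[1]
  ped2 <- ped[ped$id != leaf, ]
  class(ped2) <- class(ped)
  A2 <- additive_relationship_matrix(ped2)
  keep <- setdiff(ped$id, leaf)
  expect_equal(A[keep, keep], A2[keep, keep])
})

test_that("pedigree_summary counts match brute force", {
  ped <- pedigree(c("d", "s", "o1", "o2", "o3"),
                  dam = c(NA, NA, "d", "d", "d"),
                  sire = c(NA, NA, "s", "s", "s"))
  s <- pedigree_summary(ped)
  expect_equal(s$n_maternities, 3)
  expect_equal(s$n_paternities, 3)
  expect_equal(s$n_full_sib_pairs, 3)
  expect_equal(s$n_maternal_half_sib_pairs, 0)
  expect_equal(s$n_paternal_half_sib_pairs, 0)
  expect_equal(s$max_pedigree_depth, 1)

  set.seed(5)
  ped <- random_pedigree(n = 14, n_founders = 4)
  s <- pedigree_summary(ped)
  # exhaustive pairwise enumeration
  fs <- mhs <- phs <- 0
  for (i in 1:(nrow(ped) - 1)) for (j in (i + 1):nrow(ped)) {
    sd <- !is.na(ped$dam[i]) && !is.na(ped$dam[j]) && ped$dam[i] == ped$dam[j]
    ss <- !is.na(ped$sire[i]) && !is.na(ped$sire[j]) &&
      ped$sire[i] == ped$sire[j]
    if (sd && ss) fs <- fs + 1
    else if (sd) mhs <- mhs + 1
    else if (ss) phs <- phs + 1
  }
  expect_equal(s$n_full_sib_pairs, fs)
  expect_equal(s$n_maternal_half_sib_pairs, mhs)
  expect_equal(s$n_paternal_half_sib_pairs, phs)
  expect_equal(s$n_founders, n_founders(ped))
  expect_lte(s$n_founders, s$n_individuals)
})

test_that("pedigree round-trips through CSV with 0-encoding", {
  ped <- fam_pedigree(2)
  f <- tempfile(fileext = ".csv")
  write_pedigree(ped, f)
  txt <- readLines(f)
  expect_true(any(grepl(",0,0,", txt))) # founders written with 0s
  ped2 <- read_pedigree(f)
  expect_equal(as.data.frame(ped2), as.data.frame(ped))
  unlink(f)
})

test_that("relationship matrix export formats", {
  ped <- fam_pedigree(1)
  A <- additive_relationship_matrix(ped)
  fsq <- tempfile(fileext = ".csv")
  ftr <- tempfile(fileext = ".csv")
  write_relationship_matrix(A, fsq, "square")
  write_relationship_matrix(A, ftr, "triplet")
  sq <- utils::read.csv(fsq, row.names = 1)
  expect_equal(as.matrix(sq), A, ignore_attr = TRUE)
  tr <- utils::read.csv(ftr)
  expect_true(all(tr$a != 0))
  expect_equal(tr$a[tr$id_i == "d" & tr$id_j == "o1"], 0.5)
  unlink(c(fsq, ftr))
})
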