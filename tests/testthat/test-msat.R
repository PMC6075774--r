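# Locus diagnostics, HWE, null alleles, exclusion, likelihoods, parentage,
# sibship.

test_that("locus summaries: frequencies, heterozygosities, edge cases", {
  gt <- gt_from_list(list(a = list(c(1, 1)), b = list(c(1, 1)),
                          c = list(c(1, 1))))
  s <- locus_summary(gt, 1)
  expect_equal(unname(s$freqs), 1)
  expect_equal(s$Ho, 0)
  expect_equal(s$He, 0)
  expect_equal(s$hwe_p, 1)

  gt2 <- gt_from_list(list(a = list(c(1, 2)), b = list(c(1, 2))))
  s2 <- locus_summary(gt2, 1)
  expect_equal(unname(s2$freqs), c(0.5, 0.5))
  expect_equal(s2$Ho, 1)
  # unbiased He = (2n/(2n-1)) (1 - sum p^2) with n = 2
  expect_equal(s2$He, 4 / 3 * 0.5)

  gt3 <- gt_from_list(list(a = list(NA), b = list(NA)))
  expect_error(locus_summary(gt3, 1), "non-missing")
})

test_that("HWE exact test: enumeration total mass and MC agreement", {
  set.seed(21)
  g <- sample_hwe_genotypes(20, c(0.3, 0.3, 0.4))
  res <- hwe_exact_test(g, method = "enumeration")
  expect_equal(res$method, "enumeration")
  mc <- hwe_exact_test(g, method = "mc", n_perm = 2e5)
  expect_lt(abs(res$p_value - mc$p_value), 0.01)
  # enumeration p-value matches on a tiny biallelic sample too
  g2 <- sample_hwe_genotypes(12, c(0.5, 0.5))
  e2 <- hwe_exact_test(g2, method = "enumeration")
  m2 <- hwe_exact_test(g2, method = "mc", n_perm = 2e5)
  expect_lt(abs(e2$p_value - m2$p_value), 0.01)
})

test_that("null-allele EM: zero for clean HWE data, recovers truth, edges", {
  # exact HWE proportions at a biallelic locus: no homozygote excess
  lst <- c(rep(list(list(c(1, 1))), 25), rep(list(list(c(1, 2))), 50),
           rep(list(list(c(2, 2))), 25))
  names(lst) <- sprintf("i%03d", seq_along(lst))
  gt <- gt_from_list(lst)
  est <- estimate_null_allele_frequency(gt, 1)
  expect_lt(est$p_null, 0.01)
  expect_equal(sum(est$freqs) + est$p_null, 1, tolerance = 1e-9)

  # monomorphic visible locus: p_null = 0 by convention
  gtm <- gt_from_list(rep(list(list(c(3, 3))), 10) |>
                        stats::setNames(sprintf("i%d", 1:10)))
  expect_equal(estimate_null_allele_frequency(gtm, 1)$p_null, 0)

  # simulated truth p_null = 0.2, n = 500
  cfg <- sim_config(n_loci = 1, n_alleles = 5, null_freq = 0.2)
  ped <- pedigree(sprintf("i%03d", 1:500))
  g <- simulate_genotypes(ped, cfg, seed = 4)
  est2 <- estimate_null_allele_frequency(g$observed, 1)
  expect_lt(abs(est2$p_null - 0.2), 0.05)
})

test_that("null-allele EM is nearly unbiased at n = 2000", {
  for (pn in c(0, 0.1, 0.3)) {
    cfg <- sim_config(n_loci = 1, n_alleles = 6, null_freq = pn)
    ped <- pedigree(sprintf("i%04d", 1:2000))
    ests <- vapply(1:5, function(r) {
      g <- simulate_genotypes(ped, cfg, seed = 100 * r + 1)
      estimate_null_allele_frequency(g$observed, 1)$p_null
    }, numeric(1))
    expect_lt(abs(mean(ests) - pn), 0.02)
  }
})

test_that("exclusion probabilities match nested-loop enumeration oracle", {
  for (p in list(c(0.5, 0.5), c(0.2, 0.8), c(0.2, 0.3, 0.5),
                 c(0.1, 0.2, 0.3, 0.4))) {
    q <- exclusion_probabilities(p)
    expect_equal(q, exclusion_oracle(p), tolerance = 1e-12)
  }
  # single allele: no exclusion power
  expect_equal(unname(exclusion_probabilities(1)), c(0, 0))
  expect_error(exclusion_probabilities(numeric(0)), "empty")
  # combination rule
  expect_equal(combined_exclusion(c(0, 0, 0)), 0)
  expect_equal(combined_exclusion(c(0.5, 0.5)), 0.75)
})

test_that("combined exclusion is monotone in loci and allele count", {
  q4 <- exclusion_probabilities(rep(0.25, 4))["Q1"]
  q6 <- exclusion_probabilities(rep(1 / 6, 6))["Q1"]
  expect_gt(q6, q4) # richer locus excludes more
  combs <- vapply(1:7, function(k) combined_exclusion(rep(q4, k)), numeric(1))
  expect_true(all(diff(combs) > 0))
})

test_that("pair likelihoods: worked values, normalization, monomorphic tie", {
  gt <- gt_from_list(list(x = list(c(1, 1)), y = list(c(1, 1))))
  summ <- plain_summaries(list(c(0.5, 0.5)))
  expect_equal(exp(pair_log_likelihood(gt, "x", "y", "U", summ)), 0.0625)
  expect_equal(exp(pair_log_likelihood(gt, "x", "y", "HS", summ)), 0.09375)
  expect_equal(exp(pair_log_likelihood(gt, "x", "y", "FS", summ)), 0.140625)
  expect_equal(exp(pair_log_likelihood(gt, "x", "y", "PO", summ)), 0.125)

  # ordered-pair probabilities sum to 1 for every category, 2-6 alleles
  set.seed(3)
  for (k in c(2, 4, 6)) {
    p <- as.numeric(stats::rgamma(k, 1))
    p <- p / sum(p)
    summ <- plain_summaries(list(p))
    for (cat in names(relationship_categories())) {
      kc <- relationship_categories()[[cat]]
      tot <- 0
      for (i in 1:k) for (j in i:k) for (l in 1:k) for (m in l:k) {
        g <- gt_from_list(list(x = list(c(i, j)), y = list(c(l, m))))
        v <- exp(pair_log_likelihood(g, "x", "y", cat, summ))
        # cross-check each entry against the enumeration oracle
        expect_equal(v, pair_prob_oracle(sort(c(i, j)), sort(c(l, m)), kc, p),
                     tolerance = 1e-12)
        tot <- tot + v
      }
      expect_equal(tot, 1, tolerance = 1e-9)
    }
  }

  # monomorphic locus: all categories tie -> U by priority
  gtm <- gt_from_list(list(x = list(c(1, 1)), y = list(c(1, 1))))
  sm <- plain_summaries(list(1))
  cl <- classify_relationship(gtm, "x", "y", sm)
  expect_equal(cl$category, "U")
  expect_true(all(abs(cl$llr) < 1e-9))
})

test_that("identical multilocus genotypes prefer close kin over U", {
  lst <- list(x = rep(list(c(3, 5)), 7), y = rep(list(c(3, 5)), 7))
  gt <- gt_from_list(lst)
  summ <- plain_summaries(rep(list(rep(1 / 8, 8)), 7))
  cl <- classify_relationship(gt, "x", "y", summ)
  expect_true(cl$category %in% c("FS", "PO"))
  expect_gt(cl$logLik["FS"] - cl$logLik["U"], 0)
})

test_that("unrelated simulated pairs mostly classify as U", {
  cfg <- sim_config(n_loci = 7, n_alleles = 8)
  ped <- pedigree(sprintf("u%04d", 1:1000))
  g <- simulate_genotypes(ped, cfg, seed = 9)
  summ <- locus_summaries(g$observed, null_adjust = FALSE, hwe = FALSE,
                          exclusion = FALSE)
  u <- 0
  for (i in 1:500) {
    cl <- classify_relationship(g$observed, sprintf("u%04d", 2 * i - 1),
                                sprintf("u%04d", 2 * i), summ)
    if (cl$category == "U") u <- u + 1
  }
  expect_gt(u / 500, 0.5)
})

test_that("PO pairs are never classified U with 7 informative loci", {
  cfg <- sim_config(n_loci = 7, n_alleles = 8)
  # known equifrequent frequencies: the setting where allele sharing at
  # every locus makes U strictly dominated
  summ <- plain_summaries(rep(list(rep(1 / 8, 8)), 7))
  for (r in 1:20) {
    ped <- pedigree(c("p", "q", "kid"), dam = c(NA, NA, "p"),
                    sire = c(NA, NA, "q"))
    g <- simulate_genotypes(ped, cfg, seed = 300 + r)
    cl <- classify_relationship(g$observed, "p", "kid", summ)
    expect_false(cl$category == "U")
  }
})

test_that("parentage assignment contracts", {
  summ <- plain_summaries(rep(list(rep(0.25, 4)), 3))
  # candidate with 3 incompatible loci is excluded
  gt <- gt_from_list(list(kid = list(c(1, 1), c(2, 2), c(3, 3)),
                          cand = list(c(2, 2), c(3, 3), c(4, 4))))
  res <- assign_parentage(gt, "kid", "cand", summ, use_null = FALSE)
  expect_true(is.na(res$assigned))
  expect_equal(res$table$mismatches, 3)
  expect_true(res$table$excluded)

  # offspring-only candidate list: self excluded, NONE
  res2 <- assign_parentage(gt, "kid", "kid", summ)
  expect_true(is.na(res2$assigned))
  expect_equal(nrow(res2$table), 0)

  # empty candidate list
  res3 <- assign_parentage(gt, "kid", character(0), summ)
  expect_true(is.na(res3$assigned))
})

test_that("null-compatible homozygote mismatches are tolerated when modeled", {
  # kid apparent 1/1 (could be 1/null), candidate apparent 2/2 (2/null):
  # a null allele transmitted by the candidate explains the kid
  summ <- plain_summaries(list(c(0.5, 0.5)), p_null = 0.2)
  gt <- gt_from_list(list(kid = list(c(1, 1)), cand = list(c(2, 2))))
  with_null <- assign_parentage(gt, "kid", "cand", summ, use_null = TRUE)
  expect_equal(with_null$table$mismatches, 0)
  without <- assign_parentage(gt, "kid", "cand", summ, use_null = FALSE)
  expect_equal(without$table$mismatches, 1)
})

test_that("true parents are recovered among unrelated candidates", {
  cfg <- sim_config(n_loci = 7, n_alleles = 8)
  n_cand <- 21
  correct <- 0
  n_rep <- 60
  for (r in seq_len(n_rep)) {
    ids <- c(sprintf("c%02d", 1:n_cand), "mom", "kid")
    ped <- pedigree(ids, dam = c(rep(NA, n_cand + 1), "mom"),
                    sire = c(rep(NA, n_cand + 1), "c01"))
    g <- simulate_genotypes(ped, cfg, seed = 1000 + r)
    summ <- locus_summaries(g$observed, null_adjust = FALSE, hwe = FALSE,
                            exclusion = FALSE)
    res <- assign_parentage(g$observed, "kid", sprintf("c%02d", 1:n_cand),
                            summ, known_parent = "mom")
    if (!is.na(res$assigned) && res$assigned == "c01") correct <- correct + 1
  }
  expect_gt(correct / n_rep, 0.9)
})

test_that("full-sib partitioning recovers clutches and leaves strangers apart", {
  cfg <- sim_config(n_loci = 10, n_alleles = 12)
  ids <- c("d1", "s1", "d2", "s2", paste0("a", 1:4), paste0("b", 1:4))
  ped <- pedigree(ids,
                  dam = c(rep(NA, 4), rep("d1", 4), rep("d2", 4)),
                  sire = c(rep(NA, 4), rep("s1", 4), rep("s2", 4)))
  g <- simulate_genotypes(ped, cfg, seed = 12)
  summ <- plain_summaries(rep(list(rep(1 / 12, 12)), 10))
  part <- partition_full_sibs(g$observed, c(paste0("a", 1:4), paste0("b", 1:4)),
                              summ)
  grp <- lapply(part, as.character)
  expect_equal(length(grp), 2)
  expect_true(any(vapply(grp, function(g) setequal(g, paste0("a", 1:4)),
                         TRUE)))
  expect_true(any(vapply(grp, function(g) setequal(g, paste0("b", 1:4)),
                         TRUE)))

  # unrelated individuals stay singletons (mostly): labels present
  ped2 <- pedigree(sprintf("x%02d", 1:6))
  g2 <- simulate_genotypes(ped2, cfg, seed = 13)
  s2 <- locus_summaries(g2$observed, null_adjust = FALSE, hwe = FALSE,
                        exclusion = FALSE)
  part2 <- partition_full_sibs(g2$observed, sprintf("x%02d", 1:6), s2)
  expect_gte(length(part2), 5)

  # identical genotype pair merges into one FS group
  gt3 <- gt_from_list(list(n1 = rep(list(c(2, 4)), 7),
                           n2 = rep(list(c(2, 4)), 7)))
  s3 <- plain_summaries(rep(list(rep(1 / 8, 8)), 7))
  part3 <- partition_full_sibs(gt3, c("n1", "n2"), s3)
  expect_equal(length(part3), 1)
  expect_equal(attr(part3[[1]], "label"), "FS")
})

test_that("genotype IO round-trips (wide CSV and GenePop)", {
  cfg <- sim_config(n_loci = 3, n_alleles = 4, missing_rate = 0.1)
  ped <- pedigree(sprintf("i%02d", 1:15))
  g <- simulate_genotypes(ped, cfg, seed = 2)
  gt <- g$observed
  fc <- tempfile(fileext = ".csv")
  write_genotypes_csv(gt, fc)
  gt2 <- read_genotypes_csv(fc)
  expect_equal(gt2$alleles, gt$alleles, ignore_attr = TRUE)
  fg <- tempfile(fileext = ".gen")
  write_genepop(gt, fg)
  gt3 <- read_genepop(fg)
  expect_equal(gt3$alleles, gt$alleles, ignore_attr = TRUE)
  expect_equal(gt3$loci, gt$loci)
  unlink(c(fc, fg))
})
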