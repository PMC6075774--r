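# Microsatellite locus diagnostics, null-allele adjustment, exclusion
# probabilities, pairwise relationship likelihoods and parentage/sibship
# assignment.

#' IBD relationship categories
#'
#' The four pairwise relationship classes used for classification, with
#' their Cotterman coefficients (probability of sharing 0, 1, 2 alleles
#' identical by descent): unrelated U = (1, 0, 0), half-sib HS =
#' (0.5, 0.5, 0), full-sib FS = (0.25, 0.5, 0.25), parent-offspring
#' PO = (0, 1, 0).
#'
#' @return named list of `c(k0, k1, k2)` vectors.
#' @export
relationship_categories <- function() {
  list(U = c(k0 = 1, k1 = 0, k2 = 0),
       HS = c(k0 = 0.5, k1 = 0.5, k2 = 0),
       FS = c(k0 = 0.25, k1 = 0.5, k2 = 0.25),
       PO = c(k0 = 0, k1 = 1, k2 = 0))
}

#' Observed allele frequencies at a locus
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @return named numeric vector summing to 1 (names = allele codes).
#' @export
allele_frequencies <- function(gt, locus) {
  g <- locus_genotypes(gt, locus)
  al <- c(g[, 1], g[, 2])
  al <- al[!is.na(al)]
  if (!length(al)) stop("locus has no non-missing genotypes")
  tab <- table(al)
  stats::setNames(as.numeric(tab) / sum(tab), names(tab))
}

# ---- Hardy-Weinberg exact test -------------------------------------------

hwe_table_logprob <- function(cnt_mat) {
  # full log conditional probability of a genotype count table
  k <- nrow(cnt_mat)
  n <- sum(cnt_mat)
  # allele counts: row + col sums of the symmetric-upper representation
  ac <- sapply(seq_len(k), function(i) {
    2 * cnt_mat[i, i] + sum(cnt_mat[i, seq_len(k) > i]) +
      sum(cnt_mat[seq_len(k) < i, i])
  })
  H <- sum(cnt_mat[upper.tri(cnt_mat)])
  lgamma(n + 1) + sum(lgamma(ac + 1)) - lgamma(2 * n + 1) -
    sum(lgamma(cnt_mat[upper.tri(cnt_mat, diag = TRUE)] + 1)) + H * log(2)
}

# Enumerate all genotype count tables with the observed allele counts,
# returning the exact conditional p-value. Aborts (returns NULL) when the
# number of tables exceeds `budget`.
hwe_enumerate <- function(allele_counts, obs_stat, budget = 2e5) {
  k <- length(allele_counts)
  pairs <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  pairs <- pairs[order(pairs[, 1], pairs[, 2]), , drop = FALSE]
  n_pairs <- nrow(pairs)
  env <- new.env()
  env$p_total <- 0
  env$p_le <- 0
  env$n_tables <- 0L
  cnt <- matrix(0L, k, k)
  env$n_nodes <- 0L
  rec <- function(pi, rem) {
    env$n_nodes <- env$n_nodes + 1L
    if (env$n_tables > budget || env$n_nodes > 20L * budget) return(FALSE)
    if (pi > n_pairs) {
      if (all(rem == 0L)) {
        env$n_tables <- env$n_tables + 1L
        lp <- hwe_table_logprob(cnt)
        p <- exp(lp)
        env$p_total <- env$p_total + p
        stat <- -sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1)) +
          sum(cnt[upper.tri(cnt)]) * log(2)
        if (stat <= obs_stat + 1e-9) env$p_le <- env$p_le + p
      }
      return(TRUE)
    }
    i <- pairs[pi, 1]; j <- pairs[pi, 2]
    max_n <- if (i == j) rem[i] %/% 2L else min(rem[i], rem[j])
    for (v in 0:max_n) {
      cnt[i, j] <<- v
      rem2 <- rem
      if (i == j) rem2[i] <- rem2[i] - 2L * v
      else { rem2[i] <- rem2[i] - v; rem2[j] <- rem2[j] - v }
      # when leaving row i (last pair of the row), its count must be spent
      last_of_row <- (j == k)
      if (!last_of_row || rem2[i] == 0L) {
        if (!rec(pi + 1L, rem2)) { cnt[i, j] <<- 0L; return(FALSE) }
      }
    }
    cnt[i, j] <<- 0L
    TRUE
  }
  ok <- rec(1L, as.integer(allele_counts))
  if (!ok) return(NULL)
  list(p_value = min(1, env$p_le / env$p_total),
       n_tables = env$n_tables, total_prob = env$p_total)
}

#' Exact test for Hardy-Weinberg proportions
#'
#' Conditional exact test on the genotype array given allele counts
#' (Guo-Thompson style). Complete enumeration of genotype tables when the
#' table count stays within `enum_budget`; otherwise Monte-Carlo with
#' `n_perm` permutations of the allele vector (add-one corrected).
#'
#' @param geno n x 2 integer matrix of allele pairs (missing rows dropped).
#' @param method `"auto"`, `"enumeration"` or `"mc"`.
#' @param n_perm Monte-Carlo permutations.
#' @param enum_budget maximum number of tables to enumerate.
#' @return list with `p_value`, `method`, and for enumeration `n_tables`.
#' @export
hwe_exact_test <- function(geno, method = c("auto", "enumeration", "mc"),
                           n_perm = 1e5, enum_budget = 2e5) {
  method <- match.arg(method)
  geno <- geno[!is.na(geno[, 1]) & !is.na(geno[, 2]), , drop = FALSE]
  if (nrow(geno) < 2) stop("need at least 2 non-missing genotypes")
  codes <- sort(unique(c(geno[, 1], geno[, 2])))
  if (length(codes) < 2) return(list(p_value = 1, method = "monomorphic"))
  a1 <- match(geno[, 1], codes)
  a2 <- match(geno[, 2], codes)
  k <- length(codes)
  cnt <- matrix(0L, k, k)
  for (r in seq_len(nrow(geno))) {
    i <- min(a1[r], a2[r]); j <- max(a1[r], a2[r])
    cnt[i, j] <- cnt[i, j] + 1L
  }
  obs_stat <- -sum(lgamma(cnt[upper.tri(cnt, diag = TRUE)] + 1)) +
    sum(cnt[upper.tri(cnt)]) * log(2)
  allele_counts <- sapply(seq_len(k), function(i) {
    2 * cnt[i, i] + sum(cnt[i, seq_len(k) > i]) + sum(cnt[seq_len(k) < i, i])
  })
  if (method %in% c("auto", "enumeration")) {
    # crude size guard: enumeration is only worthwhile for few alleles
    res <- if (method == "enumeration" || k <= 4)
      hwe_enumerate(allele_counts, obs_stat, budget = enum_budget)
    else NULL
    if (!is.null(res)) {
      return(list(p_value = res$p_value, method = "enumeration",
                  n_tables = res$n_tables))
    }
    if (method == "enumeration")
      stop("enumeration budget exceeded; use method = 'mc'")
  }
  al <- as.integer(rbind(a1, a2))
  list(p_value = hwe_mc_pvalue(al, as.integer(n_perm)), method = "mc")
}

# ---- null alleles ---------------------------------------------------------

#' Estimate the null-allele frequency at a locus
#'
#' Expectation-maximization under a single-null-allele model: apparent
#' homozygotes are a mixture of true homozygotes and visible/null
#' heterozygotes, and null homozygotes fail to amplify (the likelihood is
#' conditioned on amplification by augmenting an expected count of
#' unobserved null homozygotes). Visible allele frequencies are
#' renormalized so that all frequencies plus `p_null` sum to 1.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @param tol convergence tolerance on successive `p_null` values.
#' @param max_iter maximum EM iterations.
#' @return list with `p_null` (clipped to `[0, 0.5]`), `freqs` (adjusted
#'   visible frequencies; `sum(freqs) + p_null == 1`), `converged`.
#' @export
estimate_null_allele_frequency <- function(gt, locus, tol = 1e-8,
                                           max_iter = 10000) {
  g <- locus_genotypes(gt, locus)
  g <- g[!is.na(g[, 1]), , drop = FALSE]
  if (!nrow(g)) stop("locus has no non-missing genotypes")
  codes <- sort(unique(c(g[, 1], g[, 2])))
  k <- length(codes)
  raw <- allele_frequencies(gt, locus)
  if (k < 2) {
    return(list(p_null = 0,
                freqs = stats::setNames(1, codes),
                converged = TRUE))
  }
  N <- nrow(g)
  is_hom <- g[, 1] == g[, 2]
  n_hom <- table(factor(g[is_hom, 1], levels = codes))
  # allele counts from heterozygotes
  het_counts <- table(factor(c(g[!is_hom, 1], g[!is_hom, 2]), levels = codes))
  p <- as.numeric(raw[as.character(codes)])
  p0 <- 0.05
  converged <- FALSE
  for (it in seq_len(max_iter)) {
    # E-step
    m00 <- N * p0^2 / (1 - p0^2)                 # unseen null homozygotes
    w <- as.numeric(n_hom) * 2 * p0 / (p + 2 * p0) # null-het share of homs
    w[as.numeric(n_hom) == 0] <- 0
    # M-step
    cnt_a <- 2 * as.numeric(n_hom) - w + as.numeric(het_counts)
    cnt_0 <- 2 * m00 + sum(w)
    tot <- 2 * (N + m00)
    p_new <- cnt_a / tot
    p0_new <- cnt_0 / tot
    if (abs(p0_new - p0) < tol) {
      p <- p_new; p0 <- p0_new; converged <- TRUE
      break
    }
    p <- p_new
    p0 <- p0_new
  }
  if (!converged)
    warning("null-allele EM did not converge; returning last iterate")
  p0 <- min(max(p0, 0), 0.5)
  p <- p / sum(p) * (1 - p0)
  list(p_null = p0, freqs = stats::setNames(p, codes), converged = converged)
}

# ---- exclusion probabilities ---------------------------------------------

# All unordered genotypes for k alleles, with HWE probabilities.
hwe_genotype_space <- function(p) {
  k <- length(p)
  idx <- which(upper.tri(diag(k), diag = TRUE), arr.ind = TRUE)
  g1 <- idx[, 1]; g2 <- idx[, 2]
  prob <- ifelse(g1 == g2, p[g1]^2, 2 * p[g1] * p[g2])
  list(a1 = g1, a2 = g2, prob = prob, k = k)
}

#' Parent-exclusion probabilities of a locus
#'
#' `Q1` is the probability that a random non-father is excluded given a
#' known mother-offspring pair; `Q2` the probability that a random
#' unrelated male-female pair is excluded as the parental pair of a random
#' offspring. Both are computed by exact enumeration over genotypes
#' weighted by Hardy-Weinberg frequencies. Combine loci with
#' [combined_exclusion()].
#'
#' @param freqs allele frequency vector (sums to 1).
#' @return named numeric vector `c(Q1, Q2)`.
#' @export
exclusion_probabilities <- function(freqs) {
  p <- as.numeric(freqs)
  if (!length(p)) stop("empty frequency map")
  stopifnot(abs(sum(p) - 1) < 1e-8)
  gs <- hwe_genotype_space(p)
  ng <- length(gs$prob)
  k <- gs$k
  # carry[a] = P(random HWE genotype carries allele a)
  carry <- vapply(seq_len(k), function(a)
    sum(gs$prob[gs$a1 == a | gs$a2 == a]), numeric(1))
  # carry2[a, b] = P(random genotype carries both a and b)
  carry2 <- outer(seq_len(k), seq_len(k), Vectorize(function(a, b)
    sum(gs$prob[(gs$a1 == a | gs$a2 == a) & (gs$a1 == b | gs$a2 == b)])))
  Q1 <- 0
  for (m in seq_len(ng)) {
    m_alleles <- c(gs$a1[m], gs$a2[m])
    for (o in seq_len(ng)) {
      o1 <- gs$a1[o]; o2 <- gs$a2[o]
      # P(O | M): maternal allele uniform from M, paternal from p
      pO <- 0
      for (x in unique(m_alleles)) {
        wx <- 0.5 * sum(m_alleles == x)
        if (o1 == o2) {
          if (x == o1) pO <- pO + wx * p[o1]
        } else {
          if (x == o1) pO <- pO + wx * p[o2]
          if (x == o2) pO <- pO + wx * p[o1]
        }
      }
      if (pO == 0) next
      # P(random candidate compatible): the paternal allele (the one not
      # explained by the mother) must be carried by the candidate
      m1 <- o1 %in% m_alleles
      m2 <- o2 %in% m_alleles
      compat <- if (m1 && m2) {
        carry[o1] + carry[o2] - carry2[o1, o2]
      } else if (m1) carry[o2] else if (m2) carry[o1] else 0
      Q1 <- Q1 + gs$prob[m] * pO * (1 - compat)
    }
  }
  Q2 <- 0
  for (o in seq_len(ng)) {
    o1 <- gs$a1[o]; o2 <- gs$a2[o]
    compat <- if (o1 == o2) {
      carry[o1]^2
    } else {
      # one candidate provides o1, the other o2 (either way around)
      2 * carry[o1] * carry[o2] - carry2[o1, o2]^2
    }
    Q2 <- Q2 + gs$prob[o] * (1 - compat)
  }
  c(Q1 = Q1, Q2 = Q2)
}

#' Combined exclusion probability over loci
#'
#' `1 - prod(1 - Q_l)`: the chance that at least one locus excludes.
#'
#' @param q vector of per-locus exclusion probabilities.
#' @return scalar in `[0, 1]`.
#' @export
combined_exclusion <- function(q) 1 - prod(1 - q)

# ---- locus summaries ------------------------------------------------------

#' Summarize one locus
#'
#' Allele frequencies by counting, allelic richness, observed and unbiased
#' expected heterozygosity `He = (2n/(2n-1)) (1 - sum p^2)`, EM null-allele
#' frequency, HWE exact-test p-value, and exclusion probabilities Q1/Q2.
#'
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @param null_adjust estimate the null-allele frequency?
#' @param hwe run the HWE exact test? (Monte-Carlo can dominate runtime in
#'   simulation loops that only need frequencies.)
#' @param exclusion compute Q1/Q2?
#' @param hwe_method passed to [hwe_exact_test()].
#' @return list of class `locus_summary`.
#' @export
locus_summary <- function(gt, locus, null_adjust = TRUE, hwe = TRUE,
                          exclusion = TRUE, hwe_method = "auto") {
  g <- locus_genotypes(gt, locus)
  keep <- !is.na(g[, 1])
  if (sum(keep) < 2) stop("need >= 2 non-missing genotypes at locus ", locus)
  g <- g[keep, , drop = FALSE]
  freqs <- allele_frequencies(gt, locus)
  n <- nrow(g)
  ho <- mean(g[, 1] != g[, 2])
  he <- (2 * n / (2 * n - 1)) * (1 - sum(freqs^2))
  hwe_p <- if (!hwe) NA_real_ else if (length(freqs) < 2) 1 else
    hwe_exact_test(g, method = hwe_method)$p_value
  nullest <- if (null_adjust) {
    estimate_null_allele_frequency(gt, locus)
  } else {
    list(p_null = 0, freqs = freqs, converged = TRUE)
  }
  q <- if (exclusion) exclusion_probabilities(freqs) else
    c(Q1 = NA_real_, Q2 = NA_real_)
  name <- if (is.character(locus)) locus else gt$loci[locus]
  structure(list(locus = name, n = n, freqs = freqs,
                 richness = length(freqs), Ho = ho, He = max(he, 0),
                 p_null = nullest$p_null, adj_freqs = nullest$freqs,
                 hwe_p = hwe_p, Q1 = unname(q["Q1"]), Q2 = unname(q["Q2"])),
            class = "locus_summary")
}

#' Summarize all loci of a genotype table
#' @param gt a [genotype_table()].
#' @param ... passed to [locus_summary()].
#' @return list of `locus_summary`, named by locus.
#' @export
locus_summaries <- function(gt, ...) {
  out <- lapply(gt$loci, function(l) locus_summary(gt, l, ...))
  names(out) <- gt$loci
  out
}

#' @export
print.locus_summary <- function(x, ...) {
  cat(sprintf("Locus %s: %d alleles, n = %d, Ho = %.3f, He = %.3f, p_null = %.3f, HWE p = %.3g, Q1 = %.3f, Q2 = %.3f\n",
              x$locus, x$richness, x$n, x$Ho, x$He, x$p_null, x$hwe_p,
              x$Q1, x$Q2))
  invisible(x)
}

#' Export locus summaries as a data frame
#' @param summaries result of [locus_summaries()].
#' @return data frame, one row per locus.
#' @export
locus_summary_table <- function(summaries) {
  do.call(rbind, lapply(summaries, function(s) {
    data.frame(locus = s$locus, n = s$n, richness = s$richness,
               Ho = s$Ho, He = s$He, p_null = s$p_null, hwe_p = s$hwe_p,
               Q1 = s$Q1, Q2 = s$Q2, stringsAsFactors = FALSE)
  }))
}

# ---- pairwise relationship likelihoods ------------------------------------

# Frequency vector for likelihood computations: visible alleles (named by
# code) plus the null allele coded "0" when p_null > 0.
likelihood_freqs <- function(summary, use_null = TRUE) {
  if (use_null && summary$p_null > 0) {
    c(stats::setNames(summary$p_null, "0"), summary$adj_freqs)
  } else {
    summary$freqs / sum(summary$freqs)
  }
}

# Expand an observed genotype (sorted pair) into possible true genotypes:
# an apparent homozygote may hide a null heterozygote.
expand_observed <- function(a1, a2, has_null) {
  a1 <- unname(a1)
  a2 <- unname(a2)
  if (a1 == a2 && has_null) list(c(a1, a2), c(0, a1)) else list(c(a1, a2))
}

geno_prob <- function(g, f) {
  p1 <- f[as.character(g[1])]
  p2 <- f[as.character(g[2])]
  if (is.na(p1) || is.na(p2)) return(0)
  unname(if (g[1] == g[2]) p1 * p2 else 2 * p1 * p2)
}

# P(g2 | g1 shares exactly one allele IBD): the shared allele is a uniform
# draw from g1, the other allele of g2 comes from the population.
trans_prob <- function(g2, g1, f) {
  tp <- 0
  for (x in g1) {
    if (g2[1] == g2[2]) {
      if (x == g2[1]) tp <- tp + 0.5 * f[as.character(g2[1])]
    } else {
      if (x == g2[1]) tp <- tp + 0.5 * f[as.character(g2[2])]
      if (x == g2[2]) tp <- tp + 0.5 * f[as.character(g2[1])]
    }
  }
  unname(tp)
}

# Per-locus likelihood of an observed genotype pair under IBD coefficients
# k = (k0, k1, k2), marginalizing over hidden null-carrier states.
pair_likelihood_locus <- function(obs1, obs2, kcoef, f) {
  has_null <- "0" %in% names(f)
  L <- 0
  for (g1 in expand_observed(obs1[1], obs1[2], has_null)) {
    for (g2 in expand_observed(obs2[1], obs2[2], has_null)) {
      p1 <- geno_prob(g1, f)
      L <- L + kcoef[1] * p1 * geno_prob(g2, f) +
        kcoef[2] * p1 * trans_prob(g2, g1, f) +
        kcoef[3] * p1 * (if (identical(sort(g1), sort(g2))) 1 else 0)
    }
  }
  unname(L)
}

#' Multilocus log-likelihood of a genotype pair under a relationship
#'
#' Per-locus likelihoods `P(g1, g2 | k) = k0 P(g1) P(g2) + k1 P(g1)
#' T(g2 | g1) + k2 P(g1) [g1 = g2]` are multiplied across loci (assumed
#' independent); loci missing in either individual are skipped. When a
#' locus summary carries a positive null-allele frequency, apparent
#' homozygotes are marginalized over the hidden null-carrier state.
#'
#' @param gt a [genotype_table()].
#' @param id1,id2 individual ids.
#' @param category one of `"U"`, `"HS"`, `"FS"`, `"PO"`.
#' @param summaries list from [locus_summaries()].
#' @param use_null model null alleles when estimated > 0.
#' @return log-likelihood (scalar).
#' @export
pair_log_likelihood <- function(gt, id1, id2, category, summaries,
                                use_null = TRUE) {
  kcoef <- relationship_categories()[[category]]
  if (is.null(kcoef)) stop("unknown category: ", category)
  ll <- 0
  n_used <- 0
  for (l in seq_along(gt$loci)) {
    g1 <- gt$alleles[id1, l, ]
    g2 <- gt$alleles[id2, l, ]
    if (anyNA(g1) || anyNA(g2)) next
    f <- likelihood_freqs(summaries[[l]], use_null)
    L <- pair_likelihood_locus(g1, g2, kcoef, f)
    if (L <= 0) L <- 1e-300 # numerically impossible configuration
    ll <- ll + log(L)
    n_used <- n_used + 1
  }
  if (n_used == 0) stop("no shared non-missing loci between ", id1,
                        " and ", id2)
  ll
}

#' Classify the relationship of a pair
#'
#' Maximum-likelihood classification over U, HS, FS, PO with ties broken
#' toward the less related category (priority U > HS > FS > PO), which
#' keeps the reconstructed pedigree conservative when the data cannot
#' discriminate.
#'
#' @inheritParams pair_log_likelihood
#' @return list with `category`, `logLik` (named vector over the four
#'   categories) and `llr` (log-likelihood ratios vs the chosen category's
#'   alternatives).
#' @export
classify_relationship <- function(gt, id1, id2, summaries, use_null = TRUE) {
  cats <- c("U", "HS", "FS", "PO") # priority order
  ll <- vapply(cats, function(cat)
    pair_log_likelihood(gt, id1, id2, cat, summaries, use_null), numeric(1))
  best <- cats[1]
  for (cat in cats[-1]) if (ll[cat] > ll[best] + 1e-9) best <- cat
  list(category = best, logLik = ll, llr = ll[best] - ll)
}

# ---- parentage ------------------------------------------------------------

# P(offspring observed genotype | one parent's observed genotype), other
# allele from the population; marginalizes null states.
duo_likelihood_locus <- function(obs_o, obs_p, f) {
  has_null <- "0" %in% names(f)
  L <- 0
  for (go in expand_observed(obs_o[1], obs_o[2], has_null)) {
    for (gp in expand_observed(obs_p[1], obs_p[2], has_null)) {
      # weight of the parent's true genotype within the observed class
      wp <- geno_prob(gp, f)
      L <- L + wp * trans_prob(go, gp, f)
    }
  }
  # normalize the parent-expansion mixture
  tot <- 0
  for (gp in expand_observed(obs_p[1], obs_p[2], has_null))
    tot <- tot + geno_prob(gp, f)
  if (tot > 0) L <- L / tot
  unname(L)
}

# P(offspring | known parent K and candidate C): one allele from each.
trio_likelihood_locus <- function(obs_o, obs_k, obs_c, f) {
  has_null <- "0" %in% names(f)
  L <- 0
  totk <- totc <- 0
  for (gk in expand_observed(obs_k[1], obs_k[2], has_null))
    totk <- totk + geno_prob(gk, f)
  for (gc in expand_observed(obs_c[1], obs_c[2], has_null))
    totc <- totc + geno_prob(gc, f)
  for (go in expand_observed(obs_o[1], obs_o[2], has_null)) {
    for (gk in expand_observed(obs_k[1], obs_k[2], has_null)) {
      for (gc in expand_observed(obs_c[1], obs_c[2], has_null)) {
        wk <- geno_prob(gk, f) / totk
        wc <- geno_prob(gc, f) / totc
        pm <- 0
        for (x in gk) for (y in gc) {
          if (min(x, y) == min(go) && max(x, y) == max(go)) pm <- pm + 0.25
        }
        L <- L + wk * wc * pm
      }
    }
  }
  unname(L)
}

# P(offspring | known parent K, other parent random)
trio_null_likelihood_locus <- function(obs_o, obs_k, f) {
  has_null <- "0" %in% names(f)
  L <- 0
  totk <- 0
  for (gk in expand_observed(obs_k[1], obs_k[2], has_null))
    totk <- totk + geno_prob(gk, f)
  for (go in expand_observed(obs_o[1], obs_o[2], has_null)) {
    for (gk in expand_observed(obs_k[1], obs_k[2], has_null)) {
      L <- L + geno_prob(gk, f) / totk * trans_prob(go, gk, f)
    }
  }
  unname(L)
}

#' Likelihood-based parentage assignment
#'
#' Candidates with Mendelian mismatches (zero transmission likelihood) at
#' more than `max_mismatch` loci are excluded; when null alleles are
#' modeled, an apparent-homozygote mismatch that a null allele could
#' explain is not counted. Among surviving candidates the posterior
#' probability of each is its (duo or trio) likelihood against the
#' alternatives, including an "unsampled random parent" alternative whose
#' likelihood uses population allele frequencies. Assignment requires the
#' posterior to reach `threshold` (default 0.99).
#'
#' @param gt a [genotype_table()].
#' @param offspring offspring id.
#' @param candidates character vector of candidate parent ids (the
#'   offspring itself is dropped if present).
#' @param summaries list from [locus_summaries()].
#' @param known_parent id of the already-known other parent, or `NULL`.
#' @param threshold posterior probability required to assign.
#' @param max_mismatch mismatching loci tolerated before exclusion.
#' @param use_null model null alleles.
#' @return list of class `parentage_result`: `offspring`, `assigned` (id or
#'   `NA`), `posterior`, and `table` (one row per candidate: mismatches,
#'   log-likelihood, posterior, excluded flag).
#' @export
assign_parentage <- function(gt, offspring, candidates, summaries,
                             known_parent = NULL, threshold = 0.99,
                             max_mismatch = 0, use_null = TRUE) {
  candidates <- setdiff(unique(candidates), offspring)
  empty <- list(offspring = offspring, assigned = NA_character_,
                posterior = NA_real_,
                table = data.frame(candidate = character(0),
                                   mismatches = integer(0),
                                   logLik = numeric(0),
                                   posterior = numeric(0),
                                   excluded = logical(0)))
  class(empty) <- "parentage_result"
  if (!length(candidates)) return(empty)

  loci_idx <- seq_along(gt$loci)
  fs <- lapply(summaries, likelihood_freqs, use_null = use_null)

  cand_ll <- numeric(length(candidates))
  cand_mm <- integer(length(candidates))
  null_ll <- 0
  for (l in loci_idx) {
    go <- gt$alleles[offspring, l, ]
    if (anyNA(go)) next
    f <- fs[[l]]
    gk <- if (!is.null(known_parent)) gt$alleles[known_parent, l, ] else NULL
    have_k <- !is.null(gk) && !anyNA(gk)
    null_ll <- null_ll + log(max(
      if (have_k) trio_null_likelihood_locus(go, gk, f) else geno_prob_obs(go, f),
      1e-300))
    for (ci in seq_along(candidates)) {
      gc <- gt$alleles[candidates[ci], l, ]
      if (anyNA(gc)) {
        # unscored locus: candidate gets the random-parent likelihood
        cand_ll[ci] <- cand_ll[ci] + log(max(
          if (have_k) trio_null_likelihood_locus(go, gk, f) else geno_prob_obs(go, f),
          1e-300))
        next
      }
      L <- if (have_k) trio_likelihood_locus(go, gk, gc, f)
           else duo_likelihood_locus(go, gc, f)
      if (L <= 0) {
        cand_mm[ci] <- cand_mm[ci] + 1L
      } else {
        cand_ll[ci] <- cand_ll[ci] + log(L)
      }
    }
  }
  excluded <- cand_mm > max_mismatch
  # posterior over surviving candidates + the unsampled-parent alternative
  ll_all <- c(cand_ll, null_ll)
  ll_all[c(excluded, FALSE)] <- -Inf
  w <- exp(ll_all - max(ll_all))
  post <- w / sum(w)
  cand_post <- post[seq_along(candidates)]
  best <- which.max(cand_post)
  assigned <- if (length(best) && !excluded[best] &&
                  cand_post[best] >= threshold) candidates[best]
              else NA_character_
  res <- list(
    offspring = offspring,
    assigned = assigned,
    posterior = if (length(best)) unname(cand_post[best]) else NA_real_,
    table = data.frame(candidate = candidates, mismatches = cand_mm,
                       logLik = cand_ll, posterior = cand_post,
                       excluded = excluded, stringsAsFactors = FALSE))
  class(res) <- "parentage_result"
  res
}

# HWE probability of an observed genotype (marginal over null states).
geno_prob_obs <- function(obs, f) {
  has_null <- "0" %in% names(f)
  sum(vapply(expand_observed(obs[1], obs[2], has_null),
             geno_prob, numeric(1), f = f))
}

#' @export
print.parentage_result <- function(x, ...) {
  cat("Parentage for", x$offspring, "->",
      if (is.na(x$assigned)) "unassigned" else x$assigned,
      sprintf("(posterior %.3f)\n", x$posterior))
  invisible(x)
}

# ---- sibship partitioning -------------------------------------------------

#' Partition nestlings into full-sib groups
#'
#' Greedy agglomeration on pairwise likelihoods: starting from singletons,
#' repeatedly merge the pair of groups whose union maximizes the summed
#' pairwise full-sib log-likelihood gain over "unrelated", provided no
#' cross-pair classifies as unrelated; stop when no merge has positive
#' gain. Deterministic given input order.
#'
#' @param gt a [genotype_table()].
#' @param nestlings character vector of ids (>= 2).
#' @param summaries list from [locus_summaries()].
#' @param use_null model null alleles.
#' @return list of groups; each group is a character vector of ids with a
#'   `label` attribute (`"FS"` for groups of two or more, `"singleton"`
#'   otherwise).
#' @export
partition_full_sibs <- function(gt, nestlings, summaries, use_null = TRUE) {
  n <- length(nestlings)
  if (n < 2) stop("need at least 2 nestlings")
  ll_fs <- ll_u <- matrix(0, n, n)
  is_u <- matrix(FALSE, n, n)
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      cl <- classify_relationship(gt, nestlings[i], nestlings[j],
                                  summaries, use_null)
      ll_fs[i, j] <- ll_fs[j, i] <- cl$logLik["FS"]
      ll_u[i, j] <- ll_u[j, i] <- cl$logLik["U"]
      is_u[i, j] <- is_u[j, i] <- cl$category == "U"
    }
  }
  gain <- ll_fs - ll_u
  groups <- as.list(seq_len(n))
  repeat {
    best_gain <- 0
    best_pair <- NULL
    for (a in seq_along(groups)) {
      for (b in seq_along(groups)) {
        if (b <= a) next
        ia <- groups[[a]]; ib <- groups[[b]]
        if (any(is_u[ia, ib])) next
        g <- sum(gain[ia, ib])
        if (g > best_gain + 1e-12) {
          best_gain <- g
          best_pair <- c(a, b)
        }
      }
    }
    if (is.null(best_pair)) break
    groups[[best_pair[1]]] <- c(groups[[best_pair[1]]],
                                groups[[best_pair[2]]])
    groups[[best_pair[2]]] <- NULL
  }
  lapply(groups, function(ix) {
    g <- nestlings[sort(ix)]
    attr(g, "label") <- if (length(g) >= 2) "FS" else "singleton"
    g
  })
}
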