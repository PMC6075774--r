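# Independent oracles and fixture builders used across tests. These are
# deliberately written with different algorithms than the package code
# (path counting instead of the tabular method, nested-loop enumeration
# instead of vectorized sums) so that agreement is informative.

# -- fixture builders -------------------------------------------------------

# nuclear family: two founders and n_off full sibs
fam_pedigree <- function(n_off = 2) {
  pedigree(id = c("d", "s", paste0("o", seq_len(n_off))),
           dam = c(NA, NA, rep("d", n_off)),
           sire = c(NA, NA, rep("s", n_off)),
           sex = c("F", "M", rep(NA, n_off)))
}

# random acyclic pedigree: founders first, later individuals draw parents
# uniformly from earlier ones (or none)
random_pedigree <- function(n = 12, n_founders = 4, p_known = 0.8) {
  id <- sprintf("i%02d", seq_len(n))
  dam <- sire <- rep(NA_character_, n)
  for (k in (n_founders + 1):n) {
    prev <- seq_len(k - 1)
    if (stats::runif(1) < p_known) dam[k] <- id[sample(prev, 1)]
    if (stats::runif(1) < p_known) sire[k] <- id[sample(prev, 1)]
    if (!is.na(dam[k]) && !is.na(sire[k]) && dam[k] == sire[k])
      sire[k] <- NA
  }
  suppressMessages(pedigree(id, dam, sire))
}

# genotype table from an explicit list: list(ind = list(c(a, b), ...))
gt_from_list <- function(lst, loci = NULL) {
  n <- length(lst)
  L <- length(lst[[1]])
  a <- array(NA_integer_, c(n, L, 2),
             dimnames = list(names(lst), loci, NULL))
  for (i in seq_len(n)) for (l in seq_len(L)) {
    g <- lst[[i]][[l]]
    if (!is.null(g) && !anyNA(g)) {
      a[i, l, ] <- sort(as.integer(g))
    }
  }
  genotype_table(a, loci)
}

# frequency-only locus summaries for likelihood tests
plain_summaries <- function(freq_list, p_null = NULL) {
  out <- lapply(seq_along(freq_list), function(l) {
    f <- freq_list[[l]]
    if (is.null(names(f))) names(f) <- seq_along(f)
    pn <- if (is.null(p_null)) 0 else p_null[l]
    list(locus = paste0("L", l), freqs = f / sum(f), p_null = pn,
         adj_freqs = f / sum(f) * (1 - pn))
  })
  names(out) <- paste0("L", seq_along(freq_list))
  out
}

# -- relationship-matrix oracle --------------------------------------------

# additive relatedness by the recursive kinship (coancestry) definition:
# f(i, j) with memoization; A(i, j) = 2 f(i, j). Independent of the
# tabular method's ordering logic.
kinship_oracle <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  dam <- idx[ped$dam]
  sire <- idx[ped$sire]
  ord <- match(topological_order(ped), ped$id)
  depth <- stats::setNames(rep(0L, n), ped$id)
  memo <- new.env()
  f <- function(i, j) {
    if (i > j) { t <- i; i <- j; j <- t }
    key <- paste(i, j)
    if (!is.null(memo[[key]])) return(memo[[key]])
    # ensure j is not an ancestor of i: recurse on the later individual
    pos_i <- which(ord == i)
    pos_j <- which(ord == j)
    if (pos_i > pos_j) { t <- i; i <- j; j <- t }
    val <- if (i == j) {
      0.5 * (1 + (if (!is.na(dam[i]) && !is.na(sire[i]))
        f(dam[i], sire[i]) else 0))
    } else {
      v <- 0
      if (!is.na(dam[j])) v <- v + 0.5 * f(i, dam[j])
      if (!is.na(sire[j])) v <- v + 0.5 * f(i, sire[j])
      v
    }
    memo[[key]] <- val
    val
  }
  A <- matrix(0, n, n, dimnames = list(ped$id, ped$id))
  for (i in seq_len(n)) for (j in i:n) {
    A[i, j] <- A[j, i] <- 2 * f(i, j) # diag: 2 f(i,i) = 1 + F
  }
  A
}

# -- genotype-pair probability oracle --------------------------------------

# P(g1, g2 | k) by explicit enumeration over ordered parental/IBD states,
# for unordered genotypes g1, g2 (vectors of 2) and frequency vector p.
pair_prob_oracle <- function(g1, g2, k, p) {
  gp <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  # one-allele-IBD transition by enumeration over which allele is shared
  t1 <- function(g2, g1) {
    tot <- 0
    for (x in g1) {
      if (g2[1] == g2[2]) {
        if (x == g2[1]) tot <- tot + 0.5 * p[g2[1]]
      } else {
        if (x == g2[1]) tot <- tot + 0.5 * p[g2[2]]
        if (x == g2[2]) tot <- tot + 0.5 * p[g2[1]]
      }
    }
    tot
  }
  unname(k[1] * gp(g1) * gp(g2) + k[2] * gp(g1) * t1(g2, g1) +
           k[3] * gp(g1) * (g1[1] == g2[1] && g1[2] == g2[2]))
}

# -- exclusion-probability oracle ------------------------------------------

# brute-force enumeration with plain nested loops over every genotype of
# mother, offspring and candidate(s)
exclusion_oracle <- function(p) {
  k <- length(p)
  gen <- list()
  for (i in 1:k) for (j in i:k) gen[[length(gen) + 1]] <- c(i, j)
  gp <- function(g) if (g[1] == g[2]) p[g[1]]^2 else 2 * p[g[1]] * p[g[2]]
  can_make <- function(gm, gc, go) {
    for (x in gm) for (y in gc) {
      if (min(x, y) == go[1] && max(x, y) == go[2]) return(TRUE)
    }
    FALSE
  }
  has <- function(g, a) g[1] == a || g[2] == a
  Q1 <- 0
  for (gm in gen) for (gf in gen) for (mi in 1:2) for (fi in 1:2) {
    go <- sort(c(gm[mi], gf[fi]))
    w <- gp(gm) * gp(gf) * 0.25
    for (gc in gen) {
      ok <- (has(gm, go[1]) && has(gc, go[2])) ||
        (has(gm, go[2]) && has(gc, go[1]))
      if (!ok) Q1 <- Q1 + w * gp(gc)
    }
  }
  Q2 <- 0
  for (gm in gen) for (gf in gen) for (mi in 1:2) for (fi in 1:2) {
    go <- sort(c(gm[mi], gf[fi]))
    w <- gp(gm) * gp(gf) * 0.25
    for (gcm in gen) for (gcf in gen) {
      if (!can_make(gcm, gcf, go) && !can_make(gcf, gcm, go))
        Q2 <- Q2 + w * gp(gcm) * gp(gcf)
    }
  }
  c(Q1 = Q1, Q2 = Q2)
}

# -- misc -------------------------------------------------------------------

# HWE genotype sampler at given allele frequencies
sample_hwe_genotypes <- function(n, p) {
  k <- length(p)
  cbind(sample(k, n, TRUE, p), sample(k, n, TRUE, p))
}
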