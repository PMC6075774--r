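# Synthetic colony simulator: breeding structure, gene dropping, breeding
# values and phenotypes with known (co)variance components, so that every
# analysis stage can be exercised against known truth.

#' Simulation configuration
#'
#' Describes a synthetic colony of communal stick nests. Defaults emulate
#' the field population the package targets: 28 nests (21 with a single
#' brood chamber, 6 with two, 1 with four), one breeding pair per chamber,
#' extra-pair paternity in 40% of chambers, intra-brood parasitism in 3%
#' of chambers, and 7 microsatellite loci.
#'
#' Trait truth is stated through the additive (`G`), maternal (`M`), nest
#' (`N`) and residual (`R`) covariance matrices (t x t, symmetric PSD);
#' the implied true ratios h2, me2, ne2 are reported alongside simulated
#' phenotypes. Default traits mirror the six morphological measurements
#' (weight in g; wing, tarsus, tail, bill length, bill width in mm) with
#' nestling-scale means, and a default decomposition of
#' h2 = 0.3, me2 = 0.2, ne2 = 0.1 per trait with uncorrelated components.
#'
#' @param chambers_per_nest integer vector, one entry per nest, giving the
#'   number of brood chambers in that nest.
#' @param clutch_lambda mean of the (truncated) Poisson clutch-size
#'   distribution; clutch sizes are drawn from Poisson(`clutch_lambda`)
#'   truncated to `clutch_range`.
#' @param clutch_range length-2 integer range for clutch sizes.
#' @param epp_rate probability that a chamber's brood contains extra-pair
#'   offspring.
#' @param parasitism_rate probability that a chamber's brood contains one
#'   offspring laid by a foreign female.
#' @param n_loci number of microsatellite loci.
#' @param n_alleles alleles per locus (recycled to `n_loci`).
#' @param allele_freqs `"equifrequent"`, `"dirichlet"` (symmetric, shape 1),
#'   or a list of `n_loci` frequency vectors.
#' @param null_freq per-locus null-allele frequency (recycled).
#' @param missing_rate additional genotype dropout rate.
#' @param traits character vector of trait names.
#' @param trait_means numeric vector of trait means.
#' @param G,M,N,R t x t additive, maternal, nest and residual covariance
#'   matrices; scalars are expanded to diagonal matrices.
#' @param seed default RNG seed used by the simulators.
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(chambers_per_nest = c(rep(1L, 21), rep(2L, 6), 4L),
                       clutch_lambda = 4, clutch_range = c(1L, 8L),
                       epp_rate = 0.40, parasitism_rate = 0.03,
                       n_loci = 7L, n_alleles = 8L,
                       allele_freqs = "equifrequent",
                       null_freq = 0, missing_rate = 0,
                       traits = c("weight", "wing", "tarsus", "tail",
                                  "bill_length", "bill_width"),
                       trait_means = c(101.35, 95.88, 18.44, 64.52, 9.82, 11.31),
                       G = NULL, M = NULL, N = NULL, R = NULL,
                       seed = 1L) {
  t <- length(traits)
  stopifnot(length(trait_means) == t,
            all(chambers_per_nest >= 1),
            epp_rate >= 0, epp_rate <= 1,
            parasitism_rate >= 0, parasitism_rate <= 1)
  # default phenotypic SDs on the scale of the six nestling traits
  default_sd <- c(8.24, 33.67, 1.35, 25.56, 2.64, 0.52)
  vp <- if (t == 6) default_sd^2 else rep(1, t)
  as_cov <- function(x, frac) {
    if (is.null(x)) return(diag(frac * vp, t))
    if (is.matrix(x)) {
      stopifnot(nrow(x) == t, ncol(x) == t)
      return(x)
    }
    diag(rep_len(as.numeric(x), t), t)
  }
  cfg <- list(
    chambers_per_nest = as.integer(chambers_per_nest),
    clutch_lambda = clutch_lambda,
    clutch_range = as.integer(clutch_range),
    epp_rate = epp_rate, parasitism_rate = parasitism_rate,
    n_loci = as.integer(n_loci),
    n_alleles = rep_len(as.integer(n_alleles), n_loci),
    allele_freqs = allele_freqs,
    null_freq = rep_len(as.numeric(null_freq), n_loci),
    missing_rate = missing_rate,
    traits = traits, trait_means = trait_means,
    G = as_cov(G, 0.3), M = as_cov(M, 0.2),
    N = as_cov(N, 0.1), R = as_cov(R, 0.4),
    seed = seed)
  for (nm in c("G", "M", "N", "R")) {
    ev <- eigen(cfg[[nm]], symmetric = TRUE, only.values = TRUE)$values
    if (min(ev) < -1e-8) stop(nm, " must be positive semi-definite")
  }
  class(cfg) <- "sim_config"
  cfg
}

#' True variance ratios implied by a simulation configuration
#'
#' @param cfg a [sim_config()].
#' @return data frame with per-trait true h2, me2, ne2 and the additive
#'   correlation matrix as attribute `"r_G"`.
#' @export
true_ratios <- function(cfg) {
  vp <- diag(cfg$G) + diag(cfg$M) + diag(cfg$N) + diag(cfg$R)
  safe_ratio <- function(num) ifelse(vp > 0, num / vp, 0)
  out <- data.frame(trait = cfg$traits,
                    h2 = safe_ratio(diag(cfg$G)),
                    me2 = safe_ratio(diag(cfg$M)),
                    ne2 = safe_ratio(diag(cfg$N)),
                    vp = vp)
  attr(out, "r_G") <- if (all(diag(cfg$G) > 0)) stats::cov2cor(cfg$G) else
    matrix(NA_real_, nrow(cfg$G), ncol(cfg$G))
  out
}

locus_frequencies <- function(cfg) {
  if (is.list(cfg$allele_freqs)) {
    stopifnot(length(cfg$allele_freqs) == cfg$n_loci)
    return(lapply(cfg$allele_freqs, function(p) p / sum(p)))
  }
  lapply(seq_len(cfg$n_loci), function(l) {
    k <- cfg$n_alleles[l]
    if (identical(cfg$allele_freqs, "dirichlet")) {
      g <- stats::rgamma(k, 1)
      g / sum(g)
    } else {
      rep(1 / k, k)
    }
  })
}

rtrunc_pois <- function(n, lambda, range) {
  x <- stats::rpois(n, lambda)
  bad <- x < range[1] | x > range[2]
  while (any(bad)) {
    x[bad] <- stats::rpois(sum(bad), lambda)
    bad <- x < range[1] | x > range[2]
  }
  x
}

#' Simulate the breeding structure of a colony
#'
#' One breeding pair of unrelated founder adults per chamber; clutch sizes
#' from a truncated Poisson; with probability `epp_rate` a chamber's brood
#' contains 1..clutch offspring sired by a random resident male from
#' another chamber; with probability `parasitism_rate` one offspring of the
#' brood was laid by a random female from another chamber. The returned
#' pedigree records the *genetic* parents; the truth table keeps both
#' social and genetic parentage for later scoring.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed (default `cfg$seed`).
#' @return list with `ped` ([pedigree()]), `structure` (data frame: id,
#'   age_class, nest, chamber, sex), and `truth` (per-offspring social and
#'   genetic parents plus EPP/parasitism flags).
#' @export
simulate_colony_pedigree <- function(cfg, seed = cfg$seed) {
  if (length(cfg$chambers_per_nest) == 0) stop("zero nests in configuration")
  with_seed(seed, {
    nests <- rep(seq_along(cfg$chambers_per_nest), cfg$chambers_per_nest)
    n_ch <- length(nests)
    chamber <- unlist(lapply(cfg$chambers_per_nest, seq_len))
    dam_id <- sprintf("F%03d", seq_len(n_ch))
    sire_id <- sprintf("M%03d", seq_len(n_ch))
    clutch <- rtrunc_pois(n_ch, cfg$clutch_lambda, cfg$clutch_range)
    epp_ch <- stats::runif(n_ch) < cfg$epp_rate
    par_ch <- stats::runif(n_ch) < cfg$parasitism_rate

    off <- list()
    k <- 0L
    for (c in seq_len(n_ch)) {
      ids <- sprintf("O%04d", k + seq_len(clutch[c]))
      k <- k + clutch[c]
      gdam <- rep(dam_id[c], clutch[c])
      gsire <- rep(sire_id[c], clutch[c])
      epp_flag <- rep(FALSE, clutch[c])
      par_flag <- rep(FALSE, clutch[c])
      if (epp_ch[c] && n_ch > 1) {
        n_epp <- sample.int(clutch[c], 1L)
        which_epp <- sample.int(clutch[c], n_epp)
        extra_male <- sample(sire_id[-c], 1L)
        gsire[which_epp] <- extra_male
        epp_flag[which_epp] <- TRUE
      }
      if (par_ch[c] && n_ch > 1) {
        wp <- sample.int(clutch[c], 1L)
        foreign <- sample(dam_id[-c], 1L)
        gdam[wp] <- foreign
        # a parasitic egg is not sired by the host male either
        if (!epp_flag[wp]) gsire[wp] <- sample(sire_id[-c], 1L)
        par_flag[wp] <- TRUE
      }
      off[[c]] <- data.frame(
        id = ids, nest = nests[c], chamber = c,
        social_dam = dam_id[c], social_sire = sire_id[c],
        genetic_dam = gdam, genetic_sire = gsire,
        epp = epp_flag, parasitic = par_flag,
        stringsAsFactors = FALSE)
    }
    truth <- do.call(rbind, off)
    ped <- pedigree(
      id = c(dam_id, sire_id, truth$id),
      dam = c(rep(NA, 2 * n_ch), truth$genetic_dam),
      sire = c(rep(NA, 2 * n_ch), truth$genetic_sire),
      sex = c(rep("F", n_ch), rep("M", n_ch), rep(NA, nrow(truth))))
    structure_df <- data.frame(
      id = c(dam_id, sire_id, truth$id),
      age_class = c(rep("adult", 2 * n_ch), rep("nestling", nrow(truth))),
      nest = c(nests, nests, truth$nest),
      chamber = c(seq_len(n_ch), seq_len(n_ch), truth$chamber),
      sex = c(rep("F", n_ch), rep("M", n_ch), rep(NA, nrow(truth))),
      stringsAsFactors = FALSE)
    list(ped = ped, structure = structure_df, truth = truth,
         epp_chambers = epp_ch, parasitized_chambers = par_ch)
  })
}

#' Drop genotypes through a pedigree
#'
#' Founder alleles are drawn i.i.d. from the locus frequencies; each
#' offspring receives one uniformly chosen allele from each parent (alleles
#' for an unknown parent are drawn from the population frequencies). Null
#' alleles are simulated as a non-amplifying allele: a null homozygote is
#' recorded as missing, a null heterozygote as an apparent visible
#' homozygote. Additional dropout is applied at `cfg$missing_rate`.
#'
#' @param ped a [pedigree()].
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `observed` (a [genotype_table()]) and `true_alleles`
#'   (array n x n_loci x 2 of true allele codes, null = 0).
#' @export
simulate_genotypes <- function(ped, cfg, seed = cfg$seed) {
  with_seed(seed, {
    freqs <- locus_frequencies(cfg)
    ord <- topological_order(ped)
    n <- nrow(ped)
    pos <- match(ord, ped$id)
    dam <- match(ped$dam[pos], ord)
    sire <- match(ped$sire[pos], ord)
    L <- cfg$n_loci
    tru <- array(0L, dim = c(n, L, 2), dimnames = list(ord, NULL, NULL))
    for (l in seq_len(L)) {
      p0 <- cfg$null_freq[l]
      pv <- freqs[[l]] * (1 - p0)
      codes <- c(seq_along(pv), 0L) # 0 encodes the null allele
      pr <- c(pv, p0)
      for (i in seq_len(n)) {
        for (m in 1:2) {
          par <- if (m == 1) dam[i] else sire[i]
          tru[i, l, m] <- if (is.na(par)) {
            sample(codes, 1L, prob = pr)
          } else {
            tru[par, l, sample.int(2L, 1L)]
          }
        }
      }
    }
    # observation layer
    obs <- array(NA_integer_, dim = dim(tru), dimnames = dimnames(tru))
    for (l in seq_len(L)) {
      a1 <- tru[, l, 1]; a2 <- tru[, l, 2]
      o1 <- a1; o2 <- a2
      both_null <- a1 == 0L & a2 == 0L
      one_null <- xor(a1 == 0L, a2 == 0L)
      vis <- pmax(a1, a2)
      o1[one_null] <- vis[one_null]
      o2[one_null] <- vis[one_null]
      o1[both_null] <- NA_integer_
      o2[both_null] <- NA_integer_
      drop <- stats::runif(n) < cfg$missing_rate
      o1[drop] <- NA_integer_
      o2[drop] <- NA_integer_
      obs[, l, 1] <- o1
      obs[, l, 2] <- o2
    }
    gt <- genotype_table(obs[ped$id, , , drop = FALSE],
                         loci = sprintf("L%02d", seq_len(L)))
    list(observed = gt, true_alleles = tru[ped$id, , , drop = FALSE],
         freqs = freqs)
  })
}

#' Simulate additive genetic (breeding) values
#'
#' Standard quantitative-genetics gene-dropping recursion: founders are
#' MVN(0, G); a non-founder is the mean of its known parents' vectors plus
#' a Mendelian-sampling deviate with covariance
#' `(1 - k_d (1 + F_d)/4 - k_s (1 + F_s)/4) G`, where `k` indicates a known
#' parent and `F` its inbreeding coefficient (an unknown parent contributes
#' 0 with its share of variance restored).
#'
#' @param ped a [pedigree()].
#' @param G t x t additive covariance matrix (PSD).
#' @param seed RNG seed.
#' @param n_rep number of independent replicate drops. When `n_rep > 1`
#'   the trait must be univariate (`G` 1 x 1) and the recursion is
#'   vectorized across replicates, so millions of gene drops (e.g. to
#'   check that `cov(a_i, a_j)` converges to `sigma2_A A[i, j]`) cost a
#'   handful of vector operations per individual.
#' @return `n x t` matrix of breeding values (rows named by `ped$id`), or
#'   `n x n_rep` when `n_rep > 1`.
#' @export
simulate_breeding_values <- function(ped, G, seed = NULL, n_rep = 1) {
  if (n_rep > 1) {
    G <- as.matrix(G)
    stopifnot(nrow(G) == 1, G[1, 1] >= 0)
    return(with_seed(seed, {
      ord <- topological_order(ped)
      Fi <- inbreeding_coefficients(ped)
      pos <- match(ord, ped$id)
      dam <- ped$dam[pos]
      sire <- ped$sire[pos]
      sdA <- sqrt(G[1, 1])
      a <- matrix(0, nrow(ped), n_rep, dimnames = list(ord, NULL))
      for (i in seq_along(ord)) {
        mu <- numeric(n_rep)
        vshare <- 1
        if (!is.na(dam[i])) {
          mu <- mu + 0.5 * a[dam[i], ]
          vshare <- vshare - (1 + Fi[dam[i]]) / 4
        }
        if (!is.na(sire[i])) {
          mu <- mu + 0.5 * a[sire[i], ]
          vshare <- vshare - (1 + Fi[sire[i]]) / 4
        }
        a[i, ] <- mu + sqrt(vshare) * sdA * stats::rnorm(n_rep)
      }
      a[ped$id, , drop = FALSE]
    }))
  }
  simulate_breeding_values_multi(ped, G, seed)
}

simulate_breeding_values_multi <- function(ped, G, seed = NULL) {
  G <- as.matrix(G)
  ev <- eigen(G, symmetric = TRUE)
  if (min(ev$values) < -1e-8) stop("G must be positive semi-definite")
  # matrix square root tolerant of zero eigenvalues
  Gh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(G)) %*% t(ev$vectors)
  with_seed(seed, {
    t <- nrow(G)
    ord <- topological_order(ped)
    Fi <- inbreeding_coefficients(ped)
    pos <- match(ord, ped$id)
    dam <- ped$dam[pos]
    sire <- ped$sire[pos]
    a <- matrix(0, nrow(ped), t, dimnames = list(ord, rownames(G)))
    for (i in seq_along(ord)) {
      mu <- numeric(t)
      vshare <- 1
      if (!is.na(dam[i])) {
        mu <- mu + 0.5 * a[dam[i], ]
        vshare <- vshare - (1 + Fi[dam[i]]) / 4
      }
      if (!is.na(sire[i])) {
        mu <- mu + 0.5 * a[sire[i], ]
        vshare <- vshare - (1 + Fi[sire[i]]) / 4
      }
      a[i, ] <- mu + sqrt(vshare) * (Gh %*% stats::rnorm(t))[, 1]
    }
    a[ped$id, , drop = FALSE]
  })
}

#' Simulate phenotypes
#'
#' `y_i = mean + a_i + m_dam(i) + n_nest(i) + e_i` with maternal effects
#' `m ~ MVN(0, M)` drawn once per dam, nest effects `n ~ MVN(0, N)` once
#' per nest and residuals `e ~ MVN(0, R)` per individual. Individuals with
#' an unknown dam each receive their own maternal draw (a unique
#' pseudo-dam), mirroring how the model treats them.
#'
#' @param ped a [pedigree()].
#' @param structure data frame with columns `id`, `nest`, `chamber`,
#'   `age_class` (from [simulate_colony_pedigree()]).
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return a trait table (data frame: id, age_class, nest, chamber, sex,
#'   one column per trait) with attribute `"truth"` holding the true
#'   ratios from [true_ratios()] and the individual breeding values.
#' @export
simulate_phenotypes <- function(ped, structure, cfg, seed = cfg$seed) {
  t <- length(cfg$traits)
  for (nm in c("M", "N", "R")) {
    if (!all(dim(cfg[[nm]]) == c(t, t)))
      stop("dimension mismatch between G, M, N, R and traits")
  }
  a <- simulate_breeding_values(ped, cfg$G, seed = derive_seed(seed, "bv"))
  with_seed(derive_seed(seed, "pheno"), {
    rmvn <- function(n, S) {
      ev <- eigen(S, symmetric = TRUE)
      Sh <- ev$vectors %*% diag(sqrt(pmax(ev$values, 0)), nrow(S)) %*%
        t(ev$vectors)
      matrix(stats::rnorm(n * nrow(S)), n) %*% Sh
    }
    ids <- ped$id
    n <- length(ids)
    dam <- ped$dam
    dam_key <- ifelse(is.na(dam), paste0(".self.", ids), dam)
    dams <- unique(dam_key)
    m_eff <- rmvn(length(dams), cfg$M)
    rownames(m_eff) <- dams
    st <- structure[match(ids, structure$id), ]
    nest_key <- as.character(st$nest)
    nests <- unique(nest_key)
    n_eff <- rmvn(length(nests), cfg$N)
    rownames(n_eff) <- nests
    e <- rmvn(n, cfg$R)
    y <- matrix(rep(cfg$trait_means, each = n), n) +
      a + m_eff[dam_key, , drop = FALSE] +
      n_eff[nest_key, , drop = FALSE] + e
    colnames(y) <- cfg$traits
    out <- data.frame(id = ids, age_class = st$age_class, nest = st$nest,
                      chamber = st$chamber, sex = st$sex,
                      stringsAsFactors = FALSE)
    out <- cbind(out, as.data.frame(y))
    attr(out, "truth") <- list(ratios = true_ratios(cfg),
                               breeding_values = a)
    out
  })
}

#' Simulate a complete colony data set
#'
#' Convenience wrapper: breeding structure, genotypes and phenotypes under
#' one configuration and seed.
#'
#' @param cfg a [sim_config()].
#' @param seed RNG seed.
#' @return list with `ped`, `structure`, `truth`, `genotypes`,
#'   `phenotypes`.
#' @export
simulate_colony <- function(cfg, seed = cfg$seed) {
  col <- simulate_colony_pedigree(cfg, seed = derive_seed(seed, "ped"))
  gen <- simulate_genotypes(col$ped, cfg, seed = derive_seed(seed, "geno"))
  phe <- simulate_phenotypes(col$ped, col$structure, cfg, seed = seed)
  list(ped = col$ped, structure = col$structure, truth = col$truth,
       genotypes = gen$observed, true_alleles = gen$true_alleles,
       allele_freqs = gen$freqs, phenotypes = phe)
}
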