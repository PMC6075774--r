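# Bayesian pedigree mixed models ("animal models"): Gibbs-sampled variance
# components, posterior summaries of variance ratios, genetic correlations
# and DIC model selection.

#' MCMC schedule presets
#'
#' `"paper"` follows the field-standard long schedules for this study
#' design: univariate 1,000,000 total iterations, 100,000 burn-in, thinning
#' 100 (9,000 retained samples); bivariate 4,000,000 / 400,000 / 1,000
#' (3,600 retained). `"fast"` is the scaled-down testing schedule
#' (15,000 / 5,000 / 10, i.e. 1,000 retained).
#'
#' @param preset `"paper"`, `"fast"`, or `"smoke"` (tiny, for structural
#'   tests only).
#' @param bivariate use the bivariate variant of the preset?
#' @return list with `total`, `burnin`, `thin`.
#' @export
model_schedule <- function(preset = c("fast", "paper", "smoke"),
                           bivariate = FALSE) {
  preset <- match.arg(preset)
  sched <- switch(preset,
    paper = if (bivariate) list(total = 4e6, burnin = 4e5, thin = 1000)
            else list(total = 1e6, burnin = 1e5, thin = 100),
    fast = list(total = 15000, burnin = 5000, thin = 10),
    smoke = list(total = 2500, burnin = 500, thin = 5))
  sched
}

#' Specify an animal model
#'
#' @param traits character vector of 1 (univariate) or 2 (bivariate)
#'   response trait names.
#' @param random random terms, a subset of
#'   `c("additive", "maternal", "nest")`. `"additive"` uses the pedigree
#'   relationship matrix as covariance kernel; `"maternal"` and `"nest"`
#'   are i.i.d. effects of dam and nest identity.
#' @param fixed `"intercept"` (default), `"intercept+age"` (adds the
#'   adult/nestling age class), or `"none"`.
#' @param nu prior degrees of belief for every variance term (default 1;
#'   bivariate default 1.002).
#' @param V prior scale. Univariate default: 0.05 x the sample variance of
#'   the response for every term (`NULL` = this default). Bivariate
#'   default: `diag(2)`.
#' @param schedule list with `total`, `burnin`, `thin`, or a preset name
#'   for [model_schedule()].
#' @param seed RNG seed for the sampler.
#' @return list of class `animal_model_spec`.
#' @export
animal_model_spec <- function(traits, random = "additive",
                              fixed = "intercept", nu = NULL, V = NULL,
                              schedule = "fast", seed = 1L) {
  stopifnot(length(traits) %in% 1:2,
            all(random %in% c("additive", "maternal", "nest")),
            fixed %in% c("intercept", "intercept+age", "none"))
  bi <- length(traits) == 2
  if (is.character(schedule)) schedule <- model_schedule(schedule, bi)
  stopifnot(schedule$burnin < schedule$total, schedule$thin >= 1)
  if (is.null(nu)) nu <- if (bi) 1.002 else 1
  stopifnot(nu > 0)
  structure(list(traits = traits, random = random, fixed = fixed,
                 nu = nu, V = V, schedule = schedule, seed = seed),
            class = "animal_model_spec")
}

# Build design matrices shared by the two fitters. Returns the complete-case
# data, X, the random-term Z and precision-kernel lists, and labels.
build_design <- function(spec, traits, ped) {
  stopifnot(inherits(ped, "pedigree") || is.data.frame(ped))
  resp <- spec$traits
  stopifnot(all(resp %in% names(traits)))
  keep <- traits$id %in% ped$id
  for (tr in resp) keep <- keep & !is.na(traits[[tr]])
  if (spec$fixed == "intercept+age") keep <- keep & !is.na(traits$age_class)
  dat <- traits[keep, , drop = FALSE]
  if (nrow(dat) < 10) stop("need >= 10 phenotyped individuals in the pedigree")
  for (tr in resp) {
    if (stats::var(dat[[tr]]) <= 0) stop("zero-variance response: ", tr)
  }
  X <- switch(spec$fixed,
    none = matrix(0, nrow(dat), 0),
    intercept = matrix(1, nrow(dat), 1, dimnames = list(NULL, "(Intercept)")),
    `intercept+age` = stats::model.matrix(~ age_class, dat))
  Zs <- list()
  Kinvs <- list()
  labels <- character(0)
  if ("additive" %in% spec$random) {
    # only the phenotyped individuals' breeding values enter the
    # likelihood; their prior is the exact marginal N(0, sigma2_A *
    # A[obs, obs]), so unphenotyped relatives can be dropped from the
    # location vector (their information is already inside A)
    A <- additive_relationship_matrix(ped)
    obs <- unique(dat$id)
    Aobs <- A[obs, obs, drop = FALSE]
    Ainv <- tryCatch(chol2inv(chol(Aobs)),
                     error = function(e) stop("relationship matrix is not ",
                                              "positive definite"))
    Za <- matrix(0, nrow(dat), length(obs))
    Za[cbind(seq_len(nrow(dat)), match(dat$id, obs))] <- 1
    Zs <- c(Zs, list(Za))
    Kinvs <- c(Kinvs, list(Ainv))
    labels <- c(labels, "A")
    A_obs <- Aobs
  } else A_obs <- NULL
  if ("maternal" %in% spec$random) {
    dam <- ped$dam[match(dat$id, ped$id)]
    if (all(is.na(dam))) stop("maternal term requested but every dam is unknown")
    dam_key <- ifelse(is.na(dam), paste0(".self.", dat$id), dam)
    lev <- unique(dam_key)
    Zm <- matrix(0, nrow(dat), length(lev))
    Zm[cbind(seq_len(nrow(dat)), match(dam_key, lev))] <- 1
    Zs <- c(Zs, list(Zm))
    Kinvs <- c(Kinvs, list(diag(length(lev))))
    labels <- c(labels, "M")
  }
  if ("nest" %in% spec$random) {
    if (!"nest" %in% names(dat) || all(is.na(dat$nest)))
      stop("nest term requested but no nest column present")
    lev <- unique(as.character(dat$nest))
    Zn <- matrix(0, nrow(dat), length(lev))
    Zn[cbind(seq_len(nrow(dat)), match(as.character(dat$nest), lev))] <- 1
    Zs <- c(Zs, list(Zn))
    Kinvs <- c(Kinvs, list(diag(length(lev))))
    labels <- c(labels, "N")
  }
  # per-term marginal covariance kernels (Z K Z'), used by the
  # marginal-focus DIC
  kernels <- lapply(seq_along(Zs), function(t) {
    if (labels[t] == "A") Zs[[t]] %*% A_obs %*% t(Zs[[t]])
    else tcrossprod(Zs[[t]])
  })
  names(kernels) <- labels
  list(dat = dat, X = X, Zs = Zs, Kinvs = Kinvs, labels = labels,
       A_obs = A_obs, kernels = kernels)
}

#' Fit a univariate animal model by Gibbs sampling
#'
#' Samples `y = X b + Z_a a + Z_m m + Z_n n + e` with
#' `a ~ N(0, A sigma2_A)`, i.i.d. maternal and nest effects, and
#' `e ~ N(0, I sigma2_E)`. Location effects are drawn jointly from the
#' mixed-model-equation full conditional; each variance from its scaled
#' inverse-chi-square full conditional with prior `(nu, V)` (equivalently
#' inverse-gamma(nu/2, nu V / 2)). Fixed effects get an improper flat
#' prior. Individuals whose dam is unknown receive their own maternal
#' level, keeping the maternal design full rank.
#'
#' @param spec an [animal_model_spec()] with one trait.
#' @param traits trait table (data frame with `id`, trait columns, and
#'   `nest`/`age_class` when the spec uses them).
#' @param ped a [pedigree()].
#' @param prior_only if `TRUE`, sample from the prior (no data
#'   contribution); used for prior-predictive checks.
#' @return object of class `animal_model_fit` with elements `samples`
#'   (retained draws: variance components named `VA`/`VM`/`VN`, residual
#'   `VE`, fixed effects, `deviance`), `spec`, `n_obs`, and the plug-in
#'   quantities used by [compute_dic()].
#' @export
fit_univariate <- function(spec, traits, ped, prior_only = FALSE) {
  stopifnot(inherits(spec, "animal_model_spec"), length(spec$traits) == 1)
  d <- build_design(spec, traits, ped)
  y <- d$dat[[spec$traits]]
  vy <- stats::var(y)
  Vdef <- spec$V %||% (0.05 * vy)
  n_terms <- length(d$Zs)
  nu <- rep_len(spec$nu, n_terms)
  V <- rep_len(Vdef, n_terms)
  sched <- spec$schedule
  set.seed(spec$seed)
  eigen_path <- !prior_only && identical(d$labels, "A") &&
    !anyDuplicated(d$dat$id)
  if (eigen_path) {
    eg <- eigen(d$A_obs, symmetric = TRUE)
    yt <- as.numeric(crossprod(eg$vectors, y))
    Xt <- crossprod(eg$vectors, d$X)
    res <- gibbs_univariate_eigen(yt, Xt, pmax(eg$values, 1e-10),
                                  nu_a = nu[1], V_a = V[1],
                                  nu_e = spec$nu, V_e = Vdef,
                                  n_iter = as.integer(sched$total),
                                  burnin = as.integer(sched$burnin),
                                  thin = as.integer(sched$thin))
    y <- yt # deviance/DIC work identically in the rotated basis
    X_keep <- Xt
    kern_keep <- list(A = pmax(eg$values, 1e-10)) # diagonal in this basis
  } else {
    res <- gibbs_univariate(y, d$X, d$Zs, d$Kinvs, nu, V,
                            nu_e = spec$nu, V_e = Vdef,
                            n_iter = as.integer(sched$total),
                            burnin = as.integer(sched$burnin),
                            thin = as.integer(sched$thin),
                            prior_only = prior_only)
    X_keep <- d$X
    kern_keep <- d$kernels
  }
  vnames <- paste0("V", d$labels, recycle0 = TRUE)
  cn <- c(vnames, "VE",
          if (ncol(d$X)) paste0("b_", colnames(d$X)) else character(0),
          "deviance")
  colnames(res$samples) <- cn
  structure(list(samples = res$samples, spec = spec, type = "univariate",
                 n_obs = length(y), y = y,
                 mean_fitted = as.numeric(res$mean_fitted),
                 mean_sig2e = res$mean_sig2e,
                 mean_deviance = res$mean_deviance,
                 terms = d$labels, prior_only = prior_only,
                 eigen_path = eigen_path, X = X_keep,
                 kernels = kern_keep),
            class = "animal_model_fit")
}

#' Fit a bivariate animal model
#'
#' As [fit_univariate()] but with unstructured 2x2 covariance blocks for
#' every random term and the residual, drawn from inverse-Wishart full
#' conditionals with prior `IW(nu, nu V)` (default `V = diag(2)`,
#' `nu = 1.002`). When the only random term is `"additive"` and each
#' phenotyped individual has a single record, the sampler rotates the data
#' by the eigenvectors of the phenotyped block of A, which de-correlates
#' the additive effects and makes an iteration O(n).
#'
#' @inheritParams fit_univariate
#' @return an `animal_model_fit`; covariance samples are named
#'   `VA_x, CovA_xy, VA_y`, ... and `VE_x, CovE_xy, VE_y`.
#' @export
fit_bivariate <- function(spec, traits, ped) {
  stopifnot(inherits(spec, "animal_model_spec"), length(spec$traits) == 2)
  d <- build_design(spec, traits, ped)
  Y <- as.matrix(d$dat[, spec$traits])
  Vdef <- spec$V %||% diag(2)
  sched <- spec$schedule
  n_terms <- length(d$Zs)
  nu <- rep_len(spec$nu, n_terms)
  set.seed(spec$seed)
  eigen_path <- identical(d$labels, "A") && !anyDuplicated(d$dat$id)
  if (eigen_path) {
    eg <- eigen(d$A_obs, symmetric = TRUE)
    dvals <- pmax(eg$values, 1e-10)
    Yt <- t(eg$vectors) %*% Y
    Xt <- t(eg$vectors) %*% d$X
    res <- gibbs_bivariate_eigen(Yt, Xt, dvals,
                                 nu_a = spec$nu, V_a = Vdef,
                                 nu_e = spec$nu, V_e = Vdef,
                                 n_iter = as.integer(sched$total),
                                 burnin = as.integer(sched$burnin),
                                 thin = as.integer(sched$thin))
    res$Y_rot <- Yt
  } else {
    Vs <- rep(list(Vdef), n_terms)
    res <- gibbs_bivariate(Y, d$X, d$Zs, d$Kinvs, nu, Vs,
                           nu_e = spec$nu, V_e = Vdef,
                           n_iter = as.integer(sched$total),
                           burnin = as.integer(sched$burnin),
                           thin = as.integer(sched$thin))
    res$Y_rot <- Y
  }
  cn <- c(unlist(lapply(d$labels, function(l)
            c(paste0("V", l, "_x"), paste0("Cov", l, "_xy"),
              paste0("V", l, "_y")))),
          "VE_x", "CovE_xy", "VE_y",
          if (ncol(d$X)) c(paste0("b1_", colnames(d$X)),
                           paste0("b2_", colnames(d$X))) else character(0),
          "deviance")
  colnames(res$samples) <- cn
  structure(list(samples = res$samples, spec = spec, type = "bivariate",
                 n_obs = nrow(Y), y = res$Y_rot,
                 mean_fitted = res$mean_fitted, mean_R = res$mean_R,
                 mean_deviance = res$mean_deviance,
                 terms = d$labels, eigen_path = eigen_path),
            class = "animal_model_fit")
}

#' @export
print.animal_model_fit <- function(x, ...) {
  cat(sprintf("Animal model fit (%s): traits %s; random terms %s; %d retained samples\n",
              x$type, paste(x$spec$traits, collapse = ", "),
              paste(x$terms, collapse = "+"), nrow(x$samples)))
  invisible(x)
}

#' Posterior mode and highest-posterior-density interval
#'
#' The mode is the argmax of a Gaussian kernel density estimate
#' (Silverman's rule-of-thumb bandwidth, 512-point grid over the sample
#' range); the interval is the narrowest contiguous window of sorted
#' samples containing `level` posterior mass.
#'
#' @param x numeric vector of posterior samples (>= 10 unless constant).
#' @param level credible level in (0, 1).
#' @return list with `mode`, `lower`, `upper`.
#' @export
posterior_mode_hpd <- function(x, level = 0.95) {
  stopifnot(level > 0, level < 1)
  x <- x[is.finite(x)]
  if (length(unique(x)) == 1L) {
    return(list(mode = x[1], lower = x[1], upper = x[1]))
  }
  stopifnot(length(x) >= 10)
  dens <- stats::density(x, bw = "nrd0", n = 512,
                         from = min(x), to = max(x))
  mode <- dens$x[which.max(dens$y)]
  xs <- sort(x)
  n <- length(xs)
  m <- max(1L, ceiling(level * n))
  if (m >= n) return(list(mode = mode, lower = xs[1], upper = xs[n]))
  widths <- xs[(m + 1):n] - xs[1:(n - m)]
  i <- which.min(widths)
  list(mode = mode, lower = xs[i], upper = xs[i + m])
}

#' Variance ratios (h2, me2, ne2) from a univariate fit
#'
#' Per retained sample, `VP` is the sum of all variance components
#' including the residual, `h2 = VA/VP`, `me2 = VM/VP`, `ne2 = VN/VP`
#' (0 when the term is absent). Summaries are the KDE posterior mode with
#' 95% HPD interval.
#'
#' @param fit an `animal_model_fit` from [fit_univariate()].
#' @param level credible level.
#' @return object of class `variance_decomposition`: list with `summary`
#'   (data frame: ratio, mode, lower, upper) and `samples` (matrix with
#'   columns h2, me2, ne2, VP).
#' @export
variance_ratios <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "animal_model_fit"), fit$type == "univariate")
  s <- fit$samples
  va <- if ("VA" %in% colnames(s)) s[, "VA"] else 0
  vm <- if ("VM" %in% colnames(s)) s[, "VM"] else 0
  vn <- if ("VN" %in% colnames(s)) s[, "VN"] else 0
  vp <- va + vm + vn + s[, "VE"]
  rat <- cbind(h2 = va / vp, me2 = vm / vp, ne2 = vn / vp, VP = vp)
  summ <- do.call(rbind, lapply(c("h2", "me2", "ne2"), function(r) {
    v <- rat[, r]
    if (all(v == 0)) {
      data.frame(ratio = r, mode = 0, lower = 0, upper = 0)
    } else {
      h <- posterior_mode_hpd(v, level)
      data.frame(ratio = r, mode = h$mode, lower = h$lower, upper = h$upper)
    }
  }))
  structure(list(summary = summ, samples = rat, trait = fit$spec$traits),
            class = "variance_decomposition")
}

#' @export
print.variance_decomposition <- function(x, ...) {
  cat("Variance decomposition for", x$trait, "\n")
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' Posterior correlations from a bivariate fit
#'
#' For each fitted 2x2 block (additive, maternal, nest, residual) computes
#' the per-sample correlation `r = Cov_xy / sqrt(V_x V_y)`; the genetic
#' correlation `r_G` comes from the additive block. A correlation is
#' flagged significant when its 95% HPD interval excludes zero.
#'
#' @param fit an `animal_model_fit` from [fit_bivariate()].
#' @param level credible level.
#' @return list with `summary` (data frame: block, mode, lower, upper,
#'   significant) and `samples` (matrix of per-block correlation draws).
#' @export
genetic_correlation <- function(fit, level = 0.95) {
  stopifnot(inherits(fit, "animal_model_fit"), fit$type == "bivariate")
  s <- fit$samples
  blocks <- c(fit$terms, "E")
  samples <- sapply(blocks, function(b) {
    cov <- s[, paste0("Cov", b, "_xy")]
    vx <- s[, paste0("V", b, "_x")]
    vy <- s[, paste0("V", b, "_y")]
    r <- cov / sqrt(vx * vy)
    pmin(pmax(r, -1), 1)
  })
  colnames(samples) <- paste0("r_", blocks)
  summ <- do.call(rbind, lapply(colnames(samples), function(cn) {
    h <- posterior_mode_hpd(samples[, cn], level)
    data.frame(block = cn, mode = h$mode, lower = h$lower, upper = h$upper,
               significant = h$lower > 0 | h$upper < 0)
  }))
  list(summary = summ, samples = samples)
}

#' Deviance information criterion of a fit
#'
#' `DIC = 2 mean(D) - D(theta_bar)` with the plug-in at posterior means.
#' Two likelihood foci are available:
#'
#' * `"marginal"` (default for univariate fits): location effects are
#'   integrated out, `D = -2 log N(y | X b, sum_t sigma2_t Z_t K_t Z_t' +
#'   sigma2_E I)`, so the criterion scores the variance structure itself.
#'   This is the focus used for random-effect selection: an animal model
#'   carries one additive effect per individual, and a conditional
#'   (lowest-level) deviance lets that term absorb any group-level
#'   variance, which makes conditional DIC prefer the additive-only model
#'   no matter what generated the data.
#' * `"conditional"`: `D = -2 log N(y | X b + Z u, sigma2_E I)` given the
#'   sampled location effects (the only focus available for bivariate
#'   fits, where no model search is performed).
#'
#' @param fit an `animal_model_fit`.
#' @param focus `"marginal"` or `"conditional"`.
#' @return scalar DIC.
#' @export
compute_dic <- function(fit, focus = c("marginal", "conditional")) {
  stopifnot(inherits(fit, "animal_model_fit"))
  focus <- match.arg(focus)
  if (fit$type != "univariate" && focus == "marginal") focus <- "conditional"
  if (focus == "conditional") {
    dbar <- fit$mean_deviance
    if (fit$type == "univariate") {
      e <- fit$y - fit$mean_fitted
      dhat <- fit$n_obs * log(2 * pi * fit$mean_sig2e) +
        sum(e^2) / fit$mean_sig2e
    } else {
      E <- fit$y - fit$mean_fitted
      R <- fit$mean_R
      dhat <- fit$n_obs * (2 * log(2 * pi) + determinant(R)$modulus[1]) +
        sum(diag(solve(R, crossprod(E))))
    }
    return(2 * dbar - dhat)
  }
  # marginal focus
  s <- fit$samples
  n <- fit$n_obs
  y <- fit$y
  bcols <- grep("^b_", colnames(s), value = TRUE)
  X <- fit$X
  vcols <- setdiff(colnames(s), c(bcols, "deviance", "VE"))
  kern <- fit$kernels
  marg_dev <- function(vs, ve, b) {
    r <- if (length(bcols)) y - as.numeric(X %*% b) else y
    if (fit$eigen_path) {
      v <- kern[["A"]] * vs[["VA"]] + ve
      n * log(2 * pi) + sum(log(v)) + sum(r^2 / v)
    } else {
      V <- diag(ve, n)
      for (t in seq_along(kern)) {
        V <- V + vs[[paste0("V", names(kern)[t])]] * kern[[t]]
      }
      U <- chol(V)
      n * log(2 * pi) + 2 * sum(log(diag(U))) +
        sum(backsolve(U, r, transpose = TRUE)^2)
    }
  }
  devs <- vapply(seq_len(nrow(s)), function(i) {
    vv <- stats::setNames(s[i, vcols], vcols)
    marg_dev(vv, s[i, "VE"], s[i, bcols])
  }, numeric(1))
  dbar <- mean(devs)
  vbar <- stats::setNames(colMeans(s[, vcols, drop = FALSE]), vcols)
  dhat <- marg_dev(vbar, mean(s[, "VE"]), colMeans(s[, bcols, drop = FALSE]))
  2 * dbar - dhat
}

#' Compare candidate random-effect structures by DIC
#'
#' @param dics named numeric vector (or named list) of DIC values, one per
#'   candidate model.
#' @param delta_max retention threshold on Delta-DIC (default 7).
#' @return object of class `model_comparison`: data frame with `model`,
#'   `DIC`, `delta` and `retained`, sorted by DIC.
#' @export
select_models <- function(dics, delta_max = 7) {
  dics <- unlist(dics)
  stopifnot(length(dics) >= 2, !is.null(names(dics)))
  out <- data.frame(model = names(dics), DIC = as.numeric(dics),
                    stringsAsFactors = FALSE)
  out <- out[order(out$DIC), ]
  out$delta <- out$DIC - min(out$DIC)
  out$retained <- out$delta < delta_max
  rownames(out) <- NULL
  class(out) <- c("model_comparison", "data.frame")
  out
}

#' Default candidate random-effect structures
#'
#' The four structures compared throughout: additive; additive + maternal;
#' additive + nest; additive + nest + maternal.
#'
#' @return named list of random-term vectors.
#' @export
candidate_models <- function() {
  list(
    additive = "additive",
    `additive+maternal` = c("additive", "maternal"),
    `additive+nest` = c("additive", "nest"),
    `additive+nest+maternal` = c("additive", "nest", "maternal"))
}
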