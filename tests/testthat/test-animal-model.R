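# Gibbs sampler correctness, posterior summaries, DIC machinery.

# minimal fit-shaped object for summary-function unit tests
fake_uni_fit <- function(samples) {
  structure(list(samples = samples, type = "univariate",
                 spec = list(traits = "y"), n_obs = 0),
            class = "animal_model_fit")
}

test_that("schedule presets encode the reference run lengths", {
  s <- model_schedule("paper")
  expect_equal((s$total - s$burnin) / s$thin, 9000)
  expect_equal(s$burnin, 1e5)
  expect_equal(s$thin, 100)
  sb <- model_schedule("paper", bivariate = TRUE)
  expect_equal((sb$total - sb$burnin) / sb$thin, 3600)
  expect_equal(sb$total, 4e6)
})

test_that("retained sample count follows the schedule and seeds reproduce", {
  set.seed(1)
  tt <- data.frame(id = sprintf("i%02d", 1:30), y = rnorm(30))
  ped <- pedigree(tt$id)
  spec <- animal_model_spec("y", random = "additive",
                           schedule = list(total = 900, burnin = 300,
                                           thin = 3), seed = 11)
  f1 <- fit_univariate(spec, tt, ped)
  expect_equal(nrow(f1$samples), 200)
  f2 <- fit_univariate(spec, tt, ped)
  expect_identical(f1$samples, f2$samples)
  spec2 <- spec
  spec2$seed <- 12
  f3 <- fit_univariate(spec2, tt, ped)
  expect_false(identical(f1$samples, f3$samples))
  # every variance draw positive
  expect_true(all(f1$samples[, c("VA", "VE")] > 0))
})

test_that("residual-variance posterior matches the conjugate closed form", {
  set.seed(4)
  y <- rnorm(60, 0, 2)
  tt <- data.frame(id = sprintf("i%02d", 1:60), y = y)
  ped <- pedigree(tt$id)
  # no location effects: sig2_E | y is exactly scaled-inv-chisq
  spec <- animal_model_spec("y", random = character(0), fixed = "none",
                            V = 1, nu = 2,
                            schedule = list(total = 22000, burnin = 2000,
                                            thin = 1), seed = 7)
  fit <- fit_univariate(spec, tt, ped)
  set.seed(8)
  ref <- (2 * 1 + sum(y^2)) / rchisq(2e5, 2 + 60)
  expect_lt(ks.test(fit$samples[, "VE"], ref)$statistic, 0.02)
})

test_that("prior-only sampling reproduces the inverse-gamma prior", {
  tt <- data.frame(id = sprintf("i%02d", 1:20), y = rnorm(20))
  ped <- pedigree(tt$id)
  spec <- animal_model_spec("y", random = "additive", V = 0.8, nu = 3,
                            schedule = list(total = 20000, burnin = 0,
                                            thin = 1), seed = 3)
  fp <- fit_univariate(spec, tt, ped, prior_only = TRUE)
  set.seed(9)
  ref <- 3 * 0.8 / rchisq(2e5, 3) # scaled-inv-chisq(nu, V)
  expect_lt(ks.test(fp$samples[, "VA"], ref)$statistic, 0.02)
  expect_lt(ks.test(fp$samples[, "VE"], ref)$statistic, 0.02)
})

test_that("posterior_mode_hpd: constants, normal reference, skew", {
  h <- posterior_mode_hpd(rep(0.3, 50))
  expect_equal(h$mode, 0.3)
  expect_equal(h$lower, 0.3)
  expect_equal(h$upper, 0.3)

  set.seed(10)
  x <- rnorm(1e5)
  h <- posterior_mode_hpd(x, 0.95)
  expect_lt(abs(h$mode), 0.05)
  expect_lt(abs(h$lower + 1.96), 0.05)
  expect_lt(abs(h$upper - 1.96), 0.05)

  xs <- exp(rnorm(5e4))
  h <- posterior_mode_hpd(xs)
  expect_lt(h$mode, median(xs))
})

test_that("variance_ratios arithmetic", {
  s <- cbind(VA = 1, VM = 1, VE = 2, deviance = 0)
  vr <- variance_ratios(fake_uni_fit(rbind(s, s, s, s, s, s, s, s, s, s)))
  expect_equal(unname(vr$samples[1, "h2"]), 0.25)
  expect_equal(unname(vr$samples[1, "me2"]), 0.25)
  expect_equal(unname(vr$samples[1, "ne2"]), 0)

  s0 <- cbind(VA = rep(0, 20), VE = rexp(20) + 0.1, deviance = 0)
  vr0 <- variance_ratios(fake_uni_fit(s0))
  expect_true(all(vr0$samples[, "h2"] == 0))
  # ratios always in [0, 1]
  expect_true(all(vr0$samples[, c("h2", "me2", "ne2")] >= 0 &
                    vr0$samples[, c("h2", "me2", "ne2")] <= 1))
})

test_that("genetic_correlation arithmetic and bounds", {
  mk <- function(vx, cov, vy) {
    structure(list(samples = cbind(VA_x = vx, CovA_xy = cov, VA_y = vy,
                                   VE_x = 1, CovE_xy = 0, VE_y = 1,
                                   deviance = 0),
                   type = "bivariate", terms = "A",
                   spec = list(traits = c("a", "b"))),
              class = "animal_model_fit")
  }
  g0 <- genetic_correlation(mk(rep(1, 20), rep(0, 20), rep(1, 20)))
  expect_true(all(g0$samples[, "r_A"] == 0))
  g5 <- genetic_correlation(mk(rep(1, 20), rep(0.5, 20), rep(1, 20)))
  expect_true(all(g5$samples[, "r_A"] == 0.5))
  set.seed(2)
  gr <- genetic_correlation(mk(rexp(50) + 0.01, rnorm(50, 0, 5),
                               rexp(50) + 0.01))
  expect_true(all(gr$samples >= -1 & gr$samples <= 1))
})

test_that("identical responses give genetic correlation near 1", {
  set.seed(6)
  ped <- fam_pedigree(0)
  ids <- dams <- sires <- character(0)
  for (f in 1:40) {
    ids <- c(ids, sprintf("d%d", f), sprintf("s%d", f),
             sprintf("o%d_%d", f, 1:3))
    dams <- c(dams, NA, NA, rep(sprintf("d%d", f), 3))
    sires <- c(sires, NA, NA, rep(sprintf("s%d", f), 3))
  }
  ped <- pedigree(ids, dams, sires)
  a <- simulate_breeding_values(ped, matrix(0.5), seed = 1)
  y <- as.numeric(a) + rnorm(nrow(ped), 0, sqrt(0.5))
  off <- grepl("^o", ped$id)
  tt <- data.frame(id = ped$id[off], t1 = y[off], t2 = y[off])
  spec <- animal_model_spec(c("t1", "t2"), random = "additive",
                            schedule = list(total = 3000, burnin = 1000,
                                            thin = 2), seed = 5)
  fit <- fit_bivariate(spec, tt, ped)
  expect_true(fit$eigen_path)
  gc <- genetic_correlation(fit)
  expect_gt(gc$summary$mode[gc$summary$block == "r_A"], 0.95)
})

test_that("DIC: single retained sample equals its own deviance; stacking
           data roughly doubles mean deviance", {
  set.seed(3)
  tt <- data.frame(id = sprintf("i%02d", 1:40), y = rnorm(40))
  ped <- pedigree(tt$id)
  spec <- animal_model_spec("y", random = "additive",
                            schedule = list(total = 101, burnin = 100,
                                            thin = 1), seed = 2)
  fit <- fit_univariate(spec, tt, ped)
  expect_equal(nrow(fit$samples), 1)
  expect_equal(compute_dic(fit, focus = "conditional"),
               unname(fit$samples[1, "deviance"]), tolerance = 1e-8)

  # duplicated data, intercept-only model: the conditional deviance is a
  # sum over records, so it roughly doubles
  spec2 <- animal_model_spec("y", random = character(0),
                             schedule = list(total = 2000, burnin = 1000,
                                             thin = 2), seed = 2)
  f1 <- fit_univariate(spec2, tt, ped)
  tt2 <- rbind(tt, tt)
  f2 <- fit_univariate(spec2, tt2, ped)
  ratio <- f2$mean_deviance / f1$mean_deviance
  expect_gt(ratio, 1.7)
  expect_lt(ratio, 2.3)
})

test_that("select_models applies the Delta-DIC < 7 rule", {
  cmp <- select_models(c(m1 = 100, m2 = 105.17))
  expect_equal(cmp$delta, c(0, 5.17))
  expect_true(all(cmp$retained))

  cmp2 <- select_models(c(a = 100, b = 112.4))
  expect_equal(cmp2$retained, c(TRUE, FALSE))

  cmp3 <- select_models(c(a = 50, b = 50))
  expect_equal(cmp3$delta, c(0, 0))
  expect_true(all(cmp3$retained))
  expect_error(select_models(c(a = 1)), "length")
})

test_that("input validation errors", {
  tt <- data.frame(id = sprintf("i%02d", 1:20), y = rep(1, 20))
  ped <- pedigree(tt$id)
  spec <- animal_model_spec("y", schedule = "smoke")
  expect_error(fit_univariate(spec, tt, ped), "zero-variance")

  tt$y <- rnorm(20)
  specm <- animal_model_spec("y", random = c("additive", "maternal"),
                             schedule = "smoke")
  expect_error(fit_univariate(specm, tt, ped), "dam is unknown")

  small <- tt[1:5, ]
  expect_error(fit_univariate(spec, small, ped), ">= 10")
})

test_that("maternal-effect recovery in a wing-length-like scenario", {
  # strong maternal effect (me2 = 0.8), weak additive (h2 = 0.05)
  cfg <- sim_config(traits = "y", trait_means = 0,
                    G = matrix(0.05), M = matrix(0.8), N = matrix(0),
                    R = matrix(0.15))
  col <- simulate_colony_pedigree(cfg, seed = 21)
  ph <- simulate_phenotypes(col$ped, col$structure, cfg, seed = 21)
  nest <- ph[ph$age_class == "nestling", ]
  spec <- animal_model_spec("y", random = c("additive", "maternal"),
                            schedule = list(total = 6000, burnin = 2000,
                                            thin = 4), seed = 22)
  fit <- fit_univariate(spec, nest, col$ped)
  vr <- variance_ratios(fit)
  me2 <- vr$summary[vr$summary$ratio == "me2", ]
  expect_gt(me2$mode, 0.6)
  expect_lt(me2$mode, 0.95)
  # and the qualitative pattern: maternal effect dominates heritability
  h2 <- vr$summary[vr$summary$ratio == "h2", ]
  expect_gt(me2$mode, h2$mode)
})
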