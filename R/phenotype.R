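# Descriptive and inferential phenotype statistics: fledging filter, trait
# correlations, sexual dimorphism, assortative mating.

#' Default trait columns
#' @return character vector of the six morphological trait names.
#' @export
default_traits <- function() {
  c("weight", "wing", "tarsus", "tail", "bill_length", "bill_width")
}

#' Filter to fledging-weight individuals
#'
#' Keeps rows with `weight > cutoff`. The default cutoff of 82 g is the
#' minimum adult weight observed in the target population, just below the
#' species' estimated fledging mass; nestlings below it are still growing
#' and would inflate residual variance.
#'
#' @param traits trait table with a `weight` column.
#' @param cutoff weight cutoff in grams.
#' @return filtered trait table (warns when empty). Idempotent.
#' @export
filter_fledged <- function(traits, cutoff = 82) {
  stopifnot("weight" %in% names(traits))
  out <- traits[!is.na(traits$weight) & traits$weight > cutoff, ,
                drop = FALSE]
  if (!nrow(out)) warning("no individuals above the ", cutoff, " g cutoff")
  out
}

#' Pairwise Pearson correlations between traits
#'
#' Pairwise-complete Pearson correlations with two-sided p-values from the
#' t transform on n - 2 degrees of freedom. Pairs with fewer than 3
#' complete observations or a zero-variance column are reported as `NA`.
#'
#' @param traits trait table.
#' @param columns trait columns to correlate (default [default_traits()]
#'   intersected with available columns).
#' @return list of class `trait_correlations` with matrices `r`, `p`, `n`.
#' @export
trait_correlations <- function(traits, columns = NULL) {
  columns <- columns %||% intersect(default_traits(), names(traits))
  stopifnot(length(columns) >= 2)
  k <- length(columns)
  r <- p <- n <- matrix(NA_real_, k, k, dimnames = list(columns, columns))
  diag(r) <- 1
  diag(p) <- 0
  for (i in seq_len(k - 1)) {
    for (j in (i + 1):k) {
      x <- traits[[columns[i]]]
      y <- traits[[columns[j]]]
      ok <- !is.na(x) & !is.na(y)
      n[i, j] <- n[j, i] <- sum(ok)
      if (sum(ok) < 3 || stats::sd(x[ok]) == 0 || stats::sd(y[ok]) == 0)
        next
      ct <- stats::cor.test(x[ok], y[ok], method = "pearson")
      r[i, j] <- r[j, i] <- unname(ct$estimate)
      p[i, j] <- p[j, i] <- ct$p.value
    }
  }
  diag(n) <- colSums(!is.na(traits[columns]))
  structure(list(r = r, p = p, n = n), class = "trait_correlations")
}

significance_stars <- function(p) {
  ifelse(is.na(p), "", ifelse(p < 0.001, "***",
    ifelse(p < 0.01, "**", ifelse(p < 0.05, "*", "ns"))))
}

#' @export
print.trait_correlations <- function(x, digits = 2, ...) {
  cat("Pearson trait correlations (lower triangle; stars: * < .05, ** < .01, *** < .001)\n")
  k <- nrow(x$r)
  out <- matrix("", k, k, dimnames = dimnames(x$r))
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (j < i) out[i, j] <- paste0(format(round(x$r[i, j], digits)),
                                   " ", significance_stars(x$p[i, j]))
  }
  print(out, quote = FALSE)
  invisible(x)
}

#' Wilks' lambda MANOVA with Rao's F approximation
#'
#' `Lambda = det(W) / det(T)` with W the within-group and T the total
#' SSCP matrix (listwise-complete rows). Rao's F: with p variables, g
#' groups, q = g - 1, `t = sqrt((p^2 q^2 - 4)/(p^2 + q^2 - 5))` (1 when the
#' denominator vanishes), `df1 = p q`,
#' `df2 = t (N - 1 - (p + g)/2) - (p q - 2)/2`, and
#' `F = ((1 - Lambda^(1/t)) / Lambda^(1/t)) (df2/df1)`. Exact for two
#' groups.
#'
#' @param Y numeric matrix of responses (rows = individuals).
#' @param group factor of group membership.
#' @return list with `lambda`, `F`, `df1`, `df2`, `p_value`.
#' @export
wilks_manova <- function(Y, group) {
  Y <- as.matrix(Y)
  group <- droplevels(as.factor(group))
  ok <- stats::complete.cases(Y) & !is.na(group)
  Y <- Y[ok, , drop = FALSE]
  group <- group[ok]
  g <- nlevels(group)
  if (g < 2) stop("need at least two groups")
  N <- nrow(Y)
  p <- ncol(Y)
  if (min(table(group)) < 2) stop("each group needs >= 2 complete records")
  Tm <- crossprod(scale(Y, scale = FALSE))
  W <- matrix(0, p, p)
  for (lev in levels(group)) {
    Yi <- Y[group == lev, , drop = FALSE]
    W <- W + crossprod(scale(Yi, scale = FALSE))
  }
  lambda <- det(W) / det(Tm)
  q <- g - 1
  tt <- if (p^2 + q^2 - 5 > 0) sqrt((p^2 * q^2 - 4) / (p^2 + q^2 - 5)) else 1
  df1 <- p * q
  df2 <- tt * (N - 1 - (p + g) / 2) - (p * q - 2) / 2
  lam_t <- lambda^(1 / tt)
  Fstat <- (1 - lam_t) / lam_t * df2 / df1
  list(lambda = lambda, F = Fstat, df1 = df1, df2 = df2,
       p_value = stats::pf(Fstat, df1, df2, lower.tail = FALSE))
}

#' Sexual dimorphism tests on adults
#'
#' One-way ANOVA per trait and a MANOVA (Wilks' lambda, Rao's F) across
#' all traits, comparing the sexes. ANOVA uses pairwise-available rows per
#' trait; the MANOVA uses listwise-complete multivariate records.
#'
#' @param traits trait table with a `sex` column (`"F"`/`"M"`).
#' @param columns trait columns (default [default_traits()] available).
#' @return list with `anova` (data frame: trait, F, df1, df2, p) and
#'   `manova` (from [wilks_manova()]).
#' @export
sex_dimorphism_tests <- function(traits, columns = NULL) {
  columns <- columns %||% intersect(default_traits(), names(traits))
  sex <- droplevels(as.factor(traits$sex))
  if (nlevels(sex) < 2) stop("both sexes must be present")
  an <- do.call(rbind, lapply(columns, function(tr) {
    y <- traits[[tr]]
    ok <- !is.na(y) & !is.na(sex)
    fit <- stats::anova(stats::lm(y[ok] ~ sex[ok]))
    data.frame(trait = tr, F = fit$`F value`[1],
               df1 = fit$Df[1], df2 = fit$Df[2],
               p = fit$`Pr(>F)`[1], stringsAsFactors = FALSE)
  }))
  mv <- wilks_manova(as.matrix(traits[columns]), sex)
  list(anova = an, manova = mv)
}

#' Build the mate-pair table from a pedigree
#'
#' Social pairing is taken from pedigree-assigned parentage: every
#' (dam, sire) combination that shares at least one offspring forms a
#' pair, with both members' trait values attached.
#'
#' @param ped a [pedigree()].
#' @param traits trait table.
#' @return data frame of class `pair_table`: dam, sire, n_offspring, and
#'   `<trait>_dam` / `<trait>_sire` columns.
#' @export
build_pair_table <- function(ped, traits) {
  both <- !is.na(ped$dam) & !is.na(ped$sire)
  if (!any(both)) {
    return(structure(data.frame(dam = character(0), sire = character(0),
                                n_offspring = integer(0)),
                     class = c("pair_table", "data.frame")))
  }
  key <- paste(ped$dam[both], ped$sire[both], sep = "\r")
  tab <- table(key)
  parts <- strsplit(names(tab), "\r", fixed = TRUE)
  out <- data.frame(dam = vapply(parts, `[`, "", 1),
                    sire = vapply(parts, `[`, "", 2),
                    n_offspring = as.integer(tab),
                    stringsAsFactors = FALSE)
  cols <- intersect(default_traits(), names(traits))
  for (tr in cols) {
    out[[paste0(tr, "_dam")]] <- traits[[tr]][match(out$dam, traits$id)]
    out[[paste0(tr, "_sire")]] <- traits[[tr]][match(out$sire, traits$id)]
  }
  class(out) <- c("pair_table", "data.frame")
  out
}

#' Assortative-mating correlation for one trait
#'
#' Pearson correlation between the dam and sire values of mated pairs,
#' with a two-sided p-value. Small pair counts (common in colony trapping
#' data) are flagged as low power.
#'
#' @param pairs a [build_pair_table()] result.
#' @param trait trait name.
#' @return list with `r`, `p`, `n`, `low_power` (n < 10).
#' @export
assortative_mating <- function(pairs, trait) {
  xd <- pairs[[paste0(trait, "_dam")]]
  xs <- pairs[[paste0(trait, "_sire")]]
  ok <- !is.na(xd) & !is.na(xs)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  ct <- stats::cor.test(xd[ok], xs[ok], method = "pearson")
  list(r = unname(ct$estimate), p = ct$p.value, n = sum(ok),
       low_power = sum(ok) < 10)
}

#' Read a phenotype CSV
#'
#' Header `id,age_class,nest,chamber,sex,weight,wing,tarsus,tail,
#' bill_length,bill_width` (missing columns tolerated; extra kept).
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_phenotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(df))
  df$id <- as.character(df$id)
  df
}
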