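# End-to-end pipeline: locus QC -> (optional) pedigree reconstruction ->
# relationship matrix -> fledge filter -> univariate fits and DIC tables ->
# bivariate genetic correlations -> phenotype reports, plus a run manifest
# and a plain-text report renderer.

#' Pipeline run configuration
#'
#' Exactly one pedigree source must be active: a pedigree file (or
#' in-memory pedigree), pedigree reconstruction from genotypes, or the
#' simulator (which provides the true pedigree unless
#' `reconstruct_pedigree = TRUE`).
#'
#' @param sim a [sim_config()] to simulate inputs, or `NULL` to read files.
#' @param pedigree_file,genotype_file,phenotype_file input paths (ignored
#'   when `sim` is given). `genotype_file` may be wide CSV or GenePop
#'   (detected by extension `.gen`/`.genepop`).
#' @param reconstruct_pedigree reconstruct parentage from genotypes
#'   instead of using the supplied pedigree.
#' @param preset MCMC schedule preset for the fits ([model_schedule()]).
#' @param traits trait columns to model (default [default_traits()]).
#' @param fledge_cutoff weight cutoff in g applied before modelling.
#' @param bivariate fit all pairwise bivariate (additive-only) models?
#' @param out_dir output directory (created if needed).
#' @param seed master seed; all stage seeds derive from it.
#' @return list of class `run_config`.
#' @export
run_config <- function(sim = NULL, pedigree_file = NULL,
                       genotype_file = NULL, phenotype_file = NULL,
                       reconstruct_pedigree = FALSE,
                       preset = "fast", traits = NULL,
                       fledge_cutoff = 82, bivariate = TRUE,
                       out_dir = tempfile("nestqg_run_"), seed = 1L) {
  if (!is.null(pedigree_file) && reconstruct_pedigree) {
    stop("supply either a pedigree file or reconstruct_pedigree = TRUE, ",
         "not both")
  }
  if (is.null(sim) && is.null(pedigree_file) && !reconstruct_pedigree) {
    stop("no pedigree source: give a pedigree file, enable reconstruction, ",
         "or configure the simulator")
  }
  structure(list(sim = sim, pedigree_file = pedigree_file,
                 genotype_file = genotype_file,
                 phenotype_file = phenotype_file,
                 reconstruct_pedigree = reconstruct_pedigree,
                 preset = preset, traits = traits,
                 fledge_cutoff = fledge_cutoff, bivariate = bivariate,
                 out_dir = out_dir, seed = as.integer(seed)),
            class = "run_config")
}

# Reconstruct a pedigree by likelihood parentage assignment: dams among
# adult females, then sires given the assigned dam.
reconstruct_pedigree_from_genotypes <- function(gt, structure_df, summaries,
                                                threshold = 0.99) {
  adults <- structure_df$id[structure_df$age_class == "adult"]
  sex <- structure_df$sex[match(adults, structure_df$id)]
  dams_cand <- adults[!is.na(sex) & sex == "F"]
  sires_cand <- adults[!is.na(sex) & sex == "M"]
  nestlings <- structure_df$id[structure_df$age_class == "nestling"]
  dam <- sire <- stats::setNames(rep(NA_character_, length(nestlings)),
                                 nestlings)
  for (o in nestlings) {
    rd <- assign_parentage(gt, o, dams_cand, summaries,
                           threshold = threshold)
    dam[o] <- rd$assigned
    rs <- assign_parentage(gt, o, sires_cand, summaries,
                           known_parent = if (!is.na(dam[o])) dam[o] else NULL,
                           threshold = threshold)
    sire[o] <- rs$assigned
  }
  pedigree(id = c(adults, nestlings),
           dam = c(rep(NA, length(adults)), unname(dam)),
           sire = c(rep(NA, length(adults)), unname(sire)),
           sex = c(sex, rep(NA, length(nestlings))))
}

#' Run the full analysis pipeline
#'
#' Stages: locus QC; optional parentage-based pedigree reconstruction;
#' relationship matrix; fledge-weight filter; univariate animal models for
#' every trait under the four candidate random-effect structures with DIC
#' selection; variance-ratio summaries for retained models; bivariate
#' (additive-only) fits for all trait pairs; phenotypic correlation,
#' sexual-dimorphism and assortative-mating reports. All tables are
#' written as CSV into `cfg$out_dir` together with a JSON manifest; any
#' stage failure aborts with the stage name.
#'
#' @param cfg a [run_config()].
#' @return (invisibly) the result bundle: a list with elements
#'   `locus_table`, `pedigree`, `ped_summary`, `dic_table`, `ratios`,
#'   `bivariate`, `correlations`, `dimorphism`, `assortative`, `manifest`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(cfg$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- "input"
  bundle <- list()
  tryCatch({
    if (!is.null(cfg$sim)) {
      sim <- simulate_colony(cfg$sim, seed = cfg$seed)
      gt <- sim$genotypes
      phen <- sim$phenotypes
      structure_df <- sim$structure
      ped_given <- sim$ped
      bundle$truth <- attr(phen, "truth")
    } else {
      gt <- if (!is.null(cfg$genotype_file)) {
        if (grepl("\\.(gen|genepop)$", cfg$genotype_file))
          read_genepop(cfg$genotype_file)
        else read_genotypes_csv(cfg$genotype_file)
      } else NULL
      phen <- read_phenotypes(cfg$phenotype_file)
      structure_df <- phen
      ped_given <- if (!is.null(cfg$pedigree_file))
        read_pedigree(cfg$pedigree_file) else NULL
    }

    stage <- "locus-qc"
    if (!is.null(gt)) {
      summaries <- locus_summaries(gt)
      bundle$locus_table <- locus_summary_table(summaries)
      bundle$combined_exclusion <- c(
        Q1 = combined_exclusion(bundle$locus_table$Q1),
        Q2 = combined_exclusion(bundle$locus_table$Q2))
      utils::write.csv(bundle$locus_table,
                       file.path(cfg$out_dir, "locus_summaries.csv"),
                       row.names = FALSE)
    }

    stage <- "pedigree"
    ped <- if (cfg$reconstruct_pedigree) {
      reconstruct_pedigree_from_genotypes(gt, structure_df, summaries)
    } else ped_given
    bundle$pedigree <- ped
    bundle$ped_summary <- pedigree_summary(ped)
    write_pedigree(ped, file.path(cfg$out_dir, "pedigree.csv"))

    stage <- "relationship-matrix"
    A <- additive_relationship_matrix(ped)
    write_relationship_matrix(A, file.path(cfg$out_dir, "A_matrix.csv"),
                              format = "triplet")

    stage <- "fledge-filter"
    phen_f <- filter_fledged(phen, cfg$fledge_cutoff)

    stage <- "univariate-models"
    traits <- cfg$traits %||% intersect(default_traits(), names(phen_f))
    cand <- candidate_models()
    dic_rows <- list()
    ratio_rows <- list()
    for (tr in traits) {
      dics <- numeric(0)
      fits <- list()
      for (m in names(cand)) {
        spec <- animal_model_spec(tr, random = cand[[m]],
                                  schedule = cfg$preset,
                                  seed = derive_seed(cfg$seed,
                                                     paste(tr, m)))
        fits[[m]] <- fit_univariate(spec, phen_f, ped)
        dics[m] <- compute_dic(fits[[m]])
      }
      cmp <- select_models(dics)
      cmp$trait <- tr
      dic_rows[[tr]] <- cmp
      for (m in cmp$model[cmp$retained]) {
        vr <- variance_ratios(fits[[m]])
        s <- vr$summary
        s$trait <- tr
        s$model <- m
        ratio_rows[[paste(tr, m)]] <- s
      }
    }
    bundle$dic_table <- do.call(rbind, dic_rows)
    bundle$ratios <- do.call(rbind, ratio_rows)
    rownames(bundle$dic_table) <- rownames(bundle$ratios) <- NULL
    utils::write.csv(bundle$dic_table,
                     file.path(cfg$out_dir, "dic_table.csv"),
                     row.names = FALSE)
    utils::write.csv(bundle$ratios,
                     file.path(cfg$out_dir, "variance_ratios.csv"),
                     row.names = FALSE)

    stage <- "bivariate-models"
    if (isTRUE(cfg$bivariate) && length(traits) >= 2) {
      pairs <- utils::combn(traits, 2)
      bi_rows <- list()
      for (k in seq_len(ncol(pairs))) {
        pr <- pairs[, k]
        spec <- animal_model_spec(pr, random = "additive",
                                  schedule = cfg$preset,
                                  seed = derive_seed(cfg$seed,
                                                     paste(pr, collapse = "-")))
        fit <- fit_bivariate(spec, phen_f, ped)
        gc <- genetic_correlation(fit)
        s <- gc$summary
        s$trait_x <- pr[1]
        s$trait_y <- pr[2]
        bi_rows[[k]] <- s
      }
      bundle$bivariate <- do.call(rbind, bi_rows)
      rownames(bundle$bivariate) <- NULL
      utils::write.csv(bundle$bivariate,
                       file.path(cfg$out_dir, "genetic_correlations.csv"),
                       row.names = FALSE)
    }

    stage <- "phenotype-reports"
    nest_tr <- phen_f[phen_f$age_class == "nestling", , drop = FALSE]
    bundle$correlations <- trait_correlations(
      if (nrow(nest_tr) >= 3) nest_tr else phen_f, traits)
    adults <- phen[phen$age_class == "adult", , drop = FALSE]
    bundle$dimorphism <- tryCatch(
      sex_dimorphism_tests(adults, traits),
      error = function(e) NULL)
    prs <- build_pair_table(ped, phen)
    bundle$assortative <- if (nrow(prs) >= 3) {
      do.call(rbind, lapply(traits, function(tr) {
        am <- tryCatch(assortative_mating(prs, tr), error = function(e) NULL)
        if (is.null(am)) return(NULL)
        data.frame(trait = tr, r = am$r, p = am$p, n = am$n,
                   low_power = am$low_power)
      }))
    } else NULL

    stage <- "manifest"
    manifest <- list(
      package = "nestQG",
      version = as.character(utils::packageVersion("nestQG")),
      seed = cfg$seed, preset = cfg$preset,
      fledge_cutoff = cfg$fledge_cutoff,
      traits = traits,
      simulated = !is.null(cfg$sim),
      reconstructed_pedigree = cfg$reconstruct_pedigree,
      n_individuals = nrow(ped),
      n_phenotyped = nrow(phen_f),
      timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))
    jsonlite::write_json(manifest, file.path(cfg$out_dir, "manifest.json"),
                         auto_unbox = TRUE, pretty = TRUE)
    bundle$manifest <- manifest
    invisible(bundle)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
}

#' Render a plain-text report from a pipeline bundle
#'
#' Per-trait variance-ratio summary with HPD bars, the DIC table with
#' retained models (Delta DIC < 7) marked in bold, and the phenotypic
#' correlation matrix with significance stars. Incomplete bundles produce
#' a partial report with a warning line.
#'
#' @param bundle result of [run_pipeline()].
#' @param path optional file to write the report to.
#' @return character vector of report lines, invisibly when `path` given.
#' @export
render_report <- function(bundle, path = NULL) {
  lines <- c("nestQG analysis report",
             strrep("=", 40), "")
  if (!is.null(bundle$ped_summary)) {
    ps <- bundle$ped_summary
    lines <- c(lines, sprintf(
      "Pedigree: %d individuals, %d founders, %d maternities, %d paternities",
      ps$n_individuals, ps$n_founders, ps$n_maternities, ps$n_paternities),
      "")
  }
  if (!is.null(bundle$combined_exclusion)) {
    lines <- c(lines, sprintf(
      "Combined exclusion probability: one parent known %.3f, parent pair %.3f",
      bundle$combined_exclusion["Q1"], bundle$combined_exclusion["Q2"]), "")
  }
  if (!is.null(bundle$ratios)) {
    lines <- c(lines, "Variance ratios (posterior mode [95% HPD])",
               strrep("-", 40))
    for (i in seq_len(nrow(bundle$ratios))) {
      r <- bundle$ratios[i, ]
      bar_lo <- max(0, min(1, r$lower)); bar_hi <- max(0, min(1, r$upper))
      bar <- paste0(strrep(" ", round(20 * bar_lo)),
                    strrep("#", max(1, round(20 * (bar_hi - bar_lo)))))
      lines <- c(lines, sprintf("%-12s %-22s %-4s %.3f [%.3f, %.3f] |%-21s|",
                                r$trait, r$model, r$ratio, r$mode,
                                r$lower, r$upper, bar))
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$dic_table)) {
    lines <- c(lines, "Model selection (DIC; bold = retained, Delta < 7)",
               strrep("-", 40))
    for (i in seq_len(nrow(bundle$dic_table))) {
      d <- bundle$dic_table[i, ]
      lab <- sprintf("%-12s %-24s %10.2f %8.2f", d$trait, d$model,
                     d$DIC, d$delta)
      if (d$retained) lab <- paste0("**", lab, "**")
      lines <- c(lines, lab)
    }
    lines <- c(lines, "")
  }
  if (!is.null(bundle$bivariate)) {
    gen <- bundle$bivariate[bundle$bivariate$block == "r_A", , drop = FALSE]
    if (nrow(gen)) {
      lines <- c(lines, "Genetic correlations (additive block)",
                 strrep("-", 40))
      for (i in seq_len(nrow(gen))) {
        g <- gen[i, ]
        lines <- c(lines, sprintf("%s / %s: %.3f [%.3f, %.3f]%s",
                                  g$trait_x, g$trait_y, g$mode, g$lower,
                                  g$upper,
                                  if (g$significant) " *" else ""))
      }
      lines <- c(lines, "")
    }
  } else {
    lines <- c(lines, "no pairs fitted", "")
  }
  if (!is.null(bundle$correlations)) {
    lines <- c(lines, "Phenotypic correlations",
               utils::capture.output(print(bundle$correlations)), "")
  }
  needed <- c("ped_summary", "dic_table", "ratios")
  if (!all(needed %in% names(bundle))) {
    lines <- c(lines, "WARNING: incomplete bundle; partial report")
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
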