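# Pedigree representation, validation, and the additive relationship matrix.

#' Construct a pedigree
#'
#' A pedigree is a data frame with columns `id`, `dam`, `sire`, `sex`
#' describing a directed acyclic parent map. Unknown parents are stored as
#' `NA`; founders are exactly the individuals with both parents unknown.
#' Parents that are referenced but not listed as records are auto-added as
#' founders of unknown sex (with a message), because field studies rarely
#' capture every breeding adult.
#'
#' @param id character vector of individual identifiers (unique).
#' @param dam,sire character vectors of parent identifiers; `NA`, `""`,
#'   `"0"` or `"NA"` (any case) denote an unknown parent.
#' @param sex optional character vector; `"F"`, `"M"` or `NA` (unknown).
#'   Accepts lower case and `"female"`/`"male"`.
#' @return An object of class `pedigree`: a `data.frame` with columns
#'   `id`, `dam`, `sire`, `sex` in a validated, topologically consistent
#'   state (founders need not come first; see [topological_order()]).
#' @examples
#' ped <- pedigree(id = c("m", "f", "o"), dam = c(NA, NA, "f"),
#'                 sire = c(NA, NA, "m"), sex = c("M", "F", NA))
#' n_founders(ped)
#' @export
pedigree <- function(id, dam = NA, sire = NA, sex = NA) {
  id <- as.character(id)
  n <- length(id)
  dam <- normalize_parent(rep_len(as.character(dam), n))
  sire <- normalize_parent(rep_len(as.character(sire), n))
  sex <- normalize_sex(rep_len(as.character(sex), n))
  if (anyDuplicated(id)) {
    stop("duplicate individual id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  }
  # auto-add referenced-but-unlisted parents as founders
  refd <- unique(c(dam[!is.na(dam)], sire[!is.na(sire)]))
  missing_parents <- setdiff(refd, id)
  if (length(missing_parents)) {
    message("auto-adding ", length(missing_parents),
            " referenced parent(s) as founder(s): ",
            paste(missing_parents, collapse = ", "))
    id <- c(id, missing_parents)
    dam <- c(dam, rep(NA_character_, length(missing_parents)))
    sire <- c(sire, rep(NA_character_, length(missing_parents)))
    sex <- c(sex, rep(NA_character_, length(missing_parents)))
  }
  ped <- structure(
    data.frame(id = id, dam = dam, sire = sire, sex = sex,
               stringsAsFactors = FALSE),
    class = c("pedigree", "data.frame"))
  validate_pedigree(ped)
  ped
}

normalize_parent <- function(x) {
  x <- trimws(as.character(x))
  x[x == "" | x == "0" | toupper(x) == "NA"] <- NA_character_
  x
}

normalize_sex <- function(x) {
  x <- toupper(trimws(as.character(x)))
  x[x %in% c("", "0", "NA", "U", "UNKNOWN")] <- NA_character_
  x[x %in% c("FEMALE")] <- "F"
  x[x %in% c("MALE")] <- "M"
  bad <- !is.na(x) & !x %in% c("F", "M")
  if (any(bad)) stop("unrecognized sex code(s): ",
                     paste(unique(x[bad]), collapse = ", "))
  x
}

#' Validate a pedigree
#'
#' Checks structural invariants: unique ids, all parents present as records,
#' acyclicity of the parent graph, and dam/sire sex consistency (a dam must
#' not be recorded as male, a sire not as female). Called by [pedigree()]
#' and [read_pedigree()]; exported for use after manual edits.
#'
#' @param ped a `pedigree`.
#' @return `ped`, invisibly; stops with an informative error otherwise.
#' @export
validate_pedigree <- function(ped) {
  stopifnot(is.data.frame(ped),
            all(c("id", "dam", "sire", "sex") %in% names(ped)))
  if (anyDuplicated(ped$id)) {
    stop("duplicate individual id(s): ",
         paste(unique(ped$id[duplicated(ped$id)]), collapse = ", "))
  }
  refd <- c(ped$dam[!is.na(ped$dam)], ped$sire[!is.na(ped$sire)])
  absent <- setdiff(refd, ped$id)
  if (length(absent)) {
    stop("parent(s) referenced but not listed: ",
         paste(absent, collapse = ", "))
  }
  sex_of <- stats::setNames(ped$sex, ped$id)
  bad_dam <- !is.na(ped$dam) & !is.na(sex_of[ped$dam]) & sex_of[ped$dam] == "M"
  if (any(bad_dam)) {
    stop("dam recorded as male: ", paste(unique(ped$dam[bad_dam]), collapse = ", "))
  }
  bad_sire <- !is.na(ped$sire) & !is.na(sex_of[ped$sire]) & sex_of[ped$sire] == "F"
  if (any(bad_sire)) {
    stop("sire recorded as female: ", paste(unique(ped$sire[bad_sire]), collapse = ", "))
  }
  topological_order(ped, .validated = TRUE) # errors on a cycle
  invisible(ped)
}

#' Read a pedigree from CSV
#'
#' Expects a header with columns `id`, `dam`, `sire` and optionally `sex`
#' (case-insensitive). Unknown parents may be encoded as an empty field,
#' `0`, or `NA`.
#'
#' @param path path to a CSV file.
#' @return a [pedigree()].
#' @export
read_pedigree <- function(path) {
  stopifnot(file.exists(path))
  df <- utils::read.csv(path, colClasses = "character",
                        strip.white = TRUE, check.names = FALSE)
  names(df) <- tolower(names(df))
  need <- c("id", "dam", "sire")
  if (!all(need %in% names(df))) {
    stop("pedigree file must have columns id, dam, sire (got: ",
         paste(names(df), collapse = ", "), ")")
  }
  if (!"sex" %in% names(df)) df$sex <- NA_character_
  pedigree(df$id, df$dam, df$sire, df$sex)
}

#' Write a pedigree to CSV
#'
#' Unknown parents and sexes are written as `0`, matching common
#' pedigree-file dialects.
#'
#' @param ped a `pedigree`.
#' @param path output path.
#' @export
write_pedigree <- function(ped, path) {
  out <- as.data.frame(ped)
  out$dam[is.na(out$dam)] <- "0"
  out$sire[is.na(out$sire)] <- "0"
  out$sex[is.na(out$sex)] <- "0"
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @export
print.pedigree <- function(x, ...) {
  cat("Pedigree:", nrow(x), "individuals,", n_founders(x), "founders\n")
  NextMethod()
}

#' Number of founders (both parents unknown)
#' @param ped a `pedigree`.
#' @return integer count.
#' @export
n_founders <- function(ped) sum(is.na(ped$dam) & is.na(ped$sire))

#' Topological order of a pedigree
#'
#' Returns ids ordered so that every parent precedes all of its offspring.
#' Founders come first. Deterministic: ties are broken by input order
#' (Kahn's algorithm with a position-ordered frontier).
#'
#' @param ped a `pedigree`.
#' @param .validated internal; skip re-validation.
#' @return character vector of ids, a permutation of `ped$id`.
#' @export
topological_order <- function(ped, .validated = FALSE) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  dam_i <- unname(idx[ped$dam])
  sire_i <- unname(idx[ped$sire])
  # generation depth by vectorized relaxation sweeps: founders 0, child =
  # max(parent depths) + 1. Converges in max_depth + 1 sweeps; failure to
  # converge within n sweeps means a cycle.
  depth <- rep(0L, n)
  converged <- FALSE
  for (sweep in seq_len(n + 1L)) {
    d1 <- depth[dam_i]
    d1[is.na(d1)] <- -1L
    d2 <- depth[sire_i]
    d2[is.na(d2)] <- -1L
    new_depth <- pmax(d1, d2) + 1L
    if (identical(new_depth, depth)) {
      converged <- TRUE
      break
    }
    depth <- new_depth
  }
  if (!converged) {
    # walk parent links among still-growing nodes until one repeats
    d1 <- depth[dam_i]; d1[is.na(d1)] <- -1L
    d2 <- depth[sire_i]; d2[is.na(d2)] <- -1L
    growing <- which(pmax(d1, d2) + 1L != depth | depth > n)
    cur <- growing[1L]
    seen <- logical(n)
    while (!seen[cur]) {
      seen[cur] <- TRUE
      nxt <- c(dam_i[cur], sire_i[cur])
      nxt <- nxt[!is.na(nxt) & nxt %in% growing]
      if (!length(nxt)) break
      cur <- nxt[1L]
    }
    stop("pedigree contains a cycle involving: ", ped$id[cur])
  }
  ped$id[order(depth, seq_len(n))]
}

#' Additive (numerator) relationship matrix
#'
#' Computes A by the tabular method in topological order:
#' `A[i,j] = 0.5 * (A[j, dam_i] + A[j, sire_i])` for j preceding i, an
#' unknown parent contributing 0, and `A[i,i] = 1 + 0.5 * A[dam_i, sire_i]`
#' (the diagonal is `1 + F`, with F the inbreeding coefficient). Founders
#' are assumed unrelated and non-inbred.
#'
#' @param ped a `pedigree`.
#' @return a symmetric numeric matrix with ids as dimnames, in the order of
#'   `ped$id`.
#' @examples
#' ped <- pedigree(c("d", "s", "o1", "o2"), dam = c(NA, NA, "d", "d"),
#'                 sire = c(NA, NA, "s", "s"))
#' additive_relationship_matrix(ped)["o1", "o2"] # full sibs: 0.5
#' @export
additive_relationship_matrix <- function(ped) {
  ord <- topological_order(ped)
  n <- nrow(ped)
  pos <- stats::setNames(seq_len(n), ord)
  dam_p <- pos[ped$dam[match(ord, ped$id)]]
  sire_p <- pos[ped$sire[match(ord, ped$id)]]
  A <- tabular_relationship(n, ifelse(is.na(dam_p), 0L, as.integer(dam_p)),
                            ifelse(is.na(sire_p), 0L, as.integer(sire_p)))
  dimnames(A) <- list(ord, ord)
  A[ped$id, ped$id, drop = FALSE]
}

#' Inbreeding coefficients
#'
#' `F(i) = 0.5 * A(dam_i, sire_i)`, i.e. the kinship of the parents;
#' founders and individuals with any unknown parent have `F = 0`. Computed
#' by recursive kinship with memoization, so only the ancestor pairs that
#' are actually needed are visited (the full dense A is never built --
#' founder-heavy pedigrees with 10^5 individuals are instant).
#'
#' @param ped a `pedigree`.
#' @return named numeric vector of inbreeding coefficients.
#' @export
inbreeding_coefficients <- function(ped) {
  n <- nrow(ped)
  idx <- stats::setNames(seq_len(n), ped$id)
  dam <- unname(idx[ped$dam])
  sire <- unname(idx[ped$sire])
  ord <- match(topological_order(ped), ped$id)
  pos <- integer(n)
  pos[ord] <- seq_len(n)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  kin <- function(i, j) {
    if (is.na(i) || is.na(j)) return(0)
    key <- if (i <= j) paste0(i, ".", j) else paste0(j, ".", i)
    v <- memo[[key]]
    if (!is.null(v)) return(v)
    val <- if (i == j) {
      0.5 * (1 + kin(dam[i], sire[i]))
    } else {
      # recurse through the parents of the later-born member
      if (pos[i] > pos[j]) { tmp <- i; i <- j; j <- tmp }
      0.5 * (kin(i, dam[j]) + kin(i, sire[j]))
    }
    memo[[key]] <- val
    val
  }
  stats::setNames(vapply(seq_len(n), function(k) kin(dam[k], sire[k]),
                         numeric(1)), ped$id)
}

#' Pedigree summary statistics
#'
#' Counts of individuals, founders, maternity/paternity links, full- and
#' half-sib pairs, and maximum generation depth. A full-sib pair shares a
#' known dam and a known sire; a half-sib pair shares exactly one known
#' parent (classified maternal or paternal by which parent is shared).
#'
#' @param ped a `pedigree`.
#' @return a list of class `pedigree_summary` with fields
#'   `n_individuals`, `n_founders`, `n_maternities`, `n_paternities`,
#'   `n_full_sib_pairs`, `n_maternal_half_sib_pairs`,
#'   `n_paternal_half_sib_pairs`, `max_pedigree_depth`.
#' @export
pedigree_summary <- function(ped) {
  n <- nrow(ped)
  dam <- ped$dam
  sire <- ped$sire
  same_known <- function(x, i, j) !is.na(x[i]) & !is.na(x[j]) & x[i] == x[j]
  n_fs <- n_mhs <- n_phs <- 0L
  if (n >= 2) {
    cmb <- utils::combn(n, 2)
    i <- cmb[1, ]; j <- cmb[2, ]
    sd <- same_known(dam, i, j)
    ss <- same_known(sire, i, j)
    n_fs <- sum(sd & ss)
    n_mhs <- sum(sd & !ss)
    n_phs <- sum(!sd & ss)
  }
  # generation depth: founders depth 0
  ord <- topological_order(ped)
  depth <- stats::setNames(integer(n), ped$id)
  for (id in ord) {
    k <- match(id, ped$id)
    pd <- c(dam[k], sire[k])
    pd <- pd[!is.na(pd)]
    depth[id] <- if (length(pd)) max(depth[pd]) + 1L else 0L
  }
  structure(list(
    n_individuals = n,
    n_founders = n_founders(ped),
    n_maternities = sum(!is.na(dam)),
    n_paternities = sum(!is.na(sire)),
    n_full_sib_pairs = n_fs,
    n_maternal_half_sib_pairs = n_mhs,
    n_paternal_half_sib_pairs = n_phs,
    max_pedigree_depth = max(depth)
  ), class = "pedigree_summary")
}

#' @export
print.pedigree_summary <- function(x, ...) {
  cat("Pedigree summary\n")
  for (f in names(x)) cat(sprintf("  %-26s %d\n", f, x[[f]]))
  invisible(x)
}

#' Write a relationship matrix
#'
#' Either as a square CSV with id header row/column (`format = "square"`)
#' or as a sparse triplet CSV `id_i,id_j,a` of nonzero entries
#' (`format = "triplet"`, upper triangle including the diagonal).
#'
#' @param A matrix from [additive_relationship_matrix()].
#' @param path output path.
#' @param format `"square"` or `"triplet"`.
#' @export
write_relationship_matrix <- function(A, path, format = c("square", "triplet")) {
  format <- match.arg(format)
  if (format == "square") {
    utils::write.csv(as.data.frame(A), path, row.names = TRUE)
  } else {
    keep <- which(upper.tri(A, diag = TRUE) & A != 0, arr.ind = TRUE)
    utils::write.csv(data.frame(id_i = rownames(A)[keep[, 1]],
                                id_j = colnames(A)[keep[, 2]],
                                a = A[keep]),
                     path, row.names = FALSE)
  }
  invisible(path)
}
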