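# Genotype container and file formats (wide CSV and GenePop).

#' Construct a genotype table
#'
#' Individuals x loci table of unordered codominant allele pairs. Allele
#' codes are positive integers; a cell is either a complete pair or missing
#' (half-calls are rejected). Stored internally as an n x L x 2 integer
#' array with alleles sorted within a cell.
#'
#' @param alleles n x L x 2 integer array (NA = missing), with individual
#'   ids as rownames.
#' @param loci character vector of locus names (defaults to the array's
#'   column names).
#' @return object of class `genotype_table`.
#' @export
genotype_table <- function(alleles, loci = NULL) {
  stopifnot(is.array(alleles), length(dim(alleles)) == 3, dim(alleles)[3] == 2)
  ids <- rownames(alleles)
  if (is.null(ids)) ids <- sprintf("ind%03d", seq_len(dim(alleles)[1]))
  if (is.null(loci)) loci <- colnames(alleles)
  if (is.null(loci)) loci <- sprintf("L%02d", seq_len(dim(alleles)[2]))
  a <- array(as.integer(alleles), dim = dim(alleles))
  half <- xor(is.na(a[, , 1, drop = FALSE]), is.na(a[, , 2, drop = FALSE]))
  if (any(half)) stop("half-called genotypes are not allowed")
  if (any(a <= 0, na.rm = TRUE)) stop("allele codes must be positive integers")
  # sort alleles within cells
  lo <- pmin(a[, , 1], a[, , 2])
  hi <- pmax(a[, , 1], a[, , 2])
  a[, , 1] <- lo
  a[, , 2] <- hi
  dimnames(a) <- list(ids, loci, c("a1", "a2"))
  structure(list(alleles = a, ids = ids, loci = loci),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat("GenotypeTable:", length(x$ids), "individuals x",
      length(x$loci), "loci\n")
  miss <- mean(is.na(x$alleles[, , 1]))
  cat(sprintf("  missing cells: %.1f%%\n", 100 * miss))
  invisible(x)
}

#' Extract one locus as a two-column matrix of allele pairs
#' @param gt a [genotype_table()].
#' @param locus locus name or index.
#' @return n x 2 integer matrix (NA rows = missing), rownames = ids.
#' @export
locus_genotypes <- function(gt, locus) {
  m <- cbind(gt$alleles[, locus, 1], gt$alleles[, locus, 2])
  rownames(m) <- gt$ids
  m
}

#' Read genotypes from a wide CSV
#'
#' Expected header: `id,<locus>_a,<locus>_b,...`; 0 or empty = missing.
#'
#' @param path CSV path.
#' @return a [genotype_table()].
#' @export
read_genotypes_csv <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  stopifnot("id" %in% names(df))
  acols <- grep("_a$", names(df), value = TRUE)
  loci <- sub("_a$", "", acols)
  stopifnot(all(paste0(loci, "_b") %in% names(df)))
  n <- nrow(df)
  a <- array(NA_integer_, c(n, length(loci), 2),
             dimnames = list(df$id, loci, c("a1", "a2")))
  for (j in seq_along(loci)) {
    a1 <- suppressWarnings(as.integer(df[[paste0(loci[j], "_a")]]))
    a2 <- suppressWarnings(as.integer(df[[paste0(loci[j], "_b")]]))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    a[, j, 1] <- a1
    a[, j, 2] <- a2
  }
  genotype_table(a, loci)
}

#' Write genotypes to a wide CSV
#' @param gt a [genotype_table()].
#' @param path output path.
#' @export
write_genotypes_csv <- function(gt, path) {
  out <- data.frame(id = gt$ids, stringsAsFactors = FALSE)
  for (j in seq_along(gt$loci)) {
    a1 <- gt$alleles[, j, 1]
    a2 <- gt$alleles[, j, 2]
    a1[is.na(a1)] <- 0L
    a2[is.na(a2)] <- 0L
    out[[paste0(gt$loci[j], "_a")]] <- a1
    out[[paste0(gt$loci[j], "_b")]] <- a2
  }
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a GenePop file
#'
#' Handles 2- or 3-digit allele coding; `0000`/`000000` denotes a missing
#' genotype. Multiple `Pop` blocks are concatenated; the block label is
#' kept in the `population` attribute.
#'
#' @param path GenePop file path.
#' @return a [genotype_table()].
#' @export
read_genepop <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  pop_rows <- grep("^\\s*pop\\s*$", lines, ignore.case = TRUE)
  if (!length(pop_rows)) stop("no 'Pop' line found in GenePop file")
  header <- lines[2:(pop_rows[1] - 1)]
  loci <- trimws(unlist(strsplit(header, ",")))
  loci <- loci[nzchar(loci)]
  recs <- lines[setdiff((pop_rows[1] + 1):length(lines), pop_rows)]
  pop_of <- findInterval(setdiff((pop_rows[1] + 1):length(lines), pop_rows),
                         pop_rows)
  n <- length(recs)
  a <- array(NA_integer_, c(n, length(loci), 2))
  ids <- character(n)
  for (i in seq_len(n)) {
    parts <- strsplit(recs[i], ",")[[1]]
    if (length(parts) < 2) stop("malformed GenePop record: ", recs[i])
    ids[i] <- trimws(parts[1])
    gs <- strsplit(trimws(paste(parts[-1], collapse = " ")), "\\s+")[[1]]
    if (length(gs) != length(loci))
      stop("record has ", length(gs), " genotypes but ", length(loci),
           " loci: ", ids[i])
    w <- nchar(gs[1]) / 2
    if (!w %in% c(2, 3)) stop("allele coding must be 2 or 3 digits")
    a1 <- as.integer(substr(gs, 1, w))
    a2 <- as.integer(substr(gs, w + 1, 2 * w))
    a1[a1 == 0L] <- NA_integer_
    a2[a2 == 0L] <- NA_integer_
    miss <- is.na(a1) | is.na(a2)
    a1[miss] <- NA_integer_
    a2[miss] <- NA_integer_
    a[i, , 1] <- a1
    a[i, , 2] <- a2
  }
  rownames(a) <- ids
  gt <- genotype_table(a, loci)
  attr(gt, "population") <- pop_of
  gt
}

#' Write a GenePop file (3-digit coding)
#' @param gt a [genotype_table()].
#' @param path output path.
#' @param title title line.
#' @export
write_genepop <- function(gt, path, title = "nestQG export") {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(title, con)
  writeLines(gt$loci, con)
  writeLines("Pop", con)
  for (i in seq_along(gt$ids)) {
    a1 <- gt$alleles[i, , 1]
    a2 <- gt$alleles[i, , 2]
    a1[is.na(a1)] <- 0L
    a2[is.na(a2)] <- 0L
    writeLines(paste0(gt$ids[i], " , ",
                      paste(sprintf("%03d%03d", a1, a2), collapse = " ")),
               con)
  }
  invisible(path)
}
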