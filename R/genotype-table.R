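#' Georeferenced multilocus genotype table
#'
#' The universal input container of the package: diploid codominant
#' genotypes (allele states coded as positive integers, e.g. microsatellite
#' allele sizes in base pairs or repeat units) for a set of georeferenced
#' samples, with optional group labels (genetic clusters, bioregions, demes).
#'
#' Internally genotypes are stored as an integer matrix with two columns per
#' locus (`<locus>_1`, `<locus>_2`). A genotype is either fully missing (both
#' alleles `NA`) or fully typed; allele pairs are unordered and stored in
#' canonical (sorted) order.
#'
#' @param samples data.frame with columns `sample_id`, `x`, `y` and
#'   optionally `group`. Coordinates are planar meters or geographic decimal
#'   degrees (x = longitude, y = latitude), declared via `coord_system`.
#' @param geno integer matrix, one row per sample, two columns per locus.
#' @param loci character vector of unique locus names, in column order of
#'   `geno`.
#' @param coord_system `"planar"` (meters) or `"geographic"` (decimal
#'   degrees).
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(samples, geno, loci,
                           coord_system = c("planar", "geographic")) {
  coord_system <- match.arg(coord_system)
  stopifnot(is.data.frame(samples),
            all(c("sample_id", "x", "y") %in% names(samples)))
  samples$sample_id <- as.character(samples$sample_id)
  if (anyDuplicated(samples$sample_id))
    stop("duplicate sample_id: ",
         paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
               collapse = ", "))
  if (!"group" %in% names(samples)) samples$group <- NA_character_
  samples$group <- as.character(samples$group)
  loci <- as.character(loci)
  if (anyDuplicated(loci)) stop("locus names must be unique")
  geno <- as.matrix(geno)
  storage.mode(geno) <- "integer"
  if (nrow(geno) != nrow(samples))
    stop("geno must have one row per sample")
  if (ncol(geno) != 2L * length(loci))
    stop("geno must have two columns per locus")
  # normalize: 0 is the conventional missing code on input
  geno[!is.na(geno) & geno == 0L] <- NA_integer_
  if (any(!is.na(geno) & geno < 0L))
    stop("allele states must be positive integers")
  # both-or-neither missing per locus
  a1 <- geno[, 2L * seq_along(loci) - 1L, drop = FALSE]
  a2 <- geno[, 2L * seq_along(loci), drop = FALSE]
  half <- xor(is.na(a1), is.na(a2))
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("sample '%s', locus '%s': genotype has exactly one allele",
                 samples$sample_id[bad[1L]], loci[bad[2L]]))
  }
  # canonical unordered pair: a1 <= a2
  swap <- !is.na(a1) & a1 > a2
  tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  geno[, 2L * seq_along(loci) - 1L] <- a1
  geno[, 2L * seq_along(loci)] <- a2
  colnames(geno) <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  rownames(geno) <- samples$sample_id
  structure(list(samples = samples[, c("sample_id", "x", "y", "group")],
                 geno = geno, loci = loci, ploidy = 2L,
                 coord_system = coord_system),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("genotype_table: %d samples, %d loci (%s coordinates)\n",
              n_samples(x), n_loci(x), x$coord_system))
  miss <- mean(is.na(x$geno[, 2L * seq_len(n_loci(x)) - 1L, drop = FALSE]))
  cat(sprintf("  missing genotypes: %.1f%%\n", 100 * miss))
  grp <- x$samples$group
  if (any(!is.na(grp)))
    cat("  groups:", paste(names(table(grp)), table(grp), sep = ":",
                           collapse = ", "), "\n")
  invisible(x)
}

#' @rdname genotype_table
#' @param x a `genotype_table`.
#' @export
n_samples <- function(x) nrow(x$samples)

#' @rdname genotype_table
#' @export
n_loci <- function(x) length(x$loci)

# n x L logical matrix: is the genotype typed (non-missing)?
typed_matrix <- function(x) {
  !is.na(x$geno[, 2L * seq_len(n_loci(x)) - 1L, drop = FALSE])
}

# n x L matrices of first/second allele
allele_matrix <- function(x, which = 1L) {
  x$geno[, 2L * seq_len(n_loci(x)) - (2L - which), drop = FALSE]
}

#' Subset a genotype table by sample index or group label
#'
#' @param x a `genotype_table`.
#' @param i integer/logical sample index.
#' @param group optional group label(s); selects samples whose `group` is in
#'   the set. An error is raised when no sample matches.
#' @return A `genotype_table` with the selected samples.
#' @export
subset_samples <- function(x, i = NULL, group = NULL) {
  if (!is.null(group)) {
    i <- which(x$samples$group %in% group)
    if (length(i) == 0L) stop("no samples in group(s): ",
                              paste(group, collapse = ", "))
  }
  stopifnot(!is.null(i))
  genotype_table(x$samples[i, , drop = FALSE],
                 x$geno[i, , drop = FALSE], x$loci, x$coord_system)
}

#' Read a genotype table
#'
#' Supported formats: the package's primary CSV dialect (header
#' `sample_id,x,y,group,<locus>_1,<locus>_2,...`; missing allele = empty cell
#' or 0) and the SPAGeDi text format (header line with counts, one category
#' and two coordinate columns, digit-coded genotypes, terminated by `END`;
#' missing = 0).
#'
#' @param path file path.
#' @param format `"csv"` or `"spagedi"`.
#' @param coord_system coordinate system of `x`/`y` in the file.
#' @return A validated [genotype_table()].
#' @export
read_genotypes <- function(path, format = c("csv", "spagedi"),
                           coord_system = c("planar", "geographic")) {
  format <- match.arg(format)
  coord_system <- match.arg(coord_system)
  if (format == "csv") read_genotypes_csv(path, coord_system)
  else read_genotypes_spagedi(path, coord_system)
}

read_genotypes_csv <- function(path, coord_system) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  need <- c("sample_id", "x", "y", "group")
  if (!all(need %in% names(df)))
    stop("CSV must have header sample_id,x,y,group,<locus>_1,<locus>_2,...")
  acols <- setdiff(names(df), need)
  if (length(acols) %% 2L != 0L)
    stop("odd number of allele columns: ", length(acols))
  loci <- unique(sub("_[12]$", "", acols))
  expect <- paste0(rep(loci, each = 2L), c("_1", "_2"))
  if (!all(expect %in% acols))
    stop("allele columns must come in <locus>_1/<locus>_2 pairs")
  g <- df[, expect, drop = FALSE]
  g[g == ""] <- NA
  gm <- suppressWarnings(
    matrix(as.integer(as.matrix(g)), nrow = nrow(df)))
  bad <- which(is.na(gm) & !is.na(as.matrix(g)), arr.ind = TRUE)
  if (nrow(bad) > 0L)
    stop(sprintf("line %d (sample '%s'): non-integer allele '%s'",
                 bad[1L, 1L] + 1L, df$sample_id[bad[1L, 1L]],
                 as.matrix(g)[bad[1L, , drop = FALSE]]))
  samples <- data.frame(sample_id = df$sample_id,
                        x = as.numeric(df$x), y = as.numeric(df$y),
                        group = ifelse(df$group == "", NA, df$group),
                        stringsAsFactors = FALSE)
  tryCatch(genotype_table(samples, gm, loci, coord_system),
           error = function(e)
             stop("while reading ", path, ": ", conditionMessage(e),
                  call. = FALSE))
}

read_genotypes_spagedi <- function(path, coord_system) {
  lines <- readLines(path)
  lines <- lines[!grepl("^\\s*//", lines)]
  hdr <- as.integer(strsplit(trimws(lines[1L]), "[\t ,]+")[[1L]])
  if (length(hdr) < 6L) stop("malformed SPAGeDi header line")
  n_ind <- hdr[1L]; n_cat <- hdr[2L]; n_coord <- hdr[3L]
  n_loc <- hdr[4L]; n_dig <- hdr[5L]; ploidy <- hdr[6L]
  if (ploidy != 2L) stop("only diploid SPAGeDi files are supported")
  # line 2: distance class spec (ignored); line 3: column names
  cn <- strsplit(lines[3L], "\t")[[1L]]
  loci <- cn[(1L + n_cat + n_coord + 1L):(1L + n_cat + n_coord + n_loc)]
  rows <- lines[4L:(3L + n_ind)]
  if (trimws(lines[4L + n_ind]) != "END")
    stop("SPAGeDi file must end with END after ", n_ind, " individual rows")
  parts <- strsplit(rows, "\t")
  gm <- matrix(NA_integer_, n_ind, 2L * n_loc)
  samples <- data.frame(sample_id = character(n_ind), x = numeric(n_ind),
                        y = numeric(n_ind), group = NA_character_,
                        stringsAsFactors = FALSE)
  for (i in seq_len(n_ind)) {
    p <- parts[[i]]
    if (length(p) != 1L + n_cat + n_coord + n_loc)
      stop(sprintf("line %d (sample '%s'): expected %d fields, got %d",
                   i + 3L, p[1L], 1L + n_cat + n_coord + n_loc, length(p)))
    samples$sample_id[i] <- p[1L]
    if (n_cat >= 1L) samples$group[i] <- p[2L]
    samples$x[i] <- as.numeric(p[1L + n_cat + 1L])
    samples$y[i] <- as.numeric(p[1L + n_cat + 2L])
    for (l in seq_len(n_loc)) {
      code <- p[1L + n_cat + n_coord + l]
      g <- spagedi_decode(code, n_dig)
      gm[i, 2L * l - 1L] <- g[1L]
      gm[i, 2L * l] <- g[2L]
    }
  }
  genotype_table(samples, gm, loci, coord_system)
}

spagedi_decode <- function(code, n_dig) {
  code <- trimws(code)
  if (code == "" || as.numeric(code) == 0) return(c(NA_integer_, NA_integer_))
  code <- formatC(code, width = 2L * n_dig, flag = "0")
  a <- as.integer(substr(code, 1L, n_dig))
  b <- as.integer(substr(code, n_dig + 1L, 2L * n_dig))
  if (is.na(a) || is.na(b) || a == 0L || b == 0L)
    stop("partial genotype code '", code, "' (one allele missing)")
  c(a, b)
}

#' Write a genotype table
#'
#' @param table a [genotype_table()].
#' @param path output file path.
#' @param format `"csv"` (primary dialect) or `"spagedi"`.
#' @param n_digits digits per allele for the SPAGeDi encoding.
#' @return `path`, invisibly.
#' @export
write_genotypes <- function(table, path, format = c("csv", "spagedi"),
                            n_digits = 3L) {
  format <- match.arg(format)
  if (format == "csv") {
    g <- table$geno
    g[is.na(g)] <- 0L
    df <- cbind(table$samples, as.data.frame(g))
    utils::write.csv(df, path, row.names = FALSE, quote = FALSE, na = "")
  } else {
    if (any(table$geno >= 10^n_digits, na.rm = TRUE))
      stop("allele states do not fit in ", n_digits, " digits")
    L <- n_loci(table)
    codes <- matrix("0", n_samples(table), L)
    for (l in seq_len(L)) {
      a1 <- table$geno[, 2L * l - 1L]; a2 <- table$geno[, 2L * l]
      ok <- !is.na(a1)
      codes[ok, l] <- paste0(formatC(a1[ok], width = n_digits, flag = "0"),
                             formatC(a2[ok], width = n_digits, flag = "0"))
    }
    grp <- table$samples$group
    grp[is.na(grp)] <- "pop1"
    hdr1 <- paste(n_samples(table), 1L, 2L, L, n_digits, 2L, sep = "\t")
    body <- apply(cbind(table$samples$sample_id, grp,
                        format(table$samples$x, trim = TRUE, digits = 15),
                        format(table$samples$y, trim = TRUE, digits = 15),
                        codes), 1L, paste, collapse = "\t")
    writeLines(c(hdr1, "0",
                 paste(c("Ind", "Cat", "X", "Y", table$loci),
                       collapse = "\t"),
                 body, "END"), path)
  }
  invisible(path)
}

#' Export to STRUCTURE format
#'
#' Two rows per individual, one column per locus, missing allele coded -9;
#' first column is the sample id, second the (integer-recoded) group.
#'
#' @inheritParams write_genotypes
#' @return `path`, invisibly.
#' @export
write_structure <- function(table, path) {
  L <- n_loci(table)
  grp <- as.integer(factor(table$samples$group))
  grp[is.na(grp)] <- 0L
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste(table$loci, collapse = "\t"), con)
  for (i in seq_len(n_samples(table))) {
    for (k in 1:2) {
      al <- table$geno[i, 2L * seq_len(L) - (2L - k)]
      al[is.na(al)] <- -9L
      writeLines(paste(c(table$samples$sample_id[i], grp[i], al),
                       collapse = "\t"), con)
    }
  }
  invisible(path)
}
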