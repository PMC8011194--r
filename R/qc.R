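#' Remove samples typed at too few loci
#'
#' Retains the samples whose fraction of non-missing loci is at least
#' `min_fraction` (default 0.6, i.e. at least six out of ten loci for a
#' 10-locus panel). Sample order is preserved.
#'
#' @param table a [genotype_table()].
#' @param min_fraction minimum fraction of typed loci, in (0, 1].
#' @return A filtered `genotype_table`.
#' @export
filter_min_typed_loci <- function(table, min_fraction = 0.6) {
  stopifnot(min_fraction > 0, min_fraction <= 1)
  frac <- rowMeans(typed_matrix(table))
  keep <- which(frac >= min_fraction)
  if (length(keep) == 0L) {
    warning("no sample passes the min-typed-loci filter")
    keep <- integer(0)
    return(structure(list(samples = table$samples[keep, , drop = FALSE],
                          geno = table$geno[keep, , drop = FALSE],
                          loci = table$loci, ploidy = 2L,
                          coord_system = table$coord_system),
                     class = "genotype_table"))
  }
  subset_samples(table, keep)
}

#' Screen for duplicated individuals
#'
#' Flags sample pairs whose genotypes are identical at every locus where both
#' are typed, provided they share at least `min_shared_loci` typed loci. A
#' relationship coefficient (proportion of alleles shared per locus, averaged
#' over shared loci) is reported per pair so that users can apply their own
#' cutoff.
#'
#' @param table a [genotype_table()].
#' @param min_shared_loci minimum number of loci typed in both samples.
#' @param all_pairs if `TRUE`, return every pair meeting the overlap floor
#'   (with its coefficient), not only exact matches.
#' @return data.frame with columns `id1`, `id2`, `n_shared_loci`,
#'   `coefficient`, `identical`.
#' @export
detect_duplicates <- function(table, min_shared_loci = 5L,
                              all_pairs = FALSE) {
  n <- n_samples(table)
  if (n == 0L) stop("empty genotype table")
  L <- n_loci(table)
  a1 <- allele_matrix(table, 1L)
  a2 <- allele_matrix(table, 2L)
  typed <- typed_matrix(table)
  out <- list()
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      sh <- which(typed[i, ] & typed[j, ])
      if (length(sh) < min_shared_loci) next
      # alleles shared per locus: |{a,b} intersect {c,d}| with multiplicity
      m <- vapply(sh, function(l) {
        gi <- c(a1[i, l], a2[i, l]); gj <- c(a1[j, l], a2[j, l])
        shared <- 0L
        for (al in unique(gi))
          shared <- shared + min(sum(gi == al), sum(gj == al))
        shared / 2
      }, numeric(1))
      ident <- all(m == 1)
      coef <- mean(m)
      if (ident || all_pairs)
        out[[length(out) + 1L]] <-
          data.frame(id1 = table$samples$sample_id[i],
                     id2 = table$samples$sample_id[j],
                     n_shared_loci = length(sh),
                     coefficient = coef, identical = ident,
                     stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L)
    return(data.frame(id1 = character(), id2 = character(),
                      n_shared_loci = integer(), coefficient = numeric(),
                      identical = logical(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}

#' Spatial grid subsampling
#'
#' Thins spatially over-represented areas: samples are partitioned into
#' axis-aligned square cells of side `cell_size` degrees (grid anchored at
#' 0 degrees, 0 degrees) and any cell holding more than `max_per_cell`
#' samples is reduced to a seeded uniform random subset of that size.
#'
#' @param table a [genotype_table()] with geographic coordinates.
#' @param cell_size cell side in decimal degrees (default 0.01, roughly
#'   1 km^2 near the equator).
#' @param max_per_cell maximum samples retained per cell.
#' @param seed integer seed controlling the random draws.
#' @return A subsampled `genotype_table` (sample order preserved).
#' @export
grid_subsample <- function(table, cell_size = 0.01, max_per_cell = 3L,
                           seed) {
  if (table$coord_system != "geographic")
    stop("grid_subsample expects geographic coordinates (decimal degrees); ",
         "got planar")
  stopifnot(!missing(seed))
  cell <- paste(floor(table$samples$x / cell_size),
                floor(table$samples$y / cell_size))
  keep <- withr::with_seed(seed, unlist(
    lapply(split(seq_len(n_samples(table)), cell), function(ix) {
      if (length(ix) <= max_per_cell) ix
      else sort(ix[sample.int(length(ix), max_per_cell)])
    }), use.names = FALSE))
  subset_samples(table, sort(keep))
}
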