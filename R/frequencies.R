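#' Allele frequencies per locus
#'
#' Computes per-locus allele frequencies over the non-missing gene copies of
#' the selected samples, together with the number of gene copies actually
#' observed at each locus. These are the reference frequencies used by the
#' diversity statistics and the Loiselle kinship estimator.
#'
#' @param table a [genotype_table()].
#' @param group optional group label(s) restricting the sample set.
#' @return An object of class `allele_freqs`: list with `loci`, `freq` (list
#'   of named frequency vectors, names = allele states), `counts` (allele
#'   copy counts), and `n` (gene copies per locus). Loci with zero typed
#'   copies are flagged in `$excluded` and dropped from `freq`.
#' @export
allele_frequencies <- function(table, group = NULL) {
  if (!is.null(group)) table <- subset_samples(table, group = group)
  if (n_samples(table) == 0L) stop("no samples selected")
  L <- n_loci(table)
  freq <- vector("list", L)
  counts <- vector("list", L)
  n <- integer(L)
  for (l in seq_len(L)) {
    copies <- c(table$geno[, 2L * l - 1L], table$geno[, 2L * l])
    copies <- copies[!is.na(copies)]
    n[l] <- length(copies)
    if (n[l] > 0L) {
      tab <- table(copies)
      counts[[l]] <- stats::setNames(as.integer(tab), names(tab))
      freq[[l]] <- counts[[l]] / n[l]
    }
  }
  names(freq) <- names(counts) <- table$loci
  excluded <- table$loci[n == 0L]
  if (length(excluded) > 0L)
    warning("loci with zero typed copies excluded: ",
            paste(excluded, collapse = ", "))
  structure(list(loci = table$loci[n > 0L], freq = freq[n > 0L],
                 counts = counts[n > 0L], n = n[n > 0L],
                 excluded = excluded),
            class = "allele_freqs")
}

#' @export
print.allele_freqs <- function(x, ...) {
  cat(sprintf("allele_freqs: %d loci, %d-%d alleles, %d-%d gene copies\n",
              length(x$loci),
              min(lengths(x$freq)), max(lengths(x$freq)),
              min(x$n), max(x$n)))
  invisible(x)
}
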