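# Simple association diagnostics for verifying that the epistasis signal
# was embedded where intended (and nowhere else).

#' K-locus chi-square association statistic
#'
#' Pearson chi-square of the contingency table of combination genotypes at
#' `loci` (up to `3^K` observed cells) against the 0/1 labels. Empty genotype
#' cells are dropped. Used to check that the embedded model loci carry
#' association signal while random non-model loci do not.
#'
#' @param geno integer genotype matrix (or [genotype_matrix()]).
#' @param labels 0/1 label vector, one per row.
#' @param loci integer vector of column indices to test jointly.
#' @return the chi-square statistic (numeric scalar).
#' @export
association_chisq <- function(geno, labels, loci) {
  if (inherits(geno, "genotype_matrix")) geno <- geno$data
  stopifnot(length(labels) == nrow(geno))
  codes <- geno[, loci, drop = FALSE] - 1L
  g <- combo_index(codes)
  tab <- table(factor(g), factor(labels, levels = c(0L, 1L)))
  tab <- tab[rowSums(tab) > 0L, , drop = FALSE]
  n <- sum(tab)
  expd <- outer(rowSums(tab), colSums(tab)) / n
  sum((tab - expd)^2 / expd)
}
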