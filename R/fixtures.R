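# Synthetic sampling pools. Real sampling data (e.g. a WTCCC-style
# case-control SNP matrix) is large and access-restricted; these generators
# produce pools with known per-SNP MAFs, Hardy-Weinberg genotype
# proportions, and optional block LD, so the resampler and dataset builder
# can be exercised and validated without any download.

#' Recipe for a synthetic sampling pool
#'
#' @param n_samples number of samples (rows).
#' @param n_snps number of SNPs (columns).
#' @param maf_range when `mafs` is `NULL`, true per-SNP MAFs are drawn
#'   uniformly from this range (bounds within `[0.01, 0.5]`).
#' @param mafs optional explicit vector of true MAFs, length `n_snps` (or
#'   one per block when `block_size > 0`).
#' @param block_size columns per LD block; 0 disables block LD. Columns
#'   within a block share one true MAF.
#' @param block_cor within-block copy probability in `[0, 1]`: each sample
#'   draws one latent genotype per block and each block column copies it
#'   with this probability (drawing independently otherwise), so 1 gives
#'   identical columns within a block and 0 gives independence.
#' @param control_fraction fraction of samples labeled control (0); labels
#'   are assigned independently of genotype (null background).
#' @param seed integer seed.
#' @return an object of class `pool_recipe`.
#' @export
pool_recipe <- function(n_samples, n_snps, maf_range = c(0.05, 0.5),
                        mafs = NULL, block_size = 0L, block_cor = 0,
                        control_fraction = 1, seed = 1L) {
  stopifnot(n_samples >= 1L, n_snps >= 1L)
  if (is.null(mafs)) {
    if (maf_range[1L] < 0.01 || maf_range[2L] > 0.5 ||
        maf_range[1L] > maf_range[2L]) {
      stop("maf_range bounds must satisfy 0.01 <= lo <= hi <= 0.5", call. = FALSE)
    }
  } else if (any(mafs < 0.01 | mafs > 0.5)) {
    stop("explicit MAFs must lie in [0.01, 0.5]", call. = FALSE)
  }
  if (block_size > n_snps) stop("block_size cannot exceed n_snps", call. = FALSE)
  if (block_cor < 0 || block_cor > 1) stop("block_cor must lie in [0, 1]", call. = FALSE)
  if (control_fraction < 0 || control_fraction > 1) {
    stop("control_fraction must lie in [0, 1]", call. = FALSE)
  }
  structure(list(n_samples = as.integer(n_samples), n_snps = as.integer(n_snps),
                 maf_range = maf_range, mafs = mafs,
                 block_size = as.integer(block_size), block_cor = block_cor,
                 control_fraction = control_fraction, seed = as.integer(seed)),
            class = "pool_recipe")
}

# Draw n genotype codes (1/2/3) from HWE proportions at MAF m.
.draw_hwe_codes <- function(n, m) {
  sample.int(3L, n, replace = TRUE, prob = genotype_frequencies(m))
}

#' Generate a synthetic sampling pool
#'
#' Per SNP a true MAF is drawn (or taken from the recipe) and genotypes are
#' sampled from Hardy-Weinberg proportions. With block LD enabled, columns
#' of a block share one true MAF and are copies of a per-sample latent
#' genotype with probability `block_cor`. Case/control labels are assigned
#' independently of genotype.
#'
#' @param recipe a [pool_recipe()].
#' @return a [genotype_matrix()] with attributes `true_mafs` (numeric,
#'   per column) and `block_map` (integer block id per column, or `NULL`).
#' @export
synth_pool <- function(recipe) {
  stopifnot(inherits(recipe, "pool_recipe"))
  set.seed(recipe$seed)
  n <- recipe$n_samples
  p <- recipe$n_snps
  data <- matrix(0L, nrow = n, ncol = p)

  if (recipe$block_size > 0L) {
    block_map <- ((seq_len(p) - 1L) %/% recipe$block_size) + 1L
    n_blocks <- max(block_map)
    block_mafs <- if (is.null(recipe$mafs)) {
      stats::runif(n_blocks, recipe$maf_range[1L], recipe$maf_range[2L])
    } else {
      if (length(recipe$mafs) != n_blocks) {
        stop("with block LD, give one explicit MAF per block (", n_blocks, ")",
             call. = FALSE)
      }
      recipe$mafs
    }
    true_mafs <- block_mafs[block_map]
    for (b in seq_len(n_blocks)) {
      cols <- which(block_map == b)
      latent <- .draw_hwe_codes(n, block_mafs[b])
      for (j in cols) {
        copy <- stats::runif(n) < recipe$block_cor
        col <- .draw_hwe_codes(n, block_mafs[b])
        col[copy] <- latent[copy]
        data[, j] <- col
      }
    }
  } else {
    block_map <- NULL
    true_mafs <- if (is.null(recipe$mafs)) {
      stats::runif(p, recipe$maf_range[1L], recipe$maf_range[2L])
    } else {
      if (length(recipe$mafs) != p) {
        stop("explicit MAFs must have one value per SNP", call. = FALSE)
      }
      recipe$mafs
    }
    for (j in seq_len(p)) data[, j] <- .draw_hwe_codes(n, true_mafs[j])
  }

  n_cases <- round(n * (1 - recipe$control_fraction))
  labels <- sample(c(rep(1L, n_cases), rep(0L, n - n_cases)))
  gm <- genotype_matrix(data, labels = labels)
  attr(gm, "true_mafs") <- true_mafs
  attr(gm, "block_map") <- block_map
  gm
}

#' Per-column Hardy-Weinberg goodness-of-fit check
#'
#' One 1-df chi-square per column comparing observed genotype counts with the
#' Hardy-Weinberg expectations at the column's estimated allele frequency.
#' Monomorphic columns are skipped (statistic `NA`, `skipped = TRUE`).
#'
#' @param gm a [genotype_matrix()] (or plain code matrix).
#' @return a data.frame with columns `column`, `maf`, `statistic`, `p_value`,
#'   `skipped`.
#' @export
hwe_check <- function(gm) {
  data <- if (inherits(gm, "genotype_matrix")) gm$data else gm
  if (!length(data)) stop("empty genotype matrix", call. = FALSE)
  n <- nrow(data)
  res <- lapply(seq_len(ncol(data)), function(j) {
    col <- data[, j]
    obs <- tabulate(col, nbins = 3L)
    p <- sum(col - 1L) / (2 * n) # coded-allele frequency, unfolded
    if (p == 0 || p == 1) {
      return(data.frame(column = j, maf = min(p, 1 - p), statistic = NA_real_,
                        p_value = NA_real_, skipped = TRUE))
    }
    expd <- n * c((1 - p)^2, 2 * p * (1 - p), p^2)
    stat <- sum((obs - expd)^2 / expd)
    data.frame(column = j, maf = min(p, 1 - p), statistic = stat,
               p_value = stats::pchisq(stat, df = 1, lower.tail = FALSE),
               skipped = FALSE)
  })
  do.call(rbind, res)
}
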