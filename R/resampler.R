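# Fragment resampling. A simulated sample is spliced together from genotype
# fragments of randomly chosen control donors: the SNP columns are cut into
# contiguous segments of random length, and each segment is copied wholesale
# from one donor row. Column-wise this reproduces the pool's genotype (hence
# allele-frequency) distribution exactly in expectation, while local LD is
# carried along inside each fragment.

#' Build a sampling pool from a labeled genotype matrix
#'
#' Keeps control rows only (label 0) and selects `n_snps` distinct columns
#' uniformly at random, preserving their original order; per-column MAFs are
#' computed on the control rows.
#'
#' @param gm a [genotype_matrix()] with labels.
#' @param n_snps number of SNP columns to keep; default all.
#' @param seed optional integer seed; when `NULL` the current RNG state is
#'   used.
#' @return an object of class `sampling_pool` with fields `data`,
#'   `column_mafs`, `column_flipped`, `columns` (original indices), `snp_ids`.
#' @export
build_pool <- function(gm, n_snps = NULL, seed = NULL) {
  stopifnot(inherits(gm, "genotype_matrix"))
  if (is.null(gm$labels)) {
    stop("sampling dataset has no case/control labels; cannot select controls",
         call. = FALSE)
  }
  keep <- gm$labels == 0L
  if (!any(keep)) stop("sampling dataset contains no control rows", call. = FALSE)
  if (!is.null(seed)) set.seed(seed)
  n_total <- ncol(gm$data)
  if (is.null(n_snps)) n_snps <- n_total
  if (n_snps < 1L || n_snps > n_total) {
    stop("n_snps must be between 1 and ", n_total, call. = FALSE)
  }
  cols <- sort(sample.int(n_total, n_snps))
  data <- gm$data[keep, cols, drop = FALSE]
  m <- .column_mafs(data)
  structure(list(data = data, column_mafs = m$maf, column_flipped = m$flipped,
                 columns = cols, snp_ids = gm$snp_ids[cols]),
            class = "sampling_pool")
}

#' @export
print.sampling_pool <- function(x, ...) {
  cat("Sampling pool:", nrow(x$data), "control samples x", ncol(x$data),
      "SNPs; MAF range",
      sprintf("[%.3f, %.3f]\n", min(x$column_mafs), max(x$column_mafs)))
  invisible(x)
}

#' Select model loci by MAF matching
#'
#' For each target MAF, candidate columns are those whose pool MAF lies within
#' a window `w` of the target. The window starts at 0.01 and grows in steps
#' of 0.01 whenever some target has no unclaimed candidate, until every
#' target can claim a distinct column; one candidate per target is then drawn
#' uniformly, without replacement across targets.
#'
#' @param pool a [build_pool()] result.
#' @param target_mafs numeric vector of K target MAFs.
#' @param seed optional integer seed.
#' @param step window growth per expansion round (default 0.01).
#' @return integer vector of K distinct pool column indices, with attribute
#'   `window` holding the final window half-width.
#' @export
match_loci_by_maf <- function(pool, target_mafs, seed = NULL, step = 0.01) {
  stopifnot(inherits(pool, "sampling_pool"))
  K <- length(target_mafs)
  if (K > ncol(pool$data)) {
    stop("cannot select ", K, " loci from a pool of ", ncol(pool$data),
         " SNPs", call. = FALSE)
  }
  if (any(target_mafs < 0 | target_mafs > 0.5)) {
    stop("target MAFs must lie in [0, 0.5]", call. = FALSE)
  }
  if (!is.null(seed)) set.seed(seed)
  w <- step
  repeat {
    chosen <- integer(0L)
    ok <- TRUE
    for (t in target_mafs) {
      cand <- setdiff(which(abs(pool$column_mafs - t) <= w + 1e-12), chosen)
      if (!length(cand)) { ok <- FALSE; break }
      chosen <- c(chosen, if (length(cand) == 1L) cand else sample(cand, 1L))
    }
    if (ok) return(structure(chosen, window = w))
    w <- w + step
    if (w > 0.5 + 1e-12) {
      stop("no pool columns within window 0.5 of targets ",
           paste(format(target_mafs), collapse = ", "),
           "; the MAF targets are infeasible for this pool", call. = FALSE)
    }
  }
}

#' Draw a segment plan over the SNP columns
#'
#' Cuts `[1, n_snps]` into contiguous fragments whose lengths are drawn
#' uniformly from `[len_min, len_max]`, left to right; the final fragment is
#' truncated to fit. Fragments are disjoint and cover every column exactly
#' once.
#'
#' @param n_snps number of columns to cover.
#' @param len_min,len_max fragment-length bounds (default 10 and 30 SNPs).
#' @return an object of class `segment_plan` with fields `lengths` and `ends`
#'   (cumulative breakpoints).
#' @export
draw_segment_plan <- function(n_snps, len_min = 10L, len_max = 30L) {
  if (n_snps < 1L) stop("n_snps must be at least 1", call. = FALSE)
  if (len_min < 1L || len_min > len_max) {
    stop("need 1 <= len_min <= len_max", call. = FALSE)
  }
  m <- ceiling(n_snps / len_min)
  lens <- len_min + sample.int(len_max - len_min + 1L, m, replace = TRUE) - 1L
  ends <- cumsum(lens)
  cut <- which(ends >= n_snps)[1L]
  lens <- lens[seq_len(cut)]
  lens[cut] <- lens[cut] - (ends[cut] - n_snps)
  structure(list(lengths = as.integer(lens), ends = cumsum(as.integer(lens))),
            class = "segment_plan")
}

#' Resample one simulated genotype row
#'
#' For each fragment of the plan a donor row is drawn uniformly (with
#' replacement across fragments) from the pool, and the donor's genotypes at
#' exactly those columns are copied; fragments are concatenated in column
#' order.
#'
#' @param pool a [build_pool()] result.
#' @param plan a [draw_segment_plan()] whose fragments cover the pool width.
#' @return an integer vector of genotype codes, length `ncol(pool$data)`.
#' @export
resample_row <- function(pool, plan) {
  stopifnot(inherits(pool, "sampling_pool"), inherits(plan, "segment_plan"))
  width <- ncol(pool$data)
  if (plan$ends[length(plan$ends)] != width) {
    stop("segment plan covers ", plan$ends[length(plan$ends)],
         " columns but the pool has ", width, call. = FALSE)
  }
  donors <- sample.int(nrow(pool$data), length(plan$lengths), replace = TRUE)
  donor_per_col <- rep(donors, plan$lengths)
  pool$data[cbind(donor_per_col, seq_len(width))]
}

#' Generate simulated genotype rows by fragment resampling
#'
#' Each row gets a freshly drawn segment plan (donor fragments are re-cut per
#' sample) unless `shared_plan = TRUE`, in which case one plan is drawn once
#' and reused for every row. Output is fully determined by the seed.
#'
#' @param pool a [build_pool()] result.
#' @param n number of rows to generate.
#' @param len_min,len_max fragment-length bounds.
#' @param seed optional integer seed.
#' @param shared_plan reuse a single segment plan for all rows.
#' @return a [genotype_matrix()] (unlabeled) of `n` simulated samples.
#' @export
generate_rows <- function(pool, n, len_min = 10L, len_max = 30L, seed = NULL,
                          shared_plan = FALSE) {
  stopifnot(inherits(pool, "sampling_pool"), n >= 1L)
  if (!is.null(seed)) set.seed(seed)
  width <- ncol(pool$data)
  out <- matrix(0L, nrow = n, ncol = width)
  plan <- if (shared_plan) draw_segment_plan(width, len_min, len_max) else NULL
  for (i in seq_len(n)) {
    p <- if (shared_plan) plan else draw_segment_plan(width, len_min, len_max)
    out[i, ] <- resample_row(pool, p)
  }
  genotype_matrix(out, snp_ids = pool$snp_ids)
}
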