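# Case/control label generation and dataset assembly. The epistasis signal
# is injected purely through labeling: each sample's disease status is
# Bernoulli with probability equal to the penetrance of its combination
# genotype at the model loci. Genotypes are never rewritten, so all
# non-model columns stay label-independent.

#' Case probabilities and labels from a penetrance table
#'
#' Reads the combination genotype of each row at the model loci (file codes
#' 1/2/3 map to minor-allele dosages 0/1/2), looks up its penetrance
#' `P(D|g)`, and draws the label as Bernoulli with that probability.
#'
#' @param geno integer genotype matrix (or [genotype_matrix()]).
#' @param loci integer vector of K column indices of the model loci.
#' @param table a [build_penetrance_table()] result of matching order.
#' @return integer 0/1 label vector, one per row.
#' @export
label_rows <- function(geno, loci, table) {
  if (inherits(geno, "genotype_matrix")) geno <- geno$data
  stopifnot(inherits(table, "penetrance_table"))
  if (length(loci) != table$order) {
    stop("table order is ", table$order, " but ", length(loci),
         " loci were given", call. = FALSE)
  }
  if (any(loci < 1L | loci > ncol(geno))) {
    stop("model loci out of range 1..", ncol(geno), call. = FALSE)
  }
  codes <- geno[, loci, drop = FALSE] - 1L
  idx <- combo_index(codes)
  p <- table$values[idx + 1L]
  stats::rbinom(nrow(geno), 1L, p)
}

#' @rdname label_rows
#' @param row a single genotype row.
#' @export
label_row <- function(row, loci, table) {
  label_rows(matrix(as.integer(row), nrow = 1L), loci, table)
}

.new_labeled_dataset <- function(genotypes, labels, loci, table, pool) {
  structure(list(genotypes = genotype_matrix(genotypes, labels = labels,
                                             snp_ids = pool$snp_ids),
                 labels = as.integer(labels),
                 model_loci = as.integer(loci),
                 table = table),
            class = "labeled_dataset")
}

#' @export
print.labeled_dataset <- function(x, ...) {
  cat("Labeled simulated dataset:", nrow(x$genotypes$data), "samples x",
      ncol(x$genotypes$data), "SNPs;", sum(x$labels == 1L), "cases,",
      sum(x$labels == 0L), "controls\n")
  cat("Model loci (columns):", paste(x$model_loci, collapse = ", "), "\n")
  invisible(x)
}

#' Assemble a sample-balanced case-control dataset
#'
#' Candidate rows are generated by fragment resampling and labeled by the
#' penetrance table; case rows are kept until `n_cases` is reached and
#' control rows until `n_controls`, discarding overflow. Rows appear cases
#' first then controls, each group in generation order. If the quotas are
#' not met within `1000 * (n_cases + n_controls)` candidate rows (e.g. a
#' near-zero penetrance table), a quota error is raised.
#'
#' @param pool a [build_pool()] result.
#' @param table a [build_penetrance_table()] result.
#' @param loci K pool column indices of the model loci.
#' @param n_cases,n_controls required group sizes.
#' @param len_min,len_max fragment-length bounds for resampling.
#' @param seed optional integer seed.
#' @return a `labeled_dataset`.
#' @export
assemble_balanced <- function(pool, table, loci, n_cases, n_controls,
                              len_min = 10L, len_max = 30L, seed = NULL) {
  stopifnot(inherits(pool, "sampling_pool"), n_cases >= 1L, n_controls >= 1L)
  if (!is.null(seed)) set.seed(seed)
  width <- ncol(pool$data)
  cases <- matrix(0L, nrow = n_cases, ncol = width)
  controls <- matrix(0L, nrow = n_controls, ncol = width)
  got_cases <- 0L
  got_controls <- 0L
  attempts <- 0L
  max_attempts <- 1000L * (n_cases + n_controls)
  while (got_cases < n_cases || got_controls < n_controls) {
    batch <- min(max(256L, n_cases + n_controls), max_attempts - attempts)
    if (batch < 1L) {
      stop("balanced assembly used ", attempts, " candidate rows without ",
           "filling ", n_cases, " cases / ", n_controls, " controls; the ",
           "penetrance table makes one group too rare - adjust alpha, the ",
           "target, or the group sizes", call. = FALSE)
    }
    geno <- generate_rows(pool, batch, len_min, len_max)$data
    labs <- label_rows(geno, loci, table)
    attempts <- attempts + batch
    for (lab in c(1L, 0L)) {
      rows <- which(labs == lab)
      if (!length(rows)) next
      if (lab == 1L) {
        take <- min(length(rows), n_cases - got_cases)
        if (take > 0L) {
          cases[got_cases + seq_len(take), ] <- geno[rows[seq_len(take)], ]
          got_cases <- got_cases + take
        }
      } else {
        take <- min(length(rows), n_controls - got_controls)
        if (take > 0L) {
          controls[got_controls + seq_len(take), ] <- geno[rows[seq_len(take)], ]
          got_controls <- got_controls + take
        }
      }
    }
  }
  .new_labeled_dataset(rbind(cases, controls),
                       c(rep(1L, n_cases), rep(0L, n_controls)),
                       loci, table, pool)
}

#' Assemble a sample-unbalanced dataset
#'
#' Generates exactly `n_total` rows, labels each once, and keeps the natural
#' case/control proportions implied by the penetrance table.
#'
#' @inheritParams assemble_balanced
#' @param n_total number of samples to generate.
#' @return a `labeled_dataset`.
#' @export
assemble_unbalanced <- function(pool, table, loci, n_total,
                                len_min = 10L, len_max = 30L, seed = NULL) {
  stopifnot(inherits(pool, "sampling_pool"), n_total >= 1L)
  if (!is.null(seed)) set.seed(seed)
  geno <- generate_rows(pool, n_total, len_min, len_max)$data
  labs <- label_rows(geno, loci, table)
  .new_labeled_dataset(geno, labs, loci, table, pool)
}

#' Write a labeled dataset and its metadata
#'
#' The dataset file is comma-separated with a header of SNP ids plus a final
#' `label` column, one sample per row, genotype codes 1/2/3. A companion
#' JSON metadata file (`<path>.meta.json` by default) records the model loci
#' (0-based column indices), the penetrance table, the achieved prevalence
#' and heritability, and a configuration echo.
#'
#' @param dataset a `labeled_dataset`.
#' @param path output path for the delimited dataset.
#' @param meta_path output path for the JSON metadata.
#' @param extra named list merged into the metadata (e.g. seed, config echo).
#' @return `path`, invisibly.
#' @export
write_dataset <- function(dataset, path,
                          meta_path = paste0(path, ".meta.json"),
                          extra = list()) {
  stopifnot(inherits(dataset, "labeled_dataset"))
  write_sampling_dataset(dataset$genotypes, path)
  tb <- dataset$table
  meta <- c(list(
    n_samples = length(dataset$labels),
    n_cases = sum(dataset$labels == 1L),
    n_controls = sum(dataset$labels == 0L),
    n_snps = ncol(dataset$genotypes$data),
    order = tb$order,
    model_loci_0based = dataset$model_loci - 1L,
    alpha = tb$alpha,
    f = tb$f,
    mafs = tb$mafs,
    normalized = tb$normalized,
    achieved_prevalence = prevalence(tb),
    achieved_heritability = heritability(tb),
    penetrance = as.list(stats::setNames(tb$values, tb$labels))
  ), extra)
  jsonlite::write_json(meta, meta_path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}
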