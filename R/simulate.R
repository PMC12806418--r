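# End-to-end simulation: pool building, MAF-matched locus selection,
# inverse solving of the relative penetrance, and replicate dataset
# generation, with all outputs reproducible from one seed.

#' Bundle and validate simulation parameters
#'
#' Exactly one of `prevalence` or `heritability` must be given as the target
#' used to solve the relative penetrance f. The model may be supplied as an
#' [eme_model()], a model-file path, or a canonical family name plus order.
#'
#' @param model an [eme_model()], a path to a model CSV, or one of
#'   `"additive"`, `"multiplicative"`, `"threshold"`.
#' @param order model order K; required when `model` is a family name.
#' @param alpha baseline penetrance, strictly in (0, 1).
#' @param prevalence,heritability the population target; give exactly one,
#'   strictly in (0, 1).
#' @param mafs K target MAFs used to select the model loci from the pool.
#' @param n_cases,n_controls group sizes for balanced output.
#' @param n_total total samples for unbalanced output (used when
#'   `balanced = FALSE`; defaults to `n_cases + n_controls`).
#' @param n_snps number of SNP columns to draw into the pool (default all).
#' @param n_datasets number of replicate datasets.
#' @param balanced produce sample-balanced (`TRUE`) or natural-proportion
#'   output.
#' @param len_min,len_max resampling fragment-length bounds.
#' @param normalize_mode penetrance rescaling mode, see [normalize_table()].
#' @param seed integer master seed; replicate r uses `seed + r`.
#' @param output_dir directory for output files, or `NULL` to return objects
#'   only.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(model, order = NULL, alpha,
                              prevalence = NULL, heritability = NULL,
                              mafs, n_cases = 1000L, n_controls = 1000L,
                              n_total = NULL, n_snps = NULL, n_datasets = 1L,
                              balanced = TRUE, len_min = 10L, len_max = 30L,
                              normalize_mode = c("one_plus_max", "max"),
                              seed = 1L, output_dir = NULL) {
  normalize_mode <- match.arg(normalize_mode)
  if (is.character(model) && length(model) == 1L &&
      model %in% c("additive", "multiplicative", "threshold")) {
    if (is.null(order)) stop("order K is required with a canonical model type",
                             call. = FALSE)
    model <- canonical_model(model, order)
  } else if (is.character(model) && length(model) == 1L) {
    model <- read_model_file(model)
  }
  stopifnot(inherits(model, "eme_model"))
  if (!is.null(prevalence) && !is.null(heritability)) {
    stop("give either a prevalence target or a heritability target, not both",
         call. = FALSE)
  }
  if (is.null(prevalence) && is.null(heritability)) {
    stop("one of prevalence or heritability must be given as the target",
         call. = FALSE)
  }
  target_mode <- if (is.null(heritability)) "prevalence" else "heritability"
  target_value <- if (is.null(heritability)) prevalence else heritability
  if (target_value <= 0 || target_value >= 1) {
    stop("the ", target_mode, " target must lie strictly in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1)", call. = FALSE)
  }
  if (length(mafs) != model$order) {
    stop("model order is ", model$order, " but ", length(mafs),
         " target MAFs were given", call. = FALSE)
  }
  if (is.null(n_total)) n_total <- n_cases + n_controls
  stopifnot(n_cases >= 1L, n_controls >= 1L, n_total >= 1L, n_datasets >= 1L,
            len_min >= 1L, len_min <= len_max)
  structure(list(model = model, alpha = alpha, target_mode = target_mode,
                 target_value = target_value, mafs = as.numeric(mafs),
                 n_cases = as.integer(n_cases),
                 n_controls = as.integer(n_controls),
                 n_total = as.integer(n_total),
                 n_snps = if (is.null(n_snps)) NULL else as.integer(n_snps),
                 n_datasets = as.integer(n_datasets),
                 balanced = isTRUE(balanced),
                 len_min = as.integer(len_min), len_max = as.integer(len_max),
                 normalize_mode = normalize_mode,
                 seed = as.integer(seed), output_dir = output_dir),
            class = "simulation_config")
}

#' Run the full simulation pipeline
#'
#' Stages, all driven by `config$seed`:
#' \enumerate{
#'   \item build the sampling pool from control rows of `sampling` and a
#'     random column subset of size `n_snps`;
#'   \item select the K model loci by MAF matching against `config$mafs`;
#'     the actual pool MAFs of the selected columns (not the requested
#'     targets) are used for all combination-genotype frequencies;
#'   \item solve the relative penetrance f against the prevalence or
#'     heritability target and finalize the penetrance table (rescaled into
#'     `[0,1)` if any cell exceeds 1);
#'   \item generate `n_datasets` replicate labeled datasets, replicate r
#'     seeded with `seed + r` so each is reproducible on its own.
#' }
#' When `config$output_dir` is set, each replicate is written as
#' `dataset_<r>.csv` (+ `.meta.json`) together with one `model.csv`
#' penetrance file.
#'
#' @param config a [simulation_config()].
#' @param sampling a [genotype_matrix()] with labels, or a path readable by
#'   [read_sampling_dataset()].
#' @return a list with elements `pool`, `loci`, `f`, `table`,
#'   `achieved_prevalence`, `achieved_heritability`, and `datasets` (a list
#'   of `labeled_dataset`s), invisibly.
#' @export
run_simulation <- function(config, sampling) {
  stopifnot(inherits(config, "simulation_config"))
  if (is.character(sampling)) sampling <- read_sampling_dataset(sampling)
  stopifnot(inherits(sampling, "genotype_matrix"))

  set.seed(config$seed)
  pool <- build_pool(sampling, n_snps = config$n_snps)
  loci <- match_loci_by_maf(pool, config$mafs)
  locus_mafs <- pool$column_mafs[loci]
  if (any(locus_mafs <= 0)) {
    stop("a selected model locus is monomorphic in the pool (MAF 0); ",
         "raise the MAF targets or enlarge the pool", call. = FALSE)
  }

  f <- switch(config$target_mode,
    prevalence = solve_f_given_prevalence(config$model, config$alpha,
                                          config$target_value, locus_mafs),
    heritability = solve_f_given_heritability(config$model, config$alpha,
                                              config$target_value, locus_mafs))
  table <- build_penetrance_table(config$model, config$alpha, f, locus_mafs,
                                  normalize_mode = config$normalize_mode)

  out_dir <- config$output_dir
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    write_penetrance_file(table, file.path(out_dir, "model.csv"),
                          target_mode = config$target_mode,
                          target_value = config$target_value, loci = loci)
  }

  datasets <- vector("list", config$n_datasets)
  for (r in seq_len(config$n_datasets)) {
    rep_seed <- config$seed + r
    ds <- if (config$balanced) {
      assemble_balanced(pool, table, loci, config$n_cases, config$n_controls,
                        config$len_min, config$len_max, seed = rep_seed)
    } else {
      assemble_unbalanced(pool, table, loci, config$n_total,
                          config$len_min, config$len_max, seed = rep_seed)
    }
    datasets[[r]] <- ds
    if (!is.null(out_dir)) {
      write_dataset(ds, file.path(out_dir, sprintf("dataset_%d.csv", r)),
                    extra = list(seed = config$seed, replicate = r,
                                 replicate_seed = rep_seed,
                                 target_mode = config$target_mode,
                                 target_value = config$target_value,
                                 balanced = config$balanced,
                                 len_min = config$len_min,
                                 len_max = config$len_max))
    }
  }

  invisible(list(pool = pool, loci = loci, f = f, table = table,
                 achieved_prevalence = prevalence(table),
                 achieved_heritability = heritability(table),
                 datasets = datasets))
}
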