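# Penetrance-table construction and the prevalence/heritability inverse
# problem. Genotype frequencies follow Hardy-Weinberg equilibrium and loci
# are assumed in linkage equilibrium, so the frequency of a combination
# genotype is the product of per-locus genotype frequencies.

#' Hardy-Weinberg genotype frequencies for one SNP
#'
#' For a minor-allele frequency m, returns the genotype frequencies
#' \eqn{((1-m)^2,\; 2m(1-m),\; m^2)} of (AA, Aa, aa).
#'
#' @param maf minor-allele frequency in `[0, 0.5]`.
#' @return named numeric vector `c(q_AA, q_Aa, q_aa)` summing to 1.
#' @examples
#' genotype_frequencies(0.2) # 0.64 0.32 0.04
#' @export
genotype_frequencies <- function(maf) {
  stopifnot(is.numeric(maf), length(maf) == 1L)
  if (is.na(maf) || maf < 0 || maf > 0.5) {
    stop("MAF must lie in [0, 0.5], got ", maf, call. = FALSE)
  }
  c(q_AA = (1 - maf)^2, q_Aa = 2 * maf * (1 - maf), q_aa = maf^2)
}

#' Population frequency of one combination genotype
#'
#' Under linkage equilibrium the frequency of a K-locus combination genotype
#' is the product over loci of the Hardy-Weinberg genotype frequency picked by
#' that locus's code.
#'
#' @param codes integer vector of per-locus minor-allele codes in `{0,1,2}`.
#' @param mafs numeric vector of per-locus MAFs, same length as `codes`.
#' @return a probability.
#' @export
combo_frequency <- function(codes, mafs) {
  if (length(codes) != length(mafs)) {
    stop("codes (length ", length(codes), ") and mafs (length ", length(mafs),
         ") must have equal length", call. = FALSE)
  }
  prod(vapply(seq_along(codes),
              function(k) genotype_frequencies(mafs[k])[codes[k] + 1L],
              numeric(1L)))
}

# All 3^K combination-genotype frequencies in base-3 cell order.
# kronecker() in locus order reproduces the first-locus-most-significant
# encoding of combo_index().
all_combo_frequencies <- function(mafs) {
  qs <- lapply(mafs, genotype_frequencies)
  Reduce(kronecker, qs)
}

#' Rescale a penetrance table into [0, 1)
#'
#' When solving for f produces cells above 1, every cell is divided by
#' `1 + M` where `M` is the maximum cell value (mode `"one_plus_max"`, the
#' default) or by `M` itself (mode `"max"`). Tables already within `[0, 1]`
#' are returned unchanged. The map is monotone, so the relative ordering of
#' cells is preserved.
#'
#' @param values numeric vector of non-negative penetrance values.
#' @param mode `"one_plus_max"` or `"max"`.
#' @return numeric vector of probabilities.
#' @export
normalize_table <- function(values, mode = c("one_plus_max", "max")) {
  mode <- match.arg(mode)
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("penetrance values must be finite and non-negative before rescaling",
         call. = FALSE)
  }
  if (all(values <= 1)) return(values)
  M <- max(values)
  values / (if (mode == "one_plus_max") 1 + M else M)
}

# Raw cell values F(alpha, f) without the [0,1] rescue; errors name the cell.
.eval_model_values <- function(model, alpha, f) {
  vals <- vapply(seq_along(model$funs),
                 function(i) model$funs[[i]](alpha, f), numeric(1L))
  bad <- which(!is.finite(vals) | vals < 0)
  if (length(bad)) {
    stop("cell '", model$labels[bad[1L]], "' evaluates to ", vals[bad[1L]],
         " at alpha = ", alpha, ", f = ", f,
         "; penetrance expressions must be finite and non-negative",
         call. = FALSE)
  }
  vals
}

#' Build a penetrance table from a model at given (alpha, f, MAFs)
#'
#' Evaluates every cell expression at `x = alpha`, `y = f`. If any cell
#' exceeds 1 the whole table is rescaled by [normalize_table()] and the
#' result is flagged as `normalized` (the achieved prevalence/heritability
#' then differ from the pre-rescaling targets; see [prevalence()]).
#'
#' @param model an [eme_model()].
#' @param alpha baseline penetrance in `[0, 1]`.
#' @param f relative penetrance, non-negative.
#' @param mafs per-locus MAFs, length K, each in `(0, 0.5]`.
#' @param normalize_mode passed to [normalize_table()].
#' @return an object of class `penetrance_table` with fields `order`,
#'   `values` (length `3^K`), `labels`, `mafs`, `alpha`, `f`, `normalized`.
#' @examples
#' m <- canonical_model("threshold", 2)
#' build_penetrance_table(m, alpha = 0.084, f = 2.5, mafs = c(0.5, 0.5))
#' @export
build_penetrance_table <- function(model, alpha, f, mafs,
                                   normalize_mode = c("one_plus_max", "max")) {
  stopifnot(inherits(model, "eme_model"))
  normalize_mode <- match.arg(normalize_mode)
  if (!is.numeric(alpha) || length(alpha) != 1L || alpha < 0 || alpha > 1) {
    stop("alpha must be a probability in [0, 1]", call. = FALSE)
  }
  if (!is.numeric(f) || length(f) != 1L || f < 0 || !is.finite(f)) {
    stop("f must be a finite non-negative number", call. = FALSE)
  }
  if (length(mafs) != model$order) {
    stop("model order is ", model$order, " but ", length(mafs),
         " MAFs were given", call. = FALSE)
  }
  if (any(mafs <= 0 | mafs > 0.5)) {
    stop("per-locus MAFs must lie in (0, 0.5]", call. = FALSE)
  }
  vals <- .eval_model_values(model, alpha, f)
  normalized <- any(vals > 1)
  if (normalized) vals <- normalize_table(vals, normalize_mode)
  structure(list(order = model$order, values = vals, labels = model$labels,
                 mafs = as.numeric(mafs), alpha = alpha, f = f,
                 normalized = normalized, normalize_mode = normalize_mode),
            class = "penetrance_table")
}

#' @export
print.penetrance_table <- function(x, digits = 4, ...) {
  cat("Penetrance table, order K =", x$order,
      sprintf("(alpha = %g, f = %g%s)\n", x$alpha, x$f,
              if (x$normalized) ", rescaled into [0,1)" else ""))
  cat("Locus MAFs:", paste(format(x$mafs), collapse = ", "), "\n")
  if (x$order == 2L) {
    m <- matrix(x$values, nrow = 3L, byrow = TRUE,
                dimnames = list(.locus_genotype_labels(1L),
                                .locus_genotype_labels(2L)))
    print(round(m, digits))
  } else {
    print(data.frame(genotype = x$labels, penetrance = round(x$values, digits)),
          row.names = FALSE)
  }
  cat(sprintf("Prevalence P(D) = %.6g, heritability h2 = %.6g\n",
              prevalence(x), heritability(x)))
  invisible(x)
}

#' Disease prevalence of a penetrance table
#'
#' \eqn{P(D) = \sum_i P(D|g_i) P(g_i)} with combination-genotype frequencies
#' from Hardy-Weinberg proportions at the table's locus MAFs.
#'
#' @param table a [build_penetrance_table()] result.
#' @return a probability.
#' @export
prevalence <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  sum(table$values * all_combo_frequencies(table$mafs))
}

#' Heritability of a penetrance table
#'
#' The variance-ratio heritability
#' \eqn{h^2 = \sum_i (P(D|g_i) - P(D))^2 P(g_i) / (P(D)(1 - P(D)))}.
#'
#' @param table a [build_penetrance_table()] result with prevalence strictly
#'   between 0 and 1.
#' @return a value in `[0, 1]`.
#' @export
heritability <- function(table) {
  stopifnot(inherits(table, "penetrance_table"))
  w <- all_combo_frequencies(table$mafs)
  P <- sum(table$values * w)
  if (P <= 0 || P >= 1 - 1e-9) {
    stop("heritability is undefined at prevalence ", P, call. = FALSE)
  }
  sum((table$values - P)^2 * w) / (P * (1 - P))
}

# Raw (pre-rescaling) prevalence/heritability as functions of f: the solvers
# invert these, and the [0,1] rescue is applied only to the finalized table.
.raw_prevalence <- function(model, alpha, f, w) {
  sum(.eval_model_values(model, alpha, f) * w)
}

.raw_heritability <- function(model, alpha, f, w) {
  vals <- .eval_model_values(model, alpha, f)
  P <- sum(vals * w)
  if (P <= 0 || P >= 1) return(NA_real_)
  sum((vals - P)^2 * w) / (P * (1 - P))
}

# Bisect obj on [lo, hi] with obj(lo), obj(hi) of opposite sign.
.bisect <- function(obj, lo, hi, f_lo, f_hi, tol_x = 1e-12, tol_y = 1e-10,
                    max_iter = 200L) {
  for (i in seq_len(max_iter)) {
    mid <- (lo + hi) / 2
    f_mid <- obj(mid)
    if (is.na(f_mid)) f_mid <- f_hi # push toward the defined side
    if (abs(f_mid) <= tol_y && (hi - lo) <= tol_x * max(1, mid)) return(mid)
    if (sign(f_mid) == sign(f_lo)) {
      lo <- mid; f_lo <- f_mid
    } else {
      hi <- mid; f_hi <- f_mid
    }
    if ((hi - lo) <= tol_x * max(1, mid)) break
  }
  (lo + hi) / 2
}

#' Solve the relative penetrance f for a target prevalence
#'
#' Finds `f >= 0` such that the (pre-rescaling) prevalence of
#' `build_penetrance_table(model, alpha, f, mafs)` equals `target`. The root
#' is bracketed by doubling an upper bound from 2 (capped at `2^40`) and
#' refined by bisection. Prevalence is checked for monotonicity in f on a
#' coarse grid first; if it is non-monotone the smallest root is returned
#' with a warning.
#'
#' @param model an [eme_model()].
#' @param alpha baseline penetrance.
#' @param target target prevalence in `(0, 1)`.
#' @param mafs per-locus MAFs.
#' @return the solved f.
#' @examples
#' m <- canonical_model("threshold", 2)
#' solve_f_given_prevalence(m, alpha = 0.084, target = 0.154875,
#'                          mafs = c(0.5, 0.5)) # 2.5
#' @export
solve_f_given_prevalence <- function(model, alpha, target, mafs) {
  stopifnot(inherits(model, "eme_model"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1) {
    stop("target prevalence must lie strictly in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1) for model solving", call. = FALSE)
  }
  w <- all_combo_frequencies(mafs)
  obj <- function(f) .raw_prevalence(model, alpha, f, w) - target
  f_cap <- 2^40
  v0 <- obj(0)
  if (v0 == 0) return(0)
  hi <- 2
  v_hi <- obj(hi)
  while (sign(v_hi) == sign(v0)) {
    hi <- hi * 2
    if (hi > f_cap) {
      stop("target prevalence ", target, " is unreachable for any f in [0, 2^40]",
           call. = FALSE)
    }
    v_hi <- obj(hi)
  }
  # monotonicity screen; on non-monotone specs fall back to the smallest root
  grid <- c(0, hi * 2^seq(-20, 0, by = 0.5))
  gv <- vapply(grid, function(f) .raw_prevalence(model, alpha, f, w), numeric(1L))
  if (any(diff(gv) < -1e-12)) {
    warning("prevalence is not monotone in f for this model; returning the ",
            "smallest root", call. = FALSE)
    ov <- gv - target
    sc <- which(ov[-1L] * ov[-length(ov)] <= 0)[1L]
    return(.bisect(obj, grid[sc], grid[sc + 1L], ov[sc], ov[sc + 1L]))
  }
  .bisect(obj, 0, hi, v0, v_hi)
}

#' Solve the relative penetrance f for a target heritability
#'
#' Finds the smallest `f >= 1` (the risk-increasing branch; at `f = 1` the
#' canonical models collapse to a constant table with `h2 = 0`) such that the
#' pre-rescaling heritability of the table equals `target`. The root is
#' bracketed by a multiplicative grid scan (factor 1.05 per step, capped at
#' `2^40`) and refined by bisection; if the scan detects several crossings the
#' smallest root is returned with a warning.
#'
#' @inheritParams solve_f_given_prevalence
#' @param target target heritability in `(0, 1)`.
#' @return the solved f.
#' @export
solve_f_given_heritability <- function(model, alpha, target, mafs) {
  stopifnot(inherits(model, "eme_model"))
  if (!is.numeric(target) || length(target) != 1L || target <= 0 || target >= 1) {
    stop("target heritability must lie strictly in (0, 1)", call. = FALSE)
  }
  if (alpha <= 0 || alpha >= 1) {
    stop("alpha must lie strictly in (0, 1) for model solving", call. = FALSE)
  }
  w <- all_combo_frequencies(mafs)
  obj <- function(f) {
    h <- .raw_heritability(model, alpha, f, w)
    if (is.na(h)) NA_real_ else h - target
  }
  f_cap <- 2^40
  f <- 1
  v <- obj(f)
  brackets <- list()
  while (f < f_cap) {
    f_next <- f * 1.05
    v_next <- obj(f_next)
    if (!is.na(v) && !is.na(v_next) && sign(v) != sign(v_next)) {
      brackets[[length(brackets) + 1L]] <- c(f, f_next, v, v_next)
      if (length(brackets) > 1L) break
    }
    f <- f_next
    v <- v_next
    if (length(brackets) == 1L && f > brackets[[1L]][2L] * 4) break
  }
  if (!length(brackets)) {
    stop("target heritability ", target,
         " exceeds what this model can reach for f in [1, 2^40]", call. = FALSE)
  }
  if (length(brackets) > 1L) {
    warning("heritability crosses the target more than once; returning the ",
            "smallest root", call. = FALSE)
  }
  b <- brackets[[1L]]
  .bisect(obj, b[1L], b[2L], b[3L], b[4L])
}

#' Write a finalized penetrance table with its metadata
#'
#' The output model file is CSV with header `genotype,penetrance`, preceded by
#' `#`-comment metadata recording the model order, alpha, solved f, the
#' requested target, the achieved prevalence and heritability of the
#' finalized (possibly rescaled) table, the selected locus indices and the
#' rescaling flag.
#'
#' @param table a `penetrance_table`.
#' @param path output path.
#' @param target_mode,target_value the requested target, if any.
#' @param loci selected sampling-pool column indices, if any (reported
#'   0-based in the file).
#' @return `path`, invisibly.
#' @export
write_penetrance_file <- function(table, path, target_mode = NA_character_,
                                  target_value = NA_real_, loci = NULL) {
  stopifnot(inherits(table, "penetrance_table"))
  meta <- c(
    sprintf("# order: %d", table$order),
    sprintf("# alpha: %.17g", table$alpha),
    sprintf("# f: %.17g", table$f),
    sprintf("# target_mode: %s", target_mode),
    sprintf("# target_value: %.17g", target_value),
    sprintf("# achieved_prevalence: %.17g", prevalence(table)),
    sprintf("# achieved_heritability: %.17g", heritability(table)),
    sprintf("# mafs: %s", paste(sprintf("%.17g", table$mafs), collapse = ",")),
    sprintf("# loci_0based: %s",
            if (is.null(loci)) "NA" else paste(loci - 1L, collapse = ",")),
    sprintf("# normalized: %s (mode %s)", table$normalized, table$normalize_mode)
  )
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(meta, con)
  writeLines("genotype,penetrance", con)
  writeLines(paste(table$labels, sprintf("%.17g", table$values), sep = ","), con)
  invisible(path)
}
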