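# Epistasis model specifications (eME models: epistasis with marginal effects).
# A K-order model has one penetrance expression per combination genotype;
# cells are stored in base-3 order, first locus most significant, with
# minor-allele dosage codes 0 (AA), 1 (Aa), 2 (aa) per locus.

#' Enumerate all combination genotypes of a K-locus model
#'
#' @param order number of loci K.
#' @return a `3^K x K` integer matrix; row `i` holds the per-locus
#'   minor-allele codes (0/1/2) of the combination genotype with 0-based
#'   index `i - 1` under base-3 encoding, first locus most significant.
#' @export
combo_codes <- function(order) {
  stopifnot(is.numeric(order), length(order) == 1L, order >= 1, order == round(order))
  order <- as.integer(order)
  idx <- 0:(3L^order - 1L)
  codes <- vapply(seq_len(order),
                  function(k) (idx %/% 3L^(order - k)) %% 3L,
                  numeric(length(idx)))
  matrix(as.integer(codes), ncol = order)
}

#' 0-based table index of a combination genotype
#'
#' Inverse of [combo_codes()]: base-3 encoding with the first locus most
#' significant.
#'
#' @param codes integer vector (or matrix, one combination per row) of
#'   per-locus minor-allele codes in `{0,1,2}`.
#' @return integer 0-based index (vector for matrix input).
#' @export
combo_index <- function(codes) {
  if (is.matrix(codes)) {
    K <- ncol(codes)
    return(as.integer(codes %*% 3L^((K - 1L):0L)))
  }
  K <- length(codes)
  as.integer(sum(codes * 3L^((K - 1L):0L)))
}

.locus_genotype_labels <- function(k) {
  up <- LETTERS[k]; lo <- letters[k]
  c(paste0(up, up), paste0(up, lo), paste0(lo, lo))
}

#' Genotype label of a combination genotype
#'
#' Labels loci A, B, C, ... with per-locus genotypes written `AA` (homozygous
#' common), `Aa` (heterozygous), `aa` (homozygous minor), e.g. `AaBb`.
#'
#' @param codes integer vector of per-locus codes in `{0,1,2}`.
#' @return a character scalar.
#' @export
genotype_label <- function(codes) {
  stopifnot(all(codes %in% 0:2))
  paste0(vapply(seq_along(codes),
                function(k) .locus_genotype_labels(k)[codes[k] + 1L],
                character(1L)),
         collapse = "")
}

# "AaBb" -> c(1L, 1L); code derived from the case pattern of each letter pair
.label_to_codes <- function(label) {
  n <- nchar(label)
  if (n < 2L || n %% 2L != 0L) {
    stop("genotype label '", label, "' must pair two letters per locus", call. = FALSE)
  }
  K <- n %/% 2L
  codes <- integer(K)
  for (k in seq_len(K)) {
    pair <- substr(label, 2L * k - 1L, 2L * k)
    a <- substr(pair, 1L, 1L); b <- substr(pair, 2L, 2L)
    if (toupper(a) != toupper(b) || !grepl("^[A-Za-z]$", a)) {
      stop("genotype label '", label, "': locus ", k, " ('", pair,
           "') must repeat one letter", call. = FALSE)
    }
    upper_a <- a == toupper(a); upper_b <- b == toupper(b)
    codes[k] <- if (upper_a && upper_b) 0L else if (upper_a && !upper_b) 1L
                else if (!upper_a && !upper_b) 2L
                else stop("genotype label '", label, "': locus ", k, " ('", pair,
                          "') has lower-case before upper-case", call. = FALSE)
  }
  codes
}

#' Construct an epistasis model specification
#'
#' An `eme_model` holds, for every one of the `3^K` combination genotypes of a
#' K-locus model, a penetrance expression in `x` (baseline penetrance
#' \eqn{\alpha}) and `y` (relative penetrance \eqn{f}).
#'
#' @param order number of loci K.
#' @param expressions character vector of length `3^K` with one expression per
#'   combination genotype, in base-3 cell order (see [combo_codes()]).
#' @param labels optional genotype labels; defaults to `AA..`, `Aa..`, ...
#' @return an object of class `eme_model`.
#' @seealso [canonical_model()], [read_model_file()]
#' @export
eme_model <- function(order, expressions, labels = NULL) {
  stopifnot(order >= 1, order == round(order))
  order <- as.integer(order)
  n_cells <- 3L^order
  if (length(expressions) != n_cells) {
    stop("a ", order, "-order model needs ", n_cells, " cell expressions, got ",
         length(expressions), call. = FALSE)
  }
  codes <- combo_codes(order)
  if (is.null(labels)) {
    labels <- apply(codes, 1L, genotype_label)
  }
  if (anyDuplicated(labels)) {
    stop("duplicate genotype labels: ",
         paste(unique(labels[duplicated(labels)]), collapse = ", "), call. = FALSE)
  }
  funs <- lapply(seq_len(n_cells), function(i) {
    tryCatch(compile_penetrance_expr(expressions[[i]]),
             error = function(e) stop("cell '", labels[i], "': ",
                                      conditionMessage(e), call. = FALSE))
  })
  structure(list(order = order, labels = labels,
                 expressions = as.character(expressions), funs = funs),
            class = "eme_model")
}

#' @export
print.eme_model <- function(x, ...) {
  cat("Epistasis model (eME), order K =", x$order, "\n")
  df <- data.frame(genotype = x$labels, expression = x$expressions)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Canonical epistasis model families
#'
#' Builds the three standard marginal-effect model families at any order K.
#' With `s` the total minor-allele dosage of a combination genotype
#' (sum of per-locus codes):
#' \describe{
#'   \item{additive}{\eqn{\alpha (1 + f s)}}
#'   \item{multiplicative}{\eqn{\alpha f^s}}
#'   \item{threshold}{\eqn{\alpha} if any locus is homozygous common, else
#'     \eqn{\alpha f} — risk is raised only when every locus carries at least
#'     one minor allele.}
#' }
#'
#' @param type one of `"additive"`, `"multiplicative"`, `"threshold"`.
#' @param order number of loci K.
#' @return an [eme_model()].
#' @examples
#' canonical_model("threshold", 2)
#' @export
canonical_model <- function(type = c("additive", "multiplicative", "threshold"),
                            order = 2L) {
  type <- match.arg(type)
  codes <- combo_codes(order)
  s <- rowSums(codes)
  expressions <- switch(type,
    additive = ifelse(s == 0L, "x", sprintf("x*(1+%d*y)", s)),
    multiplicative = ifelse(s == 0L, "x", sprintf("x*y^%d", s)),
    threshold = ifelse(apply(codes == 0L, 1L, any), "x", "x*y"))
  eme_model(order, expressions)
}

#' Read an epistasis model file
#'
#' The model file is CSV with a header `genotype,expression` and one row per
#' combination genotype, e.g. `AaBb,x*y^2`. The model order K is inferred from
#' the genotype-label length (two letters per locus); the file must contain
#' exactly `3^K` distinct genotypes. Rows may appear in any order; cells are
#' stored in base-3 order.
#'
#' @param path path to the CSV file.
#' @return an [eme_model()].
#' @export
read_model_file <- function(path) {
  if (!file.exists(path)) stop("model file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, header = TRUE, comment.char = "#",
                        strip.white = TRUE, colClasses = "character")
  need <- c("genotype", "expression")
  if (!all(need %in% names(df))) {
    stop("model file must have columns 'genotype' and 'expression'; found: ",
         paste(names(df), collapse = ", "), call. = FALSE)
  }
  if (nrow(df) == 0L) stop("model file has no rows", call. = FALSE)
  codes_list <- lapply(seq_len(nrow(df)), function(i) {
    tryCatch(.label_to_codes(df$genotype[i]),
             error = function(e) stop("model file row ", i, ": ",
                                      conditionMessage(e), call. = FALSE))
  })
  K <- length(codes_list[[1L]])
  lens <- lengths(codes_list)
  if (any(lens != K)) {
    stop("model file mixes genotype labels of different order (rows ",
         paste(which(lens != K), collapse = ", "), ")", call. = FALSE)
  }
  if (nrow(df) != 3L^K) {
    stop("a ", K, "-order model requires ", 3L^K, " genotype rows, found ",
         nrow(df), call. = FALSE)
  }
  idx <- vapply(codes_list, combo_index, integer(1L))
  if (anyDuplicated(idx)) {
    dup <- df$genotype[duplicated(idx)]
    stop("duplicate genotype rows in model file: ",
         paste(dup, collapse = ", "), call. = FALSE)
  }
  expressions <- character(3L^K)
  expressions[idx + 1L] <- df$expression
  eme_model(K, expressions)
}

#' Write an epistasis model file
#'
#' Writes the `genotype,expression` CSV dialect read by [read_model_file()].
#'
#' @param model an [eme_model()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_model_file <- function(model, path) {
  stopifnot(inherits(model, "eme_model"))
  utils::write.csv(data.frame(genotype = model$labels,
                              expression = model$expressions),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
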