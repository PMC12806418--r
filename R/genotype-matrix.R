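# Genotype matrices: rows are samples, columns are SNPs, entries are the
# codes 1 (homozygous common, AA), 2 (heterozygous, Aa), 3 (homozygous
# minor, aa). Case/control labels, when present, are 0 = control, 1 = case.

#' Construct a genotype matrix
#'
#' @param data integer matrix of genotype codes in `{1,2,3}`, samples in rows.
#' @param labels optional 0/1 vector (0 = control, 1 = case), one per row.
#' @param snp_ids optional column identifiers.
#' @return an object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(data, labels = NULL, snp_ids = NULL) {
  data <- as.matrix(data)
  storage.mode(data) <- "integer"
  bad <- which(!(data %in% c(1L, 2L, 3L)))
  if (length(bad)) {
    i <- arrayInd(bad[1L], dim(data))
    stop("genotype code ", data[bad[1L]], " at row ", i[1L], ", column ", i[2L],
         " is not in {1, 2, 3}", call. = FALSE)
  }
  if (!is.null(labels)) {
    labels <- as.integer(labels)
    if (length(labels) != nrow(data)) {
      stop("labels must have one entry per sample row", call. = FALSE)
    }
    if (any(!labels %in% c(0L, 1L))) {
      stop("labels must be 0 (control) or 1 (case)", call. = FALSE)
    }
  }
  if (is.null(snp_ids)) {
    snp_ids <- colnames(data)
    if (is.null(snp_ids)) snp_ids <- paste0("snp", seq_len(ncol(data)))
  }
  colnames(data) <- snp_ids
  structure(list(data = data, labels = labels, snp_ids = snp_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("Genotype matrix:", nrow(x$data), "samples x", ncol(x$data), "SNPs")
  if (!is.null(x$labels)) {
    cat(sprintf(" (%d cases, %d controls)", sum(x$labels == 1L),
                sum(x$labels == 0L)))
  }
  cat("\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$data)

#' Read a sampling SNP dataset
#'
#' Reads a delimited text file (comma or tab, auto-detected; optional header)
#' of genotype codes 1/2/3, one sample per row and one SNP per column.
#' Case/control labels are taken from a column named `label` or `class`
#' (any case) if present, or from a companion single-column file via
#' `label_path`.
#'
#' @param path path to the delimited genotype file.
#' @param label_path optional path to a one-column 0/1 label file.
#' @return a [genotype_matrix()].
#' @export
read_sampling_dataset <- function(path, label_path = NULL) {
  if (!file.exists(path)) stop("sampling dataset not found: ", path, call. = FALSE)
  dt <- data.table::fread(path, header = "auto", data.table = FALSE)
  labels <- NULL
  lab_col <- which(tolower(names(dt)) %in% c("label", "class"))
  if (length(lab_col)) {
    labels <- dt[[lab_col[1L]]]
    dt <- dt[, -lab_col[1L], drop = FALSE]
  }
  if (!is.null(label_path)) {
    if (!is.null(labels)) {
      stop("labels found both in '", path, "' and in label file '", label_path,
           "'", call. = FALSE)
    }
    labels <- data.table::fread(label_path, header = FALSE,
                                data.table = FALSE)[[1L]]
  }
  snp_ids <- if (all(grepl("^V[0-9]+$", names(dt)))) NULL else names(dt)
  genotype_matrix(as.matrix(dt), labels = labels, snp_ids = snp_ids)
}

#' Write a genotype matrix as a delimited dataset
#'
#' Comma-separated, with a header of SNP ids and, when labels are present, a
#' final `label` column. [read_sampling_dataset()] round-trips this format.
#'
#' @param gm a [genotype_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_sampling_dataset <- function(gm, path) {
  stopifnot(inherits(gm, "genotype_matrix"))
  df <- data.table::as.data.table(gm$data)
  data.table::setnames(df, gm$snp_ids)
  if (!is.null(gm$labels)) df[["label"]] <- gm$labels
  data.table::fwrite(df, path)
  invisible(path)
}

#' Minor-allele frequency of a genotype-code vector
#'
#' The minor-allele count of a sample is its code minus 1 (0, 1 or 2 copies),
#' so MAF = sum(code - 1) / (2 n). If the coded allele turns out to be the
#' major one (frequency above 0.5) the value is folded to `1 - MAF` and the
#' returned value carries the attribute `flipped = TRUE`.
#'
#' @param column integer vector of genotype codes in `{1,2,3}`.
#' @return the MAF in `[0, 0.5]`, with a logical attribute `flipped`.
#' @examples
#' compute_maf(c(1L, 2L, 3L, 2L)) # 0.5
#' @export
compute_maf <- function(column) {
  if (!length(column)) stop("cannot compute a MAF from an empty column", call. = FALSE)
  if (any(!column %in% c(1L, 2L, 3L))) {
    stop("genotype codes must be in {1, 2, 3}", call. = FALSE)
  }
  p <- sum(column - 1L) / (2 * length(column))
  flipped <- p > 0.5
  if (flipped) p <- 1 - p
  structure(p, flipped = flipped)
}

# Vectorized per-column MAFs; returns list(maf = numeric, flipped = logical)
.column_mafs <- function(data) {
  p <- colSums(data - 1L) / (2 * nrow(data))
  flipped <- p > 0.5
  p[flipped] <- 1 - p[flipped]
  list(maf = unname(p), flipped = unname(flipped))
}
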