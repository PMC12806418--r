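# Independent brute-force oracles: explicit loops over all 3^K combination
# genotypes, never touching the package's vectorized paths.

oracle_combo_freq <- function(codes, mafs) {
  fr <- 1
  for (k in seq_along(codes)) {
    m <- mafs[k]
    q <- c((1 - m)^2, 2 * m * (1 - m), m^2)
    fr <- fr * q[codes[k] + 1]
  }
  fr
}

# values indexed base-3, first locus most significant (the table convention)
oracle_prevalence <- function(values, mafs) {
  K <- length(mafs)
  P <- 0
  for (i in 0:(3^K - 1)) {
    codes <- integer(K)
    rem <- i
    for (k in K:1) {
      codes[k] <- rem %% 3
      rem <- rem %/% 3
    }
    P <- P + values[i + 1] * oracle_combo_freq(codes, mafs)
  }
  P
}

oracle_heritability <- function(values, mafs) {
  K <- length(mafs)
  P <- oracle_prevalence(values, mafs)
  num <- 0
  for (i in 0:(3^K - 1)) {
    codes <- integer(K)
    rem <- i
    for (k in K:1) {
      codes[k] <- rem %% 3
      rem <- rem %/% 3
    }
    num <- num + (values[i + 1] - P)^2 * oracle_combo_freq(codes, mafs)
  }
  num / (P * (1 - P))
}

# Raw (pre-rescaling) cell values of a model at (alpha, f)
raw_cell_values <- function(model, alpha, f) {
  vapply(model$funs, function(g) g(alpha, f), numeric(1))
}

# Small hand-buildable pools -------------------------------------------------

# A sampling_pool directly from a code matrix (all rows controls)
pool_from_matrix <- function(data) {
  gm <- genotype_matrix(data, labels = rep(0L, nrow(data)))
  build_pool(gm)
}

# Column of n genotype codes with an exact minor-allele count
column_with_count <- function(n, minor_alleles) {
  stopifnot(minor_alleles <= 2 * n)
  codes <- rep(1L, n)
  full <- minor_alleles %/% 2
  if (full > 0) codes[seq_len(full)] <- 3L
  if (minor_alleles %% 2 == 1) codes[full + 1] <- 2L
  codes
}

# Raw coded-allele frequency per column (no folding), computed independently
.column_mafs_for_test <- function(data) colSums(data - 1L) / (2 * nrow(data))
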