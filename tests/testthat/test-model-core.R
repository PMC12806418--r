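test_that("Hardy-Weinberg genotype frequencies are correct and guarded", {
  expect_equal(unname(genotype_frequencies(0.5)), c(0.25, 0.5, 0.25))
  expect_equal(unname(genotype_frequencies(0)), c(1, 0, 0))
  expect_equal(unname(genotype_frequencies(0.2)), c(0.64, 0.32, 0.04))
  expect_equal(sum(genotype_frequencies(0.137)), 1, tolerance = 1e-12)
  expect_error(genotype_frequencies(0.6), "MAF")
  expect_error(genotype_frequencies(-0.1), "MAF")
})

test_that("combination-genotype frequencies multiply per locus and normalize", {
  expect_equal(combo_frequency(c(0, 0), c(0.5, 0.5)), 0.0625)
  # K = 1 reduces to single-locus genotype frequencies
  for (code in 0:2) {
    expect_equal(combo_frequency(code, 0.23),
                 unname(genotype_frequencies(0.23)[code + 1]))
  }
  expect_error(combo_frequency(c(0, 1), 0.2), "equal length")
  set.seed(7)
  for (K in 1:4) {
    mafs <- runif(K, 0.02, 0.5)
    fr <- apply(combo_codes(K), 1, combo_frequency, mafs)
    expect_equal(sum(fr), 1, tolerance = 1e-12)
  }
})

test_that("combination genotypes encode and label consistently", {
  for (K in 1:3) {
    codes <- combo_codes(K)
    expect_equal(nrow(codes), 3^K)
    expect_equal(combo_index(codes), 0:(3^K - 1)) # bijective base-3 encoding
  }
  expect_equal(genotype_label(c(1, 1)), "AaBb")
  expect_equal(genotype_label(c(0, 2)), "AAbb")
})

test_that("penetrance tables evaluate cell expressions at (alpha, f)", {
  mult <- canonical_model("multiplicative", 2)
  tb <- build_penetrance_table(mult, 0.1, 1, c(0.3, 0.3))
  expect_equal(tb$values, rep(0.1, 9)) # f = 1 collapses to a constant table

  thr <- canonical_model("threshold", 2)
  tb1 <- build_penetrance_table(thr, 0.084, 2.5, c(0.5, 0.5))
  codes <- combo_codes(2)
  expected <- ifelse(apply(codes == 0, 1, any), 0.084, 0.210)
  expect_equal(tb1$values, expected, tolerance = 1e-15)
  expect_false(tb1$normalized)

  tb0 <- build_penetrance_table(mult, 0, 2, c(0.3, 0.3))
  expect_equal(tb0$values, rep(0, 9)) # alpha factors every canonical cell

  neg <- eme_model(1, c("x-y", "x", "x"))
  expect_error(build_penetrance_table(neg, 0.1, 2, 0.3), "AA")
  expect_error(build_penetrance_table(mult, 0.1, 2, c(0.3, 0.3, 0.3)), "MAF")
})

test_that("tables exceeding 1 are rescaled monotonically into [0, 1)", {
  expect_equal(normalize_table(c(0.5, 1.2)), c(0.5, 1.2) / 2.2)
  expect_equal(normalize_table(c(0.2, 0.9)), c(0.2, 0.9)) # untouched when <= 1
  expect_equal(normalize_table(c(0.5, 1.2), mode = "max"), c(0.5 / 1.2, 1))
  expect_error(normalize_table(c(-0.1, 2)), "non-negative")
  set.seed(11)
  for (i in 1:20) {
    v <- runif(9, 0, 3)
    out <- normalize_table(v)
    expect_equal(which.max(out), which.max(v)) # order preserved
    expect_true(all(out >= 0 & out < 1) || all(v <= 1))
  }
  # build_penetrance_table applies the rescue and flags it
  mult <- canonical_model("multiplicative", 2)
  tb <- build_penetrance_table(mult, 0.5, 3, c(0.4, 0.4))
  expect_true(tb$normalized)
  expect_true(all(tb$values >= 0 & tb$values < 1))
  expect_equal(tb$values, (0.5 * 3^rowSums(combo_codes(2))) / (1 + 0.5 * 81))
})

test_that("prevalence and heritability match the brute-force oracle", {
  thr <- canonical_model("threshold", 2)
  tb1 <- build_penetrance_table(thr, 0.084, 2.5, c(0.5, 0.5))
  expect_equal(prevalence(tb1), 0.154875, tolerance = 1e-12)
  expect_equal(heritability(tb1), oracle_heritability(tb1$values, c(0.5, 0.5)),
               tolerance = 1e-12)
  expect_equal(heritability(tb1), 0.029849661, tolerance = 1e-7)

  const <- build_penetrance_table(canonical_model("multiplicative", 2),
                                  0.1, 1, c(0.2, 0.4))
  expect_equal(prevalence(const), 0.1)
  expect_equal(heritability(const), 0)

  # vectorized summaries equal naive enumeration for K up to 4
  set.seed(42)
  for (K in 1:4) {
    mafs <- runif(K, 0.05, 0.5)
    tb <- build_penetrance_table(canonical_model("multiplicative", K),
                                 runif(1, 0.01, 0.1), runif(1, 1.1, 2), mafs)
    expect_equal(prevalence(tb), oracle_prevalence(tb$values, mafs),
                 tolerance = 1e-12)
    expect_equal(heritability(tb), oracle_heritability(tb$values, mafs),
                 tolerance = 1e-12)
    expect_true(heritability(tb) >= 0 && heritability(tb) <= 1)
  }

  ones <- build_penetrance_table(eme_model(1, rep("x", 3)), 1, 1, 0.3)
  expect_error(heritability(ones), "undefined")
})

test_that("model files parse, validate, and round-trip", {
  thr <- canonical_model("threshold", 2)
  path <- withr::local_tempfile(fileext = ".csv")
  write_model_file(thr, path)
  back <- read_model_file(path)
  expect_equal(back$expressions, thr$expressions)
  expect_equal(back$labels, thr$labels)

  # rows may come in any order; cells land by genotype label
  shuffled <- withr::local_tempfile(fileext = ".csv")
  df <- data.frame(genotype = thr$labels, expression = thr$expressions)
  set.seed(3)
  write.csv(df[sample(nrow(df)), ], shuffled, row.names = FALSE, quote = FALSE)
  expect_equal(read_model_file(shuffled)$expressions, thr$expressions)

  f <- compile_penetrance_expr("x*y^3")
  expect_equal(f(0.1, 2), 0.8)
  expect_error(compile_penetrance_expr("x*z"), "only 'x'")
  expect_error(compile_penetrance_expr("system('ls')"), "disallowed")

  eight <- withr::local_tempfile(fileext = ".csv")
  write.csv(df[1:8, ], eight, row.names = FALSE, quote = FALSE)
  expect_error(read_model_file(eight), "9 genotype rows")

  dup <- withr::local_tempfile(fileext = ".csv")
  df2 <- df; df2$genotype[2] <- df2$genotype[1]
  write.csv(df2, dup, row.names = FALSE, quote = FALSE)
  expect_error(read_model_file(dup), "duplicate")
})

test_that("canonical model families have their stated structure", {
  add1 <- build_penetrance_table(canonical_model("additive", 1), 0.1, 0.5, 0.3)
  expect_equal(add1$values, c(0.1, 0.15, 0.2))

  # multiplicative: penetrance depends only on s with constant adjacent ratio f
  m3 <- canonical_model("multiplicative", 3)
  vals <- raw_cell_values(m3, 0.07, 1.8)
  s <- rowSums(combo_codes(3))
  expect_equal(vals, 0.07 * 1.8^s, tolerance = 1e-14)

  thr <- build_penetrance_table(canonical_model("threshold", 2),
                                0.084, 2.5, c(0.5, 0.5))
  expect_equal(sort(unique(thr$values)), c(0.084, 0.210))

  expect_error(canonical_model("dominant", 2))
})

test_that("f solves from a prevalence target by bracketing and bisection", {
  thr <- canonical_model("threshold", 2)
  f <- solve_f_given_prevalence(thr, 0.084, 0.154875, c(0.5, 0.5))
  expect_equal(f, 2.5, tolerance = 1e-8)

  mult <- canonical_model("multiplicative", 2)
  expect_equal(solve_f_given_prevalence(mult, 0.1, 0.1, c(0.3, 0.3)), 1,
               tolerance = 1e-8) # target = alpha gives the constant table

  # threshold at f = 0 already has prevalence 0.0875 > 0.05: unreachable
  expect_error(solve_f_given_prevalence(thr, 0.2, 0.05, c(0.5, 0.5)),
               "unreachable")
  expect_error(solve_f_given_prevalence(thr, 0.2, 1.2, c(0.5, 0.5)), "\\(0, 1\\)")
})

test_that("f solves from a heritability target on the risk-increasing branch", {
  thr <- canonical_model("threshold", 2)
  h <- oracle_heritability(raw_cell_values(thr, 0.084, 2.5), c(0.5, 0.5))
  expect_equal(solve_f_given_heritability(thr, 0.084, h, c(0.5, 0.5)), 2.5,
               tolerance = 1e-8)

  # near-zero target lands near the constant table at f = 1
  f0 <- solve_f_given_heritability(thr, 0.1, 1e-8, c(0.3, 0.3))
  expect_lt(abs(f0 - 1), 0.01)

  expect_error(solve_f_given_heritability(thr, 0.95, 0.999, c(0.5, 0.5)),
               "exceeds")
})

test_that("solver round-trips recover f across model families and orders", {
  set.seed(19)
  for (type in c("additive", "multiplicative", "threshold")) {
    for (K in 2:3) {
      model <- canonical_model(type, K)
      for (rep in 1:4) {
        repeat { # redraw until both targets are valid probabilities
          alpha <- runif(1, 0.01, 0.3)
          f_true <- runif(1, 1.1, 5)
          mafs <- runif(K, 0.05, 0.5)
          vals <- raw_cell_values(model, alpha, f_true)
          P <- oracle_prevalence(vals, mafs)
          if (P >= 0.999) next
          h <- oracle_heritability(vals, mafs)
          if (h < 0.999) break
        }
        expect_equal(solve_f_given_prevalence(model, alpha, P, mafs), f_true,
                     tolerance = 1e-8)
        expect_equal(solve_f_given_heritability(model, alpha, h, mafs), f_true,
                     tolerance = 1e-8)
      }
    }
  }
})

test_that("heritability vanishes at the constant-table limit of each family", {
  mafs <- c(0.25, 0.4)
  for (type in c("multiplicative", "threshold")) {
    vals <- raw_cell_values(canonical_model(type, 2), 0.1, 1 + 1e-9)
    expect_lt(oracle_heritability(vals, mafs), 1e-12)
  }
  # the additive family is constant at f = 0 instead
  vals <- raw_cell_values(canonical_model("additive", 2), 0.1, 1e-9)
  expect_lt(oracle_heritability(vals, mafs), 1e-12)
})

test_that("prevalence is monotone in f for the canonical families", {
  mafs <- c(0.2, 0.35)
  for (type in c("additive", "multiplicative", "threshold")) {
    model <- canonical_model(type, 2)
    prev <- vapply(seq(0, 6, by = 0.25),
                   function(f) oracle_prevalence(raw_cell_values(model, 0.05, f),
                                                 mafs),
                   numeric(1))
    expect_true(all(diff(prev) >= -1e-14))
  }
})

test_that("penetrance files carry achieved population summaries", {
  thr <- canonical_model("threshold", 2)
  tb <- build_penetrance_table(thr, 0.084, 2.5, c(0.5, 0.5))
  path <- withr::local_tempfile(fileext = ".csv")
  write_penetrance_file(tb, path, target_mode = "prevalence",
                        target_value = 0.154875, loci = c(3L, 7L))
  lines <- readLines(path)
  expect_true(any(grepl("achieved_prevalence: 0.154875", lines)))
  expect_true(any(grepl("loci_0based: 2,6", lines)))
  body <- read.csv(path, comment.char = "#")
  expect_equal(body$penetrance, tb$values, tolerance = 1e-15)
  expect_equal(body$genotype, tb$labels)
})
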