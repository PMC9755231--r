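test_that("Type-I pairs are per-sample across-OTU moments, zeros dropped", {
  counts <- make_counts(cbind(c(1, 2, 3), c(5, 5, 5), c(0, 0, 0)))
  mv <- type1_mean_variance(counts)
  expect_equal(mv$level, "type_I")
  # [1,2,3] -> M=2, V = (1+0+1)/2 = 1
  expect_equal(mv$pairs$M, 2)
  expect_equal(mv$pairs$V, 1)
  expect_equal(mv$pairs$unit_id, "S1")
  # constant column (V=0) and all-zero column (M=0) are dropped and counted
  expect_equal(mv$n_dropped, 2L)
  expect_error(type1_mean_variance(counts[1, , drop = FALSE]), ">= 2 OTUs")
})

test_that("Type-III pairs are per-OTU across-sample moments, zeros dropped", {
  counts <- make_counts(rbind(c(1, 3), c(0, 0), c(4, 4)))
  mv <- type3_mean_variance(counts)
  expect_equal(mv$level, "type_III")
  # OTU row [1,3] -> M=2, V = ((1)^2+(1)^2)/1 = 2
  expect_equal(mv$pairs$M, 2)
  expect_equal(mv$pairs$V, 2)
  expect_equal(mv$n_dropped, 2L)
  expect_error(type3_mean_variance(counts[, 1, drop = FALSE]), ">= 2 samples")
})

test_that("population-variance option uses the n denominator", {
  counts <- make_counts(cbind(c(1, 2, 3)), samples = "S1")
  mv <- type1_mean_variance(counts, variance = "population")
  expect_equal(mv$pairs$V, 2 / 3)
})

test_that("subsetting a Type-I set equals filtering the full result", {
  set.seed(11)
  counts <- make_counts(matrix(rpois(200, 10), nrow = 20))
  full <- type1_mean_variance(counts)
  sub <- type1_mean_variance(counts, sample_subset = c("S3", "S7"))
  keep <- full$pairs[full$pairs$unit_id %in% c("S3", "S7"), ]
  rownames(keep) <- NULL
  expect_equal(sub$pairs[order(sub$pairs$unit_id), ],
               keep[order(keep$unit_id), ])
})

test_that("fit_ple recovers exact log-linear relations and matches the oracle", {
  # identity line V = M
  f <- fit_ple(mv_from_pairs(c(1, 2, 4), c(1, 2, 4)))
  expect_equal(f$b, 1, tolerance = 1e-12)
  expect_equal(f$ln_a, 0, tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # V = 2 M^2
  f <- fit_ple(mv_from_pairs(c(1, 2, 4), c(2, 8, 32)))
  expect_equal(f$b, 2, tolerance = 1e-12)
  expect_equal(f$ln_a, log(2), tolerance = 1e-12)
  expect_equal(f$r_squared, 1, tolerance = 1e-12)

  # exact recovery over random exact relations
  set.seed(5)
  for (i in 1:25) {
    b <- runif(1, 0.2, 3); lna <- runif(1, -2, 2)
    M <- exp(runif(8, 0, 4))
    f <- fit_ple(mv_from_pairs(M, exp(lna) * M^b))
    expect_equal(f$b, b, tolerance = 1e-9)
    expect_equal(f$ln_a, lna, tolerance = 1e-9)
    expect_equal(f$r_squared, 1, tolerance = 1e-9)
  }

  # noisy points: slope/intercept equal the closed-form normal equations
  set.seed(6)
  for (i in 1:25) {
    M <- exp(runif(10, 0, 4))
    V <- exp(runif(10, 0, 6))
    f <- fit_ple(mv_from_pairs(M, V))
    o <- ols_oracle(log(M), log(V))
    expect_equal(f$b, o$slope, tolerance = 1e-10)
    expect_equal(f$ln_a, o$intercept, tolerance = 1e-10)
    expect_equal(f$r_squared, o$r2, tolerance = 1e-10)
    expect_true(f$b_ci[1] <= f$b && f$b <= f$b_ci[2])
    expect_true(f$r_squared >= 0 && f$r_squared <= 1)
  }

  expect_error(fit_ple(mv_from_pairs(c(1, 2), c(1, 2))), "insufficient")
})

test_that("fits are invariant to row/column permutation and scale-covariant", {
  set.seed(8)
  counts <- make_counts(matrix(rgamma(30 * 12, shape = 1, rate = 0.2),
                               nrow = 30))
  f0 <- fit_ple(type3_mean_variance(counts))
  perm <- counts[sample(nrow(counts)), sample(ncol(counts))]
  f1 <- fit_ple(type3_mean_variance(perm))
  expect_equal(f1$b, f0$b, tolerance = 1e-12)
  expect_equal(f1$ln_a, f0$ln_a, tolerance = 1e-12)

  # scaling abundances by c maps (M,V)->(cM, c^2 V): b fixed, ln_a shifts
  for (cc in c(0.5, 3, 10)) {
    fc <- fit_ple(type3_mean_variance(counts * cc))
    expect_equal(fc$b, f0$b, tolerance = 1e-9)
    expect_equal(fc$ln_a, f0$ln_a + (2 - f0$b) * log(cc), tolerance = 1e-9)
  }
})

test_that("heterogeneity classification follows b and its CI", {
  fake_fit <- function(b, ci) {
    structure(list(b = b, b_ci = ci, level = "type_I", group_label = "x"),
              class = "ple_fit")
  }
  expect_equal(classify_heterogeneity(fake_fit(1.8, c(1.5, 2.1)),
                                      "ci_test")$category, "aggregated")
  expect_equal(classify_heterogeneity(fake_fit(1.0, c(0.9, 1.1)),
                                      "point_estimate")$category, "random")
  expect_equal(classify_heterogeneity(fake_fit(0.6, c(0.4, 0.8)),
                                      "ci_test")$category, "uniform")
  expect_equal(classify_heterogeneity(fake_fit(1.2, c(0.9, 1.5)),
                                      "ci_test")$category, "random")
  expect_equal(classify_heterogeneity(fake_fit(0.97, c(0.9, 1.1)),
                                      "point_estimate")$category, "uniform")
})

test_that("grouped fits cover groups and report unfittable ones", {
  set.seed(9)
  counts <- make_counts(matrix(rgamma(40 * 10, 2, 0.1), nrow = 40),
                        samples = sprintf("S%d", 1:10))
  meta <- make_meta(sprintf("S%d", 1:10),
                    species = rep(c("A", "B"), each = 5))
  study <- join_tables(counts, meta)

  fits <- grouped_fits(study, level = "type_III", group_by = "host_species")
  expect_setequal(names(fits), c("A", "B"))
  expect_equal(fits$A$group_label, "A")

  one <- grouped_fits(study, level = "type_I", group_by = "all")
  expect_equal(names(one), "all")
  expect_equal(one$all$n_points, 10L)

  # a species with a single sample cannot support Type-III variance
  meta2 <- make_meta(sprintf("S%d", 1:10),
                     species = c(rep("A", 9), "C"))
  study2 <- join_tables(counts, meta2)
  fits2 <- grouped_fits(study2, level = "type_III", group_by = "host_species")
  expect_equal(attr(fits2, "skipped")$group_label, "C")
  expect_equal(names(fits2), "A")
})
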