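test_that("community specs validate their invariants", {
  expect_error(ple_community_spec(2, 10, seed = 1), "n_samples")
  expect_error(ple_community_spec(10, 2, seed = 1), "n_otus")
  expect_error(ple_community_spec(10, 10, mean_range = c(-1, 5), seed = 1),
               "mean_range")
  expect_error(ple_community_spec(10, 10), "seed")
  spec <- ple_community_spec(3, 3, seed = 1)
  tab <- simulate_community(spec)
  expect_identical(dim(tab), c(3L, 3L))
  expect_silent(validate_otu_table <- tplext:::validate_otu_table(tab))
})

test_that("simulation is deterministic under a fixed seed and level-checked", {
  spec <- ple_community_spec(10, 20, target_b = 1.5, family = "power_law_gamma",
                             seed = 99, level_target = "type_III")
  expect_identical(simulate_mixed_population(spec),
                   simulate_mixed_population(spec))
  expect_error(simulate_community(spec), "type_I")
})

test_that("gamma draws match the targeted per-unit moments", {
  # moment fidelity: one OTU observed many times
  spec <- ple_community_spec(n_samples = 10000, n_otus = 3, target_b = 1.8,
                             target_ln_a = 0.5, mean_range = c(5, 50),
                             family = "power_law_gamma",
                             level_target = "type_III", seed = 17)
  tab <- simulate_mixed_population(spec)
  set.seed(17)
  M <- exp(runif(3, log(5), log(50)))   # the means the generator drew
  V <- exp(0.5) * M^1.8
  for (j in 1:3) {
    expect_equal(mean(tab[j, ]), M[j], tolerance = 0.05)
    expect_equal(var(tab[j, ]), V[j], tolerance = 0.1)
  }
})

test_that("fitted slopes recover the generating exponent", {
  spec <- ple_community_spec(100, 500, target_b = 2, target_ln_a = 0,
                             family = "power_law_gamma",
                             level_target = "type_III", seed = 4)
  fit <- fit_ple(type3_mean_variance(simulate_mixed_population(spec)))
  expect_gt(fit$b, 1.9)
  expect_lt(fit$b, 2.1)

  # Type-I gamma generator recovers its target too
  spec1 <- ple_community_spec(100, 500, target_b = 1.8, target_ln_a = 0,
                              family = "power_law_gamma",
                              level_target = "type_I", seed = 5)
  fit1 <- fit_ple(type1_mean_variance(simulate_community(spec1)))
  expect_true(fit1$b_ci[1] <= 1.8 && 1.8 <= fit1$b_ci[2])
})

test_that("negative binomial family needs overdispersion and yields integers", {
  spec <- ple_community_spec(50, 20, target_b = 2, target_ln_a = 0.2,
                             family = "negative_binomial",
                             mean_range = c(2, 50),
                             level_target = "type_III", seed = 12)
  tab <- simulate_mixed_population(spec)
  expect_true(all(tab == round(tab)))
  # V = M^b <= M for M <= 1 with b=2: infeasible for nbinom
  bad <- ple_community_spec(50, 20, target_b = 2, target_ln_a = 0,
                            family = "negative_binomial",
                            mean_range = c(0.2, 0.8),
                            level_target = "type_III", seed = 12)
  expect_error(simulate_mixed_population(bad), "V > M")
})

test_that("simulate_study builds a coherent, reproducible three-table study", {
  comm <- ple_community_spec(10, 40, target_b = 1.8, family = "power_law_gamma",
                             level_target = "type_III", seed = 1)
  sp <- list(
    ple_species_spec("Rana_a", 6, trait_mean = c(a = 12, b = 10, h = 40),
                     trait_sd = c(a = 1, b = 1, h = 3), community = comm),
    ple_species_spec("Bufo_b", 5, trait_mean = c(a = 20, b = 16, h = 70),
                     trait_sd = c(a = 2, b = 1.5, h = 5), community = comm))
  spec <- ple_study_spec(sp, n_sites = 3, seed = 31, shared_fraction = 0.5)
  study <- simulate_study(spec)
  expect_equal(ncol(study$counts), 11L)
  expect_equal(nrow(study$metadata), 11L)
  expect_length(study$taxonomy, nrow(study$counts))
  expect_true(all(study$metadata$body_length_mm >= study$metadata$head_length_mm))
  expect_true(all(study$metadata$head_width_mm > 0))
  # determinism
  expect_identical(simulate_study(spec), study)
  # round-trips through the I/O layer
  dir <- withr::local_tempdir()
  p <- file.path(dir, "otu.tsv")
  write_otu_table(study$counts, p)
  expect_equal(read_otu_table(p), study$counts, tolerance = 1e-12)
  joined <- join_tables(study$counts, study$metadata)
  expect_equal(ncol(joined$counts), 11L)

  # disjoint profiles separate the two hosts almost perfectly
  spec_dis <- ple_study_spec(sp, n_sites = 3, seed = 31, shared_fraction = 0)
  sd <- simulate_study(spec_dis)
  res <- anosim(bray_curtis(sd$counts), sd$metadata$host_species,
                n_permutations = 99, seed = 1)
  expect_gt(res$R, 0.9)
})

test_that("infeasible trait specs fail after bounded resampling", {
  comm <- ple_community_spec(10, 20, level_target = "type_III", seed = 1)
  sp <- ple_species_spec("X", 5, trait_mean = c(a = 50, b = 10, h = 5),
                         trait_sd = c(a = 0.1, b = 0.1, h = 0.1),
                         community = comm)
  spec <- ple_study_spec(list(sp), seed = 2)
  expect_error(simulate_study(spec), "h >= a")
})
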