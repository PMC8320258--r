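test_that("repertoire frequencies sum to one and respect the frequency law", {
  for (law in c("power_law", "log_normal")) {
    rep <- simulate_repertoire(
      repertoire_spec(n_clonotypes = 200, frequency_law = law, seed = 11))
    expect_equal(sum(rep$freq), 1, tolerance = 1e-12)
    expect_true(all(diff(rep$freq) <= 0))
  }
  one <- simulate_repertoire(repertoire_spec(n_clonotypes = 1, seed = 1))
  expect_equal(one$freq, 1)
})

test_that("repertoire CDR3 sequences are unique, in-frame ACGT strings", {
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 300, seed = 7))
  expect_false(anyDuplicated(rep$cdr3b_nt) > 0)
  expect_true(all(nchar(rep$cdr3b_nt) %% 3 == 0))
  expect_true(all(grepl("^[ACGT]+$", rep$cdr3b_nt)))
  expect_false(any(grepl("\\*", rep$cdr3b_aa)))
  expect_equal(rep$cdr3b_aa, tcrscreen:::translate_nt(rep$cdr3b_nt))
})

test_that("dual-alpha fraction matches the spec parameter", {
  none <- simulate_repertoire(
    repertoire_spec(n_clonotypes = 200, dual_alpha_fraction = 0, seed = 3))
  expect_equal(sum(none$dual_alpha), 0)
  expect_true(all(is.na(none$cdr3a2_nt)))

  # observed fraction within the binomial 99% CI of 1/3 at n = 3000
  rep <- simulate_repertoire(
    repertoire_spec(n_clonotypes = 3000, dual_alpha_fraction = 1 / 3,
                    seed = 5))
  ci <- qbinom(c(0.005, 0.995), 3000, 1 / 3)
  expect_gte(sum(rep$dual_alpha), ci[1])
  expect_lte(sum(rep$dual_alpha), ci[2])
})

test_that("invalid simulation parameters raise configuration errors", {
  expect_error(repertoire_spec(shape = -1), class = "tcrscreen_config_error")
  expect_error(repertoire_spec(dual_alpha_fraction = 1.2),
               class = "tcrscreen_config_error")
  expect_error(droplet_params(doublet_rate = 1),
               class = "tcrscreen_config_error")
  expect_error(droplet_params(n_cells_loaded = 100, target_recovery = 200),
               class = "tcrscreen_config_error")
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 5, seed = 1))
  expect_error(
    simulate_condition(rep, activation = activation_model(
      reactive_clonotype_ids = "NOPE"), seed = 1),
    class = "tcrscreen_config_error")
})

test_that("a noise-free condition reproduces the planted partition", {
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 1, seed = 2))
  sim <- simulate_condition(
    rep, droplet_params(target_recovery = 10, doublet_rate = 0,
                        cdr3_error_rate = 0),
    activation_model(), "stim", seed = 9)
  expect_equal(length(unique(sim$truth$barcode)), 10)
  trb <- dplyr::filter(sim$contigs, chain == "TRB", productive)
  expect_equal(unique(trb$cdr3_nt), rep$cdr3b_nt)
  cells <- sim$contigs |> filter_productive() |> group_cells()
  expect_equal(sum(cells$status == "mixed"), 0)

  # larger noise-free instance: observed partition equals planted truth
  rep2 <- simulate_repertoire(repertoire_spec(n_clonotypes = 40, seed = 4))
  sim2 <- simulate_condition(
    rep2, droplet_params(target_recovery = 200, doublet_rate = 0,
                         cdr3_error_rate = 0),
    activation_model(), "stim", seed = 10)
  cells2 <- sim2$contigs |> filter_productive() |> group_cells()
  expect_equal(sum(cells2$status == "mixed"), 0)
  key_of <- setNames(rep2$cdr3b_nt, rep2$clonotype_id)
  planted <- setNames(unname(key_of[sim2$truth$clonotype_ids]),
                      sim2$truth$barcode)
  observed <- setNames(cells2$cdr3b_nt, cells2$barcode)
  expect_equal(observed[names(planted)], planted)
})

test_that("CDR3 error process creates the expected number of artifact keys", {
  # closed form: each contig acquires >=1 substitution w.p. 1-(1-e)^L
  e <- 0.005
  L <- 36L
  rep <- simulate_repertoire(
    repertoire_spec(n_clonotypes = 20, cdr3b_length_range = c(L, L),
                    seed = 21))
  sim <- simulate_condition(
    rep, droplet_params(target_recovery = 2000, doublet_rate = 0,
                        cdr3_error_rate = e),
    activation_model(), "stim", seed = 22)
  trb <- dplyr::filter(sim$contigs, chain == "TRB", productive)
  # contigs carrying at least one substitution (distinct novel keys run a
  # little lower because independent errors can coincide on the same
  # variant)
  n_errored <- sum(!trb$cdr3_nt %in% rep$cdr3b_nt)
  p <- 1 - (1 - e)^L
  expected <- nrow(trb) * p
  se <- sqrt(nrow(trb) * p * (1 - p))
  expect_lt(abs(n_errored - expected), 3 * se)
  n_novel_keys <- length(setdiff(trb$cdr3_nt, rep$cdr3b_nt))
  expect_lte(n_novel_keys, n_errored)
  expect_gt(n_novel_keys, 0.5 * expected)
})

test_that("ambient background almost never crosses the activation threshold", {
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 100, seed = 31))
  sim <- simulate_condition(
    rep, droplet_params(target_recovery = 6000),
    activation_model(), "control", seed = 32)
  flags <- activation_call(sim$profiles |> tcrscreen:::normalize_profiles())
  # Poisson(0.05) tail beyond 5 UMIs is ~3e-9 per marker; allow < 0.1%
  expect_lt(mean(flags$activated), 0.001)
})

test_that("simulation is seed-deterministic", {
  rep <- simulate_repertoire(repertoire_spec(n_clonotypes = 30, seed = 8))
  rep2 <- simulate_repertoire(repertoire_spec(n_clonotypes = 30, seed = 8))
  expect_identical(rep, rep2)
  a <- simulate_condition(rep, droplet_params(target_recovery = 100),
                          activation_model(), "stim", seed = 12)
  b <- simulate_condition(rep, droplet_params(target_recovery = 100),
                          activation_model(), "stim", seed = 12)
  expect_identical(a, b)
})
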