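# Pooled-screen simulator: pool setup, cycle dynamics, schedule, reads,
# assay fixtures.

test_that("pool initialization is equimolar, validated and reproducible", {
  p52 <- variant_params(sprintf("V%02d", 1:52), arf = 0.01)
  st <- init_pool(p52, seed = 1)
  expect_equal(st$frequencies, rep(1 / 52, 52))
  expect_equal(st$edited_fraction, rep(0, 52))
  expect_error(init_pool(variant_params("V1", 0.01)), "two variants")
  expect_error(variant_params(c("A", "A"), 0.01), "duplicate")
  st2 <- init_pool(p52, seed = 1)
  expect_identical(st, st2)
})

test_that("the default schedule yields 11 sample points and variants count", {
  expect_equal(n_sample_points(screen_schedule()), 11)
  expect_equal(n_sample_points(screen_schedule(
    n_rounds = 1, retransform_sample = FALSE, n_pre_samples = 2)), 6)
  p <- variant_params(c("a", "b", "c"), arf = 0.01)
  st <- run_screen(p, screen_schedule(), seed = 2)
  expect_length(st$sample_log, 11)
  expect_equal(vapply(st$sample_log, `[[`, integer(1), "barcode_index"),
               1:11)
})

test_that("the whole log reproduces seed-for-seed", {
  p <- variant_params(sprintf("V%d", 1:8),
                      arf = c(0.02, 0.01, 0, 0, 0.015, 0, 0, 0.008))
  a <- run_screen(p, screen_schedule(), seed = 33)
  b <- run_screen(p, screen_schedule(), seed = 33)
  expect_identical(a$sample_log, b$sample_log)
  c2 <- run_screen(p, screen_schedule(), seed = 34)
  expect_false(identical(a$sample_log, c2$sample_log))
})

test_that("frequencies stay a simplex and inert variants die at selection", {
  p <- variant_params(c("live", "dead", "other"), arf = c(0.02, 0, 0.01))
  sch <- screen_schedule(spontaneous_resistance_p = 0)
  st <- run_screen(p, sch, seed = 3)
  fr <- screen_frequencies(st)
  expect_true(all(fr >= 0))
  expect_equal(colSums(fr), rep(1, 11), tolerance = 1e-9)
  # arf = 0 with no spontaneous resistance: exactly zero from the first
  # post-selection sample onward
  expect_true(all(fr["dead", 3:11] == 0))
  expect_true(all(fr["dead", 1:2] > 0))
})

test_that("editing gains follow the saturating action-rate closed form", {
  # deterministic expectation propagation isolates the model arithmetic
  sch <- screen_schedule(bottleneck_N = Inf, spontaneous_resistance_p = 0,
                         recovery_hours = 1)
  p <- variant_params(c("fast", "slow"), arf = 0.01, tau = c(0.05, 50))
  st <- init_pool(p, seed = 4)
  st <- run_cycle(st, p, sch)
  expected_ratio <- (1 - exp(-1 / 0.05)) / (1 - exp(-1 / 50))
  expect_equal(st$frequencies[1] / st$frequencies[2], expected_ratio,
               tolerance = 1e-9)

  # the same ratio emerges from the stochastic simulator on average
  set.seed(5)
  sch2 <- screen_schedule(bottleneck_N = 1e5,
                          spontaneous_resistance_p = 0, recovery_hours = 1)
  ratios <- replicate(60, {
    s <- init_pool(p, seed = sample.int(1e6, 1))
    s <- run_cycle(s, p, sch2)
    s$frequencies[1] / s$frequencies[2]
  })
  se <- sd(ratios) / sqrt(length(ratios))
  expect_lt(abs(mean(ratios) - expected_ratio), 3 * se + 1e-6)
})

test_that("identical variants drift around uniform and arf is monotone", {
  p <- variant_params(c("a", "b", "c", "d"), arf = 0.01, tau = 1)
  sch <- screen_schedule(bottleneck_N = 1e4)
  freqs <- vapply(1:200, function(sd) {
    run_screen(p, sch, seed = sd)$sample_log[[11]]$frequencies
  }, numeric(4))
  means <- rowMeans(freqs)
  se <- apply(freqs, 1, sd) / sqrt(200)
  expect_true(all(abs(means - 0.25) <= 3 * se + 1e-3))

  # raising one variant's arf never decreases its expected final share
  p_hi <- variant_params(c("a", "b", "c", "d"),
                         arf = c(0.015, 0.01, 0.01, 0.01), tau = 1)
  hi <- vapply(1:100, function(sd)
    run_screen(p_hi, sch, seed = sd)$sample_log[[11]]$frequencies[1],
    numeric(1))
  lo <- vapply(1:100, function(sd)
    run_screen(p, sch, seed = sd)$sample_log[[11]]$frequencies[1],
    numeric(1))
  expect_gt(mean(hi), mean(lo))
})

test_that("fast low-ARF variants overtake slow high-ARF variants at 1 h", {
  sch <- screen_schedule(recovery_hours = 1)
  p <- variant_params(c("fast", "slow"), arf = c(0.010, 0.012),
                      tau = c(0.5, 8))
  wins <- sum(vapply(1:100, function(sd) {
    fr <- screen_frequencies(run_screen(p, sch, seed = sd))
    fr["fast", 11] > fr["slow", 11]
  }, logical(1)))
  expect_gte(wins, 90)
})

test_that("plasmid dropout removes a variant before the first selection", {
  sch <- screen_schedule(bottleneck_N = 1e3)
  ids <- sprintf("V%02d", 1:52)
  p <- variant_params(ids, arf = 0.01, dropout_p = c(0.5, rep(0, 51)))
  gone <- sum(vapply(1:100, function(sd) {
    fr <- screen_frequencies(run_screen(p, sch, seed = sd))
    all(fr["V01", 1:2] == 0)
  }, logical(1)))
  expect_gte(gone, 99)
})

test_that("read emission is multinomial in the sample frequencies", {
  genes <- synth_variant_genes(n = 4, length = 400, seed = 6)
  p <- variant_params(names(genes), arf = 0.01)
  st <- init_pool(p, seed = 7)
  st <- ssapkit:::snapshot(st)

  # error-free reads are exact substrings and counts sum to depth
  reads <- generate_reads(st, genes, depth = 1000, error_rate = 0,
                          seed = 8)
  expect_equal(nrow(reads), 1000)
  idx <- sample(nrow(reads), 50)
  for (i in idx)
    expect_true(grepl(reads$sequence[i], genes[[reads$true_variant[i]]],
                      fixed = TRUE))

  # a degenerate state emits only the surviving variant
  st1 <- st
  st1$frequencies <- c(1, 0, 0, 0)
  st1$sample_log[[1]]$frequencies <- setNames(c(1, 0, 0, 0), names(genes))
  r1 <- generate_reads(st1, genes, depth = 200, error_rate = 0.05,
                       seed = 9)
  expect_true(all(r1$true_variant == names(genes)[1]))

  # mean per-variant read fraction over 50 seeds tracks the frequencies
  st2 <- st
  fr <- c(0.4, 0.3, 0.2, 0.1)
  st2$sample_log[[1]]$frequencies <- setNames(fr, names(genes))
  fracs <- vapply(1:50, function(sd) {
    r <- generate_reads(st2, genes, depth = 500, error_rate = 0,
                        seed = sd)
    as.numeric(table(factor(r$true_variant, levels = names(genes))) / 500)
  }, numeric(4))
  means <- rowMeans(fracs)
  se <- apply(fracs, 1, sd) / sqrt(50)
  expect_true(all(abs(means - fr) <= 3 * se + 1e-3))
})

test_that("CFU fixtures recover the generating ARF", {
  z <- generate_assay_fixtures(0, n_replicates = 5, seed = 10)
  expect_true(all(z$resistant_cfu[z$induced] == 0))
  o <- generate_assay_fixtures(1, n_replicates = 5, seed = 11)
  expect_true(all(o$resistant_cfu[o$induced] == o$total_cfu[o$induced]))

  arf_true <- 0.004
  f <- generate_assay_fixtures(arf_true, n_replicates = 100,
                               total_cfu = 5e4, seed = 12)
  est <- f$resistant_cfu[f$induced] / f$total_cfu[f$induced]
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - arf_true), 3 * se)
})
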