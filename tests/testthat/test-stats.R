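# ARF computation, replicate summaries, t-tests, time-course fits,
# off-target summaries.

test_that("ARF follows the ratio rule with control subtraction and clamping", {
  expect_equal(compute_arf(50, 10000), 0.5)
  expect_equal(compute_arf(30, 10000, control_arf = 0.05), 0.25)
  expect_message(z <- compute_arf(2, 10000, control_arf = 0.5), "clamped")
  expect_equal(z, 0)
  expect_error(compute_arf(1, 0), "positive")
  # scale invariance under a common dilution factor
  expect_equal(compute_arf(50, 10000), compute_arf(50 * 37, 10000 * 37))
})

test_that("replicate summaries use the n-1 denominator", {
  s <- summarize_replicates(c(1, 1, 1))
  expect_equal(s$mean, 1); expect_equal(s$sd, 0); expect_equal(s$n, 3)
  s2 <- summarize_replicates(c(10, 18))
  expect_equal(s2$sd, abs(10 - 18) / sqrt(2), tolerance = 1e-12)
  v <- c(0.43, 0.60, 0.26)
  s3 <- summarize_replicates(v)
  expect_equal(s3$mean, 0.43, tolerance = 1e-12)
  expect_equal(s3$sd, sqrt(sum((v - mean(v))^2) / 2), tolerance = 1e-12)
  expect_true(is.na(summarize_replicates(5)$sd))
  expect_error(summarize_replicates(numeric(0)))
  expect_equal(format_mean_sd(c(10, 18)), "14 ± 5.66")
})

test_that("the pooled t-test matches the closed form and the star map", {
  same <- two_tailed_t(c(1, 2, 3), c(1, 2, 3))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  expect_equal(same$stars, "")

  a <- c(1, 2, 3); b <- c(11, 12, 13)
  got <- two_tailed_t(a, b)
  want <- oracle_pooled_t(a, b)
  expect_equal(got$t, want$t, tolerance = 1e-12)
  expect_equal(got$p, want$p, tolerance = 1e-12)

  # star thresholds: p <= 0.05 *, < 0.01 **, < 0.001 ***, < 0.0001 ****
  star_of <- function(a, b) two_tailed_t(a, b)$stars
  g1 <- c(1, 2, 3); g2 <- c(3.4, 4.4, 5.4)  # p ~ 0.04
  expect_equal(oracle_pooled_t(g1, g2)$p > 0.01 &&
                 oracle_pooled_t(g1, g2)$p <= 0.05, TRUE)
  expect_equal(star_of(g1, g2), "*")
  g3 <- c(10.0, 10.1, 9.9); g4 <- c(11.0, 11.1, 10.9) # very small p
  expect_equal(star_of(g3, g4),
               if (oracle_pooled_t(g3, g4)$p < 1e-4) "****" else "***")
  expect_message(const <- two_tailed_t(c(2, 2), c(2, 2)), "convention")
  expect_equal(const$p, 1)
})

test_that("t-test decisions agree with a permutation test at alpha 0.05", {
  set.seed(81)
  agree <- 0
  for (i in 1:20) {
    shift <- sample(c(0, 0, 1.5, 3), 1)
    a <- rnorm(5); b <- rnorm(5) + shift
    t_sig <- two_tailed_t(a, b)$p <= 0.05
    p_sig <- oracle_permutation_p(a, b) <= 0.05
    if (t_sig == p_sig) agree <- agree + 1
  }
  expect_gte(agree, 18)
})

test_that("time-course fractions and the action-rate fit behave", {
  flat <- time_course_fraction(c(1, 4, 24), c(2, 2, 2))
  expect_equal(flat$fractions$fraction_of_final, rep(1, 3))
  expect_lte(flat$tau, 0.5) # immediate saturation pushes tau to the floor

  # parameter recovery: A = 1.5, tau = 3 h with 2% noise
  set.seed(82)
  t <- c(0.5, 1, 2, 3, 5, 8, 12, 24)
  y <- 1.5 * (1 - exp(-t / 3)) * (1 + rnorm(length(t), 0, 0.02))
  fit <- time_course_fraction(t, y)
  expect_lt(abs(fit$tau - 3) / 3, 0.15)

  # the published-style two-point fraction: 1.10 / 1.53
  tc <- time_course_fraction(c(1, 24), c(1.10, 1.53))
  expect_equal(tc$fractions$fraction_of_final[1], 1.10 / 1.53,
               tolerance = 1e-9)
  expect_error(time_course_fraction(c(1, 24), c(1, 0)), "final ARF")
})

test_that("off-target counts subtract the parental set and the intended edit", {
  parental <- data.frame(position = c(100, 200), ref = c("A", "C"),
                         alt = c("G", "T"), stringsAsFactors = FALSE)
  ontarget <- data.frame(position = 555, ref = "A", alt = "C",
                         stringsAsFactors = FALSE)
  same <- cbind(colony_id = "c1", parental)
  expect_equal(offtarget_summary(same, parental)$per_colony$off_target, 0)

  extras <- data.frame(position = c(300, 400, 500), ref = "G", alt = "A",
                       stringsAsFactors = FALSE)
  colony <- rbind(cbind(colony_id = "c1", parental),
                  cbind(colony_id = "c1", ontarget),
                  cbind(colony_id = "c1", extras))
  out <- offtarget_summary(colony, parental, ontarget = ontarget)
  expect_equal(out$per_colony$off_target, 3)

  two <- rbind(
    cbind(colony_id = "c1",
          data.frame(position = 1:10, ref = "A", alt = "C")),
    cbind(colony_id = "c2",
          data.frame(position = 1:18 + 100, ref = "A", alt = "C")))
  res <- offtarget_summary(two, parental)
  expect_equal(res$label, "14 ± 5.66")
})

test_that("estimated ARF sits within 3 standard errors of the truth", {
  arf_true <- 0.006
  f <- generate_assay_fixtures(arf_true, n_replicates = 100,
                               total_cfu = 1e5, seed = 83)
  ind <- f[f$induced, ]
  ctrl_arf <- mean(100 * f$resistant_cfu[!f$induced] / f$total_cfu[!f$induced])
  arfs <- compute_arf(ind$resistant_cfu, ind$total_cfu, ctrl_arf)
  se <- sd(arfs) / sqrt(nrow(ind))
  expect_lt(abs(mean(arfs) - 100 * arf_true), 3 * se)
})

test_that("the ARF summary table subtracts controls and stars baselines", {
  cfu <- rbind(
    data.frame(strain_id = "R12", locus = "rpsL", replicate = 1:3,
               induced = TRUE, resistant_cfu = c(600, 650, 700),
               total_cfu = 1e5),
    data.frame(strain_id = "R12", locus = "rpsL", replicate = 1:3,
               induced = FALSE, resistant_cfu = c(10, 12, 8),
               total_cfu = 1e5),
    data.frame(strain_id = "Rec2", locus = "rpsL", replicate = 1:3,
               induced = TRUE, resistant_cfu = c(100, 120, 110),
               total_cfu = 1e5),
    data.frame(strain_id = "Rec2", locus = "rpsL", replicate = 1:3,
               induced = FALSE, resistant_cfu = c(9, 11, 10),
               total_cfu = 1e5))
  out <- arf_summary(cfu, baseline = "Rec2")
  r12 <- out[out$strain_id == "R12", ]
  expect_equal(r12$mean, mean(100 * c(600, 650, 700) / 1e5) - 0.01,
               tolerance = 1e-9)
  expect_true(nzchar(r12$stars))
  expect_equal(out$stars[out$strain_id == "Rec2"], "")
})
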