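test_that("count reconstruction from percentages is exact in total", {
  expect_identical(reconstruct_counts(208, c(mirror = 13.0, nude = 87.0)),
                   c(mirror = 27L, nude = 181L))
  expect_identical(reconstruct_counts(100, c(nude = 100)), c(nude = 100L))
  expect_identical(
    reconstruct_counts(161, c(irregular = 15.5, mirror = 25.5, nude = 59.0)),
    c(irregular = 25L, mirror = 41L, nude = 95L)
  )
  # rounding residual always absorbed so totals match exactly
  set.seed(11)
  for (i in 1:50) {
    n <- sample(20:500, 1)
    p <- as.vector(stats::rmultinom(1, 1000, c(0.2, 0.3, 0.5))) / 10
    counts <- reconstruct_counts(n, stats::setNames(p, c("a1", "a2", "a3")[1:3]))
    expect_identical(sum(counts), as.integer(n))
  }
  expect_error(reconstruct_counts(100, c(nude = 90)), "within 0.5 of 100")
  expect_error(reconstruct_counts(100, c(nude = -5, mirror = 105)),
               "non-negative")
})

test_that("multinomial log-likelihood matches closed form and dmultinom", {
  surv <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
  expect_equal(multinomial_loglik(c(scattered = 1, nude = 2), surv), log(4 / 9))
  expect_equal(multinomial_loglik(c(nude = 5),
                                  condition_on_survival(
                                    cross_distribution("ssNN", "ssNN",
                                                       weak_n_model()))), 0)
  expect_equal(multinomial_loglik(c(scaled = 1), surv), -Inf)

  # oracle cross-check on random counts
  set.seed(4)
  d <- condition_on_survival(cross_distribution("SsNn", "SsNn"))
  p <- probabilities(d, c("scaled", "linear", "scattered", "nude"))
  for (i in 1:25) {
    x <- as.vector(stats::rmultinom(1, sample(5:300, 1), p))
    names(x) <- names(p)
    expect_equal(multinomial_loglik(x, d),
                 stats::dmultinom(x, prob = p, log = TRUE))
  }
  expect_error(multinomial_loglik(c(nude = -1), surv), "non-negative")
})

test_that("irregular and mirror counts pool against the aggregate scattered class", {
  surv <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
  ll_merged <- multinomial_loglik(c(irregular = 10, mirror = 20, nude = 70), surv)
  ll_direct <- multinomial_loglik(c(scattered = 30, nude = 70), surv)
  expect_equal(ll_merged, ll_direct)
  # unmerged: scattered mass split by the observation parameter
  ll_split <- multinomial_loglik(c(irregular = 10, mirror = 20, nude = 70),
                                 surv, merge_scattered = FALSE, split = 0.5)
  x <- c(irregular = 10, mirror = 20, nude = 70)
  p <- c(irregular = 1 / 6, mirror = 1 / 6, nude = 2 / 3)
  expect_equal(ll_split, stats::dmultinom(x, prob = p, log = TRUE))
})

test_that("the nude x nude Hungarian cross is decisively rejected by the chi-square", {
  oc <- observed_cross("26nu.nu", c("nude", "nude"),
                       reconstruct_counts(208, c(mirror = 13.0, nude = 87.0)))
  surv <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
  g <- goodness_of_fit(oc, surv)
  # independent direct evaluation of the Pearson formula
  e <- 208 * c(1 / 3, 2 / 3)
  x2 <- sum((c(27, 181) - e)^2 / e)
  expect_equal(g$statistic, x2)
  expect_equal(g$statistic, 38.77, tolerance = 1e-3)
  expect_identical(g$df, 1L)
  expect_lt(g$p_value, 0.001)
})

test_that("chi-square GOF agrees with stats::chisq.test and is invariant to padding", {
  d <- condition_on_survival(cross_distribution("SsNn", "SsNn"))
  x <- c(scaled = 60, linear = 95, irregular = 10, mirror = 12, nude = 23)
  g <- goodness_of_fit(x, d)
  p <- probabilities(d, c("scaled", "linear", "scattered", "nude"))
  ref <- suppressWarnings(
    stats::chisq.test(c(60, 95, 22, 23), p = unname(p))
  )
  expect_equal(g$statistic, unname(ref$statistic))
  expect_equal(g$p_value, unname(ref$p.value))
  expect_identical(g$df, 3L)
  # a zero-probability, zero-count category changes nothing
  g2 <- goodness_of_fit(c(x, lethal = 0), d)
  expect_equal(g2$statistic, g$statistic)
  # perfect agreement gives statistic 0
  g3 <- goodness_of_fit(c(scattered = 100, nude = 200),
                        condition_on_survival(cross_distribution("ssNn", "ssNn")))
  expect_equal(g3$statistic, 0)
  # two-category X2 equals the squared standardized binomial deviation
  for (k in c(40, 69, 90)) {
    gk <- goodness_of_fit(c(scattered = k, nude = 208 - k),
                          condition_on_survival(cross_distribution("ssNn", "ssNn")))
    z2 <- (k - 208 / 3)^2 / (208 * (1 / 3) * (2 / 3))
    expect_equal(gk$statistic, z2)
  }
})

test_that("degenerate and impossible fits are reported, not errored", {
  certain <- condition_on_survival(cross_distribution("ssnn", "ssnn"))
  g <- goodness_of_fit(c(mirror = 50, irregular = 30), certain)
  expect_true(g$degenerate)
  expect_identical(g$df, 0L)
  g2 <- goodness_of_fit(c(scattered = 10, nude = 50), certain)
  expect_equal(g2$statistic, Inf)
  expect_equal(g2$p_value, 0)
})

test_that("exact multinomial test matches enumeration of the binomial case", {
  surv <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
  obs <- c(scattered = 10, nude = 50)
  g <- goodness_of_fit(obs, surv, method = "exact")
  expect_equal(g$method, "exact-multinomial")
  # independent enumeration: sum binomial masses no larger than the observed
  n <- 60
  mass <- stats::dbinom(0:n, n, 1 / 3)
  p_ref <- sum(mass[mass <= stats::dbinom(10, n, 1 / 3) * (1 + 1e-9)])
  expect_equal(g$p_value, p_ref, tolerance = 1e-9)
  # exact and chi-square agree qualitatively here
  expect_lt(g$p_value, 0.05)
  # three-category case: probabilities sum over the full outcome space
  g3 <- goodness_of_fit(c(scaled = 4, linear = 10, nude = 6),
                        condition_on_survival(
                          cross_distribution("SsNn", "ssNn")),
                        method = "exact")
  expect_gte(g3$p_value, 0)
  expect_lte(g3$p_value, 1)
  expect_error(goodness_of_fit(c(scattered = 300, nude = 300), surv,
                               method = "exact"), "n <= 500")
})

test_that("chi-square GOF holds its nominal type-I error", {
  set.seed(20)
  d <- condition_on_survival(cross_distribution("SsNn", "SsNn"))
  p <- probabilities(d, c("scaled", "linear", "scattered", "nude"))
  reject <- logical(2000)
  for (i in seq_along(reject)) {
    x <- stats::setNames(as.vector(stats::rmultinom(1, 200, p)), names(p))
    reject[i] <- goodness_of_fit(x, d)$p_value < 0.05
  }
  expect_gte(mean(reject), 0.03)
  expect_lte(mean(reject), 0.07)
})

test_that("hypothesis ranking recovers the generating genotype class", {
  set.seed(9)
  surv <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
  p <- probabilities(surv, c("scattered", "nude"))
  top_standard <- 0L
  for (i in 1:20) {
    x <- as.vector(stats::rmultinom(1, 300, p))
    oc <- observed_cross("sim", c("nude", "nude"),
                         c(mirror = x[1], nude = x[2]))
    r <- rank_parent_hypotheses(oc, list(standard_model()))
    if (grepl("ssNn x ssNn", r$hypothesis[1], fixed = TRUE)) {
      top_standard <- top_standard + 1L
    }
  }
  expect_identical(top_standard, 20L)
})

test_that("ranking direction is forced when no nudes are observed", {
  # the published nude x mirror cross with 0/233 nudes
  oc <- observed_cross("25mi.nu", c("nude", "mirror"), c(mirror = 233))
  r <- rank_parent_hypotheses(oc, list(standard_model(), weak_n_model(),
                                       strong_s_model()))
  # classes predicting a larger nude fraction rank strictly below those
  # predicting a smaller one; all-nude classes are impossible (-Inf)
  ll_of <- function(pat) r$loglik[grepl(pat, r$hypothesis, fixed = TRUE) &
                                    r$model == "strong-s"][1]
  expect_lt(ll_of("ss*Nn x ssnn"), ll_of("ssNn x ssnn"))  # 3/4 vs 1/2 nude
  expect_true(all(r$loglik[grepl("ssNN x ssnn", r$hypothesis, fixed = TRUE)] == -Inf))
  expect_equal(r$loglik, sort(r$loglik, decreasing = TRUE))
  # registration order breaks the standard/weak-N tie for ssNn x ssnn
  tied <- r[r$loglik == max(r$loglik), ]
  expect_equal(tied$model[1], "standard")
})

test_that("an empty observation ties all hypotheses at log-likelihood zero", {
  oc <- observed_cross("empty", c("nude", "nude"), c(nude = 0L))
  r <- rank_parent_hypotheses(oc, list(standard_model(), weak_n_model()))
  expect_true(all(r$loglik == 0))
})

test_that("survival comparison reports Student's t with group summaries", {
  same <- compare_survival(c(88, 90, 92), c(88, 90, 92))
  expect_equal(same$statistic, 0)
  expect_equal(same$p_value, 1)

  far <- compare_survival(c(90, 92), c(10, 12))
  # closed form: pooled sd sqrt(2), se = sqrt(2 * (1/2 + 1/2)) = sqrt(2)
  expect_equal(far$statistic, 80 / sqrt(2))
  expect_lt(far$p_value, 0.01)
  expect_equal(unname(far$means), c(91, 11))

  welch <- compare_survival(c(90, 92, 94), c(70, 80, 90), var_equal = FALSE)
  expect_match(welch$method, "Welch")
  expect_error(compare_survival(90, c(80, 82)), "at least 2")
})
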