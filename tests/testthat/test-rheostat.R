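test_that("the default signal profile has peaks on the dorsal and ventral lines", {
  prof <- signal_profile()
  b <- prof$baseline
  expect_true(all(b >= 0))
  for (line in c("dorsal", "ventral")) {
    r <- prof$rows[[line]]
    expect_true(all(b[r, ] > b[r - 1, ]))
    expect_true(all(b[r, ] > b[r + 1, ]))
  }
  expect_error(signal_profile(n_rows = 50, dorsal_row = 40, lateral_row = 30,
                              ventral_row = 45))
})

test_that("the threshold rule produces full, empty and line-restricted maps", {
  prof <- signal_profile()
  params <- rheostat_params(noise_sd = 0)
  # wild-type attenuation, threshold below the minimum signal: full coverage
  m <- simulate_scale_map("SSnn", prof, params)
  expect_true(all(m))
  # zero attenuation: empty map
  p0 <- rheostat_params(attenuation = c(scaled = 1, linear = 0.55,
                                        scattered = 0.35, nude = 0),
                        noise_sd = 0)
  m0 <- simulate_scale_map("ssNn", prof, p0)
  expect_false(any(m0))
  # mirror-like attenuation: dorsal and ventral lines retained, flanks bare
  pm <- rheostat_params(attenuation = c(scaled = 1, linear = 0.55,
                                        scattered = 0.30, nude = 0.12),
                        noise_sd = 0)
  mm <- simulate_scale_map("ssnn", prof, pm)
  expect_true(all(mm[prof$rows[["dorsal"]], ]))
  expect_true(all(mm[prof$rows[["ventral"]], ]))
  expect_false(any(mm[prof$rows[["lateral"]], ]))
  flanks <- setdiff(seq_len(nrow(mm)), prof$rows)
  expect_lt(mean(mm[flanks, ]), 0.05)
  cl <- classify_scale_map(mm, prof)
  expect_equal(cl$category, "mirror")
  # non-viable genotypes are rejected
  expect_error(simulate_scale_map("ssNN", prof, params), "lethal")
})

test_that("classification covers the degenerate maps", {
  prof <- signal_profile()
  full <- matrix(TRUE, 100, 30)
  class(full) <- c("scale_map", class(full))
  expect_equal(classify_scale_map(full, prof)$category, "scaled")
  empty <- matrix(FALSE, 100, 30)
  class(empty) <- c("scale_map", class(empty))
  cl <- classify_scale_map(empty, prof)
  expect_equal(cl$category, "nude")
  expect_equal(cl$nude_subtype, "nude2")
  sparse <- empty
  sparse[40, 1:3] <- TRUE
  expect_equal(classify_scale_map(sparse, prof)$nude_subtype, "nude1")
})

test_that("simulated maps classify back to their attenuation class", {
  prof <- signal_profile()
  params <- rheostat_params()
  intended <- c(SSnn = "scaled", SsNn = "linear", ssnn = "scattered",
                ssNn = "nude")
  set.seed(33)
  for (g in names(intended)) {
    got <- replicate(50, {
      m <- stats::rlnorm(1, 0, params$fish_sdlog)
      cl <- classify_scale_map(
        simulate_scale_map(g, prof, params, fish_effect = m), prof)
      if (cl$category %in% c("irregular", "mirror")) "scattered" else cl$category
    })
    expect_gte(mean(got == intended[[g]]), 0.9)
  }
})

test_that("the scattered class splits into irregular and mirror presentations", {
  sim <- simulate_cross("ssnn", "ssnn", n = 150, seed = 5)
  expect_equal(sim$lethal_count, 0L)
  expect_true(all(sim$fish$category %in% c("irregular", "mirror")))
  expect_gt(sum(sim$fish$category == "irregular"), 10)
  expect_gt(sum(sim$fish$category == "mirror"), 10)
})

test_that("simulation is reproducible byte for byte from its seed", {
  a <- simulate_cross("SsNn", "ssNn", n = 120, seed = 77)
  b <- simulate_cross("SsNn", "ssNn", n = 120, seed = 77)
  expect_identical(a, b)
  c2 <- simulate_cross("SsNn", "ssNn", n = 120, seed = 78)
  expect_false(identical(a$fish, c2$fish))
  # split layer too
  d1 <- simulate_cross("ssNn", "ssNn", n = 200, seed = 9, method = "split")
  d2 <- simulate_cross("ssNn", "ssNn", n = 200, seed = 9, method = "split")
  expect_identical(d1, d2)
})

test_that("expected coverage and teeth dose are monotone in attenuation", {
  prof <- signal_profile()
  # noise-free coverage as attenuation falls over a grid
  atts <- seq(1, 0.05, by = -0.05)
  cov <- vapply(atts, function(a) {
    mean(a * prof$baseline >= 1)
  }, numeric(1))
  expect_true(all(diff(cov) <= 0))
  # teeth means by category follow the same order in a simulated cohort
  set.seed(99)
  fish <- rbind(
    simulate_cross("SSnn", "Ssnn", n = 60, method = "split")$fish,
    simulate_cross("SSNn", "SSNn", n = 80, method = "split")$fish,
    simulate_cross("ssnn", "ssnn", n = 60, method = "split")$fish,
    simulate_cross("ssNn", "ssNn", n = 120, method = "split")$fish
  )
  agg <- tapply(fish$teeth_count, fish$category, mean)
  expect_gt(agg[["scaled"]], agg[["irregular"]])
  expect_gt(agg[["scaled"]], agg[["mirror"]])
  expect_gt(min(agg[["irregular"]], agg[["mirror"]]), agg[["nude"]])
})

test_that("simulated crosses reproduce the transmission expectations", {
  # nude x nude, standard model: ~25% lethal, ~2/3 nude among survivors
  sim <- simulate_cross("ssNn", "ssNn", n = 2000, seed = 101)
  p_lethal <- sim$lethal_count / 2000
  expect_lt(abs(p_lethal - 0.25), 3 * sqrt(0.25 * 0.75 / 2000))
  ns <- sum(sim$cross$counts)
  p_nude <- sim$cross$counts[["nude"]] / ns
  expect_lt(abs(p_nude - 2 / 3), 3 * sqrt((2 / 3) * (1 / 3) / ns))
  # forced transmissions
  sim2 <- simulate_cross("ssnn", "ssnn", n = 200, seed = 8, method = "split")
  expect_equal(sim2$lethal_count, 0L)
  expect_true(all(sim2$fish$category %in% c("irregular", "mirror")))
  # weak-N model: no lethality, nude fraction near 3/4
  sim3 <- simulate_cross("ssNn", "ssNn", n = 2000, model = weak_n_model(),
                         seed = 12, method = "split")
  expect_identical(sim3$lethal_count, 0L)
  p_nude3 <- sim3$cross$counts[["nude"]] / 2000
  expect_lt(abs(p_nude3 - 3 / 4), 3 * sqrt(0.75 * 0.25 / 2000))
})

test_that("simulated category frequencies converge to the exact expectation", {
  surv <- condition_on_survival(cross_distribution("SsNn", "ssNn"))
  expected <- probabilities(surv, c("scaled", "linear", "scattered", "nude"))
  sim <- simulate_cross("SsNn", "ssNn", n = 5000, seed = 55, method = "split")
  counts <- sim$cross$counts
  obs <- c(
    scaled = counts[["scaled"]],
    linear = counts[["linear"]],
    scattered = sum(counts[c("irregular", "mirror")]),
    nude = counts[["nude"]]
  ) / sum(counts)
  # Kolmogorov distance between the two distributions over the 4 categories
  expect_lt(max(abs(cumsum(obs) - cumsum(expected))), 0.05)
})

test_that("simulated survival rates reflect the lethal class", {
  with_lethal <- simulate_survival_rates(
    list(c("ssNn", "ssNn"), c("SsNn", "ssNn"), c("SsNn", "SsNn")),
    seed = 40)
  without <- simulate_survival_rates(
    list(c("ssNn", "ssnn"), c("ssnn", "ssnn"), c("SSnn", "ssNn")),
    seed = 41)
  expect_true(all(with_lethal < min(without)))
  res <- compare_survival(without, with_lethal)
  expect_lt(res$p_value, 0.05)
})
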