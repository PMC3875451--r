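# Brute-force transmission oracle, kept independent of the package's
# cross_distribution() path: enumerate the 16 equiprobable parental allele
# draws numerically and pool by phenotype. For the standard model the
# genotype -> phenotype map is frozen from the published Punnett square
# rather than calling phenotype_of().

oracle_standard_map <- c(
  SSnn = "scaled", Ssnn = "scaled", ssnn = "scattered",
  SSNn = "linear", SsNn = "linear", ssNn = "nude",
  SSNN = "lethal", SsNN = "lethal", ssNN = "lethal"
)

oracle_alleles <- function(g) {
  toks <- regmatches(g, gregexpr("s\\*|S|s|N|n", g))[[1]]
  list(s = toks[toks %in% c("S", "s", "s*")], n = toks[toks %in% c("N", "n")])
}

oracle_canonical <- function(s_pair, n_pair) {
  s <- s_pair[order(match(s_pair, c("S", "s", "s*")))]
  n <- n_pair[order(match(n_pair, c("N", "n")))]
  paste(c(s, n), collapse = "")
}

# returns named numeric probabilities over phenotype categories
oracle_cross <- function(p1, p2, model = NULL) {
  a1 <- oracle_alleles(p1)
  a2 <- oracle_alleles(p2)
  probs <- c(scaled = 0, linear = 0, scattered = 0, nude = 0, lethal = 0)
  for (i in 1:2) for (j in 1:2) for (k in 1:2) for (l in 1:2) {
    z <- oracle_canonical(c(a1$s[i], a2$s[k]), c(a1$n[j], a2$n[l]))
    ph <- if (is.null(model)) {
      unname(oracle_standard_map[z])
    } else {
      phenotype_of(z, model)
    }
    probs[ph] <- probs[ph] + 1 / 16
  }
  probs[probs > 0]
}

expect_dist_equal <- function(dist, expected_probs, tol = 1e-12) {
  p <- probabilities(dist, names(expected_probs))
  expect_equal(unname(p), unname(expected_probs), tolerance = tol)
  expect_equal(sum(probabilities(dist)), 1, tolerance = tol)
}

# a minimal valid fish record data frame, all fins normal
make_fish <- function(n = 1, category = "scaled", teeth = 10L) {
  fish <- data.frame(
    id = sprintf("f%03d", seq_len(n)),
    family = "test",
    category = rep_len(category, n),
    stringsAsFactors = FALSE
  )
  for (col in paste0("fin_", c("dorsal", "caudal", "anal", "pectoral_left",
                               "pectoral_right", "pelvic_left", "pelvic_right"))) {
    fish[[col]] <- "normal"
  }
  fish$teeth_count <- rep_len(teeth, n)
  fish
}
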