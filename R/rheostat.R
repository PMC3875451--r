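#' Default dorso-ventral signal profile for the rheostat model
#'
#' The rheostat model posits a graded scale-inducing signal over the body
#' surface with preferential locations — a line below the dorsal fin and one
#' above the belly — where the signal peaks, plus an intermediate maximum over
#' the lateral line. A scale forms wherever the genotype-attenuated signal
#' clears a fixed threshold, so progressively stronger attenuation strips the
#' flanks first, then the lateral line, and finally the dorsal/ventral lines.
#'
#' The grid has `n_rows` dorso-ventral positions by `n_cols` head-to-tail
#' columns. Flank (off-line) baseline values are laid down deterministically
#' by passing a golden-ratio low-discrepancy sequence through a piecewise
#' linear quantile function, giving a reproducible spread of signal strengths
#' whose tail fractions calibrate how much flank survives each attenuation
#' class (see the package vignette for the calibration).
#'
#' @param n_rows,n_cols Grid resolution (default 100 x 30).
#' @param dorsal_row,lateral_row,ventral_row Row indices of the three
#'   preferential lines.
#' @param peak_dorsal,peak_lateral,peak_ventral Baseline signal on those rows.
#' @param flank_quantiles List with numeric vectors `p` (cumulative fractions,
#'   increasing from 0 to 1) and `b` (baseline values at those fractions)
#'   defining the flank quantile function.
#' @return Object of class `signal_profile`: list with `baseline` (matrix) and
#'   `rows` (named indices).
#' @export
signal_profile <- function(n_rows = 100L, n_cols = 30L,
                           dorsal_row = 12L, lateral_row = 50L, ventral_row = 88L,
                           peak_dorsal = 4.5, peak_lateral = 2.28,
                           peak_ventral = 4.2,
                           flank_quantiles = list(
                             p = c(0, 0.45, 0.68, 0.78, 0.92, 1),
                             b = c(1.28, 1.82, 2.70, 2.857, 3.00, 3.30)
                           )) {
  stopifnot(n_rows >= 10L, n_cols >= 2L,
            dorsal_row < lateral_row, lateral_row < ventral_row,
            ventral_row <= n_rows)
  stopifnot(length(flank_quantiles$p) == length(flank_quantiles$b),
            !is.unsorted(flank_quantiles$p), !is.unsorted(flank_quantiles$b),
            flank_quantiles$p[1] == 0, flank_quantiles$p[length(flank_quantiles$p)] == 1,
            all(flank_quantiles$b >= 0))
  baseline <- matrix(0, n_rows, n_cols)
  flank <- which(!(seq_len(n_rows) %in% c(dorsal_row, lateral_row, ventral_row)))
  nf <- length(flank) * n_cols
  phi <- (sqrt(5) - 1) / 2
  u <- ((seq_len(nf) * phi) %% 1)
  vals <- stats::approx(flank_quantiles$p, flank_quantiles$b, xout = u,
                        rule = 2)$y
  baseline[flank, ] <- matrix(vals, length(flank), n_cols)
  baseline[dorsal_row, ] <- peak_dorsal
  baseline[lateral_row, ] <- peak_lateral
  baseline[ventral_row, ] <- peak_ventral
  structure(
    list(baseline = baseline,
         rows = c(dorsal = dorsal_row, lateral = lateral_row,
                  ventral = ventral_row)),
    class = "signal_profile"
  )
}

#' @export
print.signal_profile <- function(x, ...) {
  cat("<signal_profile>", nrow(x$baseline), "x", ncol(x$baseline),
      "grid; lines at rows", paste(x$rows, collapse = "/"),
      sprintf("; baseline range [%.3g, %.3g]\n",
              min(x$baseline), max(x$baseline)))
  invisible(x)
}

#' Parameters of the rheostat (signal x threshold) simulator
#'
#' The falling-signal parameterization: genotypes attenuate the shared signal
#' profile by a class-specific multiplier while the threshold stays fixed
#' (the equivalent rising-threshold view would produce the same maps). The
#' default attenuations place the fully scaled classes at 1.0, linears at
#' 0.55, the scattered (ssnn) class at 0.35 — deliberately straddling the
#' irregular/mirror classification boundary so both presentations arise from
#' per-fish signal variability — and nudes at 0.12.
#'
#' Teeth and fin phenotypes are dose-coupled to the same effective signal:
#' teeth counts are Binomial(10, p) with logit(p) interpolated over
#' attenuation through `teeth_response` knots (calibrated so simulated means
#' approximate the published Singapore gradient: scaled ~9.3, scattered ~7,
#' nude <1 with ~70% toothless); per-fin severity is Binomial(4, q)/4 over
#' the five fin states with logit(q) interpolated through `fin_response`
#' knots (calibrated to mean fin scores ~4.5 nude, ~1.2 mirror, <1
#' irregular, ~0 scaled).
#'
#' @param attenuation Named multipliers in (0, 1] per phenotype class
#'   (`scaled`, `linear`, `scattered`, `nude`); must be non-increasing in
#'   that order.
#' @param threshold Signal threshold (the "green line").
#' @param noise_sd SD of per-position signal noise.
#' @param fish_sdlog SD (log scale) of the per-fish lognormal signal
#'   multiplier; this is what splits the ssnn class into irregular vs mirror.
#' @param teeth_response,fin_response Lists with `attenuation` and `logit`
#'   knot vectors for the dose-response interpolations.
#' @return Object of class `rheostat_params`.
#' @export
rheostat_params <- function(attenuation = c(scaled = 1.0, linear = 0.55,
                                            scattered = 0.35, nude = 0.12),
                            threshold = 1.0, noise_sd = 0.08,
                            fish_sdlog = 0.06,
                            teeth_response = list(
                              attenuation = c(0.12, 0.35, 1.0),
                              logit = c(-3.32, 0.847, 2.586)
                            ),
                            fin_response = list(
                              attenuation = c(0.12, 0.33, 0.37, 1.0),
                              logit = c(0.588, -1.578, -2.05, -4.6)
                            )) {
  need <- c("scaled", "linear", "scattered", "nude")
  stopifnot(all(need %in% names(attenuation)))
  a <- attenuation[need]
  if (any(a < 0) || any(a > 1)) stop("attenuations must lie in [0, 1]")
  if (is.unsorted(rev(a))) {
    stop("attenuation must be non-increasing from scaled through nude")
  }
  stopifnot(threshold > 0, noise_sd >= 0, fish_sdlog >= 0)
  structure(
    list(attenuation = a, threshold = threshold, noise_sd = noise_sd,
         fish_sdlog = fish_sdlog, teeth_response = teeth_response,
         fin_response = fin_response),
    class = "rheostat_params"
  )
}

#' Attenuation multiplier of a genotype
#'
#' Maps a (viable) genotype to its signal attenuation through its phenotype
#' class under the allele model.
#'
#' @param genotype Genotype string or `carp_genotype`.
#' @param model An [allele_model()].
#' @param params A [rheostat_params()].
#' @return Single numeric multiplier.
#' @export
attenuation_of <- function(genotype, model = standard_model(),
                           params = rheostat_params()) {
  ph <- phenotype_of(genotype, model)
  if (ph == "lethal") {
    stop("genotype ", sQuote(format(as_genotype(genotype))),
         " is lethal; it has no attenuation")
  }
  unname(params$attenuation[[ph]])
}

interp_logit <- function(knots, x) {
  stats::plogis(stats::approx(knots$attenuation, knots$logit, xout = x,
                              rule = 2)$y)
}

#' Simulate one fish's scale map
#'
#' Realises the threshold rule: a scale is present at a position exactly when
#' the attenuated, noise-perturbed signal clears the threshold,
#' `attenuation x (baseline + noise) >= threshold`. Uses R's global RNG
#' stream; seed it for reproducibility.
#'
#' @param genotype Viable genotype (string or `carp_genotype`).
#' @param profile A [signal_profile()].
#' @param params A [rheostat_params()].
#' @param model An [allele_model()].
#' @param fish_effect Per-fish signal multiplier (1 = population typical).
#' @return Logical matrix of class `scale_map` (same shape as the profile).
#' @examples
#' set.seed(1)
#' m <- simulate_scale_map("SSnn", signal_profile())
#' mean(m)  # full coverage
#' @export
simulate_scale_map <- function(genotype, profile = signal_profile(),
                               params = rheostat_params(),
                               model = standard_model(), fish_effect = 1) {
  stopifnot(inherits(profile, "signal_profile"),
            inherits(params, "rheostat_params"))
  att <- attenuation_of(genotype, model, params) * fish_effect
  b <- profile$baseline
  noise <- matrix(stats::rnorm(length(b), 0, params$noise_sd), nrow(b), ncol(b))
  map <- att * (b + noise) >= params$threshold
  class(map) <- c("scale_map", class(map))
  map
}

#' Classification rule constants for scale maps
#'
#' @param scaled_min_coverage Coverage at or above which a map is scaled.
#' @param linear_dorsal_min Minimum dorsal-line completeness for linear.
#' @param linear_lateral_min Minimum lateral-line completeness for linear.
#' @param linear_flank_max Maximum flank coverage tolerated for linear
#'   ("sparse flanks").
#' @param line_min Minimum completeness for a dorsal/ventral line to count as
#'   present (mirror rule).
#' @param mirror_max_coverage Maximum total coverage for mirror.
#' @param nude_max_coverage Maximum total coverage for nude.
#' @return Named list.
#' @export
classification_rules <- function(scaled_min_coverage = 0.95,
                                 linear_dorsal_min = 0.80,
                                 linear_lateral_min = 0.60,
                                 linear_flank_max = 0.75,
                                 line_min = 0.50,
                                 mirror_max_coverage = 0.25,
                                 nude_max_coverage = 0.05) {
  as.list(environment())
}

#' Classify a scale map into a phenotype category
#'
#' Rule-based classification mirroring how live fish are scored from photos:
#' near-complete coverage is scaled; a complete dorsal line with a populated
#' lateral line over sparse flanks is linear; dorsal and ventral lines only,
#' at low coverage, is mirror; near-total absence is nude (sub-typed by
#' residual scale count); everything else — substantial but incomplete cover
#' without the linear row structure — is irregular.
#'
#' @param map A `scale_map` logical matrix.
#' @param profile The [signal_profile()] the map was generated on.
#' @param rules A [classification_rules()] list.
#' @return List with `category`, `nude_subtype` (`NA` unless nude),
#'   `coverage`, and `lines` (completeness of the three rows).
#' @export
classify_scale_map <- function(map, profile = signal_profile(),
                               rules = classification_rules()) {
  stopifnot(is.logical(map),
            all(dim(map) == dim(profile$baseline)))
  cov <- mean(map)
  lines <- vapply(profile$rows, function(r) mean(map[r, ]), numeric(1))
  flank_rows <- setdiff(seq_len(nrow(map)), profile$rows)
  flank_cov <- mean(map[flank_rows, ])
  category <- if (cov >= rules$scaled_min_coverage) {
    "scaled"
  } else if (lines[["dorsal"]] >= rules$linear_dorsal_min &&
             lines[["lateral"]] >= rules$linear_lateral_min &&
             flank_cov <= rules$linear_flank_max) {
    "linear"
  } else if (lines[["dorsal"]] >= rules$line_min &&
             lines[["ventral"]] >= rules$line_min &&
             lines[["lateral"]] < rules$line_min &&
             cov <= rules$mirror_max_coverage) {
    "mirror"
  } else if (cov <= rules$nude_max_coverage) {
    "nude"
  } else {
    "irregular"
  }
  nude_subtype <- NA_character_
  if (category == "nude") {
    # phenomenological: residual scales mark the mildest nude sub-type; the
    # genetic basis of the three sub-types is unknown
    nude_subtype <- if (sum(map) > 0) "nude1" else "nude2"
  }
  list(category = category, nude_subtype = nude_subtype, coverage = cov,
       lines = lines)
}

#' Simulate a cross end to end
#'
#' Draws `n` zygotes by independent gamete sampling from the two parents,
#' removes (and counts) the lethal zygotes — emulating pre-hatching loss —
#' and realises every survivor as a fish record. Two observation layers are
#' available, mutually exclusive per run:
#'
#' * `method = "rheostat"`: each survivor gets a per-fish signal multiplier, a
#'   simulated scale map classified into a category (the irregular/mirror
#'   split within ssnn emerges mechanically from signal variability around
#'   the classification boundary), plus dose-coupled teeth counts and fin
#'   states.
#' * `method = "split"`: the category is taken directly from the genotype's
#'   phenotype class, with scattered fish presenting as irregular with
#'   probability `model$scattered_split`; teeth and fins are still
#'   dose-coupled. Orders of magnitude faster; use when only category counts
#'   matter.
#'
#' @param p1,p2 Parent genotypes, viable under `model`.
#' @param n Number of zygotes (> 0).
#' @param model An [allele_model()].
#' @param params A [rheostat_params()].
#' @param profile A [signal_profile()] (rheostat method only).
#' @param seed Optional integer; if given, `set.seed(seed)` is called so the
#'   whole simulation is reproducible byte for byte.
#' @param method `"rheostat"` or `"split"`.
#' @param label Cross label for the resulting records.
#' @param location Stored in the `observed_cross`.
#' @return List with `fish` (data frame: one row per survivor with id,
#'   family, genotype, category, nude_subtype, coverage, fin states, teeth),
#'   `cross` (an [observed_cross()] of category counts), and `lethal_count`.
#' @examples
#' sim <- simulate_cross("ssNn", "ssnn", n = 200, seed = 42, method = "split")
#' sim$cross
#' @export
simulate_cross <- function(p1, p2, n, model = standard_model(),
                           params = rheostat_params(),
                           profile = signal_profile(), seed = NULL,
                           method = c("rheostat", "split"),
                           label = NULL, location = "simulated") {
  method <- match.arg(method)
  stopifnot(length(n) == 1L, n > 0, n == round(n))
  g1 <- stop_if_not_viable(p1, model)
  g2 <- stop_if_not_viable(p2, model)
  if (!is.null(seed)) set.seed(seed)
  if (is.null(label)) {
    label <- sprintf("%s x %s", format(g1), format(g2))
  }

  # gamete sampling: one allele per locus per parent, independently
  pick <- function(al) al[sample.int(2L, n, replace = TRUE)]
  zyg_s1 <- pick(g1$s); zyg_s2 <- pick(g2$s)
  zyg_n1 <- pick(g1$n); zyg_n2 <- pick(g2$n)
  geno <- character(n)
  for (i in seq_len(n)) {
    geno[i] <- format(new_genotype(c(zyg_s1[i], zyg_s2[i]),
                                   c(zyg_n1[i], zyg_n2[i])))
  }
  ugeno <- unique(geno)
  pheno_map <- vapply(ugeno, function(g) phenotype_of(g, model), character(1))
  pheno <- unname(pheno_map[geno])

  lethal_count <- sum(pheno == "lethal")
  keep <- pheno != "lethal"
  geno <- geno[keep]
  pheno <- pheno[keep]
  ns <- length(geno)
  if (ns == 0L) stop("no survivors simulated; increase n")

  att_class <- unname(params$attenuation[pheno])
  m <- stats::rlnorm(ns, 0, params$fish_sdlog)
  eff <- pmin(att_class * m, 1)

  if (method == "rheostat") {
    category <- character(ns)
    nude_subtype <- rep(NA_character_, ns)
    coverage <- numeric(ns)
    for (i in seq_len(ns)) {
      map <- simulate_scale_map(geno[i], profile, params, model,
                                fish_effect = m[i])
      cl <- classify_scale_map(map, profile)
      category[i] <- cl$category
      nude_subtype[i] <- cl$nude_subtype
      coverage[i] <- cl$coverage
    }
  } else {
    category <- pheno
    is_sc <- category == "scattered"
    if (any(is_sc)) {
      irr <- stats::runif(sum(is_sc)) < model$scattered_split
      category[is_sc] <- ifelse(irr, "irregular", "mirror")
    }
    nude_subtype <- rep(NA_character_, ns)
    coverage <- rep(NA_real_, ns)
  }

  teeth_p <- interp_logit(params$teeth_response, eff)
  teeth <- stats::rbinom(ns, 10L, teeth_p)

  fin_q <- interp_logit(params$fin_response, eff)
  fins <- matrix("", ns, 7L, dimnames = list(NULL, fin_columns()))
  for (j in seq_len(7L)) {
    sev <- stats::rbinom(ns, 4L, fin_q)
    fins[, j] <- fin_states()[sev + 1L]
  }

  # nude sub-types: residual scales mark nude1; otherwise fin severity splits
  # nude2 (partial fin loss) from nude3 (total fin loss) - phenomenological
  is_nude <- category == "nude"
  if (any(is_nude)) {
    n_absent <- rowSums(fins[is_nude, , drop = FALSE] == "absent")
    has_residual <- if (method == "rheostat") {
      coverage[is_nude] > 0
    } else {
      teeth[is_nude] > 0
    }
    nude_subtype[is_nude] <- ifelse(has_residual, "nude1",
                                    ifelse(n_absent == 7L, "nude3", "nude2"))
  }
  nude_subtype[!is_nude] <- NA_character_

  fish <- data.frame(
    id = sprintf("%s_%04d", gsub("[^A-Za-z0-9]", "", label), seq_len(ns)),
    family = label,
    genotype = geno,
    category = category,
    nude_subtype = nude_subtype,
    coverage = coverage,
    attenuation = eff,
    stringsAsFactors = FALSE
  )
  fish <- cbind(fish, as.data.frame(fins, stringsAsFactors = FALSE))
  fish$teeth_count <- teeth

  counts_tab <- table(factor(category, levels = phenotype_categories(TRUE)))
  counts <- stats::setNames(as.integer(counts_tab), names(counts_tab))
  counts <- counts[counts > 0]
  cross <- observed_cross(label,
                          c(phenotype_of(g1, model), phenotype_of(g2, model)),
                          counts, location = location)
  list(fish = fish, cross = cross, lethal_count = lethal_count)
}

#' Simulate per-cross egg survival rates
#'
#' Egg-level survival for a set of crosses: each cross's survival percentage
#' is a binomial draw around a baseline hatching rate, multiplied by the
#' fraction of zygotes expected to be viable under the allele model (3/4 when
#' both parents are Nn carriers under the standard model, 1 otherwise).
#'
#' @param parent_pairs List of length-2 genotype vectors.
#' @param eggs_per_cross Eggs scored per cross.
#' @param baseline Baseline (non-genetic) egg survival probability.
#' @param model An [allele_model()].
#' @param seed Optional integer seed.
#' @return Numeric vector of survival percentages, one per cross.
#' @export
simulate_survival_rates <- function(parent_pairs, eggs_per_cross = 400L,
                                    baseline = 0.89,
                                    model = standard_model(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  vapply(parent_pairs, function(pp) {
    d <- cross_distribution(pp[1], pp[2], model)
    p_lethal <- unname(probabilities(d, "lethal"))
    p <- baseline * (1 - p_lethal)
    100 * stats::rbinom(1L, eggs_per_cross, p) / eggs_per_cross
  }, numeric(1))
}
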