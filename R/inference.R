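# Align observed counts with a model distribution's categories. If
# merge_scattered, irregular + mirror (+ any pre-aggregated scattered) counts
# are pooled against the model's aggregate scattered probability; otherwise
# the model's scattered mass is split into irregular/mirror with `split`.
align_counts <- function(counts, dist, merge_scattered = TRUE, split = 0.5) {
  stopifnot(inherits(dist, "phenotype_dist"))
  if (dist$includes_lethal && "lethal" %in% names(dist$num)) {
    stop("counts must be compared against a survivor-level distribution; ",
         "apply condition_on_survival() first")
  }
  if (merge_scattered) {
    sc <- sum(counts[names(counts) %in% c("irregular", "mirror", "scattered")])
    counts <- counts[!names(counts) %in% c("irregular", "mirror", "scattered")]
    if (sc > 0 || "scattered" %in% names(dist$num)) {
      counts <- c(counts, scattered = sc)
    }
    p <- probabilities(dist)
  } else {
    p <- split_scattered(dist, split)
    if ("scattered" %in% names(counts)) {
      stop("counts carry the aggregate scattered category; ",
           "use merge_scattered = TRUE")
    }
  }
  cats <- union(names(p), names(counts))
  x <- stats::setNames(integer(length(cats)), cats)
  x[names(counts)] <- counts
  pp <- stats::setNames(numeric(length(cats)), cats)
  pp[names(p)] <- p
  list(counts = x, prob = pp)
}

#' Multinomial log-likelihood of observed counts
#'
#' Log of the multinomial probability mass of the observed category counts
#' under a survivor-level expected distribution, including the multinomial
#' coefficient (so absolute values are comparable across reports; rankings are
#' unaffected). Returns `-Inf` when any non-zero count falls on a category of
#' expected probability zero.
#'
#' @param counts Named non-negative integer vector of observed counts.
#' @param dist Survivor-level [phenotype_dist()].
#' @param merge_scattered Pool irregular + mirror counts against the model's
#'   aggregate scattered probability (the genetic model predicts only the
#'   aggregate). If `FALSE`, the model's scattered mass is split
#'   irregular/mirror with probability `split` of irregular.
#' @param split Irregular fraction used when `merge_scattered = FALSE`.
#' @return A single numeric log-likelihood.
#' @examples
#' d <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
#' multinomial_loglik(c(scattered = 1, nude = 2), d)  # log(4/9)
#' @export
multinomial_loglik <- function(counts, dist, merge_scattered = TRUE, split = 0.5) {
  if (any(counts < 0)) stop("counts must be non-negative")
  al <- align_counts(counts, dist, merge_scattered, split)
  x <- al$counts
  p <- al$prob
  if (any(x > 0 & p == 0)) return(-Inf)
  keep <- x > 0
  lgamma(sum(x) + 1) - sum(lgamma(x[keep] + 1)) + sum(x[keep] * log(p[keep]))
}

#' Goodness of fit of observed counts to an expected distribution
#'
#' Pearson chi-square (default) or exact multinomial test of an observed
#' cross's category counts against a survivor-level expected distribution.
#' Categories with expected probability zero and zero count are dropped from
#' the degrees of freedom; a non-zero count on a zero-probability category
#' yields an infinite statistic and p-value 0. A single-category comparison is
#' degenerate (df 0): the fit is perfect by construction and reported as such.
#'
#' The exact method enumerates all outcome tables (feasible for at most 4
#' categories and n up to 500) and sums the probability of every table at
#' most as probable as the observed one.
#'
#' @param observed An [observed_cross()] or a named count vector.
#' @param dist Survivor-level [phenotype_dist()].
#' @inheritParams multinomial_loglik
#' @param method `"chisq"` or `"exact"`.
#' @return An object of class `gof_result`: list with `statistic`, `df`,
#'   `p_value`, `method`, `observed`, `expected`, `degenerate`.
#' @examples
#' oc <- observed_cross("26nu.nu", c("nude", "nude"), c(mirror = 27, nude = 181))
#' d <- condition_on_survival(cross_distribution("ssNn", "ssNn"))
#' goodness_of_fit(oc, d)
#' @export
goodness_of_fit <- function(observed, dist, merge_scattered = TRUE, split = 0.5,
                            method = c("chisq", "exact")) {
  method <- match.arg(method)
  counts <- if (inherits(observed, "observed_cross")) observed$counts else observed
  al <- align_counts(counts, dist, merge_scattered, split)
  x <- al$counts
  p <- al$prob
  keep <- !(p == 0 & x == 0)
  x <- x[keep]
  p <- p[keep]
  n <- sum(x)
  e <- n * p
  if (any(p == 0 & x > 0)) {
    res <- list(statistic = Inf, df = sum(keep) - 1L, p_value = 0,
                method = "chi-square", observed = x, expected = e,
                degenerate = FALSE)
    class(res) <- "gof_result"
    return(res)
  }
  if (length(x) == 1L) {
    res <- list(statistic = 0, df = 0L, p_value = NA_real_, method = "degenerate",
                observed = x, expected = e, degenerate = TRUE)
    class(res) <- "gof_result"
    return(res)
  }
  if (method == "chisq") {
    if (any(e < 1)) {
      warning("expected count below 1 in some category; ",
              "chi-square approximation may be poor")
    }
    stat <- sum((x - e)^2 / e)
    df <- length(x) - 1L
    res <- list(statistic = stat, df = df,
                p_value = stats::pchisq(stat, df, lower.tail = FALSE),
                method = "chi-square", observed = x, expected = e,
                degenerate = FALSE)
  } else {
    k <- length(x)
    if (k > 4L || n > 500L) {
      stop("exact multinomial test supported for at most 4 categories and n <= 500")
    }
    if (choose(n + k - 1, k - 1) > 2e6) {
      stop("exact multinomial enumeration too large; use method = \"chisq\"")
    }
    tables <- enumerate_compositions(n, k)
    logp <- apply(tables, 1L, function(row) {
      stats::dmultinom(row, size = n, prob = p, log = TRUE)
    })
    obs_logp <- stats::dmultinom(x, size = n, prob = p, log = TRUE)
    p_value <- sum(exp(logp[logp <= obs_logp + 1e-9]))
    res <- list(statistic = sum((x - e)^2 / e), df = length(x) - 1L,
                p_value = min(1, p_value), method = "exact-multinomial",
                observed = x, expected = e, degenerate = FALSE)
  }
  class(res) <- "gof_result"
  res
}

# All ordered k-part compositions of n (rows sum to n).
enumerate_compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, ncol = 1L))
  out <- vector("list", n + 1L)
  for (first in 0:n) {
    rest <- enumerate_compositions(n - first, k - 1L)
    out[[first + 1L]] <- cbind(first, rest, deparse.level = 0)
  }
  do.call(rbind, out)
}

#' @export
print.gof_result <- function(x, ...) {
  cat("<gof_result>", x$method, "\n")
  if (x$degenerate) {
    cat("  degenerate fit: single category, df 0\n")
  } else {
    cat(sprintf("  X-squared = %.4g, df = %d, p = %.4g\n",
                x$statistic, x$df, x$p_value))
  }
  invisible(x)
}

#' Rank parental-genotype and allele-model hypotheses for a cross
#'
#' For every supplied allele model, enumerates the genotype-pair equivalence
#' classes compatible with the recorded parental phenotypes
#' ([expected_for_cross_type()]), conditions each class's offspring
#' distribution on survival, and computes the multinomial log-likelihood of
#' the observed counts. All hypotheses are returned ranked by log-likelihood;
#' ties keep model/class registration order. Classes whose expectation puts
#' probability zero on an observed category get `-Inf`.
#'
#' @param observed An [observed_cross()].
#' @param models List of [allele_model()] objects (registration order breaks
#'   ties).
#' @param merge_scattered Pool irregular/mirror counts against aggregate
#'   scattered (see [multinomial_loglik()]).
#' @return A data frame of class `hypothesis_ranking`: columns `rank`,
#'   `model`, `class_id`, `hypothesis` (member pairs, "|"-separated),
#'   `loglik`. Zero rows when no model admits a compatible genotype pair.
#' @examples
#' oc <- observed_cross("toy", c("nude", "nude"),
#'                      c(irregular = 20, mirror = 30, nude = 100))
#' rank_parent_hypotheses(oc, list(standard_model(), weak_n_model()))
#' @export
rank_parent_hypotheses <- function(observed, models = list(standard_model()),
                                   merge_scattered = TRUE) {
  stopifnot(inherits(observed, "observed_cross"), length(models) >= 1L)
  rows <- list()
  for (mi in seq_along(models)) {
    model <- models[[mi]]
    stopifnot(inherits(model, "allele_model"))
    classes <- expected_for_cross_type(observed$parent_phenotypes[1],
                                       observed$parent_phenotypes[2], model)
    for (cl in classes) {
      surv <- condition_on_survival(cl$distribution)
      ll <- multinomial_loglik(observed$counts, surv,
                               merge_scattered = merge_scattered,
                               split = model$scattered_split)
      rows[[length(rows) + 1L]] <- data.frame(
        model = model$name,
        class_id = cl$class_id,
        hypothesis = paste(cl$members, collapse = " | "),
        loglik = ll,
        stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    out <- data.frame(rank = integer(0), model = character(0),
                      class_id = integer(0), hypothesis = character(0),
                      loglik = numeric(0), stringsAsFactors = FALSE)
    class(out) <- c("hypothesis_ranking", class(out))
    return(out)
  }
  out <- do.call(rbind, rows)
  ord <- order(-out$loglik)  # stable: ties keep registration order
  out <- out[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  out <- out[, c("rank", "model", "class_id", "hypothesis", "loglik")]
  rownames(out) <- NULL
  class(out) <- c("hypothesis_ranking", class(out))
  out
}

#' Two-group comparison of survival rates
#'
#' Compares per-cross survival percentages between two groups of crosses with
#' a two-sample t-test (pooled-variance Student's t by default; Welch behind
#' the flag), reporting group means and standard deviations alongside.
#'
#' @param group_a,group_b Numeric vectors of per-cross survival rates (%),
#'   each of length at least 2.
#' @param var_equal Pooled-variance Student's t-test if `TRUE` (default);
#'   Welch if `FALSE`.
#' @return List with `statistic`, `p_value`, `means`, `sds`, `n`, `method`.
#' @examples
#' compare_survival(c(88, 91, 93), c(85, 89, 90))
#' @export
compare_survival <- function(group_a, group_b, var_equal = TRUE) {
  if (length(group_a) < 2L || length(group_b) < 2L) {
    stop("each group needs at least 2 survival values")
  }
  ht <- stats::t.test(group_a, group_b, var.equal = var_equal)
  list(
    statistic = unname(ht$statistic),
    p_value = ht$p.value,
    means = c(a = mean(group_a), b = mean(group_b)),
    sds = c(a = stats::sd(group_a), b = stats::sd(group_b)),
    n = c(a = length(group_a), b = length(group_b)),
    method = if (var_equal) "Student's t-test (pooled variance)" else "Welch t-test"
  )
}
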