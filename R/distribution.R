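#' Exact phenotype distributions
#'
#' Transmission probabilities in the two-locus system are exact fractions
#' (every cross probability has a denominator dividing 16), so distributions
#' are stored as integer numerators over a single common denominator and only
#' converted to floating point at the reporting boundary.
#'
#' @param num Named non-negative integer vector of numerators; names are
#'   phenotype categories.
#' @param den Positive integer common denominator; `sum(num)` must equal `den`.
#' @param includes_lethal Logical; does the distribution describe zygotes
#'   (lethal class included) or survivors?
#' @return An object of class `phenotype_dist`.
#' @seealso [cross_distribution()], [condition_on_survival()]
#' @export
phenotype_dist <- function(num, den, includes_lethal = any(names(num) == "lethal")) {
  stopifnot(is.numeric(num), !is.null(names(num)), all(num >= 0),
            length(den) == 1L, den > 0, all(num == round(num)), den == round(den))
  if (sum(num) != den) {
    stop("numerators must sum to the denominator (", sum(num), " != ", den, ")")
  }
  bad <- setdiff(names(num), c(phenotype_categories(), phenotype_categories(TRUE)))
  if (length(bad)) stop("unknown phenotype categories: ", paste(bad, collapse = ", "))
  num <- num[num > 0]
  g <- Reduce(gcd2, c(num, den))
  structure(
    list(num = stats::setNames(as.integer(num / g), names(num)),
         den = as.integer(den / g),
         includes_lethal = isTRUE(includes_lethal)),
    class = "phenotype_dist"
  )
}

gcd2 <- function(a, b) if (b == 0) a else gcd2(b, a %% b)

#' Probabilities of a phenotype distribution as numerics
#'
#' @param dist A [phenotype_dist()].
#' @param categories Optional category names to extract (absent ones are 0).
#' @return Named numeric vector of probabilities.
#' @export
probabilities <- function(dist, categories = NULL) {
  stopifnot(inherits(dist, "phenotype_dist"))
  p <- dist$num / dist$den
  if (is.null(categories)) return(p)
  out <- stats::setNames(numeric(length(categories)), categories)
  hit <- intersect(categories, names(p))
  out[hit] <- p[hit]
  out
}

#' @export
format.phenotype_dist <- function(x, ...) {
  paste(sprintf("%s %d/%d", names(x$num), x$num, x$den), collapse = ", ")
}

#' @export
print.phenotype_dist <- function(x, ...) {
  level <- if (x$includes_lethal) "zygote" else "survivor"
  cat("<phenotype_dist> (", level, " level)\n", sep = "")
  df <- as.data.frame(x)
  df$percent <- sprintf("%.4g%%", 100 * df$probability)
  print(df, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.phenotype_dist <- function(x, ...) {
  data.frame(
    category = names(x$num),
    numerator = x$num,
    denominator = x$den,
    probability = x$num / x$den,
    stringsAsFactors = FALSE
  )
}

#' @export
`==.phenotype_dist` <- function(e1, e2) {
  identical(e1$num[order(names(e1$num))], e2$num[order(names(e2$num))]) &&
    identical(e1$den, e2$den)
}

#' Condition a zygote-level distribution on survival
#'
#' Removes the lethal class and renormalises the remaining categories, exactly
#' (integer arithmetic). E.g. the nude x nude zygote expectation
#' 25% scattered / 50% nude / 25% lethal becomes 1/3 scattered, 2/3 nude among
#' survivors. Idempotent: distributions without a lethal class are returned
#' unchanged.
#'
#' @param dist A [phenotype_dist()].
#' @return A survivor-level `phenotype_dist`.
#' @examples
#' d <- cross_distribution("ssNn", "ssNn")
#' condition_on_survival(d)
#' @export
condition_on_survival <- function(dist) {
  stopifnot(inherits(dist, "phenotype_dist"))
  lethal <- dist$num[names(dist$num) == "lethal"]
  if (!length(lethal) || lethal == 0L) {
    out <- dist
    out$includes_lethal <- FALSE
    return(out)
  }
  if (lethal == dist$den) {
    stop("all offspring are lethal; survivor distribution is undefined")
  }
  num <- dist$num[names(dist$num) != "lethal"]
  phenotype_dist(num, dist$den - lethal, includes_lethal = FALSE)
}

#' Split the aggregate scattered class into irregular and mirror
#'
#' The genetic model predicts only the aggregate scattered category; the
#' irregular/mirror presentation is an observation-layer split with
#' probability `model$scattered_split` of irregular. The result uses numeric
#' probabilities (the split need not be rational).
#'
#' @param dist A [phenotype_dist()].
#' @param split Probability that a scattered fish presents as irregular.
#' @return Named numeric probability vector over observed categories.
#' @export
split_scattered <- function(dist, split = 0.5) {
  stopifnot(split >= 0, split <= 1)
  p <- probabilities(dist)
  sc <- if ("scattered" %in% names(p)) p[["scattered"]] else 0
  p <- p[names(p) != "scattered"]
  out <- c(p, irregular = sc * split, mirror = sc * (1 - split))
  out[out > 0]
}
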