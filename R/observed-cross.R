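#' Construct an observed cross record
#'
#' One cross's offspring phenotype counts, as recorded on live fish: the
#' lethal class is unobservable and never appears in the counts.
#'
#' @param label Cross label, e.g. `"26nu.nu"`.
#' @param parent_phenotypes Length-2 character vector of parental phenotypes.
#' @param counts Named non-negative integer vector over observed categories
#'   (subset of scaled, linear, irregular, mirror, nude; `scattered` accepted
#'   for pre-aggregated data).
#' @param location Free-text origin of the cross (e.g. `"HUN"`, `"SIN"`).
#' @param total_n Total offspring; defaults to `sum(counts)` and must match it.
#' @return An object of class `observed_cross`.
#' @examples
#' observed_cross("26nu.nu", c("nude", "nude"), c(mirror = 27, nude = 181))
#' @export
observed_cross <- function(label, parent_phenotypes, counts, location = NA_character_,
                           total_n = sum(counts)) {
  stopifnot(is.character(label), length(label) == 1L)
  stopifnot(length(parent_phenotypes) == 2L)
  ok_cats <- c(phenotype_categories(TRUE), "scattered")
  bad <- setdiff(names(counts), ok_cats)
  if (length(bad)) stop("unknown observed categories: ", paste(bad, collapse = ", "))
  if (any(counts < 0) || any(counts != round(counts))) {
    stop("counts must be non-negative integers")
  }
  if (sum(counts) != total_n) {
    stop("counts sum to ", sum(counts), " but total_n is ", total_n)
  }
  bad_ph <- setdiff(parent_phenotypes, setdiff(ok_cats, character(0)))
  if (length(bad_ph)) stop("unknown parental phenotypes: ", paste(bad_ph, collapse = ", "))
  structure(
    list(
      label = label,
      location = location,
      parent_phenotypes = as.character(parent_phenotypes),
      total_n = as.integer(total_n),
      counts = stats::setNames(as.integer(counts), names(counts))
    ),
    class = "observed_cross"
  )
}

#' @export
print.observed_cross <- function(x, ...) {
  cat("<observed_cross>", x$label,
      sprintf("(%s x %s, n = %d", x$parent_phenotypes[1], x$parent_phenotypes[2],
              x$total_n),
      if (!is.na(x$location)) paste0(", ", x$location) else "", ")\n", sep = " ")
  print(x$counts)
  invisible(x)
}

#' Reconstruct integer counts from printed percentages
#'
#' Published cross tables report per-category percentages alongside the total
#' offspring number. This inverts that: each category gets the nearest integer
#' to `pct/100 * n`, and any rounding residual is absorbed by the
#' largest-count category so the total matches `total_n` exactly.
#'
#' @param total_n Positive integer total.
#' @param percentages Named numeric vector of percentages; must sum to 100
#'   within 0.5.
#' @return Named integer vector of counts summing to `total_n`.
#' @examples
#' reconstruct_counts(208, c(mirror = 13.0, nude = 87.0))
#' @export
reconstruct_counts <- function(total_n, percentages) {
  stopifnot(length(total_n) == 1L, total_n > 0, total_n == round(total_n))
  if (any(percentages < 0)) stop("percentages must be non-negative")
  if (abs(sum(percentages) - 100) > 0.5) {
    stop("percentages sum to ", format(sum(percentages)),
         "; must be within 0.5 of 100")
  }
  counts <- round(percentages / 100 * total_n)
  resid <- total_n - sum(counts)
  if (resid != 0) {
    i <- which.max(counts)
    counts[i] <- counts[i] + resid
  }
  stats::setNames(as.integer(counts), names(percentages))
}
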