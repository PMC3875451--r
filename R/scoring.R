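#' Fin inventory and state vocabulary
#'
#' Seven fins are scored per fish: dorsal, caudal, anal, and the paired
#' pectoral and pelvic fins. Each fin is recorded in one of five states of
#' increasing severity.
#'
#' @return Character vector.
#' @export
fin_names <- function() {
  c("dorsal", "caudal", "anal", "pectoral_left", "pectoral_right",
    "pelvic_left", "pelvic_right")
}

#' @rdname fin_names
#' @export
fin_states <- function() {
  c("normal", "slightly_reduced", "reduced", "stunted", "absent")
}

#' Per-fin scoring weights for the cumulative fin-defect scale
#'
#' The cumulative scale awards, per fin: absent 1 point, stunted 0.75,
#' reduced 0.5, slightly reduced 0.25, normal 0. Weights must decrease
#' strictly from absent to normal.
#'
#' @param absent,stunted,reduced,slightly_reduced,normal Points per fin state.
#' @return Named numeric vector of class `score_weights`.
#' @export
score_weights <- function(absent = 1, stunted = 0.75, reduced = 0.5,
                          slightly_reduced = 0.25, normal = 0) {
  w <- c(normal = normal, slightly_reduced = slightly_reduced,
         reduced = reduced, stunted = stunted, absent = absent)
  if (any(diff(w) <= 0)) {
    stop("weights must strictly decrease from absent to normal")
  }
  structure(w, class = "score_weights")
}

fin_columns <- function() paste0("fin_", fin_names())

check_fish_frame <- function(fish) {
  stopifnot(is.data.frame(fish))
  missing_cols <- setdiff(fin_columns(), names(fish))
  if (length(missing_cols)) {
    stop("fish records lack fin columns: ", paste(missing_cols, collapse = ", "))
  }
  for (col in fin_columns()) {
    bad <- setdiff(unique(fish[[col]]), fin_states())
    if (length(bad)) {
      stop("unknown fin state(s) in ", col, ": ", paste(bad, collapse = ", "))
    }
  }
  invisible(fish)
}

#' Cumulative fin-defect score per fish
#'
#' Sums the per-fin weights over all seven fins; with the default weights the
#' score is a multiple of 0.25 between 0 (all fins normal) and 7 (all fins
#' absent).
#'
#' @param fish Data frame of fish records with columns `fin_dorsal`,
#'   `fin_caudal`, `fin_anal`, `fin_pectoral_left`, `fin_pectoral_right`,
#'   `fin_pelvic_left`, `fin_pelvic_right` holding states from
#'   [fin_states()].
#' @param weights A [score_weights()] vector.
#' @return Numeric vector of per-fish scores.
#' @export
fin_defect_score <- function(fish, weights = score_weights()) {
  check_fish_frame(fish)
  stopifnot(inherits(weights, "score_weights"))
  scores <- numeric(nrow(fish))
  for (col in fin_columns()) {
    scores <- scores + unname(weights[fish[[col]]])
  }
  scores
}

pairwise_group_tests <- function(values, groups, var_equal = TRUE) {
  tab <- table(groups)
  usable <- names(tab)[tab >= 2L]
  dropped <- setdiff(names(tab), usable)
  if (length(dropped)) {
    warning("categories with fewer than 2 fish excluded from tests: ",
            paste(dropped, collapse = ", "))
  }
  if (length(usable) < 2L) {
    return(data.frame(group1 = character(0), group2 = character(0),
                      statistic = numeric(0), p_value = numeric(0),
                      p_holm = numeric(0), stringsAsFactors = FALSE))
  }
  combos <- utils::combn(usable, 2L)
  rows <- lapply(seq_len(ncol(combos)), function(i) {
    a <- values[groups == combos[1, i]]
    b <- values[groups == combos[2, i]]
    if (stats::sd(a) == 0 && stats::sd(b) == 0) {
      # degenerate constant groups: t.test cannot run; equal means carry no
      # evidence of difference, unequal constant means are an exact separation
      eq <- mean(a) == mean(b)
      return(data.frame(group1 = combos[1, i], group2 = combos[2, i],
                        statistic = if (eq) 0 else sign(mean(a) - mean(b)) * Inf,
                        p_value = if (eq) 1 else 0, stringsAsFactors = FALSE))
    }
    ht <- stats::t.test(a, b, var.equal = var_equal)
    data.frame(group1 = combos[1, i], group2 = combos[2, i],
               statistic = unname(ht$statistic), p_value = ht$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_holm <- stats::p.adjust(out$p_value, method = "holm")
  out
}

#' Per-category fin-score summaries with pairwise comparisons
#'
#' Mean, standard deviation and n of the cumulative fin-defect score per
#' phenotype category, plus all pairwise Student's t-tests between categories
#' with at least two fish. Pairwise p-values are reported unadjusted, with a
#' Holm-adjusted column alongside.
#'
#' @inheritParams fin_defect_score
#' @param category Optional vector of per-fish categories; defaults to
#'   `fish$category`.
#' @return List with `summary` (data frame: category, n, mean, sd) and
#'   `tests` (data frame of pairwise comparisons).
#' @export
group_score_summary <- function(fish, weights = score_weights(),
                                category = fish$category) {
  scores <- fin_defect_score(fish, weights)
  stopifnot(length(category) == length(scores))
  summary <- summarise_by_category(scores, category)
  tests <- pairwise_group_tests(scores, category)
  list(summary = summary, tests = tests)
}

summarise_by_category <- function(values, groups) {
  cats <- unique(groups)
  data.frame(
    category = cats,
    n = vapply(cats, function(g) sum(groups == g), integer(1)),
    mean = vapply(cats, function(g) mean(values[groups == g]), numeric(1)),
    sd = vapply(cats, function(g) stats::sd(values[groups == g]), numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

#' Per-category pharyngeal teeth summaries with pairwise comparisons
#'
#' Mean teeth count, range and n per phenotype category, the fraction of fish
#' with zero teeth (the most severe nudes lack teeth entirely), and all
#' pairwise Student's t-tests between categories with at least two fish.
#'
#' @param fish Data frame with columns `teeth_count` (integer 0-10) and
#'   `category`.
#' @param category Optional per-fish category vector.
#' @return List with `summary` (category, n, mean, min, max, frac_zero) and
#'   `tests` (pairwise comparisons with Holm column).
#' @export
teeth_summary <- function(fish, category = fish$category) {
  stopifnot(is.data.frame(fish), "teeth_count" %in% names(fish))
  teeth <- fish$teeth_count
  if (any(is.na(teeth)) || any(teeth < 0) || any(teeth > 10)) {
    stop("teeth_count must be populated integers in [0, 10]")
  }
  stopifnot(length(category) == length(teeth))
  cats <- unique(category)
  summary <- data.frame(
    category = cats,
    n = vapply(cats, function(g) sum(category == g), integer(1)),
    mean = vapply(cats, function(g) mean(teeth[category == g]), numeric(1)),
    min = vapply(cats, function(g) min(teeth[category == g]), numeric(1)),
    max = vapply(cats, function(g) max(teeth[category == g]), numeric(1)),
    frac_zero = vapply(cats, function(g) mean(teeth[category == g] == 0), numeric(1)),
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  tests <- pairwise_group_tests(teeth, category)
  list(summary = summary, tests = tests)
}
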