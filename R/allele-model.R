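#' Phenotype categories used throughout the package
#'
#' The five observable scale-pattern categories plus the unobservable lethal
#' class. "scattered" is the classical aggregate category; at the observation
#' layer it splits into "irregular" and "mirror".
#'
#' @param observed Logical; if `TRUE`, return the five categories an observer
#'   can record on live fish (irregular/mirror instead of the aggregate, no
#'   lethal class).
#' @return Character vector of category names.
#' @export
phenotype_categories <- function(observed = FALSE) {
  if (observed) {
    c("scaled", "linear", "irregular", "mirror", "nude")
  } else {
    c("scaled", "linear", "scattered", "nude", "lethal")
  }
}

#' Define an allele model for the two-locus scale-pattern system
#'
#' An allele model fixes how two-locus genotypes map to phenotypes. The
#' standard model is the classical one: the dominant S allele rescues scale
#' cover (scaled with nn, linear with Nn), ss gives scattered (nn) or nude
#' (Nn), and NN homozygotes die before hatching. Two variant hypotheses are
#' provided for crosses that deviate from the classical ratios:
#'
#' * `weak_n_model()`: a milder N allele whose homozygote is viable and nude —
#'   no lethal class at all.
#' * `strong_s_model()`: a third S-locus allele (`s*`) causing complete
#'   loss-of-function, so fish with two loss-of-function doses including at
#'   least one `s*` (i.e. `ss*` or `s*s*`) are nude-like even without N.
#'
#' @param name Identifier used in rankings and reports.
#' @param nn_lethal Logical; do NN homozygotes die before hatching?
#' @param nn_phenotype Phenotype assigned to viable NN fish (used only when
#'   `nn_lethal = FALSE`).
#' @param strong_s Logical; admit the `s*` allele at the S locus.
#' @param scattered_split Probability that a scattered individual presents as
#'   irregular rather than mirror. This is an observation-layer parameter: the
#'   genetic model predicts only the aggregate scattered class.
#' @return An object of class `allele_model`.
#' @examples
#' standard_model()
#' weak_n_model()
#' @export
allele_model <- function(name, nn_lethal = TRUE, nn_phenotype = "nude",
                         strong_s = FALSE, scattered_split = 0.5) {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  stopifnot(isTRUE(nn_lethal) || isFALSE(nn_lethal))
  stopifnot(isTRUE(strong_s) || isFALSE(strong_s))
  if (!is.numeric(scattered_split) || length(scattered_split) != 1L ||
      scattered_split < 0 || scattered_split > 1) {
    stop("`scattered_split` must be a single probability in [0, 1]")
  }
  if (!nn_lethal) {
    if (!nn_phenotype %in% setdiff(phenotype_categories(), "lethal")) {
      stop("`nn_phenotype` must be a viable phenotype category")
    }
  }
  structure(
    list(
      name = name,
      nn_lethal = nn_lethal,
      nn_phenotype = if (nn_lethal) NULL else nn_phenotype,
      strong_s = strong_s,
      scattered_split = scattered_split
    ),
    class = "allele_model"
  )
}

#' @rdname allele_model
#' @export
standard_model <- function(scattered_split = 0.5) {
  allele_model("standard", nn_lethal = TRUE, strong_s = FALSE,
               scattered_split = scattered_split)
}

#' @rdname allele_model
#' @export
weak_n_model <- function(scattered_split = 0.5) {
  allele_model("weak-N", nn_lethal = FALSE, nn_phenotype = "nude",
               strong_s = FALSE, scattered_split = scattered_split)
}

#' @rdname allele_model
#' @export
strong_s_model <- function(scattered_split = 0.5) {
  allele_model("strong-s", nn_lethal = TRUE, strong_s = TRUE,
               scattered_split = scattered_split)
}

#' @export
print.allele_model <- function(x, ...) {
  cat("<allele_model>", x$name, "\n")
  cat("  NN lethal:      ", x$nn_lethal, "\n")
  if (!x$nn_lethal) cat("  NN phenotype:   ", x$nn_phenotype, "\n")
  cat("  s* allele:      ", x$strong_s, "\n")
  cat("  scattered split:", x$scattered_split, "(irregular fraction)\n")
  invisible(x)
}
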