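S_ALLELE_ORDER <- c("S", "s", "s*")
N_ALLELE_ORDER <- c("N", "n")

#' Parse a two-locus genotype
#'
#' Genotypes are written in the field's compact notation, S locus first:
#' `"SsNn"`, `"ssnn"`, `"ssNn"`, ... Under the strong-s model a third S-locus
#' allele is written `s*`, e.g. `"ss*nn"` or `"s*s*Nn"`. The allele order
#' within a locus is not significant; genotypes are stored and printed in
#' canonical order (S before s before s*, N before n).
#'
#' @param x A genotype string, or an object already parsed by `as_genotype()`.
#' @return An object of class `carp_genotype` with fields `s` and `n`, each a
#'   length-2 character vector of alleles.
#' @examples
#' as_genotype("nNsS")   # canonicalises to SsNn
#' as_genotype("ss*nn")
#' @export
as_genotype <- function(x) {
  if (inherits(x, "carp_genotype")) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  tokens <- regmatches(x, gregexpr("s\\*|S|s|N|n", x))[[1]]
  if (paste(tokens, collapse = "") != x) {
    stop("cannot parse genotype string: ", sQuote(x))
  }
  s <- tokens[tokens %in% S_ALLELE_ORDER]
  n <- tokens[tokens %in% N_ALLELE_ORDER]
  if (length(s) != 2L || length(n) != 2L) {
    stop("genotype must carry exactly two alleles per locus: ", sQuote(x))
  }
  new_genotype(s, n)
}

new_genotype <- function(s, n) {
  structure(
    list(
      s = s[order(match(s, S_ALLELE_ORDER))],
      n = n[order(match(n, N_ALLELE_ORDER))]
    ),
    class = "carp_genotype"
  )
}

#' @export
format.carp_genotype <- function(x, ...) paste(c(x$s, x$n), collapse = "")

#' @export
print.carp_genotype <- function(x, ...) {
  cat("<carp_genotype>", format(x), "\n")
  invisible(x)
}

#' @export
`==.carp_genotype` <- function(e1, e2) {
  format(as_genotype(e1)) == format(as_genotype(e2))
}

#' Map a genotype to its phenotype under an allele model
#'
#' Under the standard model: any NN homozygote is lethal; genotypes with at
#' least one S are scaled (nn) or linear (Nn); ss genotypes are scattered (nn)
#' or nude (Nn). The weak-N model makes NN viable and nude; the strong-s model
#' maps S-locus pairs with two loss-of-function doses including `s*` (`ss*`,
#' `s*s*`) to nude regardless of the N locus (NN lethality unchanged).
#'
#' @param genotype A genotype string or `carp_genotype`.
#' @param model An [allele_model()].
#' @return One of `"scaled"`, `"linear"`, `"scattered"`, `"nude"`, `"lethal"`.
#' @examples
#' phenotype_of("Ssnn")  # scaled
#' phenotype_of("ssNn")  # nude
#' phenotype_of("SsNN")  # lethal
#' phenotype_of("ssNN", weak_n_model())  # nude
#' @export
phenotype_of <- function(genotype, model = standard_model()) {
  g <- as_genotype(genotype)
  stopifnot(inherits(model, "allele_model"))
  if (any(g$s == "s*") && !model$strong_s) {
    stop("genotype ", sQuote(format(g)), " carries s* but the ",
         sQuote(model$name), " model does not admit that allele")
  }
  n_big <- sum(g$n == "N")
  if (n_big == 2L) {
    if (model$nn_lethal) return("lethal")
    return(model$nn_phenotype)
  }
  has_S <- any(g$s == "S")
  if (has_S) {
    return(if (n_big == 1L) "linear" else "scaled")
  }
  # two loss-of-function doses at the S locus
  if (any(g$s == "s*")) return("nude")
  if (n_big == 1L) "nude" else "scattered"
}

#' Is a genotype viable under a model?
#'
#' @inheritParams phenotype_of
#' @return Logical.
#' @export
is_viable <- function(genotype, model = standard_model()) {
  phenotype_of(genotype, model) != "lethal"
}

stop_if_not_viable <- function(genotype, model) {
  g <- as_genotype(genotype)
  if (!is_viable(g, model)) {
    stop("parent genotype ", sQuote(format(g)), " is not viable under the ",
         sQuote(model$name), " model (NN homozygotes die before hatching)")
  }
  g
}

#' Enumerate all two-locus genotypes admitted by a model
#'
#' @param model An [allele_model()].
#' @param viable_only Drop genotypes whose phenotype is lethal.
#' @return Character vector of canonical genotype strings.
#' @export
all_genotypes <- function(model = standard_model(), viable_only = TRUE) {
  s_alleles <- if (model$strong_s) S_ALLELE_ORDER else c("S", "s")
  s_pairs <- utils::combn(length(s_alleles) + 1L, 2L) # pairs with repetition
  s_pairs <- lapply(seq_len(ncol(s_pairs)), function(i) {
    idx <- s_pairs[, i] - c(0L, 1L)
    s_alleles[idx]
  })
  n_pairs <- list(c("N", "N"), c("N", "n"), c("n", "n"))
  out <- character(0)
  for (sp in s_pairs) {
    for (np in n_pairs) {
      g <- new_genotype(sp, np)
      if (!viable_only || is_viable(g, model)) out <- c(out, format(g))
    }
  }
  out
}

#' Genotypes compatible with an observed parental phenotype
#'
#' Inverts the phenotype map: which viable genotypes could a parent showing
#' the given scale pattern carry? `irregular` and `mirror` are treated as the
#' aggregate `scattered`.
#'
#' @param phenotype One of the observable categories (or `"scattered"`).
#' @param model An [allele_model()].
#' @return Character vector of canonical genotype strings.
#' @examples
#' compatible_genotypes("linear")           # SSNn, SsNn
#' compatible_genotypes("nude")             # ssNn
#' compatible_genotypes("nude", weak_n_model())  # ssNN joins ssNn
#' @export
compatible_genotypes <- function(phenotype, model = standard_model()) {
  stopifnot(is.character(phenotype), length(phenotype) == 1L)
  if (phenotype == "lethal") {
    stop("lethal is not an observable parental phenotype")
  }
  target <- if (phenotype %in% c("irregular", "mirror")) "scattered" else phenotype
  if (!target %in% phenotype_categories()) {
    stop("unknown phenotype category: ", sQuote(phenotype))
  }
  gs <- all_genotypes(model, viable_only = TRUE)
  gs[vapply(gs, function(g) phenotype_of(g, model) == target, logical(1))]
}
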