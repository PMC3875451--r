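#' Gamete distribution of a parent genotype
#'
#' Each gamete carries one allele per locus; the two loci assort
#' independently (they sit on different chromosomes), so every combination of
#' one S-locus and one N-locus allele is drawn with probability 1/4 and equal
#' gametes are pooled. Probabilities are exact fractions.
#'
#' @param parent Genotype string or `carp_genotype`.
#' @param model An [allele_model()]; the parent must be viable under it.
#' @return A data frame with columns `gamete`, `s_allele`, `n_allele`,
#'   `numerator`, `denominator`, `probability`.
#' @examples
#' gamete_distribution("SsNn")  # four gametes, 1/4 each
#' gamete_distribution("ssnn")  # single gamete sn
#' @export
gamete_distribution <- function(parent, model = standard_model()) {
  g <- stop_if_not_viable(parent, model)
  combos <- expand.grid(s = g$s, n = g$n, KEEP.OUT.ATTRS = FALSE,
                        stringsAsFactors = FALSE)
  key <- paste0(combos$s, combos$n)
  num <- tapply(rep(1L, 4L), key, sum)
  # order gametes canonically: S before s before s*, N before n
  s_of <- sub("[Nn]$", "", names(num))
  n_of <- substring(names(num), nchar(names(num)))
  ord <- order(match(s_of, S_ALLELE_ORDER), match(n_of, N_ALLELE_ORDER))
  num <- num[ord]
  g2 <- Reduce(gcd2, c(num, 4L))
  data.frame(
    gamete = names(num),
    s_allele = s_of[ord],
    n_allele = n_of[ord],
    numerator = as.integer(num / g2),
    denominator = as.integer(4L / g2),
    probability = as.numeric(num) / 4,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
}

# Enumerate the 16 equiprobable parental allele combinations of a cross and
# return one row per zygote cell (weight 1/16 each, before pooling).
zygote_cells <- function(p1, p2, model) {
  g1 <- stop_if_not_viable(p1, model)
  g2 <- stop_if_not_viable(p2, model)
  idx <- expand.grid(s1 = 1:2, n1 = 1:2, s2 = 1:2, n2 = 1:2)
  cells <- lapply(seq_len(nrow(idx)), function(i) {
    z <- new_genotype(c(g1$s[idx$s1[i]], g2$s[idx$s2[i]]),
                      c(g1$n[idx$n1[i]], g2$n[idx$n2[i]]))
    data.frame(
      gamete1 = paste0(g1$s[idx$s1[i]], g1$n[idx$n1[i]]),
      gamete2 = paste0(g2$s[idx$s2[i]], g2$n[idx$n2[i]]),
      genotype = format(z),
      phenotype = phenotype_of(z, model),
      stringsAsFactors = FALSE
    )
  })
  do.call(rbind, cells)
}

#' Expected offspring phenotype distribution of a cross
#'
#' Enumerates all 16 equiprobable gamete combinations of the two parents and
#' pools them by phenotype under the chosen allele model. The result is a
#' zygote-level distribution: the lethal class (NN homozygotes under the
#' standard model) is included. Use [condition_on_survival()] for the
#' distribution among hatched offspring.
#'
#' @param p1,p2 Parent genotypes (strings or `carp_genotype`); both must be
#'   viable under `model`. The result is symmetric in parent order.
#' @param model An [allele_model()].
#' @return A [phenotype_dist()] with `includes_lethal = TRUE`.
#' @examples
#' cross_distribution("SsNn", "SsNn")  # 3:6:1:2:4 / 16
#' cross_distribution("ssNn", "ssnn")  # half nude, half scattered
#' @export
cross_distribution <- function(p1, p2, model = standard_model()) {
  cells <- zygote_cells(p1, p2, model)
  num <- tapply(rep(1L, nrow(cells)), cells$phenotype, sum)
  ord <- order(match(names(num), phenotype_categories()))
  phenotype_dist(num[ord], 16L, includes_lethal = TRUE)
}

#' Punnett square of a cross
#'
#' The classical gamete-by-gamete grid: one row per (father gamete, mother
#' gamete) combination with its exact probability and the resulting zygote
#' genotype and phenotype. Aggregating the grid by phenotype reproduces
#' [cross_distribution()].
#'
#' @inheritParams cross_distribution
#' @return A data frame with columns `gamete1`, `gamete2`, `genotype`,
#'   `phenotype`, `numerator`, `denominator`, `probability`; one row per
#'   distinct gamete pair.
#' @examples
#' punnett_table("SsNn", "SsNn")  # 16 cells, 4 lethal
#' @export
punnett_table <- function(p1, p2, model = standard_model()) {
  cells <- zygote_cells(p1, p2, model)
  key <- paste(cells$gamete1, cells$gamete2, sep = " x ")
  agg <- tapply(rep(1L, nrow(cells)), key, sum)
  first <- cells[!duplicated(key), , drop = FALSE]
  first <- first[order(match(paste(first$gamete1, first$gamete2, sep = " x "),
                             names(agg))), , drop = FALSE]
  n <- as.integer(agg[paste(first$gamete1, first$gamete2, sep = " x ")])
  out <- data.frame(
    gamete1 = first$gamete1,
    gamete2 = first$gamete2,
    genotype = first$genotype,
    phenotype = first$phenotype,
    numerator = n,
    denominator = 16L,
    probability = n / 16,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  out[order(out$gamete1, out$gamete2, method = "radix"), , drop = FALSE]
}

#' Enumerate genotype hypotheses for a pair of parental phenotypes
#'
#' Lists every viable parental genotype pair compatible with the two observed
#' phenotypes under an allele model, computes each pair's zygote-level
#' offspring distribution, and groups pairs with identical distributions into
#' equivalence classes (e.g. SSnn x SSnn and SSnn x Ssnn both give all-scaled
#' offspring). Classes are never silently collapsed: every member pair is
#' listed.
#'
#' @param phenotype1,phenotype2 Observable parental phenotypes (`"scaled"`,
#'   `"linear"`, `"irregular"`, `"mirror"`, `"scattered"`, `"nude"`).
#' @param model An [allele_model()].
#' @return A list of equivalence classes, each a list with elements `members`
#'   (character vector of `"g1 x g2"` pair labels), `distribution`
#'   (zygote-level [phenotype_dist()]) and `class_id`.
#' @examples
#' # the classical footnote case: the linear parent may be SSNn or SsNn
#' expected_for_cross_type("linear", "nude")
#' @export
expected_for_cross_type <- function(phenotype1, phenotype2,
                                    model = standard_model()) {
  gs1 <- compatible_genotypes(phenotype1, model)
  gs2 <- compatible_genotypes(phenotype2, model)
  seen <- character(0)
  pairs <- list()
  for (a in gs1) {
    for (b in gs2) {
      key <- paste(sort(c(a, b), method = "radix"), collapse = " x ")
      if (key %in% seen) next
      seen <- c(seen, key)
      pairs[[key]] <- cross_distribution(a, b, model)
    }
  }
  if (!length(pairs)) return(list())
  dist_key <- vapply(pairs, format, character(1))
  classes <- split(names(pairs), factor(dist_key, levels = unique(dist_key)))
  out <- vector("list", length(classes))
  for (i in seq_along(classes)) {
    out[[i]] <- list(
      class_id = i,
      members = unname(classes[[i]]),
      distribution = pairs[[classes[[i]][1]]]
    )
  }
  out
}
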