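#' Read a cross table from CSV
#'
#' Expects one row per cross with columns `label`, `location`,
#' `parent1_phenotype`, `parent2_phenotype`, `total_n`, and one column per
#' observed category (`scaled`, `linear`, `irregular`, `mirror`, `nude`;
#' missing columns are treated as zero). In `"percentages"` mode the category
#' columns hold percentages of `total_n` and are converted to integer counts
#' via [reconstruct_counts()]; in `"counts"` mode they are integer counts.
#'
#' @param path CSV file path.
#' @param mode `"counts"` or `"percentages"`.
#' @return List of [observed_cross()] records (empty, with a warning, for an
#'   empty file). Malformed rows are reported with their row number.
#' @export
load_cross_table <- function(path, mode = c("counts", "percentages")) {
  mode <- match.arg(mode)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) {
    warning("cross table ", sQuote(path), " contains no rows")
    return(list())
  }
  required <- c("label", "parent1_phenotype", "parent2_phenotype", "total_n")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("cross table lacks required columns: ",
         paste(missing_cols, collapse = ", "))
  }
  cat_cols <- intersect(phenotype_categories(TRUE), names(df))
  if (!length(cat_cols)) stop("cross table has no phenotype category columns")
  out <- vector("list", nrow(df))
  for (i in seq_len(nrow(df))) {
    vals <- stats::setNames(as.numeric(df[i, cat_cols]), cat_cols)
    vals[is.na(vals)] <- 0
    counts <- tryCatch(
      if (mode == "percentages") {
        reconstruct_counts(df$total_n[i], vals)
      } else {
        stats::setNames(as.integer(vals), names(vals))
      },
      error = function(e) stop("row ", i, " (", df$label[i], "): ",
                               conditionMessage(e), call. = FALSE)
    )
    counts <- counts[counts > 0]
    out[[i]] <- tryCatch(
      observed_cross(
        label = df$label[i],
        parent_phenotypes = c(df$parent1_phenotype[i], df$parent2_phenotype[i]),
        counts = counts,
        location = if ("location" %in% names(df)) df$location[i] else NA_character_,
        total_n = df$total_n[i]
      ),
      error = function(e) stop("row ", i, " (", df$label[i], "): ",
                               conditionMessage(e), call. = FALSE)
    )
  }
  out
}

#' Write observed crosses to CSV
#'
#' Inverse of [load_cross_table()] in counts mode: a write-then-read
#' round-trip reproduces the records exactly.
#'
#' @param crosses List of [observed_cross()] records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_cross_table <- function(crosses, path) {
  cats <- phenotype_categories(TRUE)
  rows <- lapply(crosses, function(oc) {
    stopifnot(inherits(oc, "observed_cross"))
    counts <- stats::setNames(integer(length(cats)), cats)
    counts[names(oc$counts)] <- oc$counts
    cbind(
      data.frame(label = oc$label, location = oc$location,
                 parent1_phenotype = oc$parent_phenotypes[1],
                 parent2_phenotype = oc$parent_phenotypes[2],
                 total_n = oc$total_n, stringsAsFactors = FALSE),
      as.data.frame(as.list(counts))
    )
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' The 19 published crosses
#'
#' The packaged transcription of the 19-cross phenotype table: labels, cross
#' types, locations, parental origins and IDs, total offspring numbers, and
#' observed category percentages, together with the printed expected-
#' percentage strings kept verbatim for provenance. The two linear x mirror
#' rows carry expected cells that are inconsistent with Punnett arithmetic
#' for the admissible parental genotypes; they are flagged
#' (`inconsistent_with_model`) rather than corrected, and the package's own
#' exact expectations should be obtained from [expected_for_cross_type()].
#'
#' @param raw If `TRUE`, return the full transcription data frame; otherwise
#'   a list of [observed_cross()] records (counts reconstructed from the
#'   printed percentages and totals).
#' @return Data frame or list of `observed_cross`.
#' @examples
#' length(table2_crosses())  # 19
#' subset(table2_crosses(raw = TRUE), inconsistent_with_model)$label
#' @export
table2_crosses <- function(raw = FALSE) {
  path <- system.file("extdata", "table2_crosses.csv", package = "carpscales",
                      mustWork = TRUE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (raw) return(df)
  crosses <- vector("list", nrow(df))
  cats <- phenotype_categories(TRUE)
  for (i in seq_len(nrow(df))) {
    pct <- stats::setNames(as.numeric(df[i, paste0("obs_", cats)]), cats)
    pct <- pct[pct > 0]
    counts <- reconstruct_counts(df$f1_n[i], pct)
    crosses[[i]] <- observed_cross(
      label = df$label[i],
      parent_phenotypes = c(df$parent1_phenotype[i], df$parent2_phenotype[i]),
      counts = counts,
      location = df$location[i],
      total_n = df$f1_n[i]
    )
  }
  crosses
}

#' Write a phenotype distribution to CSV
#'
#' @param dist A [phenotype_dist()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distribution <- function(dist, path) {
  utils::write.csv(as.data.frame(dist), path, row.names = FALSE)
  invisible(path)
}

#' Write a scale map as a plain-text grid or PGM image
#'
#' @param map A `scale_map` logical matrix.
#' @param path Output path; `format = "pgm"` writes a binary-valued ASCII
#'   (P2) portable graymap, `"csv"` a 0/1 grid.
#' @param format `"csv"` or `"pgm"`.
#' @return `path`, invisibly.
#' @export
write_scale_map <- function(map, path, format = c("csv", "pgm")) {
  format <- match.arg(format)
  m <- matrix(as.integer(map), nrow(map), ncol(map))
  if (format == "csv") {
    utils::write.table(m, path, sep = ",", row.names = FALSE,
                       col.names = FALSE)
  } else {
    lines <- c("P2", paste(ncol(m), nrow(m)), "1",
               apply(m, 1L, paste, collapse = " "))
    writeLines(lines, path)
  }
  invisible(path)
}
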