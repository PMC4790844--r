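FEATHER_COLS <- c("sample_id", "colony_id", "latitude", "longitude", ISO_COLS)
GENOTYPE_COLS <- c("sample_id", "locus_id", "allele_a", "allele_b")

#' Read and validate a feather isotope table
#'
#' Reads a comma-separated, UTF-8, "."-decimal CSV with the canonical columns
#' `sample_id, colony_id, latitude, longitude, d2H, d13C, d15N`. Rows with a
#' missing isotope value are excluded with a warning reporting how many were
#' dropped; structural problems (missing column, duplicated sample id,
#' non-numeric isotope entry, inconsistent colony coordinates) are hard
#' errors naming the offender.
#'
#' @param path CSV file path.
#' @param header_map optional named character vector mapping file headers to
#'   canonical names, e.g. `c(dD = "d2H", site = "colony_id")`, to
#'   accommodate other column-naming dialects.
#' @return A validated `feather_table` data.frame, row order preserved.
#' @export
read_feathers <- function(path, header_map = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, check.names = FALSE,
                        colClasses = "character")
  if (!is.null(header_map)) {
    hit <- names(df) %in% names(header_map)
    names(df)[hit] <- unname(header_map[names(df)[hit]])
  }
  missing_cols <- setdiff(FEATHER_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, FEATHER_COLS]
  dup <- df$sample_id[duplicated(df$sample_id)]
  if (length(dup))
    stop("duplicated sample_id: ", paste(unique(dup), collapse = ", "))
  for (col in c("latitude", "longitude", ISO_COLS)) {
    raw <- trimws(df[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) & is.na(val))
    if (length(bad))
      stop("non-numeric value in column '", col, "' at data row ", bad[1],
           " (sample_id ", df$sample_id[bad[1]], "): '", raw[bad[1]], "'")
    df[[col]] <- val
  }
  if (anyNA(df$latitude) || anyNA(df$longitude))
    stop("missing coordinates at data row ",
         which(is.na(df$latitude) | is.na(df$longitude))[1])
  incomplete <- !stats::complete.cases(df[, ISO_COLS])
  if (any(incomplete)) {
    warning(sum(incomplete), " row(s) with missing isotope values excluded: ",
            paste(df$sample_id[incomplete], collapse = ", "))
    df <- df[!incomplete, , drop = FALSE]
  }
  if (nrow(df) == 0L) stop("no complete rows in ", path)
  coords <- unique(df[, c("colony_id", "latitude", "longitude")])
  if (anyDuplicated(coords$colony_id))
    stop("inconsistent coordinates for colony ",
         coords$colony_id[duplicated(coords$colony_id)][1])
  rownames(df) <- NULL
  class(df) <- c("feather_table", "data.frame")
  df
}

#' Write a feather isotope table to CSV
#'
#' Values are written at full double precision so a write/read round trip is
#' lossless.
#'
#' @param feathers a `feather_table`.
#' @param path output CSV path.
#' @return `path`, invisibly.
#' @export
write_feathers <- function(feathers, path) {
  stopifnot(all(FEATHER_COLS %in% names(feathers)))
  out <- as.data.frame(feathers)[, FEATHER_COLS]
  for (col in c("latitude", "longitude", ISO_COLS))
    out[[col]] <- format(out[[col]], digits = 17, trim = TRUE,
                         scientific = FALSE)
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a long-format genotype table
#'
#' Columns `sample_id, locus_id, allele_a, allele_b`; allele lengths are
#' positive integers (base pairs) or empty/NA for a missing locus. Storage
#' order of the two alleles carries no meaning.
#'
#' @param path CSV file path.
#' @return A `genotype_table` data.frame.
#' @export
read_genotypes <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  missing_cols <- setdiff(GENOTYPE_COLS, names(df))
  if (length(missing_cols))
    stop("missing required column(s): ", paste(missing_cols, collapse = ", "))
  df <- df[, GENOTYPE_COLS]
  for (col in c("allele_a", "allele_b")) {
    raw <- trimws(df[[col]])
    val <- suppressWarnings(as.numeric(raw))
    bad <- which(!is.na(raw) & nzchar(raw) &
                   (is.na(val) | val <= 0 | val != round(val)))
    if (length(bad))
      stop("allele lengths must be positive integers; bad value in '", col,
           "' at data row ", bad[1], ": '", raw[bad[1]], "'")
    df[[col]] <- as.integer(round(val))
  }
  if (anyDuplicated(df[, c("sample_id", "locus_id")]))
    stop("duplicated (sample_id, locus_id) pair")
  rownames(df) <- NULL
  class(df) <- c("genotype_table", "data.frame")
  df
}

#' @rdname read_genotypes
#' @param genotypes a `genotype_table`.
#' @export
write_genotypes <- function(genotypes, path) {
  stopifnot(all(GENOTYPE_COLS %in% names(genotypes)))
  utils::write.csv(as.data.frame(genotypes)[, GENOTYPE_COLS], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Drop colonies with too few samples
#'
#' Colonies represented by fewer than `min_n` feathers carry too little
#' information to estimate a trivariate covariance and are removed before
#' assignment (the convention in this analysis: colonies of 1 or 3 samples are
#' dropped, colonies of 6 are kept, hence the default of 5). Removals are
#' reported via [message()]. Filtering is idempotent.
#'
#' @param feathers a `feather_table`.
#' @param min_n minimum colony size retained (>= 1).
#' @return The filtered `feather_table`.
#' @export
filter_min_colony_size <- function(feathers, min_n = 5) {
  stopifnot(min_n >= 1)
  sizes <- table(feathers$colony_id)
  drop <- names(sizes)[sizes < min_n]
  if (length(drop))
    iso_message("excluding %d colony(ies) with n < %d: %s",
                length(drop), min_n,
                paste(sprintf("%s (n = %d)", drop, as.integer(sizes[drop])),
                      collapse = ", "))
  out <- feathers[!(feathers$colony_id %in% drop), , drop = FALSE]
  if (nrow(out) == 0L)
    stop("all colonies fall below the minimum size of ", min_n)
  rownames(out) <- NULL
  class(out) <- c("feather_table", "data.frame")
  out
}
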