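`%||%` <- function(a, b) if (is.null(a)) b else a

# Canonical isotope column names, in fixed axis order (H, C, N).
ISO_COLS <- c("d2H", "d13C", "d15N")

#' Deterministic child seed for a named random-number substream
#'
#' Derives an integer seed for one purpose (e.g. "isotopes", "genotypes",
#' "duplicates") from a root seed, so that consuming more random numbers for
#' one purpose never shifts the draws of another, and adding colonies does not
#' perturb unrelated streams.
#'
#' @param seed integer root seed.
#' @param stream character label of the substream.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
#' @examples
#' child_seed(1, "isotopes")
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stream))
  codes <- utf8ToInt(stream)
  # multiplicative hash of the label; all intermediates stay below 2^53 so
  # double arithmetic is exact
  h <- (sum(codes * seq_along(codes)) * 2654435761) %% 2147483647
  as.integer(((seed %% 2147483647) * 48271 + h) %% 2147483647)
}

# Extract the n x 3 isotope matrix from a feather table.
iso_matrix <- function(feathers) {
  stopifnot(all(ISO_COLS %in% names(feathers)))
  m <- as.matrix(feathers[, ISO_COLS])
  storage.mode(m) <- "double"
  m
}

# Symmetry check with tolerance.
is_symmetric <- function(m, tol = 1e-8) {
  is.matrix(m) && nrow(m) == ncol(m) &&
    max(abs(m - t(m))) <= tol * max(1, max(abs(m)))
}

# Smallest eigenvalue (symmetric part enforced).
min_eigen <- function(m) {
  min(eigen((m + t(m)) / 2, symmetric = TRUE, only.values = TRUE)$values)
}

iso_message <- function(...) message("[isocolony] ", sprintf(...))
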