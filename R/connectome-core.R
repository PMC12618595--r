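# Data model and I/O for parcellations and connectivity matrices.
#
# All correlations and regressions in the package operate on the canonical
# edge ordering defined by upper_triangle(): row-major over pairs (i, j)
# with i < j (1-based region indices over the parcellation order).

SYM_TOL <- 1e-8

#' Create a parcellation
#'
#' A parcellation is the fixed set of named brain regions (cortical plus
#' subcortical, Desikan-Killiany style) whose pairwise connections all
#' connectivity matrices describe. Optionally carries region centroid
#' coordinates in mm, from which Euclidean-distance matrices are derived.
#'
#' @param labels Character vector of unique region names.
#' @param centroids Optional numeric matrix, one row per region, 3 columns
#'   (x, y, z in mm). All entries must be finite.
#' @return An object of class `scfc_parcellation` with fields `labels`, `n`,
#'   `centroids`.
#' @export
parcellation <- function(labels, centroids = NULL) {
  labels <- as.character(labels)
  if (anyDuplicated(labels) > 0)
    stop_scfc("scfc_label_error", "parcellation labels must be unique")
  if (length(labels) < 2)
    stop_scfc("scfc_dimension_error", "parcellation needs at least 2 regions")
  if (!is.null(centroids)) {
    centroids <- as.matrix(centroids)
    if (nrow(centroids) != length(labels) || ncol(centroids) != 3)
      stop_scfc("scfc_dimension_error",
                "centroids must be %d x 3, got %d x %d",
                length(labels), nrow(centroids), ncol(centroids))
    if (!all(is.finite(centroids)))
      stop_scfc("scfc_value_error", "centroids must be finite")
    rownames(centroids) <- labels
  }
  structure(list(labels = labels, n = length(labels), centroids = centroids),
            class = "scfc_parcellation")
}

#' @export
print.scfc_parcellation <- function(x, ...) {
  cat(sprintf("<scfc_parcellation> %d regions%s\n", x$n,
              if (is.null(x$centroids)) "" else " (with centroids)"))
  invisible(x)
}

#' Create a connectivity matrix
#'
#' Wraps a square symmetric matrix over a parcellation, tagged by kind:
#' `"SC"` (structural, one of the five edge-weight variants), `"FC"`
#' (functional, one of the four frequency bands) or `"ED"` (Euclidean
#' distance). SC and ED entries must be nonnegative; FC entries may be
#' negative (amplitude-amplitude correlations). The diagonal must be zero
#' and asymmetry beyond 1e-8 is rejected (see `symmetrize`).
#'
#' @param values Square numeric matrix, n x n over `parc`.
#' @param kind One of `"SC"`, `"FC"`, `"ED"`.
#' @param variant For SC one of [sc_variants()]; for FC one of [fc_bands()];
#'   omitted for ED.
#' @param parc A [parcellation()].
#' @param normalized Logical flag: has the matrix been max-normalized?
#' @param symmetrize If `TRUE`, replace `values` by `(values + t(values))/2`
#'   instead of rejecting asymmetric input.
#' @return An object of class `scfc_matrix`.
#' @export
conn_matrix <- function(values, kind, variant = NULL, parc,
                        normalized = FALSE, symmetrize = FALSE) {
  kind <- match.arg(kind, MATRIX_KINDS)
  variant <- check_variant(kind, variant)
  values <- as.matrix(values)
  if (nrow(values) != parc$n || ncol(values) != parc$n)
    stop_scfc("scfc_dimension_error",
              "matrix is %d x %d but parcellation has %d regions",
              nrow(values), ncol(values), parc$n)
  if (!is.numeric(values) || !all(is.finite(values)))
    stop_scfc("scfc_value_error", "matrix entries must be finite numerics")
  if (symmetrize) values <- (values + t(values)) / 2
  asym <- max(abs(values - t(values)))
  if (asym > SYM_TOL)
    stop_scfc("scfc_asymmetry_error",
              "matrix asymmetric (max |m - t(m)| = %.3g > %.1g)", asym, SYM_TOL)
  values <- (values + t(values)) / 2   # remove sub-tolerance asymmetry
  if (any(abs(diag(values)) > 0))
    stop_scfc("scfc_diagonal_error", "diagonal must be exactly zero")
  if (kind %in% c("SC", "ED") && any(values < 0))
    stop_scfc("scfc_negative_error", "%s entries must be nonnegative", kind)
  if (normalized) {
    off <- max(abs(offdiag(values)))
    if (abs(off - 1) > 1e-10)
      stop_scfc("scfc_value_error",
                "normalized flag set but max off-diagonal |entry| is %.6g", off)
  }
  dimnames(values) <- list(parc$labels, parc$labels)
  structure(list(values = values, kind = kind, variant = variant,
                 parcellation = parc, normalized = normalized),
            class = "scfc_matrix")
}

check_variant <- function(kind, variant) {
  if (kind == "ED") {
    if (!is.null(variant))
      stop_scfc("scfc_variant_error", "ED matrices carry no variant")
    return(NULL)
  }
  allowed <- if (kind == "SC") SC_VARIANTS else FC_BANDS
  if (is.null(variant) || !variant %in% allowed)
    stop_scfc("scfc_variant_error", "%s variant must be one of: %s",
              kind, paste(allowed, collapse = ", "))
  variant
}

offdiag <- function(m) m[row(m) != col(m)]

#' @export
print.scfc_matrix <- function(x, ...) {
  cat(sprintf("<scfc_matrix> %s%s, %d x %d%s\n", x$kind,
              if (is.null(x$variant)) "" else paste0("/", x$variant),
              nrow(x$values), ncol(x$values),
              if (x$normalized) ", normalized" else ""))
  invisible(x)
}

#' Max-normalize a connectivity matrix
#'
#' Divides every entry by the maximum off-diagonal absolute value, so the
#' largest connection has weight 1 (nonnegative matrices map into `[0, 1]`).
#' Idempotent; a monotone (order-preserving) transform of the entries.
#'
#' @param m An `scfc_matrix` with at least one nonzero off-diagonal entry.
#' @return The normalized `scfc_matrix` with the `normalized` flag set.
#' @export
normalize_matrix <- function(m) {
  stopifnot(inherits(m, "scfc_matrix"))
  mx <- max(abs(offdiag(m$values)))
  if (mx == 0)
    stop_scfc("scfc_degenerate_error", "cannot normalize an all-zero matrix")
  m$values <- m$values / mx
  m$normalized <- TRUE
  m
}

#' Extract / rebuild the canonical edge vector
#'
#' `upper_triangle()` flattens the unique edges of a symmetric matrix into a
#' vector in row-major order over pairs (i, j), i < j; `from_upper_triangle()`
#' is its inverse, rebuilding the symmetric zero-diagonal matrix. All edge-wise
#' statistics in the package use this ordering.
#'
#' @param m An `scfc_matrix` or a plain square symmetric matrix.
#' @param v Numeric vector of length `n * (n - 1) / 2`.
#' @param n Region count.
#' @return `upper_triangle()`: numeric vector of length `n(n-1)/2`;
#'   `from_upper_triangle()`: an n x n symmetric matrix.
#' @export
upper_triangle <- function(m) {
  vals <- if (inherits(m, "scfc_matrix")) m$values else m
  t(vals)[lower.tri(vals)]   # transpose so ordering is row-major over i < j
}

#' @rdname upper_triangle
#' @export
from_upper_triangle <- function(v, n) {
  if (length(v) != n * (n - 1) / 2)
    stop_scfc("scfc_dimension_error",
              "edge vector has length %d, expected %d for n = %d",
              length(v), n * (n - 1) / 2, n)
  out <- matrix(0, n, n)
  out[lower.tri(out)] <- v
  out <- t(out)            # filled row-major over upper triangle
  out[lower.tri(out)] <- t(out)[lower.tri(out)]
  out
}

#' Read / write a connectivity matrix as delimited text
#'
#' Matrix files are plain CSV (comma default; tab accepted on read) with one
#' header row of region labels. The header, when present, must match the
#' parcellation's label order exactly. Kind and variant are not encoded in
#' the file; the caller asserts them.
#'
#' @param path File path.
#' @param parc Target [parcellation()].
#' @inheritParams conn_matrix
#' @return `read_matrix()`: a validated `scfc_matrix`. `write_matrix()`:
#'   `path`, invisibly. Round-trips preserve entries to better than 1e-12
#'   relative tolerance (15 significant digits are written).
#' @export
read_matrix <- function(path, parc, kind, variant = NULL,
                        normalized = FALSE, symmetrize = FALSE) {
  if (!file.exists(path))
    stop_scfc("scfc_io_error", "no such file: %s", path)
  first <- readLines(path, n = 1L)
  sep <- if (grepl("\t", first, fixed = TRUE)) "\t" else ","
  has_header <- !grepl("^[-+0-9.eE \t,]*$", first)
  raw <- utils::read.csv(path, header = has_header, sep = sep,
                         check.names = FALSE, colClasses = "character")
  if (has_header && !identical(names(raw), parc$labels))
    stop_scfc("scfc_label_error",
              "file header labels do not match parcellation order")
  vals <- suppressWarnings(matrix(as.numeric(as.matrix(raw)),
                                  nrow = nrow(raw)))
  if (anyNA(vals))
    stop_scfc("scfc_value_error", "non-numeric cell in %s", path)
  conn_matrix(vals, kind = kind, variant = variant, parc = parc,
              normalized = normalized, symmetrize = symmetrize)
}

#' @rdname read_matrix
#' @param m An `scfc_matrix` to write.
#' @export
write_matrix <- function(m, path) {
  stopifnot(inherits(m, "scfc_matrix"))
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  txt <- apply(m$values, 1, function(r)
    paste(formatC(r, digits = 15, format = "g"), collapse = ","))
  ok <- tryCatch({
    writeLines(c(paste(m$parcellation$labels, collapse = ","), txt), path)
    TRUE
  }, error = function(e) FALSE)
  if (!ok) stop_scfc("scfc_io_error", "cannot write %s", path)
  invisible(path)
}
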