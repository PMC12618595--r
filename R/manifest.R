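# Subjects, cohorts and the subject manifest file.

#' Create a subject record
#'
#' @param id Subject identifier (coerced to character).
#' @param age Age in years, positive.
#' @param group `"healthy"` or `"psychosis"` (case-insensitive).
#' @param panss For psychosis subjects, a list/vector with integer fields
#'   `total`, `positive`, `negative`, `general` (Positive and Negative
#'   Syndrome Scale); must be absent for healthy subjects. Components are
#'   validated for nonnegativity only (they need not sum to the total).
#' @return An object of class `scfc_subject`.
#' @export
subject <- function(id, age, group, panss = NULL) {
  group <- tolower(as.character(group))
  if (!group %in% c("healthy", "psychosis"))
    stop_scfc("scfc_group_error", "group must be healthy or psychosis, got %s",
              group)
  age <- as.numeric(age)
  if (!is.finite(age) || age <= 0)
    stop_scfc("scfc_value_error", "age must be positive")
  if (group == "psychosis") {
    if (is.null(panss))
      stop_scfc("scfc_panss_error", "psychosis subject %s lacks PANSS scores",
                id)
    panss <- as.list(panss)
    need <- c("total", "positive", "negative", "general")
    if (!all(need %in% names(panss)))
      stop_scfc("scfc_panss_error", "PANSS needs fields %s",
                paste(need, collapse = ", "))
    panss <- lapply(panss[need], function(x) {
      xn <- suppressWarnings(as.numeric(x))
      if (!is.finite(xn) || xn != round(xn) || xn < 0)
        stop_scfc("scfc_panss_error", "PANSS scores must be nonnegative integers")
      as.integer(xn)
    })
  } else if (!is.null(panss) && !all(is.na(unlist(panss)))) {
    stop_scfc("scfc_panss_error", "healthy subject %s must not carry PANSS", id)
  } else {
    panss <- NULL
  }
  structure(list(id = as.character(id), age = age, group = group,
                 panss = panss), class = "scfc_subject")
}

#' Assemble a cohort
#'
#' A cohort bundles subject metadata with the keyed set of connectivity
#' matrices, all over one shared parcellation. Matrices are keyed by
#' `(subject id, kind, variant)`; the Euclidean-distance matrix may be shared
#' cohort-wide under the key `ED`.
#'
#' @param subjects List of [subject()] records.
#' @param matrices Named list of `scfc_matrix` objects; names
#'   `"<id>.<kind>.<variant>"` (`"<id>.ED"` for distance matrices, or a single
#'   `"ED"` entry shared by all subjects).
#' @param parc The shared [parcellation()].
#' @return An object of class `scfc_cohort`.
#' @export
cohort <- function(subjects, matrices, parc) {
  ids <- vapply(subjects, function(s) s$id, "")
  if (anyDuplicated(ids) > 0)
    stop_scfc("scfc_value_error", "duplicate subject ids")
  for (nm in names(matrices)) {
    m <- matrices[[nm]]
    stopifnot(inherits(m, "scfc_matrix"))
    if (!identical(m$parcellation$labels, parc$labels))
      stop_scfc("scfc_label_error", "matrix %s uses a different parcellation", nm)
    sid <- strsplit(nm, ".", fixed = TRUE)[[1]][1]
    if (nm != "ED" && !sid %in% ids)
      stop_scfc("scfc_value_error", "matrix %s references unknown subject", nm)
  }
  structure(list(subjects = subjects, matrices = matrices, parcellation = parc),
            class = "scfc_cohort")
}

#' @export
print.scfc_cohort <- function(x, ...) {
  groups <- table(vapply(x$subjects, function(s) s$group, ""))
  cat(sprintf("<scfc_cohort> %d subjects (%s), %d matrices, %d regions\n",
              length(x$subjects),
              paste(names(groups), groups, sep = ": ", collapse = ", "),
              length(x$matrices), x$parcellation$n))
  invisible(x)
}

matrix_key <- function(id, kind, variant = NULL) {
  if (kind == "ED") paste(id, "ED", sep = ".") else
    paste(id, kind, variant, sep = ".")
}

#' Fetch one subject's matrix from a cohort
#'
#' @param coh An `scfc_cohort`.
#' @param id Subject id.
#' @param kind,variant Matrix key; a cohort-wide `"ED"` entry is returned for
#'   any subject when no subject-specific distance matrix exists.
#' @return An `scfc_matrix`.
#' @export
get_matrix <- function(coh, id, kind, variant = NULL) {
  key <- matrix_key(id, kind, variant)
  m <- coh$matrices[[key]]
  if (is.null(m) && kind == "ED") m <- coh$matrices[["ED"]]
  if (is.null(m))
    stop_scfc("scfc_missing_matrix_error", "no matrix %s in cohort", key)
  m
}

#' Read / write a subject manifest
#'
#' The manifest is a CSV with columns `id, age, group, panss_total,
#' panss_positive, panss_negative, panss_general`; the PANSS columns are
#' empty for healthy subjects and mandatory integers for psychosis subjects.
#' Group strings are case-insensitive.
#'
#' @param path CSV file path.
#' @return `read_manifest()`: list of [subject()] records.
#' @export
read_manifest <- function(path) {
  if (!file.exists(path))
    stop_scfc("scfc_io_error", "no such file: %s", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = "character")
  need <- c("id", "age", "group", "panss_total", "panss_positive",
            "panss_negative", "panss_general")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop_scfc("scfc_manifest_error", "manifest missing columns: %s",
              paste(miss, collapse = ", "))
  lapply(seq_len(nrow(df)), function(i) {
    row <- df[i, ]
    pn <- c(total = row$panss_total, positive = row$panss_positive,
            negative = row$panss_negative, general = row$panss_general)
    empty <- is.na(pn) | !nzchar(trimws(pn))
    if (tolower(row$group) == "psychosis" && any(empty))
      stop_scfc("scfc_panss_error",
                "psychosis subject %s has missing PANSS fields", row$id)
    subject(row$id, row$age, row$group,
            panss = if (all(empty)) NULL else as.list(pn))
  })
}

#' @rdname read_manifest
#' @param subjects List of [subject()] records to write.
#' @export
write_manifest <- function(subjects, path) {
  rows <- lapply(subjects, function(s) {
    p <- s$panss
    data.frame(id = s$id, age = s$age, group = s$group,
               panss_total = if (is.null(p)) "" else p$total,
               panss_positive = if (is.null(p)) "" else p$positive,
               panss_negative = if (is.null(p)) "" else p$negative,
               panss_general = if (is.null(p)) "" else p$general,
               stringsAsFactors = FALSE)
  })
  dir.create(dirname(path), showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
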