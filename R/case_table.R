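#' Construct a case table
#'
#' A case table holds the pool of known cases: a complete numeric feature
#' matrix and a binary outcome per case. All model fitting, weighting and
#' attribution in the package operates on this object. The pool must be
#' complete -- no missing entries are allowed, because per-patient weighting
#' and the weighted fit need every case's full feature vector.
#'
#' @param X numeric matrix (cases x features) with column names, or a
#'   data.frame coercible to one. No missing values.
#' @param y binary outcome vector (0/1), one per case.
#' @param scaling optional list of per-feature `offset` and `range` vectors
#'   recording how raw values map to the encoded scale (see
#'   [encode_query()]). `NULL` means values are already on their final scale.
#' @return An object of class `case_table` with elements `X`, `y`,
#'   `feature_names`, `n`, `p` and `scaling`.
#' @seealso [load_cases()] to build one from a CSV file.
#' @export
case_table <- function(X, y, scaling = NULL) {
  if (is.data.frame(X)) X <- as.matrix(X)
  if (!is.matrix(X) || !is.numeric(X)) {
    stop("`X` must be a numeric matrix or data.frame of numerics", call. = FALSE)
  }
  if (is.null(colnames(X))) stop("`X` must have column names", call. = FALSE)
  if (anyDuplicated(colnames(X))) {
    stop("duplicate feature names in `X`", call. = FALSE)
  }
  if (anyNA(X)) stop("missing values in the case pool are not allowed", call. = FALSE)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("length(y) must equal nrow(X)", call. = FALSE)
  if (anyNA(y) || !all(y %in% c(0, 1))) {
    stop("`y` must be binary 0/1 with no missing values", call. = FALSE)
  }
  structure(
    list(
      X = X,
      y = as.integer(y),
      feature_names = colnames(X),
      n = nrow(X),
      p = ncol(X),
      scaling = scaling
    ),
    class = "case_table"
  )
}

#' @export
print.case_table <- function(x, ...) {
  cat(sprintf(
    "case_table: %d cases x %d features (%d positive, %d negative)\n",
    x$n, x$p, sum(x$y == 1), sum(x$y == 0)
  ))
  cat("features:", paste(x$feature_names, collapse = ", "), "\n")
  cat("scaling:", if (is.null(x$scaling)) "none" else "min-max to [0,1]", "\n")
  invisible(x)
}

#' @export
as.data.frame.case_table <- function(x, row.names = NULL, optional = FALSE,
                                     outcome_column = "class", ...) {
  df <- as.data.frame(x$X)
  df[[outcome_column]] <- x$y
  df
}

# Map a character/factor column to 0/1 under the recognised binary codings.
# Returns NULL if the column is not recognisably binary-coded.
.decode_binary_column <- function(v) {
  if (is.numeric(v)) {
    return(if (all(v %in% c(0, 1))) as.numeric(v) else NULL)
  }
  v <- trimws(as.character(v))
  codings <- list(
    c(pos = "Yes", neg = "No"),
    c(pos = "Male", neg = "Female"),
    c(pos = "Positive", neg = "Negative"),
    c(pos = "1", neg = "0")
  )
  lv <- unique(v[!is.na(v)])
  for (cd in codings) {
    if (all(lv %in% cd)) {
      out <- ifelse(v == cd[["pos"]], 1, 0)
      out[is.na(v)] <- NA
      return(as.numeric(out))
    }
  }
  NULL
}

#' Load a pool of known cases from CSV
#'
#' Reads a CSV of labelled cases, encodes binary string columns
#' (Yes/No, Male/Female, Positive/Negative, 0/1) to 0/1, optionally min-max
#' scales continuous columns to `[0, 1]`, and validates completeness. The
#' scaling parameters are retained in the returned object so that incoming
#' patient values can be encoded identically with [encode_query()].
#'
#' @param path path to a CSV file with a header row.
#' @param outcome_column name of the binary outcome column (default
#'   `"class"`). It is removed from the feature set.
#' @param scaling `"minmax"` (default) to scale continuous features to
#'   `[0, 1]`, or `"none"` to leave values as read.
#' @return A [case_table()].
#' @export
load_cases <- function(path, outcome_column = "class",
                       scaling = c("minmax", "none")) {
  scaling <- match.arg(scaling)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!outcome_column %in% names(df)) {
    stop("outcome column '", outcome_column, "' not present in ", path,
      call. = FALSE
    )
  }

  y <- .decode_binary_column(df[[outcome_column]])
  if (is.null(y) || anyNA(y)) {
    stop("outcome column '", outcome_column, "' is not binary-coded",
      call. = FALSE
    )
  }
  feat <- df[setdiff(names(df), outcome_column)]

  enc <- lapply(feat, function(v) {
    b <- .decode_binary_column(v)
    if (!is.null(b)) b else if (is.numeric(v)) as.numeric(v) else v
  })
  bad <- names(enc)[!vapply(enc, is.numeric, logical(1))]
  if (length(bad)) {
    stop("non-numeric, non-binary-coded column(s): ",
      paste(bad, collapse = ", "),
      call. = FALSE
    )
  }
  X <- do.call(cbind, enc)
  colnames(X) <- names(enc)
  if (anyNA(X)) {
    stop("the case pool must be complete: missing values found", call. = FALSE)
  }

  sc <- NULL
  if (scaling == "minmax") {
    offset <- apply(X, 2, min)
    range <- apply(X, 2, max) - offset
    range[range == 0] <- 1 # constant column: encodes to 0
    X <- sweep(sweep(X, 2, offset, "-"), 2, range, "/")
    sc <- list(offset = offset, range = range)
  }
  case_table(X, y, scaling = sc)
}

#' Create a patient query
#'
#' A patient query is the partial feature record of an incoming patient:
#' a named numeric vector over the observed subset of the pool's features.
#' The outcome is never part of a query.
#'
#' @param ... either a single named numeric vector / list, or name = value
#'   pairs.
#' @return A named numeric vector of class `patient_query`.
#' @export
patient_query <- function(...) {
  args <- list(...)
  if (length(args) == 1L && is.null(names(args)) && !is.null(names(args[[1]]))) {
    v <- unlist(args[[1]])
  } else if (!is.null(names(args)) && all(names(args) != "") &&
    all(lengths(args) == 1L)) {
    # name = value pairs; values may carry stray names of their own
    v <- stats::setNames(unlist(lapply(args, unname)), names(args))
  } else {
    v <- unlist(args)
  }
  v <- vapply(v, as.numeric, numeric(1))
  if (length(v) == 0L) stop("a patient query must observe at least one feature", call. = FALSE)
  if (is.null(names(v)) || any(names(v) == "")) {
    stop("all query values must be named by feature", call. = FALSE)
  }
  if (anyNA(v)) stop("query values must not be missing", call. = FALSE)
  structure(v, class = "patient_query")
}

#' @export
print.patient_query <- function(x, ...) {
  cat("patient_query:", length(x), "observed feature(s)\n")
  print(stats::setNames(as.numeric(x), names(x)))
  invisible(x)
}

#' Encode or decode a patient query with the pool's scaling
#'
#' `encode_query()` maps raw feature values onto the scale of an encoded
#' [case_table()] using the min-max parameters stored at load time, clipping
#' to `[0, 1]` so out-of-range incoming values cannot leave the encoded
#' domain. `decode_query()` inverts the (unclipped) map back to raw units.
#' With `scaling = "none"` tables both are the identity.
#'
#' @param query a [patient_query()] or named numeric vector.
#' @param table a [case_table()].
#' @return A `patient_query` on the encoded (resp. raw) scale.
#' @export
encode_query <- function(query, table) {
  stopifnot(inherits(table, "case_table"))
  nm <- names(query)
  .check_known_features(nm, table)
  v <- as.numeric(query)
  if (!is.null(table$scaling)) {
    v <- (v - table$scaling$offset[nm]) / table$scaling$range[nm]
    v <- pmin(pmax(v, 0), 1)
  }
  patient_query(stats::setNames(v, nm))
}

#' @rdname encode_query
#' @export
decode_query <- function(query, table) {
  stopifnot(inherits(table, "case_table"))
  nm <- names(query)
  .check_known_features(nm, table)
  v <- as.numeric(query)
  if (!is.null(table$scaling)) {
    v <- v * table$scaling$range[nm] + table$scaling$offset[nm]
  }
  patient_query(stats::setNames(v, nm))
}

.check_known_features <- function(nm, table) {
  unknown <- setdiff(nm, table$feature_names)
  if (length(unknown)) {
    stop("unknown feature(s): ", paste(unknown, collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

#' Partition features into observed (initial) and missing (candidate)
#'
#' Given a patient query, splits the pool's features into the initial set
#' (already observed for this patient) and the candidate set (missing,
#' hence recommendable). Both are returned in the pool's canonical column
#' order, which is the tie-break order used throughout the package.
#'
#' @param query a [patient_query()] (or named vector); only its names are
#'   used. Alternatively a character vector of observed feature names.
#' @param table a [case_table()].
#' @return An object of class `feature_partition` with elements `initial`
#'   and `candidate`.
#' @export
identify_missing <- function(query, table) {
  stopifnot(inherits(table, "case_table"))
  nm <- if (is.character(query)) query else names(query)
  .check_known_features(nm, table)
  feature_partition(
    initial = table$feature_names[table$feature_names %in% nm],
    candidate = table$feature_names[!table$feature_names %in% nm]
  )
}

#' @rdname identify_missing
#' @param initial,candidate character vectors of feature names forming a
#'   disjoint partition of the table's features.
#' @export
feature_partition <- function(initial, candidate) {
  if (length(intersect(initial, candidate))) {
    stop("initial and candidate sets must be disjoint", call. = FALSE)
  }
  structure(list(initial = initial, candidate = candidate),
    class = "feature_partition"
  )
}

#' @export
print.feature_partition <- function(x, ...) {
  cat(
    "feature_partition\n  initial:  ",
    paste(x$initial, collapse = ", "),
    "\n  candidate:",
    if (length(x$candidate)) paste(x$candidate, collapse = ", ") else "(none)",
    "\n"
  )
  invisible(x)
}
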