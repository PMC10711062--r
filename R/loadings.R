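#' Coerce a rectangular object to a labelled loading matrix
#'
#' Loading matrices are the currency of every stage of the package: unrotated
#' loadings from extraction, target patterns, rotated patterns and population
#' patterns are all p x q numeric matrices with variable labels on the rows
#' and factor labels on the columns. This helper accepts a numeric matrix or
#' a data frame whose first column holds variable labels (the on-disk CSV
#' convention, see [read_loadings()]) and returns the matrix form.
#'
#' @param x A numeric matrix, or a data frame whose first column is a
#'   character vector of variable labels and whose remaining columns are
#'   numeric loadings.
#' @return A numeric matrix with `dimnames`.
#' @examples
#' df <- tibble::tibble(variable = c("x1", "x2"), F1 = c(.7, .6), F2 = c(0, .1))
#' as_loading_matrix(df)
#' @export
as_loading_matrix <- function(x) {
  if (is.matrix(x)) {
    m <- x
  } else if (is.data.frame(x)) {
    if (ncol(x) < 2) {
      abort("A loading data frame needs a label column plus at least one factor column.")
    }
    first <- x[[1]]
    if (is.numeric(first)) {
      # all-numeric frame: treat every column as loadings
      m <- as.matrix(x)
      rownames(m) <- paste0("x", seq_len(nrow(m)))
    } else {
      m <- as.matrix(x[, -1, drop = FALSE])
      rownames(m) <- as.character(first)
    }
  } else {
    abort("`x` must be a matrix or data frame of loadings.")
  }
  if (!is.numeric(m)) {
    bad <- which(!vapply(seq_len(ncol(m)), function(j) is.numeric(m[, j]), logical(1)))
    abort(paste0("Non-numeric loading column(s): ", paste(bad, collapse = ", ")))
  }
  storage.mode(m) <- "double"
  if (anyNA(m) || any(!is.finite(m))) {
    idx <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort(sprintf("Non-finite loading at row %d, column %d.", idx[1], idx[2]))
  }
  if (nrow(m) < ncol(m)) {
    abort(sprintf("Need at least as many variables as factors (got %d x %d).",
                  nrow(m), ncol(m)))
  }
  if (is.null(rownames(m))) rownames(m) <- paste0("x", seq_len(nrow(m)))
  if (is.null(colnames(m))) colnames(m) <- paste0("F", seq_len(ncol(m)))
  m
}

#' Build the uniform independent-clusters target pattern
#'
#' Constructs the binary target matrix of a perfect independent clusters
#' model (ICM): the Kronecker product of a q x q identity with a unit vector
#' of length p/q, so that variables fall into q contiguous blocks, each block
#' loading on exactly one factor.
#'
#' @param p Number of observed variables.
#' @param q Number of factors; must divide `p` for the uniform construction.
#' @return A p x q 0/1 matrix with variable and factor labels and attribute
#'   `construction = "uniform-icm"`.
#' @examples
#' build_icm_target(9, 3)
#' @seealso [as_target()] for supplying a custom binary pattern when block
#'   sizes are unequal.
#' @export
build_icm_target <- function(p, q) {
  stopifnot(length(p) == 1, length(q) == 1, p >= 1, q >= 1)
  if (p %% q != 0) {
    abort(sprintf(
      "q = %d does not divide p = %d; supply a custom 0/1 target via as_target().",
      q, p))
  }
  tgt <- kronecker(diag(q), matrix(1, p / q, 1))
  dimnames(tgt) <- list(paste0("x", seq_len(p)), paste0("F", seq_len(q)))
  attr(tgt, "construction") <- "uniform-icm"
  tgt
}

#' Validate a custom binary target pattern
#'
#' @param x A 0/1 matrix or labelled data frame (see [as_loading_matrix()]).
#' @return The validated 0/1 matrix with attribute `construction = "custom"`.
#' @export
as_target <- function(x) {
  m <- as_loading_matrix(x)
  if (!all(m %in% c(0, 1))) {
    abort("A target pattern may contain only 0 and 1 entries.")
  }
  empty <- which(colSums(m) == 0)
  if (length(empty) > 0) {
    abort(paste0("Target column(s) without any salient entry: ",
                 paste(empty, collapse = ", ")))
  }
  attr(m, "construction") <- "custom"
  m
}

# Resolve the `target` argument of the rotation front ends: NULL / "icm"
# build the uniform pattern for the dimensions at hand, anything else goes
# through as_target().
resolve_target <- function(target, p, q) {
  if (is.null(target) || (is.character(target) && identical(target, "icm"))) {
    return(build_icm_target(p, q))
  }
  tgt <- as_target(target)
  if (!all(dim(tgt) == c(p, q))) {
    abort(sprintf("Target is %d x %d but the loadings are %d x %d.",
                  nrow(tgt), ncol(tgt), p, q))
  }
  tgt
}

#' Read a loading matrix from CSV or TSV
#'
#' Expects a header row of factor labels and a first column of variable
#' labels. The delimiter is auto-detected from the header line (comma or
#' tab). Unicode minus signs are normalized to ASCII on read.
#'
#' @param path Path to a CSV/TSV file.
#' @return A labelled numeric matrix.
#' @export
read_loadings <- function(path) {
  header <- readLines(path, n = 1L, encoding = "UTF-8")
  delim <- if (grepl("\t", header)) "\t" else ","
  raw <- readr::read_delim(path, delim = delim, col_types = readr::cols(.default = "c"),
                           progress = FALSE, show_col_types = FALSE)
  if (ncol(raw) < 2) abort(sprintf("'%s': expected a label column plus loadings.", path))
  hdr <- names(raw)
  if (all(!is.na(suppressWarnings(as.numeric(gsub("−", "-", hdr)))))) {
    abort(sprintf("'%s': header row looks numeric; a factor-label header is required.", path))
  }
  vals <- as.matrix(raw[, -1, drop = FALSE])
  vals <- gsub("−", "-", vals)
  num <- suppressWarnings(array(as.numeric(vals), dim = dim(vals)))
  if (anyNA(num)) {
    idx <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf("'%s': non-numeric cell at data row %d, column '%s'.",
                  path, idx[1], hdr[idx[2] + 1]))
  }
  dimnames(num) <- list(as.character(raw[[1]]), hdr[-1])
  as_loading_matrix(num)
}

#' Write a loading matrix to CSV
#'
#' The inverse of [read_loadings()]: first column `variable`, header row of
#' factor labels, 15 significant digits so that write/read round-trips are
#' lossless.
#'
#' @param x Loading matrix (or data frame accepted by [as_loading_matrix()]).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_loadings <- function(x, path) {
  m <- as_loading_matrix(x)
  df <- tibble::as_tibble(m)
  df <- tibble::add_column(df, variable = rownames(m), .before = 1)
  readr::write_csv(df, path, progress = FALSE)
  invisible(path)
}

#' Pivot a loading matrix to a long tibble
#'
#' @param x Loading matrix or data frame.
#' @return A tibble with columns `variable`, `factor`, `loading`.
#' @export
loadings_tbl <- function(x) {
  m <- as_loading_matrix(x)
  tibble::tibble(
    variable = rep(rownames(m), times = ncol(m)),
    factor   = rep(colnames(m), each = nrow(m)),
    loading  = as.vector(m)
  )
}
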