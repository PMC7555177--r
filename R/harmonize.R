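# Harmonization of heterogeneous expression matrices onto a common log2
# scale: positive shift to clear non-positive values, quantile
# normalization, log2 transform, with a reverse-transform path for data
# already stored as log2.

# helpers so each step works on either a bare matrix or a dataset object
.values <- function(x) if (inherits(x, "expression_dataset")) x$values else x
.with_values <- function(x, m) {
  if (inherits(x, "expression_dataset")) {
    x$values <- m
    x
  } else {
    m
  }
}

#' Shift a matrix so all values are positive
#'
#' If the minimum value m is <= 0, adds (-m + 0.01) to every entry so the
#' new minimum is exactly 0.01; otherwise returns the input unchanged. The
#' small offset clears zeros ahead of the log2 transform.
#'
#' @param x an [expression_dataset()] or numeric matrix.
#' @return object of the same type with a strictly positive value matrix.
#' @export
positive_shift <- function(x) {
  m <- .values(x)
  mn <- min(m, na.rm = TRUE)
  if (mn <= 0) {
    m <- m + (-mn + 0.01)
  }
  .with_values(x, m)
}

#' Quantile normalize the columns of an expression matrix
#'
#' Forces every sample (column) onto the common reference distribution
#' given by the row-wise mean of the sorted columns; ties within a column
#' receive the average of the reference values they span. Missing cells are
#' imputed as the row median first (flagged via the `n_imputed` attribute).
#'
#' @param x an [expression_dataset()] or numeric matrix.
#' @return object of the same type; all columns share one sorted-value
#'   multiset afterwards.
#' @export
quantile_normalize <- function(x) {
  m <- .values(x)
  n_imputed <- 0L
  if (anyNA(m)) {
    med <- apply(m, 1, stats::median, na.rm = TRUE)
    idx <- which(is.na(m), arr.ind = TRUE)
    n_imputed <- nrow(idx)
    m[idx] <- med[idx[, 1]]
    if (anyNA(m)) {
      stop("rows with all values missing cannot be imputed", call. = FALSE)
    }
  }
  out <- limma::normalizeQuantiles(m, ties = TRUE)
  dimnames(out) <- dimnames(m)
  res <- .with_values(x, out)
  if (inherits(res, "expression_dataset")) {
    attr(res, "n_imputed") <- n_imputed
  }
  res
}

#' Harmonize a dataset onto the common quantile-normalized log2 scale
#'
#' Pipeline: values stored as log2 are first reverse-transformed (2^x);
#' then [positive_shift()], [quantile_normalize()], and a final log2
#' transform. The output always carries `is_log2 = TRUE`.
#'
#' @param dataset an [expression_dataset()].
#' @return harmonized [expression_dataset()], all values finite, log2 scale.
#' @export
harmonize <- function(dataset) {
  stopifnot(inherits(dataset, "expression_dataset"))
  m <- dataset$values
  if (dataset$is_log2) {
    m <- 2^m
    if (any(!is.finite(m[!is.na(m)]))) {
      stop("numeric range error: non-finite values after reverse ",
           "log2 transform", call. = FALSE)
    }
  }
  m <- .values(positive_shift(m))
  dataset$values <- m
  dataset$is_log2 <- FALSE
  dataset <- quantile_normalize(dataset)
  dataset$values <- log2(dataset$values)
  if (any(!is.finite(dataset$values))) {
    stop("numeric range error: non-finite values after log2 transform",
         call. = FALSE)
  }
  dataset$is_log2 <- TRUE
  dataset
}

#' Guess whether a matrix is already log2 transformed
#'
#' Microarray log2 intensities rarely exceed ~20, while linear-scale
#' intensities reach the thousands. Values at or below `threshold`
#' (default 30, boundary inclusive) are taken as log2. Advisory only;
#' override per dataset where the scale is known.
#'
#' @param x an [expression_dataset()] or numeric matrix.
#' @param threshold maximum-value cutoff separating the two scales.
#' @return `TRUE` if the matrix looks log2-scaled, else `FALSE`.
#' @export
detect_log_scale <- function(x, threshold = 30) {
  mx <- max(.values(x), na.rm = TRUE)
  mx <= threshold
}
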