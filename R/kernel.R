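#' Construct a similarity kernel matrix
#'
#' A kernel is a named square matrix of pairwise similarities in \[0, 1\]
#' over one entity type (miRNAs or diseases). Symmetry is required (not
#' silently repaired); the diagonal is forced to exactly 1 when it is
#' within `1e-8` of 1 and rejected otherwise.
#'
#' @param S named square numeric matrix.
#' @param label kernel flavour: one of `"functional"`, `"sequence"`,
#'   `"semantic"`, `"hamming"`.
#' @param tol tolerance for symmetry / diagonal checks.
#' @return The validated matrix with class `kernel_matrix` and a `label`
#'   attribute.
#' @export
kernel_matrix <- function(S, label = c("functional", "sequence", "semantic", "hamming"),
                          tol = 1e-8) {
  label <- match.arg(label)
  if (!is.matrix(S)) S <- as.matrix(S)
  storage.mode(S) <- "double"
  if (nrow(S) != ncol(S)) stop("kernel must be square", call. = FALSE)
  if (is.null(rownames(S)) || is.null(colnames(S))) {
    stop("kernel must have row and column names", call. = FALSE)
  }
  if (!identical(rownames(S), colnames(S))) {
    stop("kernel row and column names must match", call. = FALSE)
  }
  asym <- abs(S - t(S))
  if (any(asym > tol)) {
    w <- which(asym == max(asym), arr.ind = TRUE)[1, ]
    stop(sprintf("kernel not symmetric: S(%s, %s)=%.6g but S(%s, %s)=%.6g",
                 rownames(S)[w[1]], colnames(S)[w[2]], S[w[1], w[2]],
                 rownames(S)[w[2]], colnames(S)[w[1]], S[w[2], w[1]]),
         call. = FALSE)
  }
  dg <- diag(S)
  if (any(abs(dg - 1) > tol)) {
    bad <- which.max(abs(dg - 1))
    stop(sprintf("kernel diagonal must be 1; entry for %s is %.6g",
                 rownames(S)[bad], dg[bad]), call. = FALSE)
  }
  if (any(dg != 1)) {
    message("kernel diagonal within tolerance of 1; forcing to exactly 1")
    diag(S) <- 1
  }
  if (min(S) < -tol || max(S) > 1 + tol) {
    stop("kernel entries must lie in [0, 1]", call. = FALSE)
  }
  S[S < 0] <- 0
  S[S > 1] <- 1
  structure(S, class = c("kernel_matrix", "matrix"), label = label)
}

#' @export
print.kernel_matrix <- function(x, ...) {
  cat(sprintf("<kernel_matrix: %s> %d x %d entities\n",
              attr(x, "label"), nrow(x), ncol(x)))
  invisible(x)
}

#' Read a similarity kernel from a named-matrix TSV file
#'
#' The file holds a square matrix with a header row and first-column row
#' names. Rows/columns are reordered to `expected_names` (the file may hold
#' a superset); the reorder is a pure permutation/subset, never a value
#' change.
#'
#' @param path file path.
#' @param expected_names ordered identifiers the kernel must cover; `NULL`
#'   keeps the file's own (lexicographically sorted) order.
#' @param label kernel flavour, recorded on the result.
#' @return A `kernel_matrix`.
#' @export
read_kernel_matrix <- function(path, expected_names = NULL,
                               label = c("functional", "sequence", "semantic", "hamming")) {
  label <- match.arg(label)
  M <- read_named_matrix(path)
  if (is.null(colnames(M))) stop("kernel file must have a header row", call. = FALSE)
  if (!is.null(expected_names)) {
    missing <- setdiff(expected_names, rownames(M))
    if (length(missing)) {
      stop("kernel is missing entities: ", paste(missing, collapse = ", "),
           call. = FALSE)
    }
    M <- M[expected_names, expected_names, drop = FALSE]
  } else {
    ord <- canonical_order(rownames(M))
    M <- M[ord, ord, drop = FALSE]
  }
  kernel_matrix(M, label = label)
}

#' Write a kernel (or any named square matrix) as TSV
#'
#' @param K matrix with row/column names.
#' @param path output path.
#' @export
write_kernel_matrix <- function(K, path) {
  write_named_matrix(unclass(K), path)
}

#' Strip kernel class and label, returning the bare similarity matrix
#'
#' @param x a `kernel_matrix`.
#' @param ... unused.
#' @return A plain named numeric matrix.
#' @method as.matrix kernel_matrix
#' @export
as.matrix.kernel_matrix <- function(x, ...) sim_matrix(x)

# Internal: bare matrix view (drops class and label attribute).
sim_matrix <- function(x) {
  x <- unclass(x)
  attr(x, "label") <- NULL
  x
}

# Internal: check a kernel-like matrix is aligned with entity names.
check_alignment <- function(K, names, what) {
  if (!identical(rownames(K), names)) {
    stop(what, " is not aligned with the association data entity names",
         call. = FALSE)
  }
  invisible(TRUE)
}
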