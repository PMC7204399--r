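#' Construct a miRNA-disease association object
#'
#' Wraps a Boolean bipartite matrix of experimentally verified
#' miRNA-disease associations. Rows are miRNAs, columns are diseases, and
#' an entry of 1 marks a known association. Entity names are sorted
#' lexicographically (C locale) so that every downstream matrix shares one
#' canonical order.
#'
#' @param MD numeric matrix with entries in \{0, 1\}; must carry row names
#'   (miRNA identifiers) and column names (disease identifiers).
#' @return An object of class `association_data`: a list with elements
#'   `mirna_names`, `disease_names`, and the reordered 0/1 matrix `MD`.
#' @examples
#' MD <- matrix(c(1, 0, 1, 1), 2, 2,
#'              dimnames = list(c("m1", "m2"), c("d1", "d2")))
#' association_data(MD)
#' @export
association_data <- function(MD) {
  if (!is.matrix(MD)) MD <- as.matrix(MD)
  storage.mode(MD) <- "double"
  if (is.null(rownames(MD)) || is.null(colnames(MD))) {
    stop("association matrix must have row (miRNA) and column (disease) names",
         call. = FALSE)
  }
  if (nrow(MD) < 2L || ncol(MD) < 2L) {
    stop("need at least 2 miRNAs and 2 diseases", call. = FALSE)
  }
  if (anyDuplicated(rownames(MD))) stop("duplicate miRNA names", call. = FALSE)
  if (anyDuplicated(colnames(MD))) stop("duplicate disease names", call. = FALSE)
  bad <- which(!(MD %in% c(0, 1)))
  if (length(bad)) {
    i <- ((bad[1] - 1L) %% nrow(MD)) + 1L
    j <- ((bad[1] - 1L) %/% nrow(MD)) + 1L
    stop(sprintf("association entries must be 0 or 1; cell (%s, %s) is %s",
                 rownames(MD)[i], colnames(MD)[j], format(MD[i, j])),
         call. = FALSE)
  }
  mo <- canonical_order(rownames(MD))
  do <- canonical_order(colnames(MD))
  MD <- MD[mo, do, drop = FALSE]
  structure(
    list(mirna_names = rownames(MD), disease_names = colnames(MD), MD = MD),
    class = "association_data"
  )
}

# Locale-independent lexicographic order (radix = C-locale byte order).
canonical_order <- function(x) order(x, method = "radix")

#' @export
print.association_data <- function(x, ...) {
  cat(sprintf("<association_data> %d miRNAs x %d diseases, %d known associations\n",
              length(x$mirna_names), length(x$disease_names), sum(x$MD)))
  invisible(x)
}

#' @export
dim.association_data <- function(x) dim(x$MD)

#' Build association data from an edge table
#'
#' @param edges data frame whose first two columns are miRNA and disease
#'   identifiers; an optional third column holds 0/1 flags (rows flagged 0
#'   contribute the entities but not an association).
#' @param mirna_names,disease_names optional identifier vectors forcing the
#'   entity universe (useful when some entities have no associations).
#' @return An `association_data` object; all pairs not listed with a 1 are 0.
#' @export
as_association_data <- function(edges, mirna_names = NULL, disease_names = NULL) {
  edges <- as.data.frame(edges)
  if (nrow(edges) == 0L) stop("no associations", call. = FALSE)
  if (ncol(edges) < 2L) stop("edge table needs at least two columns", call. = FALSE)
  m <- as.character(edges[[1]])
  d <- as.character(edges[[2]])
  if (ncol(edges) >= 3L) {
    v <- suppressWarnings(as.numeric(as.character(edges[[3]])))
    bad <- which(is.na(v) | !(v %in% c(0, 1)))
    if (length(bad)) {
      stop(sprintf("association value must be 0 or 1 (row %d: '%s')",
                   bad[1], as.character(edges[[3]])[bad[1]]), call. = FALSE)
    }
  } else {
    v <- rep(1, length(m))
  }
  key <- paste(m, d, sep = "\r")
  agg <- tapply(v, key, function(z) length(unique(z)))
  conflict <- names(agg)[agg > 1L]
  if (length(conflict)) {
    pair <- strsplit(conflict[1], "\r", fixed = TRUE)[[1]]
    stop(sprintf("conflicting duplicate entries for pair (%s, %s)",
                 pair[1], pair[2]), call. = FALSE)
  }
  mn <- sort(unique(c(m, mirna_names)), method = "radix")
  dn <- sort(unique(c(d, disease_names)), method = "radix")
  MD <- matrix(0, length(mn), length(dn), dimnames = list(mn, dn))
  pos <- v == 1
  MD[cbind(match(m[pos], mn), match(d[pos], dn))] <- 1
  association_data(MD)
}

#' Read an association table from disk
#'
#' Two tab-separated layouts are supported. `edge_list`: rows of
#' `(mirna_id, disease_id)` or `(mirna_id, disease_id, 0/1)`, with an
#' optional header; every pair not listed as associated is taken to be 0.
#' `matrix`: a named 0/1 matrix with a header row of disease names and
#' first-column miRNA names.
#'
#' @param path file path.
#' @param format `"edge_list"` or `"matrix"`.
#' @return An `association_data` object.
#' @export
read_association_table <- function(path, format = c("edge_list", "matrix")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  if (format == "edge_list") {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    if (!length(lines)) stop("no associations", call. = FALSE)
    cells <- strsplit(lines, "\t", fixed = TRUE)
    first <- tolower(trimws(cells[[1]]))
    if (first[1] %in% c("mirna_id", "mirna", "mir")) {
      cells <- cells[-1]
      if (!length(cells)) stop("no associations", call. = FALSE)
    }
    ncols <- lengths(cells)
    if (any(ncols < 2L)) {
      stop(sprintf("row %d has fewer than two fields", which(ncols < 2L)[1]),
           call. = FALSE)
    }
    edges <- data.frame(
      mirna_id = vapply(cells, `[[`, "", 1L),
      disease_id = vapply(cells, `[[`, "", 2L),
      stringsAsFactors = FALSE
    )
    if (any(ncols >= 3L)) {
      edges$value <- vapply(cells, function(z) if (length(z) >= 3L) z[[3L]] else "1", "")
    }
    as_association_data(edges)
  } else {
    M <- read_named_matrix(path)
    association_data(M)
  }
}

#' Write an association table to disk
#'
#' @param ad an `association_data` object.
#' @param path output file path.
#' @param format `"edge_list"` (positive pairs only, with header) or
#'   `"matrix"` (full named 0/1 matrix; lossless for entities without
#'   associations).
#' @export
write_association_table <- function(ad, path, format = c("edge_list", "matrix")) {
  format <- match.arg(format)
  stopifnot(inherits(ad, "association_data"))
  if (format == "matrix") {
    write_named_matrix(ad$MD, path)
  } else {
    idx <- which(ad$MD == 1, arr.ind = TRUE)
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    tb <- tibble::tibble(
      mirna_id = ad$mirna_names[idx[, 1]],
      disease_id = ad$disease_names[idx[, 2]],
      value = 1
    )
    readr::write_tsv(tb, path)
  }
  invisible(path)
}

# Shared named-matrix TSV helpers (header row = column names, first column =
# row names under the header "name").
read_named_matrix <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 2L) stop("named matrix file needs row names and data columns",
                          call. = FALSE)
  rn <- as.character(df[[1]])
  M <- as.matrix(df[, -1, drop = FALSE])
  storage.mode(M) <- "double"
  rownames(M) <- rn
  M
}

write_named_matrix <- function(M, path) {
  tb <- tibble::as_tibble(M, .name_repair = "minimal")
  tb <- tibble::add_column(tb, name = rownames(M), .before = 1)
  readr::write_tsv(tb, path)
  invisible(path)
}
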