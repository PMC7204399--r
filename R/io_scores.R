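#' Write prediction scores as a long-format table
#'
#' One row per miRNA-disease pair with columns
#' `(mirna_id, disease_id, score, known_flag)`, sorted by score descending
#' with ties broken by `(mirna_id, disease_id)` ascending. Scores are
#' written with shortest round-trip precision, so
#' `read_scores(write_scores(x))` reproduces them bit-exactly.
#'
#' @param scores an `md_scores`.
#' @param path output file path.
#' @export
write_scores <- function(scores, path) {
  stopifnot(inherits(scores, "md_scores"))
  tb <- tidy(scores)
  # %.17g guarantees the double survives the text round trip bit-exactly
  tb$score <- sprintf("%.17g", tb$score)
  readr::write_tsv(tb, path)
  invisible(path)
}

#' @rdname write_scores
#' @return `read_scores` returns the long tibble.
#' @export
read_scores <- function(path) {
  # base strtod parsing is exact to the last bit; some fast TSV parsers are not
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("character", "character", "numeric",
                                         "integer"))
  tibble::as_tibble(df)
}

#' Write an evaluation report
#'
#' Writes a YAML summary (protocol, AUC, fold/score counts, configuration)
#' plus TSVs of the ROC points and the per-fold records.
#'
#' @param eval an `md_eval`.
#' @param prefix path prefix; files `<prefix>_summary.yaml`,
#'   `<prefix>_roc.tsv`, and `<prefix>_folds.tsv` are written.
#' @return Invisibly, the paths written.
#' @export
write_eval_report <- function(eval, prefix) {
  stopifnot(inherits(eval, "md_eval"))
  paths <- c(summary = paste0(prefix, "_summary.yaml"),
             roc = paste0(prefix, "_roc.tsv"),
             folds = paste0(prefix, "_folds.tsv"))
  cfg <- eval$config_used
  yaml::write_yaml(list(
    protocol = eval$protocol,
    auc = eval$auc,
    n_folds = nrow(eval$fold_records),
    n_positive_scores = length(eval$pos_scores),
    n_pooled_negative_scores = length(eval$neg_scores),
    alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma,
    k_neighbors = cfg$fusion$k_neighbors,
    iterations = cfg$fusion$iterations, delta = cfg$fusion$delta
  ), paths[["summary"]])
  readr::write_tsv(eval$roc_points, paths[["roc"]])
  readr::write_tsv(eval$fold_records, paths[["folds"]])
  invisible(paths)
}
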