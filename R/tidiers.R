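#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy prediction scores into a long tibble
#'
#' @param x an `md_scores`.
#' @param ... unused.
#' @return Tibble `(mirna_id, disease_id, score, known_flag)` sorted by
#'   score descending, ties by identifiers ascending.
#' @method tidy md_scores
#' @export
tidy.md_scores <- function(x, ...) {
  known <- x$known_mask
  if (is.null(known)) known <- matrix(NA_real_, nrow(x$Fpf), ncol(x$Fpf))
  tb <- tibble::tibble(
    mirna_id = rep(rownames(x$Fpf), times = ncol(x$Fpf)),
    disease_id = rep(colnames(x$Fpf), each = nrow(x$Fpf)),
    score = as.vector(x$Fpf),
    known_flag = as.integer(as.vector(known))
  )
  tb[order(-tb$score, tb$mirna_id, tb$disease_id, method = "radix"), ]
}

#' @rdname tidy.md_scores
#' @method glance md_scores
#' @export
glance.md_scores <- function(x, ...) {
  cfg <- x$config
  tibble::tibble(
    n_mirna = nrow(x$Fpf), n_disease = ncol(x$Fpf),
    n_known = if (is.null(x$known_mask)) NA_integer_ else as.integer(sum(x$known_mask)),
    alpha = if (is.null(cfg)) NA_real_ else cfg$alpha,
    beta = if (is.null(cfg)) NA_real_ else cfg$beta,
    gamma = if (is.null(cfg)) NA_real_ else cfg$gamma
  )
}

#' Tidy an evaluation report
#'
#' `tidy()` returns the ROC points; `glance()` a one-row summary.
#'
#' @param x an `md_eval`.
#' @param ... unused.
#' @method tidy md_eval
#' @export
tidy.md_eval <- function(x, ...) x$roc_points

#' @rdname tidy.md_eval
#' @method glance md_eval
#' @export
glance.md_eval <- function(x, ...) {
  tibble::tibble(
    protocol = x$protocol,
    auc = x$auc,
    n_folds = nrow(x$fold_records),
    n_positives = length(x$pos_scores),
    n_negatives = length(x$neg_scores)
  )
}

#' Plot the ROC curve of an evaluation report
#'
#' @param object an `md_eval`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot md_eval
#' @export
autoplot.md_eval <- function(object, ...) {
  ggplot2::ggplot(object$roc_points, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_line(colour = "#2166ac") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate", y = "True positive rate",
      title = sprintf("%s ROC (AUC = %.4f)", object$protocol, object$auc)
    ) +
    ggplot2::theme_minimal()
}

#' Plot final scores as a heatmap
#'
#' Known associations are outlined so planted or recovered structure is
#' visible at a glance.
#'
#' @param object an `md_scores`.
#' @param ... unused.
#' @return A ggplot.
#' @method autoplot md_scores
#' @export
autoplot.md_scores <- function(object, ...) {
  tb <- tidy(object)
  p <- ggplot2::ggplot(tb, ggplot2::aes(x = .data$disease_id, y = .data$mirna_id,
                                        fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "score") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text = ggplot2::element_blank())
  if (!all(is.na(tb$known_flag))) {
    p <- p + ggplot2::geom_tile(
      data = tb[which(tb$known_flag == 1L), ],
      fill = NA, colour = "white", linewidth = 0.2
    )
  }
  p
}

#' @importFrom rlang .data
NULL
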