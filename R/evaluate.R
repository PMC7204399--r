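#' Rank-statistic AUC (Mann-Whitney, ties count one half)
#'
#' @param pos,neg numeric score vectors for positives and negatives.
#' @return AUC in \[0, 1\]: the probability a random positive outscores a
#'   random negative, with ties contributing 0.5.
#' @export
auc_rank <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  if (np == 0L || nn == 0L) stop("need at least one positive and one negative",
                                 call. = FALSE)
  r <- rank(c(pos, neg))               # midranks handle ties
  (sum(r[seq_len(np)]) - np * (np + 1) / 2) / (np * nn)
}

#' ROC curve by pooled threshold sweep
#'
#' Sweeps the decision threshold across all distinct pooled scores.
#' Tied positive/negative scores at one threshold produce a diagonal
#' segment, so the trapezoidal area equals [auc_rank()].
#'
#' @inheritParams auc_rank
#' @return Tibble of `(fpr, tpr)` points, starting at (0, 0) and ending at
#'   (1, 1), nondecreasing in both coordinates.
#' @export
roc_points <- function(pos, neg) {
  np <- length(pos); nn <- length(neg)
  scores <- c(pos, neg)
  is_pos <- rep(c(TRUE, FALSE), c(np, nn))
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]; p <- is_pos[ord]
  tp <- cumsum(p); fp <- cumsum(!p)
  last <- c(s[-1] != s[-length(s)], TRUE)   # keep one point per threshold
  tibble::tibble(fpr = c(0, fp[last] / nn), tpr = c(0, tp[last] / np))
}

trapezoid_auc <- function(roc) {
  sum(diff(roc$fpr) * (utils::head(roc$tpr, -1) + utils::tail(roc$tpr, -1)) / 2)
}

new_md_eval <- function(pos, neg, fold_records, protocol, config) {
  roc <- roc_points(pos, neg)
  structure(list(
    auc = auc_rank(pos, neg),
    roc_points = roc,
    fold_records = fold_records,
    pos_scores = pos,
    neg_scores = neg,
    protocol = protocol,
    config_used = config
  ), class = "md_eval")
}

#' @export
print.md_eval <- function(x, ...) {
  cat(sprintf("<md_eval: %s> AUC = %.4f over %d folds (%d positives, %d pooled negatives)\n",
              x$protocol, x$auc, nrow(x$fold_records),
              length(x$pos_scores), length(x$neg_scores)))
  invisible(x)
}

#' Global leave-one-out cross-validation over known associations
#'
#' Each known pair is removed in turn; the Hamming kernels, kernel fusion,
#' weighted networks, and scores are recomputed on the masked data; the
#' held-out pair's final score is pooled against that fold's scores of all
#' pairs unknown in the original data (the candidate set). One ROC is built
#' from the pooled scores and the AUC is the tie-aware rank statistic.
#'
#' @inheritParams predict_associations
#' @param fast_loocv if `TRUE`, the Hamming kernels and kernel fusion are
#'   computed once on the full data and only the weighted networks and
#'   projections are recomputed per fold. This is a labeled shortcut for
#'   large instances, not the reference protocol: masking then no longer
#'   reaches the similarity side.
#' @return An `md_eval` with `protocol = "loocv_pair"`.
#' @export
loocv <- function(ad, kernels, config = model_config(), fast_loocv = FALSE,
                  hamming_override = NULL) {
  stopifnot(inherits(ad, "association_data"))
  known <- which(ad$MD == 1, arr.ind = TRUE)
  if (nrow(known) == 0L) stop("no known associations to hold out", call. = FALSE)
  cand <- ad$MD == 0
  fused_full <- if (fast_loocv) {
    fuse_both_sides(ad, kernels, config$fusion, hamming_override)
  }
  pos <- numeric(nrow(known))
  neg <- vector("list", nrow(known))
  outranked <- integer(nrow(known))
  for (f in seq_len(nrow(known))) {
    i <- known[f, 1]; j <- known[f, 2]
    masked <- ad
    masked$MD[i, j] <- 0
    sc <- predict_associations(masked, kernels, config,
                               hamming_override = hamming_override,
                               fused = fused_full)
    pos[f] <- sc$Fpf[i, j]
    fold_neg <- sc$Fpf[cand]
    neg[[f]] <- fold_neg
    outranked[f] <- sum(fold_neg > pos[f])
  }
  records <- tibble::tibble(
    mirna_id = ad$mirna_names[known[, 1]],
    disease_id = ad$disease_names[known[, 2]],
    score = pos,
    n_outranking = outranked
  )
  new_md_eval(pos, unlist(neg, use.names = FALSE), records, "loocv_pair", config)
}

#' Entity-level cross-validation (new miRNA / isolated disease)
#'
#' Simulates an entity without any known associations: for each miRNA
#' (disease) that has at least one known association, its whole row
#' (column) is zeroed, the full pipeline is recomputed on the masked data,
#' and the entity's true associations are scored against its unknown pairs
#' from the same fold. All folds pool into one ROC/AUC.
#'
#' @inheritParams loocv
#' @param protocol `"new_mirna"` or `"isolated_disease"`.
#' @return An `md_eval`.
#' @export
loocv_entity <- function(ad, kernels, config = model_config(),
                         protocol = c("new_mirna", "isolated_disease"),
                         fast_loocv = FALSE, hamming_override = NULL) {
  protocol <- match.arg(protocol)
  stopifnot(inherits(ad, "association_data"))
  by_row <- protocol == "new_mirna"
  deg <- if (by_row) rowSums(ad$MD) else colSums(ad$MD)
  entities <- which(deg > 0)
  if (!length(entities)) stop("no entity has a known association", call. = FALSE)
  fused_full <- if (fast_loocv) {
    fuse_both_sides(ad, kernels, config$fusion, hamming_override)
  }
  pos <- list(); neg <- list()
  rec <- vector("list", length(entities))
  for (e in seq_along(entities)) {
    idx <- entities[e]
    masked <- ad
    if (by_row) masked$MD[idx, ] <- 0 else masked$MD[, idx] <- 0
    sc <- predict_associations(masked, kernels, config,
                               hamming_override = hamming_override,
                               fused = fused_full)
    profile <- if (by_row) ad$MD[idx, ] else ad$MD[, idx]
    scores <- if (by_row) sc$Fpf[idx, ] else sc$Fpf[, idx]
    p <- scores[profile == 1]
    q <- scores[profile == 0]
    pos[[e]] <- p
    neg[[e]] <- q
    rec[[e]] <- tibble::tibble(
      entity_id = if (by_row) ad$mirna_names[idx] else ad$disease_names[idx],
      n_positives = length(p),
      mean_positive_score = mean(p),
      n_outranking = sum(vapply(p, function(z) sum(q > z), 0L))
    )
  }
  new_md_eval(unlist(pos, use.names = FALSE), unlist(neg, use.names = FALSE),
              dplyr::bind_rows(rec), protocol, config)
}

#' Sweep the equilibrium parameters over a grid
#'
#' Runs [loocv()] at every grid point. By default `alpha` and `beta` are
#' tied to the same value (the reference sweep protocol); pass `beta`
#' explicitly for a full cross.
#'
#' @inheritParams loocv
#' @param alpha,gamma numeric grids.
#' @param beta optional grid; `NULL` ties `beta = alpha`.
#' @return Tibble with columns `alpha`, `beta`, `gamma`, `auc`, sorted as
#'   generated; the best row (ties: first) is attached as attribute
#'   `"best"`.
#' @export
parameter_sweep <- function(ad, kernels, alpha, gamma, beta = NULL,
                            config = model_config(), fast_loocv = FALSE) {
  stopifnot(length(alpha) >= 1L, length(gamma) >= 1L)
  grid <- if (is.null(beta)) {
    tidyr::expand_grid(alpha = alpha, gamma = gamma) |>
      dplyr::mutate(beta = alpha, .after = "alpha")
  } else {
    tidyr::expand_grid(alpha = alpha, beta = beta, gamma = gamma)
  }
  grid$auc <- purrr::pmap_dbl(grid, function(alpha, beta, gamma) {
    cfg <- model_config(alpha = alpha, beta = beta, gamma = gamma,
                        fusion = config$fusion)
    loocv(ad, kernels, cfg, fast_loocv = fast_loocv)$auc
  })
  attr(grid, "best") <- grid[which.max(grid$auc), ]
  grid
}

#' Rank unverified candidate miRNAs for one disease
#'
#' Only pairs unknown in the data used for scoring are eligible. Ties are
#' broken by miRNA identifier (ascending) so rankings are reproducible.
#'
#' @param scores an `md_scores` with a `known_mask`.
#' @param disease_id disease identifier.
#' @param top_n number of candidates to return; capped at the number of
#'   unknown pairs.
#' @return Tibble `(rank, mirna_id, score)`.
#' @export
rank_candidates <- function(scores, disease_id, top_n = 50L) {
  stopifnot(inherits(scores, "md_scores"))
  if (is.null(scores$known_mask)) stop("scores carry no known_mask", call. = FALSE)
  j <- match(disease_id, colnames(scores$Fpf))
  if (is.na(j)) stop("unknown disease: ", disease_id, call. = FALSE)
  eligible <- scores$known_mask[, j] == 0
  tb <- tibble::tibble(
    mirna_id = rownames(scores$Fpf)[eligible],
    score = scores$Fpf[eligible, j]
  )
  tb <- tb[order(-tb$score, tb$mirna_id, method = "radix"), ]
  tb <- utils::head(tb, top_n)
  tibble::add_column(tb, rank = seq_len(nrow(tb)), .before = 1)
}

#' Permutation null band for a pooled AUC
#'
#' Re-draws which of the pooled scores are labeled positive, keeping the
#' number of positives fixed, and recomputes the rank-statistic AUC for
#' each replicate. The quantile band describes the AUC values compatible
#' with "no signal".
#'
#' @param eval_or_pos an `md_eval`, or a numeric positive-score vector.
#' @param neg negative scores (ignored when an `md_eval` is given).
#' @param n_reps number of label permutations.
#' @param probs quantiles to report.
#' @param seed integer seed for the permutation draws.
#' @return List with `quantiles` (named numeric) and `draws` (all replicate
#'   AUCs).
#' @export
auc_permutation_null <- function(eval_or_pos, neg = NULL, n_reps = 200L,
                                 probs = c(0.025, 0.975), seed = 1L) {
  if (inherits(eval_or_pos, "md_eval")) {
    pos <- eval_or_pos$pos_scores
    neg <- eval_or_pos$neg_scores
  } else {
    pos <- eval_or_pos
  }
  np <- length(pos); nn <- length(neg); n <- np + nn
  r <- rank(c(pos, neg))
  draws <- with_seed(seed, {
    vapply(seq_len(n_reps), function(b) {
      idx <- sample.int(n, np)
      (sum(r[idx]) - np * (np + 1) / 2) / (np * nn)
    }, numeric(1))
  })
  list(quantiles = stats::quantile(draws, probs, names = TRUE), draws = draws)
}

# Evaluate an expression under a temporary RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}
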