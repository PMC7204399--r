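#' Similarity-weighted bipartite association networks
#'
#' The Boolean association matrix carries no strength information, so each
#' known column/row is augmented with similarity-propagated contributions
#' from other entities. On the miRNA side,
#' `MDm(i,j) = MD(i,j) + alpha * sum_{k != i} S_m(i,k) MD(k,j)`; on the
#' disease side, `MDd(i,j) = MD(i,j) + beta * sum_{k != j} MD(i,k) S_d(k,j)`.
#' With `alpha = 0` (`beta = 0`) the network is the Boolean matrix itself.
#'
#' @param ad an [association_data()].
#' @param fused a `fused_similarity` for the matching side (or a plain
#'   square similarity matrix).
#' @param alpha,beta contribution weight in \[0, 1\].
#' @return The weighted `n_m x n_d` matrix.
#' @export
mirna_weighted_network <- function(ad, fused, alpha) {
  stopifnot(inherits(ad, "association_data"), alpha >= 0, alpha <= 1)
  S <- fused_matrix(fused)
  check_alignment(S, ad$mirna_names, "miRNA similarity")
  S0 <- S
  diag(S0) <- 0                        # the k = i self term is excluded
  ad$MD + alpha * (S0 %*% ad$MD)
}

#' @rdname mirna_weighted_network
#' @export
disease_weighted_network <- function(ad, fused, beta) {
  stopifnot(inherits(ad, "association_data"), beta >= 0, beta <= 1)
  S <- fused_matrix(fused)
  check_alignment(S, ad$disease_names, "disease similarity")
  S0 <- S
  diag(S0) <- 0                        # the k = j self term is excluded
  ad$MD + beta * (ad$MD %*% S0)
}

fused_matrix <- function(x) {
  if (inherits(x, "fused_similarity")) x$S_star else sim_matrix(x)
}

#' Space-projection scores
#'
#' Projects each entity's weighted association profile onto the similarity
#' space of the other dimension. The miRNA-space score of pair `(d_i, m_j)`
#' is the inner product of disease `i`'s row of the disease-weighted
#' network (transposed) with miRNA `j`'s similarity column, divided by the
#' Euclidean norm of that column; the disease-space score is the mirror
#' construction. The final score mixes the two:
#' `Fpf = (1 - gamma) * t(Fpm) + gamma * Fpd`. Columns with zero similarity
#' norm score 0.
#'
#' @param MDd disease-side weighted network (`n_m x n_d`).
#' @param MDm miRNA-side weighted network (`n_m x n_d`).
#' @param mirna_fused,disease_fused fused similarities (or plain matrices).
#' @param gamma mixing weight in \[0, 1\].
#' @param known_mask the 0/1 association matrix the networks were built
#'   from; carried on the result so ranking/evaluation can exclude known
#'   pairs. Scores themselves are not zeroed at known positions.
#' @param config optional `model_config` recorded on the result.
#' @return An `md_scores` object with matrices `Fpm` (`n_d x n_m`), `Fpd`
#'   (`n_m x n_d`), `Fpf` (`n_m x n_d`), and `known_mask`.
#' @export
space_projection <- function(MDd, MDm, mirna_fused, disease_fused, gamma,
                             known_mask = NULL, config = NULL) {
  stopifnot(gamma >= 0, gamma <= 1)
  Sm <- fused_matrix(mirna_fused)
  Sd <- fused_matrix(disease_fused)
  stopifnot(nrow(MDd) == nrow(Sm), ncol(MDd) == nrow(Sd),
            all(dim(MDd) == dim(MDm)))
  m_norm <- sqrt(colSums(Sm^2))
  d_norm <- sqrt(colSums(Sd^2))
  Fpm <- crossprod(MDd, Sm)            # t(MDd) %*% Sm, n_d x n_m
  Fpm <- sweep_safe(Fpm, m_norm)
  Fpd <- MDm %*% Sd                    # n_m x n_d
  Fpd <- sweep_safe(Fpd, d_norm)
  Fpf <- (1 - gamma) * t(Fpm) + gamma * Fpd
  structure(list(Fpm = Fpm, Fpd = Fpd, Fpf = Fpf,
                 known_mask = known_mask, config = config),
            class = "md_scores")
}

# Divide columns by norms, mapping zero-norm columns to 0 instead of NaN.
sweep_safe <- function(M, norms) {
  pos <- norms > 0
  M[, pos] <- sweep(M[, pos, drop = FALSE], 2, norms[pos], "/")
  M[, !pos] <- 0
  M
}

#' @export
print.md_scores <- function(x, ...) {
  cat(sprintf("<md_scores> %d miRNAs x %d diseases\n", nrow(x$Fpf), ncol(x$Fpf)))
  invisible(x)
}

#' Run the full prediction pipeline
#'
#' Computes both Hamming kernels from the association matrix, fuses the
#' three kernels on each side, builds both similarity-weighted networks,
#' and returns the projection scores. Deterministic given inputs and
#' configuration.
#'
#' @param ad an [association_data()].
#' @param kernels named list of the four externally supplied kernels:
#'   `mirna_functional`, `mirna_sequence`, `disease_semantic`,
#'   `disease_functional`, aligned with `ad` (use [read_kernel_matrix()]
#'   with `expected_names` to align).
#' @param config a [model_config()].
#' @param hamming_override optional list with elements `mirna` and
#'   `disease`: fixed kernels used in place of the Hamming kernels computed
#'   from `ad` (used by evaluation protocols to hold the similarity side
#'   constant).
#' @param fused optional precomputed list with elements `mirna` and
#'   `disease` (`fused_similarity` objects); when supplied, kernel fusion
#'   is skipped entirely and only the weighted networks and projections are
#'   recomputed.
#' @return An `md_scores` object.
#' @export
predict_associations <- function(ad, kernels, config = model_config(),
                                 hamming_override = NULL, fused = NULL) {
  stopifnot(inherits(ad, "association_data"), inherits(config, "model_config"))
  if (is.null(fused)) {
    fused <- fuse_both_sides(ad, kernels, config$fusion, hamming_override)
  }
  MDm <- mirna_weighted_network(ad, fused$mirna, config$alpha)
  MDd <- disease_weighted_network(ad, fused$disease, config$beta)
  space_projection(MDd, MDm, fused$mirna, fused$disease, config$gamma,
                   known_mask = ad$MD, config = config)
}

# Fuse miRNA and disease similarity kernels for the given (possibly
# masked) association data.
fuse_both_sides <- function(ad, kernels, fusion_cfg, hamming_override = NULL) {
  req <- c("mirna_functional", "mirna_sequence", "disease_semantic",
           "disease_functional")
  if (!all(req %in% names(kernels))) {
    stop("kernels must contain: ", paste(req, collapse = ", "), call. = FALSE)
  }
  for (nm in c("mirna_functional", "mirna_sequence")) {
    check_alignment(sim_matrix(kernels[[nm]]), ad$mirna_names, nm)
  }
  for (nm in c("disease_semantic", "disease_functional")) {
    check_alignment(sim_matrix(kernels[[nm]]), ad$disease_names, nm)
  }
  mm_h <- if (!is.null(hamming_override)) hamming_override$mirna
          else hamming_similarity(ad, "mirna")
  dd_h <- if (!is.null(hamming_override)) hamming_override$disease
          else hamming_similarity(ad, "disease")
  list(
    mirna = fuse_similarities(kernels$mirna_functional, kernels$mirna_sequence,
                              mm_h, fusion_cfg),
    disease = fuse_similarities(kernels$disease_functional, kernels$disease_semantic,
                                dd_h, fusion_cfg)
  )
}
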