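#' Top-k neighbor sets of a similarity matrix
#'
#' For each entity `i`, the neighbor set is the `k` entities with the
#' largest similarity to `i`, with `i` itself always included. Ties at the
#' k-th rank are broken by ascending entity index, so the sets are
#' deterministic across platforms.
#'
#' @param S square similarity matrix.
#' @param k neighbor-set size (including self), `1 <= k <= nrow(S)`.
#' @return List of integer index vectors, ordered self-first then by
#'   decreasing similarity.
#' @keywords internal
top_k_neighbors <- function(S, k) {
  n <- nrow(S)
  if (k > n) stop(sprintf("k_neighbors (%d) exceeds matrix dimension (%d)", k, n),
                  call. = FALSE)
  lapply(seq_len(n), function(i) {
    key <- S[i, ]
    key[i] <- Inf                      # self is always a neighbor
    order(-key, seq_len(n))[seq_len(k)]
  })
}

#' Sparse (k-nearest-neighbor, row-normalized) kernel
#'
#' Restricts each row of a similarity kernel to the entity's neighbor set
#' and renormalizes it to sum to 1 over that set; entries outside the set
#' are 0. A row whose neighbor-set similarity mass is 0 falls back to the
#' self-only row (`P[i,i] = 1`).
#'
#' @param S a `kernel_matrix` (or plain square matrix).
#' @param k neighbor-set size, self included.
#' @return A `sparse_kernel`: list with the row-stochastic matrix `P` and
#'   the per-row `neighbor_sets`.
#' @export
sparse_kernel <- function(S, k) {
  S <- sim_matrix(S)
  nb <- top_k_neighbors(S, k)
  n <- nrow(S)
  P <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    idx <- nb[[i]]
    mass <- sum(S[i, idx])
    if (mass > 0) {
      P[i, idx] <- S[i, idx] / mass
    } else {
      P[i, i] <- 1
    }
  }
  structure(list(P = P, neighbor_sets = nb), class = "sparse_kernel")
}

#' Ratio-normalized initial status of three kernels
#'
#' Each kernel entry is divided by the elementwise sum of the three
#' kernels, so the three outputs sum to 1 wherever that sum is nonzero.
#' Entries with a zero three-way sum are set to 0 in all three outputs
#' (no similarity is invented where none exists).
#'
#' @param S_a,S_b,S_c three aligned square kernels.
#' @return List of the three normalized matrices, in input order.
#' @export
initial_status <- function(S_a, S_b, S_c) {
  mats <- lapply(list(S_a, S_b, S_c), sim_matrix)
  d <- unique(lapply(mats, dim))
  if (length(d) != 1L) stop("kernels must share dimensions", call. = FALSE)
  tot <- mats[[1]] + mats[[2]] + mats[[3]]
  zero <- tot == 0
  tot[zero] <- 1                       # placeholder; zeroed below
  out <- lapply(mats, function(M) {
    R <- M / tot
    R[zero] <- 0
    R
  })
  names(out) <- c("a", "b", "c")
  out
}

#' Cross-diffusion of three normalized kernels through their sparse kernels
#'
#' Runs `cfg$iterations` Jacobi-style rounds. In each round every kernel is
#' updated simultaneously from the previous round's states: it diffuses the
#' average of the *other two* current states through its own sparse kernel,
#' anchored to the average of the other two *initial* states:
#' `next_x = delta * P_x (cur_y + cur_z)/2 P_x' + (1 - delta) (init_y + init_z)/2`.
#'
#' @param normalized list of three initial-status matrices (see
#'   [initial_status()]).
#' @param sparse list of three matching `sparse_kernel` objects.
#' @param cfg a [fusion_config()].
#' @return List of the three matrices after the final round.
#' @export
cross_diffusion <- function(normalized, sparse, cfg) {
  stopifnot(length(normalized) == 3L, length(sparse) == 3L,
            inherits(cfg, "fusion_config"))
  P <- lapply(sparse, function(sk) sk$P)
  dims <- unique(c(lapply(normalized, dim), lapply(P, dim)))
  if (length(dims) != 1L) stop("all six matrices must share dimensions", call. = FALSE)
  init <- normalized
  cur <- normalized
  others <- list(c(2L, 3L), c(1L, 3L), c(1L, 2L))
  for (round in seq_len(cfg$iterations)) {
    nxt <- vector("list", 3L)
    for (x in 1:3) {
      oth <- others[[x]]
      cur_avg <- (cur[[oth[1]]] + cur[[oth[2]]]) / 2
      init_avg <- (init[[oth[1]]] + init[[oth[2]]]) / 2
      nxt[[x]] <- cfg$delta * (P[[x]] %*% cur_avg %*% t(P[[x]])) +
        (1 - cfg$delta) * init_avg
    }
    cur <- nxt
  }
  names(cur) <- names(normalized)
  cur
}

#' Mutual-neighbor weight matrix
#'
#' Entry `(i, j)` is 1 when `i` and `j` are in each other's top-k neighbor
#' sets, 0 when neither is in the other's set, and 0.5 otherwise. Used to
#' damp similarity noise after fusion. The diagonal is 1 (self is always
#' its own neighbor).
#'
#' @param S_temp square matrix the neighborhoods are computed from.
#' @param k neighbor-set size, self included.
#' @return Symmetric matrix with entries in \{0, 0.5, 1\}.
#' @export
neighbor_weight_matrix <- function(S_temp, k) {
  S_temp <- sim_matrix(S_temp)
  nb <- top_k_neighbors(S_temp, k)
  n <- nrow(S_temp)
  Nmat <- matrix(0, n, n, dimnames = dimnames(S_temp))
  for (i in seq_len(n)) Nmat[i, nb[[i]]] <- 1
  (Nmat + t(Nmat)) / 2
}

#' Fuse three similarity kernels into one integrated kernel
#'
#' The full fusion pipeline for one entity type: sparse kernels
#' ([sparse_kernel()]), ratio normalization ([initial_status()]),
#' cross-diffusion ([cross_diffusion()]), averaging of the three diffused
#' matrices into `S_temp`, and elementwise damping by the mutual-neighbor
#' weight matrix computed from `S_temp`, giving `S_star = S_temp * W`.
#'
#' @param functional,second,hamming the three aligned kernels (miRNA side:
#'   functional, sequence, Hamming; disease side: functional, semantic,
#'   Hamming).
#' @param cfg a [fusion_config()].
#' @return A `fused_similarity`: list with `S_star`, `S_temp`, and `W`.
#' @export
fuse_similarities <- function(functional, second, hamming, cfg = fusion_config()) {
  stopifnot(inherits(cfg, "fusion_config"))
  mats <- list(sim_matrix(functional), sim_matrix(second), sim_matrix(hamming))
  nm <- rownames(mats[[1]])
  for (M in mats[-1]) {
    if (!identical(rownames(M), nm)) {
      stop("kernels must be aligned on the same entities", call. = FALSE)
    }
  }
  sparse <- lapply(mats, sparse_kernel, k = cfg$k_neighbors)
  norm <- initial_status(mats[[1]], mats[[2]], mats[[3]])
  diffused <- cross_diffusion(norm, sparse, cfg)
  S_temp <- (diffused[[1]] + diffused[[2]] + diffused[[3]]) / 3
  W <- neighbor_weight_matrix(S_temp, cfg$k_neighbors)
  structure(list(S_star = S_temp * W, S_temp = S_temp, W = W),
            class = "fused_similarity")
}

#' @export
print.fused_similarity <- function(x, ...) {
  cat(sprintf("<fused_similarity> %d entities\n", nrow(x$S_star)))
  invisible(x)
}
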