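# Independent naive-loop transcriptions of every model equation. These are
# deliberately written as explicit element loops / sums, sharing no code
# with the package internals, and serve as the reference the vectorized
# pipeline is checked against.

oracle_hamming <- function(MD, side) {
  P <- if (side == "disease") MD else t(MD)
  n <- ncol(P)
  len <- nrow(P)
  S <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      mism <- 0
      for (k in seq_len(len)) if (P[k, i] != P[k, j]) mism <- mism + 1
      S[i, j] <- 1 - mism / len
    }
  }
  dimnames(S) <- list(colnames(P), colnames(P))
  S
}

# top-k neighbor set: similarity descending, self forced in, index-ascending
# tie break (same deterministic rule the package documents)
oracle_neighbors <- function(S, k) {
  n <- nrow(S)
  lapply(seq_len(n), function(i) {
    key <- S[i, ]
    key[i] <- Inf
    order(-key, seq_len(n))[seq_len(k)]
  })
}

oracle_sparse <- function(S, k) {
  n <- nrow(S)
  nb <- oracle_neighbors(S, k)
  P <- matrix(0, n, n)
  for (i in seq_len(n)) {
    mass <- 0
    for (j in nb[[i]]) mass <- mass + S[i, j]
    if (mass > 0) {
      for (j in nb[[i]]) P[i, j] <- S[i, j] / mass
    } else {
      P[i, i] <- 1
    }
  }
  P
}

oracle_initial_status <- function(Sa, Sb, Sc) {
  n <- nrow(Sa)
  out <- list(a = matrix(0, n, n), b = matrix(0, n, n), c = matrix(0, n, n))
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      tot <- Sa[i, j] + Sb[i, j] + Sc[i, j]
      if (tot > 0) {
        out$a[i, j] <- Sa[i, j] / tot
        out$b[i, j] <- Sb[i, j] / tot
        out$c[i, j] <- Sc[i, j] / tot
      }
    }
  }
  out
}

oracle_cross_diffusion <- function(norm, P, iterations, delta) {
  init <- norm
  cur <- norm
  n <- nrow(norm[[1]])
  others <- list(c(2, 3), c(1, 3), c(1, 2))
  for (round in seq_len(iterations)) {
    nxt <- vector("list", 3)
    for (x in 1:3) {
      y <- others[[x]][1]; z <- others[[x]][2]
      avg <- (cur[[y]] + cur[[z]]) / 2
      anchor <- (init[[y]] + init[[z]]) / 2
      M <- matrix(0, n, n)
      for (i in seq_len(n)) {
        for (j in seq_len(n)) {
          M[i, j] <- delta * drop(P[[x]][i, ] %*% avg %*% P[[x]][j, ]) +
            (1 - delta) * anchor[i, j]
        }
      }
      nxt[[x]] <- M
    }
    cur <- nxt
  }
  cur
}

oracle_weight_matrix <- function(S, k) {
  n <- nrow(S)
  nb <- oracle_neighbors(S, k)
  W <- matrix(0, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      i_in_j <- i %in% nb[[j]]
      j_in_i <- j %in% nb[[i]]
      W[i, j] <- if (i_in_j && j_in_i) 1 else if (!i_in_j && !j_in_i) 0 else 0.5
    }
  }
  W
}

oracle_fuse <- function(S1, S2, S3, k, iterations, delta) {
  P <- list(oracle_sparse(S1, k), oracle_sparse(S2, k), oracle_sparse(S3, k))
  norm <- oracle_initial_status(S1, S2, S3)
  diff <- oracle_cross_diffusion(norm, P, iterations, delta)
  S_temp <- (diff[[1]] + diff[[2]] + diff[[3]]) / 3
  W <- oracle_weight_matrix(S_temp, k)
  list(S_star = S_temp * W, S_temp = S_temp, W = W)
}

oracle_weighted_networks <- function(MD, Sm, Sd, alpha, beta) {
  n_m <- nrow(MD); n_d <- ncol(MD)
  MDm <- matrix(0, n_m, n_d)
  MDd <- matrix(0, n_m, n_d)
  for (i in seq_len(n_m)) {
    for (j in seq_len(n_d)) {
      cm <- 0
      for (k in seq_len(n_m)) if (k != i) cm <- cm + Sm[i, k] * MD[k, j]
      MDm[i, j] <- MD[i, j] + alpha * cm
      cd <- 0
      for (k in seq_len(n_d)) if (k != j) cd <- cd + MD[i, k] * Sd[k, j]
      MDd[i, j] <- MD[i, j] + beta * cd
    }
  }
  list(MDm = MDm, MDd = MDd)
}

oracle_projection <- function(MDd, MDm, Sm, Sd, gamma) {
  n_m <- nrow(MDm); n_d <- ncol(MDm)
  Fpm <- matrix(0, n_d, n_m)
  for (i in seq_len(n_d)) {
    for (j in seq_len(n_m)) {
      nrm <- sqrt(sum(Sm[, j]^2))
      Fpm[i, j] <- if (nrm > 0) sum(t(MDd)[i, ] * Sm[, j]) / nrm else 0
    }
  }
  Fpd <- matrix(0, n_m, n_d)
  for (i in seq_len(n_m)) {
    for (j in seq_len(n_d)) {
      nrm <- sqrt(sum(Sd[, j]^2))
      Fpd[i, j] <- if (nrm > 0) sum(MDm[i, ] * Sd[, j]) / nrm else 0
    }
  }
  Fpf <- (1 - gamma) * t(Fpm) + gamma * Fpd
  list(Fpm = Fpm, Fpd = Fpd, Fpf = Fpf)
}

# brute-force tie-aware rank statistic
oracle_auc <- function(pos, neg) {
  tot <- 0
  for (p in pos) {
    for (q in neg) tot <- tot + (p > q) + 0.5 * (p == q)
  }
  tot / (length(pos) * length(neg))
}
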