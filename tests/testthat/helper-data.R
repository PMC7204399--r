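# Small random fixtures built in code. All draws go through local seeds so
# test order never changes results.

rnd_names <- function(prefix, n) sprintf("%s%02d", prefix, seq_len(n))

# random symmetric similarity kernel in [0, 1] with unit diagonal
random_kernel <- function(n, seed, names = rnd_names("e", n),
                          label = "functional") {
  set.seed(seed)
  U <- matrix(runif(n * n), n, n)
  S <- (U + t(U)) / 2
  diag(S) <- 1
  dimnames(S) <- list(names, names)
  kernel_matrix(S, label = label)
}

# random Boolean association data guaranteed to hold >= 1 association
random_ad <- function(n_m, n_d, p = 0.3, seed = 1) {
  set.seed(seed)
  repeat {
    MD <- matrix(rbinom(n_m * n_d, 1, p), n_m,
                 dimnames = list(rnd_names("m", n_m), rnd_names("d", n_d)))
    if (sum(MD) >= 1) break
  }
  association_data(MD)
}

# matched external kernels for an association_data
random_kernels <- function(ad, seed = 1) {
  n_m <- length(ad$mirna_names); n_d <- length(ad$disease_names)
  list(
    mirna_functional = random_kernel(n_m, seed, ad$mirna_names, "functional"),
    mirna_sequence = random_kernel(n_m, seed + 1, ad$mirna_names, "sequence"),
    disease_semantic = random_kernel(n_d, seed + 2, ad$disease_names, "semantic"),
    disease_functional = random_kernel(n_d, seed + 3, ad$disease_names, "functional")
  )
}

tiny_config <- function(alpha = 0.02, beta = 0.02, gamma = 0.27, k = 4L,
                        iterations = 3L, delta = 0.1) {
  model_config(alpha, beta, gamma,
               fusion = fusion_config(k_neighbors = k, iterations = iterations,
                                      delta = delta))
}
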