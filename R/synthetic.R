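#' Specification for a synthetic benchmark dataset
#'
#' Describes a block-structured miRNA-disease world: entities are assigned
#' to latent groups; a miRNA and a disease in matching groups associate
#' with probability `p_in`, otherwise `p_out`; the four external similarity
#' kernels blend the same-group indicator with a constant background and
#' symmetric Gaussian noise. This emulates the shape of curated association
#' data plus precomputed functional/sequence/semantic kernels at desk
#' scale.
#'
#' @param n_mirna,n_disease entity counts.
#' @param n_groups number of planted groups.
#' @param p_in,p_out association probabilities for matching / non-matching
#'   group pairs (`p_out <= p_in`; equality gives a no-signal control).
#' @param kernel_signal weight in \[0, 1\] of the same-group indicator in
#'   each kernel (0 = pure background).
#' @param noise_sd standard deviation of the symmetric Gaussian kernel
#'   noise.
#' @param seed integer seed; generation is fully reproducible.
#' @return A `synthetic_spec` list.
#' @export
synthetic_spec <- function(n_mirna = 60L, n_disease = 40L, n_groups = 4L,
                           p_in = 0.4, p_out = 0.02, kernel_signal = 0.7,
                           noise_sd = 0.1, seed = 1L) {
  stopifnot(n_mirna >= 2L, n_disease >= 2L, n_groups >= 1L)
  if (!(p_out >= 0 && p_out <= p_in && p_in <= 1)) {
    stop("need 0 <= p_out <= p_in <= 1", call. = FALSE)
  }
  if (kernel_signal < 0 || kernel_signal > 1) stop("kernel_signal must be in [0, 1]", call. = FALSE)
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  structure(list(n_mirna = as.integer(n_mirna), n_disease = as.integer(n_disease),
                 n_groups = as.integer(n_groups), p_in = p_in, p_out = p_out,
                 kernel_signal = kernel_signal, noise_sd = noise_sd,
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate a synthetic dataset with planted association structure
#'
#' @param spec a [synthetic_spec()].
#' @return List with `association` (an [association_data()]), the four
#'   kernels (`mirna_functional`, `mirna_sequence`, `disease_semantic`,
#'   `disease_functional`), the group assignments (`mirna_groups`,
#'   `disease_groups`, named by entity), and the `spec` itself.
#' @examples
#' sim <- generate_synthetic(synthetic_spec(n_mirna = 12, n_disease = 10))
#' sim$association
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  with_seed(spec$seed, {
    mn <- sprintf("mir-%03d", seq_len(spec$n_mirna))
    dn <- sprintf("dis-%03d", seq_len(spec$n_disease))
    gm <- rep_len(seq_len(spec$n_groups), spec$n_mirna)
    gd <- rep_len(seq_len(spec$n_groups), spec$n_disease)
    names(gm) <- mn; names(gd) <- dn
    match_grid <- outer(gm, gd, "==")
    p <- ifelse(match_grid, spec$p_in, spec$p_out)
    MD <- matrix(stats::rbinom(length(p), 1, p), nrow = spec$n_mirna,
                 dimnames = list(mn, dn))
    # lexicographic names with zero padding: association_data keeps order
    ad <- association_data(MD)
    kernels <- list(
      mirna_functional = block_kernel(gm, spec, "functional"),
      mirna_sequence = block_kernel(gm, spec, "sequence"),
      disease_semantic = block_kernel(gd, spec, "semantic"),
      disease_functional = block_kernel(gd, spec, "functional")
    )
    list(association = ad, kernels = kernels,
         mirna_groups = gm, disease_groups = gd, spec = spec)
  })
}

# One noisy block-structured kernel: signal * same-group + background,
# plus symmetric Gaussian noise, clipped to [0, 1], unit diagonal. The
# noise is symmetrized before clipping so symmetry is exact.
block_kernel <- function(groups, spec, label) {
  n <- length(groups)
  ind <- outer(groups, groups, "==") * 1
  base <- spec$kernel_signal * ind + (1 - spec$kernel_signal) * 0.5
  E <- matrix(stats::rnorm(n * n, sd = spec$noise_sd), n, n)
  E <- (E + t(E)) / 2
  S <- pmin(pmax(base + E, 0), 1)
  diag(S) <- 1
  dimnames(S) <- list(names(groups), names(groups))
  kernel_matrix(S, label = label)
}

#' Write a synthetic dataset as the standard TSV files
#'
#' Writes the association edge list, the four kernel matrices, and a YAML
#' manifest echoing the generating specification.
#'
#' @param sim result of [generate_synthetic()].
#' @param dir output directory (created if needed).
#' @return Invisibly, the named vector of file paths written.
#' @export
write_synthetic <- function(sim, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(
    association = file.path(dir, "associations.tsv"),
    mirna_functional = file.path(dir, "mirna_functional.tsv"),
    mirna_sequence = file.path(dir, "mirna_sequence.tsv"),
    disease_semantic = file.path(dir, "disease_semantic.tsv"),
    disease_functional = file.path(dir, "disease_functional.tsv"),
    manifest = file.path(dir, "manifest.yaml")
  )
  # matrix layout is lossless even for entities without any association
  write_association_table(sim$association, paths[["association"]], "matrix")
  for (nm in names(sim$kernels)) write_kernel_matrix(sim$kernels[[nm]], paths[[nm]])
  yaml::write_yaml(unclass(sim$spec), paths[["manifest"]])
  invisible(paths)
}
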