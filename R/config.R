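#' Fusion (cross-diffusion) configuration
#'
#' @param k_neighbors neighbor-set size used for the sparse kernels and the
#'   mutual-neighbor weight matrix; the set always contains the entity
#'   itself. Default 36, the reference setting for the miRNA side; the
#'   disease side mirrors it and both are configurable.
#' @param iterations number of cross-diffusion update rounds, default 10.
#' @param delta diffusion weight in \[0, 1\]; `1 - delta` anchors each round
#'   to the initial normalized kernels. Default 0.1.
#' @return A `fusion_config` list.
#' @export
fusion_config <- function(k_neighbors = 36L, iterations = 10L, delta = 0.1) {
  k_neighbors <- as.integer(k_neighbors)
  iterations <- as.integer(iterations)
  if (is.na(k_neighbors) || k_neighbors < 1L) stop("k_neighbors must be >= 1", call. = FALSE)
  if (is.na(iterations) || iterations < 1L) stop("iterations must be >= 1", call. = FALSE)
  if (!is.numeric(delta) || delta < 0 || delta > 1) stop("delta must be in [0, 1]", call. = FALSE)
  structure(list(k_neighbors = k_neighbors, iterations = iterations, delta = delta),
            class = "fusion_config")
}

#' Model configuration
#'
#' Holds the three equilibrium parameters of the scoring model and the
#' fusion settings. Defaults are the reference selection
#' `alpha = beta = 0.02`, `gamma = 0.27`.
#'
#' @param alpha weight of similarity-propagated contributions in the
#'   miRNA-side weighted network, in \[0, 1\].
#' @param beta same for the disease side.
#' @param gamma mixing weight of the disease-space projection score in the
#'   final score (`1 - gamma` weights the miRNA-space projection).
#' @param fusion a [fusion_config()].
#' @return A `model_config` list.
#' @export
model_config <- function(alpha = 0.02, beta = 0.02, gamma = 0.27,
                         fusion = fusion_config()) {
  for (nm in c("alpha", "beta", "gamma")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0 || v > 1) {
      stop(nm, " must be a single value in [0, 1]", call. = FALSE)
    }
  }
  stopifnot(inherits(fusion, "fusion_config"))
  structure(list(alpha = alpha, beta = beta, gamma = gamma, fusion = fusion),
            class = "model_config")
}

#' @export
print.model_config <- function(x, ...) {
  cat(sprintf("<model_config> alpha=%g beta=%g gamma=%g | k=%d iterations=%d delta=%g\n",
              x$alpha, x$beta, x$gamma, x$fusion$k_neighbors,
              x$fusion$iterations, x$fusion$delta))
  invisible(x)
}

#' Read / write a flat key-value configuration file
#'
#' The file is YAML with flat keys `alpha`, `beta`, `gamma`, `k_neighbors`,
#' `iterations`, `delta`, and optionally `seed`. Missing keys fall back to
#' the defaults of [model_config()] / [fusion_config()].
#'
#' @param path file path.
#' @return For `read_model_config`, a `model_config` with the file's `seed`
#'   (or `NA`) attached as attribute `"seed"`.
#' @export
read_model_config <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path, call. = FALSE)
  kv <- yaml::read_yaml(path)
  if (is.null(kv)) kv <- list()
  take <- function(key, default) if (!is.null(kv[[key]])) kv[[key]] else default
  fus <- fusion_config(
    k_neighbors = take("k_neighbors", 36L),
    iterations = take("iterations", 10L),
    delta = take("delta", 0.1)
  )
  cfg <- model_config(
    alpha = take("alpha", 0.02),
    beta = take("beta", 0.02),
    gamma = take("gamma", 0.27),
    fusion = fus
  )
  attr(cfg, "seed") <- as.integer(take("seed", NA_integer_))
  cfg
}

#' @rdname read_model_config
#' @param cfg a `model_config`.
#' @param seed optional integer echoed into the file.
#' @export
write_model_config <- function(cfg, path, seed = NULL) {
  stopifnot(inherits(cfg, "model_config"))
  kv <- list(alpha = cfg$alpha, beta = cfg$beta, gamma = cfg$gamma,
             k_neighbors = cfg$fusion$k_neighbors,
             iterations = cfg$fusion$iterations, delta = cfg$fusion$delta)
  if (!is.null(seed)) kv$seed <- as.integer(seed)
  yaml::write_yaml(kv, path)
  invisible(path)
}
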