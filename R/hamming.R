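#' Hamming similarity from Boolean association profiles
#'
#' For two entities, the Hamming similarity is one minus the fraction of
#' profile positions at which their association vectors differ. Disease
#' profiles are the columns of the association matrix (length `n_m`); miRNA
#' profiles are the columns of its transpose (length `n_d`). Identical
#' profiles - including two all-zero profiles, which arise under masking -
#' have similarity exactly 1.
#'
#' @param ad an [association_data()] object (possibly masked).
#' @param side `"disease"` or `"mirna"`.
#' @return A `kernel_matrix` with label `"hamming"`.
#' @examples
#' MD <- matrix(c(1, 0, 1, 1, 1, 0), 3, 2,
#'              dimnames = list(c("m1", "m2", "m3"), c("d1", "d2")))
#' hamming_similarity(association_data(MD), "disease")
#' @export
hamming_similarity <- function(ad, side = c("disease", "mirna")) {
  side <- match.arg(side)
  stopifnot(inherits(ad, "association_data"))
  P <- if (side == "disease") ad$MD else t(ad$MD)
  # mismatches(i,j) = #\{k : P[k,i] != P[k,j]\} for 0/1 profiles
  mism <- crossprod(P, 1 - P) + crossprod(1 - P, P)
  S <- 1 - mism / nrow(P)
  S <- (S + t(S)) / 2   # exact in theory; guards bitwise asymmetry
  diag(S) <- 1
  kernel_matrix(S, label = "hamming")
}
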