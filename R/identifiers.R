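# Orthogonal random feature (ORF) node identifiers.

#' Generate a seeded bank of orthogonal random feature identifiers
#'
#' Rows of the returned matrix are orthonormal vectors assigned to node
#' indices (row k holds the identifier of node index k - 1, shared across all
#' graphs). A node token v carries the concatenation [P_v, P_v]; an edge
#' token (u, v) carries [P_u, P_v]; mutual orthogonality makes incidence
#' detectable through attention inner products:
#' concat(P_u,P_v) . concat(P_u,P_w) = 1 + delta(v, w).
#'
#' The bank is the row-orthonormal factor of a seeded Gaussian square matrix
#' (QR with sign-fixed diagonal), so regeneration from the same seed is
#' bit-identical and max |P P' - I| < 1e-5.
#'
#' @param dP identifier dimension (and maximum number of addressable nodes).
#' @param seed integer seed.
#' @return a dP x dP numeric matrix with orthonormal rows.
#' @examples
#' P <- orfBank(16, seed = 1)
#' max(abs(P %*% t(P) - diag(16)))
#' @export
orfBank <- function(dP = 64L, seed = 1L) {
  stopifnot(dP >= 1L)
  withSeed(deriveSeed(seed, 101L), {
    M <- matrix(stats::rnorm(dP * dP), dP, dP)
    qrd <- qr(M)
    Q <- qr.Q(qrd)
    sgn <- sign(diag(qr.R(qrd)))
    sgn[sgn == 0] <- 1
    t(Q) * sgn          # rows orthonormal, sign-fixed for stability
  })
}
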