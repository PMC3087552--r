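#' GTR substitution-model parameters
#'
#' Builds the normalized general time-reversible rate matrix
#' `Q[a,b] = s[ab] * pi[b]` (a != b), with rows summing to zero and the
#' matrix scaled so that `-sum(pi_a Q[a,a]) = 1`, i.e. one expected
#' substitution per site per unit branch length. The spectral decomposition
#' of the reversible Q is cached so transition matrices `P(t) = exp(Qt)`
#' are cheap.
#'
#' @param freqs Base frequencies (A, C, G, T); must sum to 1.
#' @param rates Exchangeabilities in the order AC, AG, AT, CG, CT, GT.
#' @return A list of class `gtr_params` with elements `freqs`, `rates`,
#'   `Q` and the eigendecomposition used by [gtr_transition_matrix()].
#' @export
gtr_params <- function(freqs = rep(0.25, 4),
                       rates = c(1, 1, 1, 1, 1, 1)) {
  if (length(freqs) != 4L || abs(sum(freqs) - 1) > 1e-8 || any(freqs <= 0)) {
    abort("`freqs` must be 4 positive numbers summing to 1")
  }
  if (length(rates) != 6L || any(rates <= 0) || any(!is.finite(rates))) {
    abort("`rates` must be 6 positive exchangeabilities")
  }
  S <- matrix(0, 4, 4, dimnames = list(BASES, BASES))
  S[upper.tri(S)] <- rates[c(1, 2, 4, 3, 5, 6)]  # fill column-wise: AC,AG,CG,AT,CT,GT
  S <- S + t(S)
  Q <- S %*% diag(freqs)
  diag(Q) <- -rowSums(Q)
  scale <- -sum(freqs * diag(Q))
  Q <- Q / scale
  # symmetrize: B = D^{1/2} Q D^{-1/2} has real eigensystem
  d <- sqrt(freqs)
  B <- diag(d) %*% Q %*% diag(1 / d)
  eig <- eigen((B + t(B)) / 2, symmetric = TRUE)
  structure(list(freqs = freqs, rates = rates, Q = Q,
                 eig_values = eig$values,
                 left = diag(1 / d) %*% eig$vectors,
                 right = t(eig$vectors) %*% diag(d)),
            class = "gtr_params")
}

#' Transition-probability matrix of a GTR model
#'
#' @param params A [gtr_params()] object.
#' @param t Branch length in expected substitutions per site.
#' @return The 4x4 matrix `P(t) = exp(Qt)`.
#' @export
gtr_transition_matrix <- function(params, t) {
  if (t < 0) abort("branch length must be >= 0")
  P <- params$left %*% diag(exp(params$eig_values * t)) %*% params$right
  P[P < 0] <- 0
  P <- P / rowSums(P)
  dimnames(P) <- list(BASES, BASES)
  P
}

#' Estimate empirical GTR parameters from an alignment
#'
#' Frequencies are the observed base composition; exchangeabilities come
#' from symmetrized mismatch counts over all sequence pairs,
#' `s[ab] = n[ab] / (pi_a pi_b)`, normalized to `s[GT] = 1`. This is a
#' moment-style estimate, robust at desk scale, not a joint ML fit.
#'
#' @param aln Alignment tibble.
#' @param pseudocount Added to every pair count so sparse alignments stay
#'   well-defined.
#' @return A [gtr_params()] object.
#' @export
estimate_gtr_params <- function(aln, pseudocount = 1) {
  N <- matrix(pseudocount, 4, 4, dimnames = list(BASES, BASES))
  n <- nrow(aln)
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      N <- N + pair_count_matrix(aln$sequence[i], aln$sequence[j])
    }
  }
  Nsym <- N + t(N)
  freqs <- rowSums(Nsym) / sum(Nsym)
  pairs <- rbind(c(1, 2), c(1, 3), c(1, 4), c(2, 3), c(2, 4), c(3, 4))
  s <- apply(pairs, 1, function(p) {
    Nsym[p[1], p[2]] / (freqs[p[1]] * freqs[p[2]])
  })
  s <- s / s[6]
  gtr_params(freqs = as.numeric(freqs), rates = as.numeric(s))
}

#' Jukes-Cantor distance between two aligned rows
#'
#' Columns where either row carries a gap or N are excluded. The distance is
#' `-(3/4) log(1 - (4/3) p)` with `p` the mismatch fraction; saturation
#' (`p >= 0.75`) is an error.
#'
#' @param seq_a,seq_b Aligned rows of equal length.
#' @return Distance in substitutions per site.
#' @export
jc_distance <- function(seq_a, seq_b) {
  N <- pair_count_matrix(seq_a, seq_b)
  n <- sum(N)
  if (n == 0L) abort("no usable columns (all gaps/N)")
  p <- (n - sum(diag(N))) / n
  if (p >= 0.75) {
    abort(sprintf("distance undefined: mismatch fraction %.3f >= 0.75", p))
  }
  -0.75 * log(1 - (4 / 3) * p)
}

#' Maximum-likelihood pairwise distance under the GTR model
#'
#' Maximizes the pair likelihood
#' `prod_sites pi_a P_ab(t)` over the branch length `t >= 0`, with `Q`
#' normalized to one expected substitution per unit `t`, by one-dimensional
#' numerical optimization (tolerance 1e-10, bounds expanded as needed).
#'
#' @param seq_a,seq_b Aligned rows (gap/N columns excluded).
#' @param params A [gtr_params()] object.
#' @return ML distance in substitutions per site.
#' @export
gtr_ml_distance <- function(seq_a, seq_b, params = gtr_params()) {
  N <- pair_count_matrix(seq_a, seq_b)
  gtr_ml_distance_counts(N, params)
}

gtr_ml_distance_counts <- function(N, params) {
  n <- sum(N)
  if (n == 0L) abort("no usable columns (all gaps/N)")
  if (sum(diag(N)) == n) return(0)
  p <- (n - sum(diag(N))) / n
  if (p >= 0.75) {
    abort(sprintf("distance undefined: mismatch fraction %.3f >= 0.75", p))
  }
  loglik <- function(t) {
    P <- gtr_transition_matrix(params, t)
    L <- log(pmax(params$freqs * P, 1e-300))
    sum(N * L)
  }
  upper <- 2
  repeat {
    opt <- optimize(loglik, c(0, upper), maximum = TRUE, tol = 1e-10)
    if (opt$maximum < upper * 0.99 || upper > 512) break
    upper <- upper * 4
  }
  if (upper > 512) {
    abort("GTR distance failed to converge (saturated pair)")
  }
  opt$maximum
}
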