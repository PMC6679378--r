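# Independent brute-force oracles used to check the implementation.

# Two-regression least-squares LOD via explicit normal equations.
oracle_lod <- function(y, X0, X1) {
  rss <- function(X) {
    b <- solve(crossprod(X), crossprod(X, y))
    sum((y - X %*% b)^2)
  }
  (length(y) / 2) * log10(rss(X0) / rss(X1))
}

# Exhaustive hidden-path enumeration of F2 genotype probabilities along one
# chromosome (grid loci at positions pos_cM; obs: vector of observed codes
# 1/2/3 or NA per grid locus).  Returns loci x 3 posterior matrix.
oracle_genoprob <- function(obs, pos_cM, error_rate) {
  L <- length(pos_cM)
  Ts <- lapply(eqtlcross::haldane_r(diff(pos_cM)), eqtlcross::f2_transition_matrix)
  prior <- c(0.25, 0.5, 0.25)
  emit <- function(o, s) {
    if (is.na(o)) 1 else if (o == s) 1 - error_rate else error_rate / 2
  }
  states <- as.matrix(expand.grid(rep(list(1:3), L)))
  w <- numeric(nrow(states))
  for (i in seq_len(nrow(states))) {
    st <- states[i, ]
    p <- prior[st[1]] * emit(obs[1], st[1])
    if (L > 1) for (k in seq_len(L - 1)) {
      p <- p * Ts[[k]][st[k], st[k + 1]] * emit(obs[k + 1], st[k + 1])
    }
    w[i] <- p
  }
  post <- matrix(0, L, 3)
  for (k in seq_len(L)) for (s in 1:3) {
    post[k, s] <- sum(w[states[, k] == s])
  }
  post / rowSums(post)
}

# Exhaustive hypergeometric upper tail: draw n from a universe of size N
# containing K marked elements; P(X >= k) by enumerating all C(N, n) draws.
oracle_hyper_tail <- function(k, K, n, N) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # elements 1..K are the marked ones
  mean(hits >= k)
}

# Small standard fixture: one cross on a 2-chromosome map.
make_toy_cross <- function(n = 60, seed = 11, lengths = c(100, 100),
                           spacing = 10) {
  map <- sim_map(lengths, spacing)
  arch <- sim_architecture(n, seed = seed)
  list(map = map, cross = sim_f2_cross(map, arch))
}
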