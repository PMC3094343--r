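# Shared fixture builders. Everything is generated in code under fixed seeds.

# admixed collection with known truth; returns markers, Q, P, cfg
sim_fixture <- function(n = 100, k = 2, fst = 0.25, alpha = 0.05, m = 200,
                        seed = 1, marker_seed = seed + 1000, ...) {
  cfg <- sim_config(n_accessions = n, n_subpops = k, fst = fst,
                    admix_alpha = alpha, n_markers = m, seed = seed, ...)
  pop <- simulate_population(cfg)
  markers <- simulate_markers(pop$Q, pop$subpop_allele_freqs,
                              seed = marker_seed)
  list(cfg = cfg, Q = pop$Q, P = pop$subpop_allele_freqs, markers = markers)
}

# small random binary marker matrix with no all-zero rows
rand_markers <- function(n = 20, m = 30, p = 0.4, seed = 1) {
  set.seed(seed)
  repeat {
    sc <- matrix(rbinom(n * m, 1, p), n, m)
    if (all(rowSums(sc) > 0) && all(colSums(sc) > 0)) break
  }
  marker_matrix(sc)
}

# brute-force BH step-up definition, independent of stats::p.adjust
bh_bruteforce <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- numeric(m)
  prev <- Inf
  for (r in m:1) {
    prev <- min(prev, p[o[r]] * m / r)
    adj[o[r]] <- min(prev, 1)
  }
  adj
}

# dense REML log-likelihood via explicit V = lambda*K + I (oracle path)
reml_dense <- function(lambda, y, X, K) {
  n <- length(y); p <- ncol(X)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  rss <- as.numeric(t(r) %*% Vi %*% r)
  s2 <- rss / (n - p)
  as.numeric(-0.5 * ((n - p) * (log(2 * pi * s2) + 1) +
                       determinant(V)$modulus +
                       determinant(XtViX)$modulus -
                       determinant(crossprod(X))$modulus))
}

# dense GLS marker test at a given lambda (oracle for scan_mixed)
gls_marker_test <- function(y, X0, x, K, lambda) {
  n <- length(y)
  V <- lambda * K + diag(n)
  Vi <- solve(V)
  X <- cbind(X0, x)
  XtViX <- t(X) %*% Vi %*% X
  beta <- solve(XtViX, t(X) %*% Vi %*% y)
  r <- y - X %*% beta
  s2 <- as.numeric(t(r) %*% Vi %*% r) / (n - ncol(X))
  covb <- solve(XtViX) * s2
  tstat <- beta[ncol(X)] / sqrt(covb[ncol(X), ncol(X)])
  2 * pt(-abs(tstat), n - ncol(X))
}
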