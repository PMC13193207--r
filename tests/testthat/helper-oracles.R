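# Independent brute-force oracles used to pin down expected values.
# Each is computed by enumeration / closed form, never by calling the
# package code it checks.

# exact two-sided rank-sum p by enumerating all group-A rank assignments
oracle_ranksum_p <- function(a, b) {
  x <- c(a, b)
  n <- length(x); na <- length(a)
  r <- rank(x)
  obs <- sum(r[seq_len(na)])
  idx <- utils::combn(n, na)
  sums <- apply(idx, 2, function(i) sum(r[i]))
  pl <- mean(sums <= obs)
  pu <- mean(sums >= obs)
  min(1, 2 * min(pl, pu))
}

# exact two-sided signed-rank p by enumerating all 2^n sign vectors
oracle_signedrank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  sums <- drop(signs %*% r)
  pl <- mean(sums <= obs)
  pu <- mean(sums >= obs)
  min(1, 2 * min(pl, pu))
}

# hypergeometric upper tail P(X >= k) by enumerating all draws of size n
oracle_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  in_set <- seq_len(K)
  overlaps <- apply(draws, 2, function(d) sum(d %in% in_set))
  mean(overlaps >= k)
}

# second, independently coded NIPALS PLS1 (autoscaled X, centred y)
oracle_nipals <- function(X, y, ncomp) {
  X <- scale(as.matrix(X))
  y <- y - mean(y)
  W <- NULL; TT <- NULL; PP <- NULL; qs <- c(); ssy <- c()
  for (a in seq_len(ncomp)) {
    w <- as.vector(t(X) %*% y)
    w <- w / sqrt(sum(w * w))
    t_ <- as.vector(X %*% w)
    p_ <- as.vector(t(X) %*% t_) / sum(t_ * t_)
    q_ <- sum(y * t_) / sum(t_ * t_)
    ssy <- c(ssy, q_^2 * sum(t_ * t_))
    X <- X - outer(t_, p_)
    y <- y - q_ * t_
    W <- cbind(W, w); TT <- cbind(TT, t_); PP <- cbind(PP, p_)
    qs <- c(qs, q_)
  }
  list(weights = W, scores = TT, loadings = PP, q = qs, ssy = ssy)
}

oracle_vip <- function(W, ssy) {
  p <- nrow(W)
  sqrt(p * as.vector(W^2 %*% ssy) / sum(ssy))
}

# two-sided two-sample pooled t p-value from the textbook formula
oracle_t_p <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- ((na - 1) * var(a) + (nb - 1) * var(b)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  2 * pt(-abs(t), na + nb - 2)
}

# weighted least-squares line by the closed-form normal equations
oracle_wls_line <- function(x, y, w) {
  sw <- sum(w)
  xb <- sum(w * x) / sw; yb <- sum(w * y) / sw
  slope <- sum(w * (x - xb) * (y - yb)) / sum(w * (x - xb)^2)
  c(intercept = yb - slope * xb, slope = slope)
}

# small null-free cohort config helpers used across test files
null_config <- function(seed, n_features = c(protein = 1000), ...) {
  sim_config(n_features = n_features,
             n_cross_only = setNames(rep(0, length(n_features)), names(n_features)),
             n_long_only = setNames(rep(0, length(n_features)), names(n_features)),
             n_improvement = setNames(rep(0, length(n_features)), names(n_features)),
             n_aggravation = setNames(rep(0, length(n_features)), names(n_features)),
             mnar_midpoint = -1e3, mcar_rate = 0, seed = seed, ...)
}

# quiet wrappers: the pipeline legitimately warns about constant PLS
# features and degenerate arms on extreme synthetic inputs
quiet <- function(expr) suppressWarnings(suppressMessages(expr))
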