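# Independent brute-force oracles used throughout the suite. All of them
# enumerate over definitions directly and never call the package's
# recursive implementations.

# joint log-probability of one (path, obs) pair
path_logprob <- function(model, path, obs) {
  lp <- log(model$pi[path[1]]) + log(model$B[path[1], obs[1]])
  for (t in seq_along(obs)[-1])
    lp <- lp + log(model$A[path[t - 1], path[t]]) +
      log(model$B[path[t], obs[t]])
  unname(lp)
}

# all N^T hidden paths of length T
all_paths <- function(N, T_len)
  as.matrix(expand.grid(rep(list(seq_len(N)), T_len)))

# exhaustive-enumeration forward quantities: loglik, per-position state
# posteriors, best path and its score
enum_hmm <- function(model, obs) {
  paths <- all_paths(model$N, length(obs))
  lp <- apply(paths, 1, path_logprob, model = model, obs = obs)
  w <- exp(lp - max(lp))
  post <- matrix(0, length(obs), model$N)
  for (t in seq_along(obs))
    for (s in seq_len(model$N))
      post[t, s] <- sum(w[paths[, t] == s])
  post <- post / rowSums(post)
  best <- which.max(lp)  # expand.grid varies the first position fastest,
  # so the first maximum is the lexicographically smallest best path,
  # matching the lowest-index tie-break
  list(loglik = max(lp) + log(sum(w)), gamma = post,
       best_path = unname(paths[best, ]), best_score = lp[best])
}

# brute-force Benjamini-Hochberg straight from the definition
bh_brute <- function(p, q) {
  m <- length(p)
  ord <- order(p)
  ps <- p[ord]
  ks <- which(ps <= seq_len(m) / m * q)
  k <- if (length(ks)) max(ks) else 0L
  sig <- logical(m)
  if (k > 0) sig[ord[seq_len(k)]] <- TRUE
  list(significant = sig, k = k)
}

# a tiny ethogram for fast low-dimensional tests
tiny_ethogram <- function(M = 4) {
  ethogram(data.frame(code = LETTERS[seq_len(M)],
                      label = paste("behavior", seq_len(M)),
                      context = rep(c("nest", "out-of-nest"),
                                    length.out = M),
                      stringsAsFactors = FALSE))
}

# wrap plain observation vectors as a seq_set over a tiny ethogram
tiny_seq_set <- function(obs_list, M = 4, group = "G1") {
  n <- length(obs_list)
  meta <- data.frame(subject_id = sprintf("s%02d", seq_len(n)),
                     group = group, day = 1L, hour_block = "H1",
                     stringsAsFactors = FALSE)
  seq_set(meta, obs_list, tiny_ethogram(M))
}

# deterministic small model: state i emits symbol i
identity_model <- function(N, self = 0.8) {
  A <- matrix((1 - self) / (N - 1), N, N)
  diag(A) <- self
  B <- diag(N)
  # keep rows strictly stochastic but emissions effectively identifying
  B <- (B + 1e-9) / rowSums(B + 1e-9)
  hmm_params(A, B, rep(1 / N, N), tol = 1e-6)
}
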