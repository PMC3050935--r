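#' @useDynLib ethohmm, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom utils tail head
#' @importFrom stats setNames
NULL

#' Default state names of the 7-state maternal-behavior model
#'
#' Blanket nursing (BLN), arched-back nursing (ABN), licking/grooming pups
#' (LG), self-grooming (GRO), eating (EAT), activity (ACT) and sleeping
#' (SLP) — the canonical latent states used to segment rodent maternal
#' behavior.
#'
#' @return Character vector of length 7.
#' @export
default_state_names <- function()
  c("BLN", "ABN", "LG", "GRO", "EAT", "ACT", "SLP")

#' Construct a discrete-emission HMM parameter set
#'
#' @param A N x N row-stochastic state-transition matrix.
#' @param B N x M row-stochastic emission matrix (states x symbols).
#' @param pi Length-N initial-state probability vector.
#' @param state_names Optional state labels (default `S1..SN`, or the
#'   canonical 7 maternal-state names when N = 7).
#' @param tol Tolerance for the stochasticity checks.
#' @return An object of class `hmm_params` with elements `A`, `B`, `pi`,
#'   `N`, `M`, `state_names`.
#' @examples
#' m <- hmm_params(A = matrix(c(.9, .1, .2, .8), 2, byrow = TRUE),
#'                 B = matrix(c(.7, .3, .1, .9), 2, byrow = TRUE),
#'                 pi = c(.5, .5))
#' m$N; m$M
#' @export
hmm_params <- function(A, B, pi, state_names = NULL, tol = 1e-10) {
  A <- as.matrix(A); B <- as.matrix(B); pi <- as.numeric(pi)
  N <- nrow(A); M <- ncol(B)
  if (ncol(A) != N) stop("A must be square")
  if (nrow(B) != N) stop("B must have one row per state")
  if (length(pi) != N) stop("pi must have one entry per state")
  if (any(A < 0) || any(B < 0) || any(pi < 0))
    stop("probabilities must be non-negative")
  if (any(abs(rowSums(A) - 1) > tol)) stop("rows of A must sum to 1")
  if (any(abs(rowSums(B) - 1) > tol)) stop("rows of B must sum to 1")
  if (abs(sum(pi) - 1) > tol) stop("pi must sum to 1")
  if (is.null(state_names))
    state_names <- if (N == 7) default_state_names() else paste0("S", seq_len(N))
  if (length(state_names) != N) stop("need one state name per state")
  dimnames(A) <- list(state_names, state_names)
  rownames(B) <- state_names
  names(pi) <- state_names
  structure(list(A = A, B = B, pi = pi, N = N, M = M,
                 state_names = state_names),
            class = "hmm_params")
}

#' @export
print.hmm_params <- function(x, ...) {
  cat(sprintf("hmm_params: %d states, %d symbols\n", x$N, x$M))
  cat("states:", paste(x$state_names, collapse = " "), "\n")
  invisible(x)
}

# accept a bare integer vector, a list element of seq_set$obs, or an
# ObservationSequence-style list with an $obs field
as_obs <- function(seq, M) {
  if (is.list(seq) && !is.null(seq$obs)) seq <- seq$obs
  o <- as.integer(seq)
  if (length(o) < 1L) stop("sequence must have length >= 1")
  if (anyNA(o) || any(o < 1L) || any(o > M))
    stop("observation symbols must be integers in 1..", M)
  o
}

# all observation vectors of a seq_set (or a plain list of vectors)
obs_list_of <- function(seqs, M) {
  lst <- if (inherits(seqs, "seq_set")) seqs$obs else seqs
  if (!is.list(lst)) lst <- list(lst)
  lapply(lst, as_obs, M = M)
}

#' Sequence log-likelihood under an HMM
#'
#' Scaled (normalized-alpha) forward recursion; numerically safe for
#' sequences of length up to at least 1e5. A sequence that is impossible
#' under the model returns `-Inf` with attribute `impossible = TRUE`.
#'
#' @param model An `hmm_params`.
#' @param seq Integer observation vector (1-based symbol indices), or a
#'   sequence object with an `obs` field.
#' @return Log-probability in nats (<= 0).
#' @export
log_likelihood <- function(model, seq) {
  o <- as_obs(seq, model$M)
  ll <- .loglik_cpp(model$A, model$B, model$pi, o - 1L)
  if (!is.finite(ll)) attr(ll, "impossible") <- TRUE
  ll
}

#' Total log-likelihood of a set of sequences
#' @param model An `hmm_params`.
#' @param seqs A `seq_set` or list of observation vectors.
#' @return Summed log-likelihood in nats.
#' @export
total_log_likelihood <- function(model, seqs) {
  sum(vapply(obs_list_of(seqs, model$M), function(o)
    .loglik_cpp(model$A, model$B, model$pi, o - 1L), numeric(1)))
}

#' Forward-backward posteriors
#'
#' @param model An `hmm_params`.
#' @param seq Observation vector (1-based).
#' @return List with `gamma` (T x N per-position state posteriors, rows sum
#'   to 1), `xi` (N x N x (T-1) per-position transition posteriors, each
#'   slice sums to 1) and `loglik`.
#' @export
forward_backward <- function(model, seq) {
  o <- as_obs(seq, model$M)
  r <- .forward_backward_cpp(model$A, model$B, model$pi, o - 1L)
  if (!r$ok) stop("sequence has zero probability under the model")
  dimnames(r$gamma) <- list(NULL, model$state_names)
  list(gamma = r$gamma, xi = r$xi, loglik = r$loglik)
}

#' Viterbi decoding
#'
#' Most probable hidden-state path. Ties are broken toward the lower state
#' index, so decoding is fully deterministic.
#'
#' @param model An `hmm_params`.
#' @param seq Observation vector (1-based).
#' @return List with `path` (integer state indices, 1-based), `states`
#'   (state names along the path) and `score` (joint log-probability of the
#'   path and the observations).
#' @export
viterbi <- function(model, seq) {
  o <- as_obs(seq, model$M)
  r <- .viterbi_cpp(model$A, model$B, model$pi, o - 1L)
  if (!r$ok) stop("sequence has zero probability under the model")
  path <- as.integer(r$path) + 1L
  list(path = path, states = model$state_names[path], score = r$score)
}

#' Multi-sequence Baum-Welch training
#'
#' Expectation-maximization for the HMM parameters: expected transition,
#' emission and initial-state counts are pooled over all sequences (each
#' observation hour is an independent sequence) and the initial distribution
#' is re-estimated from position-1 posteriors. Iteration stops when the
#' relative log-likelihood improvement falls below `tol` or after
#' `max_iter` iterations. Exact zeros appearing in re-estimated emission
#' rows are floored at `floor_eps` and the row renormalized, preventing
#' absorbing zeros; the number of floored entries is reported.
#'
#' @param init Initial `hmm_params`.
#' @param seqs A `seq_set` or list of observation vectors.
#' @param tol Relative log-likelihood convergence tolerance (> 0).
#' @param max_iter Maximum EM iterations (>= 1).
#' @param floor_eps Floor applied to exact-zero emission estimates.
#' @return An object of class `hmm_fit`: list with `model` (`hmm_params`),
#'   `loglik_trajectory` (non-decreasing, one entry per iteration, ending at
#'   the returned model's log-likelihood), `n_iter`, `converged`,
#'   `n_floored`.
#' @export
baum_welch <- function(init, seqs, tol = 1e-6, max_iter = 500,
                       floor_eps = 1e-12) {
  stopifnot(inherits(init, "hmm_params"), tol > 0, max_iter >= 1)
  obs <- lapply(obs_list_of(seqs, init$M), function(o) o - 1L)
  r <- .baum_welch_cpp(init$A, init$B, init$pi, obs, tol,
                       as.integer(max_iter), floor_eps)
  model <- hmm_params(r$A, r$B, as.numeric(r$pi),
                      state_names = init$state_names, tol = 1e-8)
  structure(list(model = model,
                 loglik_trajectory = as.numeric(r$loglik_trajectory),
                 n_iter = r$n_iter, converged = r$converged,
                 n_floored = r$n_floored),
            class = "hmm_fit")
}

#' @export
print.hmm_fit <- function(x, ...) {
  cat(sprintf("hmm_fit: %d states, loglik %.2f after %d iterations (%s)\n",
              x$model$N, tail(x$loglik_trajectory, 1), x$n_iter,
              if (x$converged) "converged" else "max_iter reached"))
  invisible(x)
}

#' Sample an observation sequence from an HMM
#'
#' Generative dual of the model: draws a hidden path from `pi` and `A`, then
#' symbols from `B`. Uses R's global RNG stream, so results are reproducible
#' under `set.seed()`.
#'
#' @param model An `hmm_params`.
#' @param T_len Sequence length (>= 1).
#' @return List with `obs` (1-based symbol indices) and `path` (1-based
#'   hidden-state indices).
#' @export
sample_sequence <- function(model, T_len) {
  stopifnot(T_len >= 1)
  path <- integer(T_len)
  obs <- integer(T_len)
  path[1] <- sample.int(model$N, 1L, prob = model$pi)
  for (t in seq_len(T_len)[-1])
    path[t] <- sample.int(model$N, 1L, prob = model$A[path[t - 1L], ])
  for (t in seq_len(T_len))
    obs[t] <- sample.int(model$M, 1L, prob = model$B[path[t], ])
  list(obs = obs, path = path)
}

#' Write an HMM to a YAML file
#'
#' Stores A, B, pi with state names (and optional behavior codes for the
#' emission columns) in a plain-text YAML document.
#'
#' @param model An `hmm_params`.
#' @param path Output file.
#' @param symbol_names Optional length-M character vector labeling emission
#'   columns (e.g. ethogram codes).
#' @return Invisibly, `path`.
#' @export
write_hmm <- function(model, path, symbol_names = NULL) {
  doc <- list(state_names = model$state_names,
              symbol_names = symbol_names,
              A = lapply(seq_len(model$N), function(i) as.numeric(model$A[i, ])),
              B = lapply(seq_len(model$N), function(i) as.numeric(model$B[i, ])),
              pi = as.numeric(model$pi))
  yaml::write_yaml(doc, path, precision = 17)
  invisible(path)
}

#' Read an HMM written by [write_hmm()]
#' @param path YAML file.
#' @return An `hmm_params`.
#' @export
read_hmm <- function(path) {
  doc <- yaml::read_yaml(path)
  A <- do.call(rbind, lapply(doc$A, as.numeric))
  B <- do.call(rbind, lapply(doc$B, as.numeric))
  hmm_params(A, B, as.numeric(doc$pi), state_names = doc$state_names,
             tol = 1e-8)
}
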