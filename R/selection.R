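#' Free-parameter count of a discrete HMM
#'
#' Each of the N transition rows has N-1 free entries, each of the N
#' emission rows has M-1, and the initial distribution has N-1:
#' d = N(N-1) + N(M-1) + (N-1).
#'
#' @param N Number of states (>= 1).
#' @param M Number of symbols (>= 2).
#' @return Integer free-parameter count.
#' @examples
#' count_free_params(7, 21)  # 188
#' @export
count_free_params <- function(N, M) {
  stopifnot(N >= 1, M >= 2)
  as.integer(N * (N - 1) + N * (M - 1) + (N - 1))
}

#' Bayesian Information Criterion of an HMM on a sequence set
#'
#' BIC = -2 log L + d log(p), where L is the total data likelihood from the
#' scaled forward recursion, d the free-parameter count and p the total
#' number of observations across all sequences. Lower is better.
#'
#' @param model An `hmm_params`.
#' @param seqs A `seq_set` or list of observation vectors.
#' @return Object of class `bic_result`: list with `loglik`, `d`, `p`,
#'   `bic`.
#' @export
bic <- function(model, seqs) {
  obs <- obs_list_of(seqs, model$M)
  if (length(obs) == 0L) stop("empty sequence set")
  ll <- total_log_likelihood(model, obs)
  d <- count_free_params(model$N, model$M)
  p <- sum(lengths(obs))
  structure(list(loglik = ll, d = d, p = p, bic = -2 * ll + d * log(p)),
            class = "bic_result")
}

#' @export
print.bic_result <- function(x, ...) {
  cat(sprintf("BIC %.2f  (loglik %.2f, d = %d, p = %d)\n",
              x$bic, x$loglik, x$d, x$p))
  invisible(x)
}

# expected state occupancy (summed gamma) of a model over sequences
expected_occupancy <- function(model, seqs) {
  obs <- obs_list_of(seqs, model$M)
  occ <- numeric(model$N)
  for (o in obs) {
    r <- .forward_backward_cpp(model$A, model$B, model$pi, o - 1L)
    if (!r$ok) stop("sequence has zero probability under the model")
    occ <- occ + colSums(r$gamma)
  }
  occ
}

#' Merge two HMM states and retrain
#'
#' Builds an (N-1)-state model in which states `i` and `j` are collapsed:
#' their emission rows and outgoing transition rows are averaged with
#' weights given by the states' expected occupancy under `model` on `seqs`,
#' incoming transition probabilities and initial probabilities are summed.
#' By default the merged model is then retrained by Baum-Welch on the same
#' data.
#'
#' @param model An `hmm_params` with N >= 2.
#' @param i,j Distinct state indices (or state names) to merge.
#' @param seqs A `seq_set` used for the occupancy weights and retraining.
#' @param retrain Retrain the merged model by Baum-Welch (default TRUE).
#' @param ... Passed on to [baum_welch()] (`tol`, `max_iter`).
#' @return The merged (and, by default, retrained) `hmm_params`; when
#'   retrained, the full `hmm_fit` is attached as attribute `"fit"`.
#' @export
merge_states <- function(model, i, j, seqs, retrain = TRUE, ...) {
  if (model$N <= 1L) stop("cannot merge states of a 1-state model")
  if (is.character(i)) i <- match(i, model$state_names)
  if (is.character(j)) j <- match(j, model$state_names)
  stopifnot(i %in% seq_len(model$N), j %in% seq_len(model$N), i != j)
  lo <- min(i, j); hi <- max(i, j)
  occ <- expected_occupancy(model, seqs)
  w <- occ[c(lo, hi)]
  if (sum(w) <= 0) w <- c(1, 1)
  w <- w / sum(w)

  keep <- setdiff(seq_len(model$N), hi)  # merged state lives at index lo
  # outgoing rows: occupancy-weighted average, then sum the two incoming cols
  A_rows <- model$A
  A_rows[lo, ] <- w[1] * model$A[lo, ] + w[2] * model$A[hi, ]
  A_new <- A_rows[keep, keep, drop = FALSE]
  A_new[, which(keep == lo)] <- A_rows[keep, lo] + A_rows[keep, hi]
  A_new <- A_new / rowSums(A_new)

  B_new <- model$B
  B_new[lo, ] <- w[1] * model$B[lo, ] + w[2] * model$B[hi, ]
  B_new <- B_new[keep, , drop = FALSE]
  B_new <- B_new / rowSums(B_new)

  pi_new <- model$pi
  pi_new[lo] <- pi_new[lo] + pi_new[hi]
  pi_new <- pi_new[keep]
  pi_new <- pi_new / sum(pi_new)

  nm <- model$state_names
  nm[lo] <- paste0(nm[lo], "+", nm[hi])
  merged <- hmm_params(A_new, B_new, pi_new, state_names = nm[keep],
                       tol = 1e-8)
  if (!retrain) return(merged)
  fit <- baum_welch(merged, seqs, ...)
  structure(fit$model, fit = fit)
}

#' Split one state in two by adding a random emission profile
#'
#' Robustness probe, inverse of [merge_states()]: appends an extra state
#' whose emission row is drawn uniformly on the simplex, gives it a small
#' share of every state's outgoing probability and of the initial
#' distribution, and renormalizes.
#'
#' @param model An `hmm_params`.
#' @param share Probability mass moved onto the new state from each row
#'   (default 0.05).
#' @return An `hmm_params` with N + 1 states.
#' @export
add_random_state <- function(model, share = 0.05) {
  N <- model$N
  b_new <- stats::runif(model$M)
  b_new <- b_new / sum(b_new)
  A <- cbind(model$A * (1 - share), rep(share, N))
  new_row <- c(rep((1 - 0.5) / N, N), 0.5)  # mildly sticky new state
  A <- rbind(A, new_row / sum(new_row))
  B <- rbind(model$B, b_new)
  pi <- c(model$pi * (1 - share), share)
  hmm_params(A / rowSums(A), B, pi / sum(pi),
             state_names = c(model$state_names, "RND"), tol = 1e-8)
}

#' Random HMM initializer
#'
#' Every transition, emission and initial probability is drawn i.i.d.
#' uniform on (0, 1) and each row is normalized to the simplex. Uses R's
#' global RNG, so results are reproducible under `set.seed()`.
#'
#' @param N Number of states.
#' @param M Number of symbols.
#' @param state_names Optional state labels.
#' @return An `hmm_params`.
#' @export
random_init <- function(N, M, state_names = NULL) {
  norm_rows <- function(x) x / rowSums(x)
  A <- norm_rows(matrix(stats::runif(N * N), N, N))
  B <- norm_rows(matrix(stats::runif(N * M), N, M))
  pi <- stats::runif(N)
  hmm_params(A, B, pi / sum(pi), state_names = state_names, tol = 1e-8)
}

#' Random-restart robustness sweep
#'
#' Fits Baum-Welch from `n_restarts` independent uniform-random initial
#' models and reports which fits land on the top log-likelihood plateau.
#' The plateau window is `[best - window_width, best]`; by default
#' `window_width` scales with data size at 0.02 nats per observation, which
#' reproduces a c. 2000-nat window on a c. 100,000-observation study.
#' Plateau membership is a reporting construct for inspecting restart
#' robustness, not an inference.
#'
#' @param seqs A `seq_set`.
#' @param n_restarts Number of random initial models (>= 1).
#' @param window_width Plateau width in nats; `NULL` (default) uses
#'   `0.02 * n_obs(seqs)`.
#' @param N Number of hidden states of every restart (default 7).
#' @param tol,max_iter Passed to [baum_welch()].
#' @return Object of class `sweep_result`: list with `fits` (list of
#'   `hmm_fit`), `final_logliks`, `best` (index of the best fit),
#'   `plateau_window` (length-2 numeric) and `plateau_members` (indices).
#' @export
restart_sweep <- function(seqs, n_restarts, window_width = NULL,
                          N = 7, tol = 1e-6, max_iter = 500) {
  stopifnot(n_restarts >= 1)
  M <- n_symbols(seqs$ethogram)
  if (is.null(window_width)) window_width <- 0.02 * n_obs(seqs)
  fits <- vector("list", n_restarts)
  for (k in seq_len(n_restarts)) {
    init <- random_init(N, M)
    fits[[k]] <- baum_welch(init, seqs, tol = tol, max_iter = max_iter)
  }
  ll <- vapply(fits, function(f) tail(f$loglik_trajectory, 1), numeric(1))
  best <- which.max(ll)
  window <- c(ll[best] - window_width, ll[best])
  members <- which(ll >= window[1])
  structure(list(fits = fits, final_logliks = ll, best = best,
                 plateau_window = window, plateau_members = members),
            class = "sweep_result")
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("restart sweep: %d fits, best loglik %.2f, %d on plateau [%.2f, %.2f]\n",
              length(x$fits), x$final_logliks[x$best],
              length(x$plateau_members), x$plateau_window[1],
              x$plateau_window[2]))
  invisible(x)
}

# total variation distance between two probability rows
tv_distance <- function(p, q) 0.5 * sum(abs(p - q))

# minimum-cost assignment by depth-first search with pruning; rows of
# `cost` are assigned to distinct columns. Sizes here are at most ~9.
min_cost_assignment <- function(cost) {
  n <- nrow(cost); m <- ncol(cost)
  stopifnot(n <= m, n <= 9)
  best_cost <- Inf
  best_perm <- integer(n)
  perm <- integer(n)
  used <- logical(m)
  lower <- sum(apply(cost, 1, min))  # admissible bound
  rec <- function(r, acc) {
    if (acc >= best_cost) return()
    if (r > n) {
      best_cost <<- acc
      best_perm <<- perm[seq_len(n)]
      return()
    }
    ord <- order(cost[r, ])
    for (cidx in ord) {
      if (!used[cidx]) {
        used[cidx] <<- TRUE
        perm[r] <<- cidx
        rec(r + 1L, acc + cost[r, cidx])
        used[cidx] <<- FALSE
      }
    }
  }
  rec(1L, 0)
  list(assignment = best_perm, cost = best_cost)
}

#' Match states of two HMMs by emission profile
#'
#' Finds the bijection between the states of `model_a` and `model_b` (onto
#' a subset of the larger model when state counts differ) that minimizes
#' the total variation distance between matched emission rows, by optimal
#' assignment.
#'
#' @param model_a,model_b `hmm_params` sharing one symbol alphabet (equal M).
#' @return Object of class `state_match`: list with `mapping` (for each
#'   state of the smaller model, the matched state index in the other
#'   model), `distances` (per matched pair) and `total` (summed distance).
#'   `from` records which model the mapping indexes from (`"a"` if
#'   `model_a` has at most as many states).
#' @export
match_states <- function(model_a, model_b) {
  if (model_a$M != model_b$M) stop("models must share one symbol alphabet")
  swap <- model_a$N > model_b$N
  small <- if (swap) model_b else model_a
  large <- if (swap) model_a else model_b
  cost <- matrix(0, small$N, large$N)
  for (i in seq_len(small$N))
    for (j in seq_len(large$N))
      cost[i, j] <- tv_distance(small$B[i, ], large$B[j, ])
  sol <- min_cost_assignment(cost)
  structure(list(mapping = sol$assignment,
                 distances = cost[cbind(seq_len(small$N), sol$assignment)],
                 total = sol$cost,
                 from = if (swap) "b" else "a"),
            class = "state_match")
}

#' @export
print.state_match <- function(x, ...) {
  cat("state match:", paste(seq_along(x$mapping), "->", x$mapping,
                            collapse = ", "), "\n")
  cat("TV distances:", paste(sprintf("%.3f", x$distances), collapse = " "),
      "\n")
  invisible(x)
}

#' Align a model's state order to a reference model
#'
#' Permutes states of `model` so that state k matches state k of `ref`
#' under the optimal emission-profile assignment of [match_states()].
#'
#' @param model,ref `hmm_params` with equal N and M.
#' @return The permuted `hmm_params` (with `ref`'s state names).
#' @export
align_states <- function(model, ref) {
  if (model$N != ref$N) stop("models must have equal state counts")
  m <- match_states(ref, model)
  perm <- m$mapping  # ref state k corresponds to model state perm[k]
  hmm_params(model$A[perm, perm, drop = FALSE],
             model$B[perm, , drop = FALSE],
             model$pi[perm], state_names = ref$state_names, tol = 1e-8)
}
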