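test_that("free-parameter count follows the row-simplex counting argument", {
  expect_equal(count_free_params(1, 2), 1)
  # 2 states, 2 symbols: 2 free transition + 2 free emission + 1 initial
  expect_equal(count_free_params(2, 2), 5)
  # counting oracle: sum the free entries row by row
  d_oracle <- function(N, M) N * (N - 1) + N * (M - 1) + (N - 1)
  for (N in 1:8) for (M in 2:6)
    expect_equal(count_free_params(N, M), d_oracle(N, M))
  expect_equal(count_free_params(7, 21), 188)
})

test_that("bic combines loglik, d and p and responds to data duplication", {
  set.seed(201)
  m <- random_init(2, 4)
  obs <- replicate(3, sample.int(4, 30, TRUE), simplify = FALSE)
  b <- bic(m, obs)
  expect_equal(b$p, 90)
  expect_equal(b$d, count_free_params(2, 4))
  expect_equal(b$loglik, sum(sapply(obs, function(o) log_likelihood(m, o))),
               tolerance = 1e-10)
  expect_equal(b$bic, -2 * b$loglik + b$d * log(b$p), tolerance = 1e-10)
  # duplicated data: loglik and p double, bic recomputed consistently
  b2 <- bic(m, c(obs, obs))
  expect_equal(b2$loglik, 2 * b$loglik, tolerance = 1e-10)
  expect_equal(b2$p, 2 * b$p)
  expect_equal(b2$bic, -2 * 2 * b$loglik + b$d * log(2 * b$p),
               tolerance = 1e-10)
  # a deterministic perfect model has loglik 0, so bic = d log p
  md <- hmm_params(matrix(1), matrix(c(1 - 1e-15, 1e-15), 1), 1)
  bd <- bic(md, list(rep(1L, 10)))
  expect_equal(bd$bic, bd$d * log(10), tolerance = 1e-8)
  expect_error(bic(m, list()), "empty")
  # at fixed loglik and p, bic strictly increases with d
  expect_gt(-2 * b$loglik + count_free_params(3, 4) * log(b$p), b$bic)
})

test_that("merging two lumpable states preserves likelihoods exactly", {
  # states 2 and 3 have identical emission rows and identical transition
  # rows, and every state treats them interchangeably: exact lumpability
  A <- matrix(c(.6, .2, .2,
                .3, .35, .35,
                .3, .35, .35), 3, byrow = TRUE)
  B <- matrix(c(.8, .1, .1,
                .1, .1, .8,
                .1, .1, .8), 3, byrow = TRUE)
  m <- hmm_params(A, B, c(.4, .3, .3))
  set.seed(202)
  obs <- replicate(5, sample_sequence(m, 40)$obs, simplify = FALSE)
  ss <- tiny_seq_set(obs, M = 3)
  merged <- merge_states(m, 2, 3, ss, retrain = FALSE)
  expect_equal(merged$N, 2)
  expect_equal(rowSums(merged$A), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(merged$B), rep(1, 2), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(merged$pi), 1, tolerance = 1e-12)
  for (o in obs)
    expect_equal(log_likelihood(merged, o), log_likelihood(m, o),
                 tolerance = 1e-8)
})

test_that("merged-and-retrained models never beat the larger model", {
  set.seed(203)
  truth <- random_init(4, 5)
  obs <- replicate(20, sample_sequence(truth, 60)$obs, simplify = FALSE)
  ss <- tiny_seq_set(obs, M = 5)
  fit4 <- baum_welch(structured_init(tiny_ethogram(5), noise = 0.2,
                                     anchors = c(S1 = "A", S2 = "B",
                                                 S3 = "C", S4 = "D")),
                     ss, max_iter = 200)
  merged <- merge_states(fit4$model, 1, 2, ss, max_iter = 200)
  ll4 <- total_log_likelihood(fit4$model, ss)
  ll3 <- total_log_likelihood(merged, ss)
  expect_lte(ll3, ll4 + 1e-6)
  expect_equal(merged$N, 3)
})

test_that("merge_states rejects degenerate requests", {
  m1 <- hmm_params(matrix(1), matrix(c(.6, .4), 1), 1)
  expect_error(merge_states(m1, 1, 1, list(c(1L, 2L))), "1-state")
})

test_that("random initial models are simplex-valued and seed-reproducible", {
  set.seed(204); m1 <- random_init(5, 9)
  set.seed(204); m2 <- random_init(5, 9)
  set.seed(205); m3 <- random_init(5, 9)
  expect_equal(rowSums(m1$A), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(rowSums(m1$B), rep(1, 5), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_equal(sum(m1$pi), 1, tolerance = 1e-12)
  expect_identical(m1, m2)
  expect_gt(max(abs(m1$B - m3$B)), 1e-6)
})

test_that("restart sweep identifies the plateau and always keeps the best", {
  set.seed(206)
  truth <- random_init(2, 4)
  obs <- replicate(10, sample_sequence(truth, 60)$obs, simplify = FALSE)
  ss <- tiny_seq_set(obs)
  sw <- restart_sweep(ss, n_restarts = 1, N = 2, max_iter = 50)
  expect_equal(sw$plateau_members, 1L)
  expect_equal(sw$best, 1L)
  sw5 <- restart_sweep(ss, n_restarts = 5, N = 2, max_iter = 100)
  expect_true(sw5$best %in% sw5$plateau_members)
  expect_true(all(sw5$final_logliks[sw5$plateau_members] >=
                    sw5$plateau_window[1] - 1e-9))
  expect_equal(sw5$plateau_window[2] - sw5$plateau_window[1],
               0.02 * n_obs(ss))
})

test_that("state matching recovers identity and permutations exactly", {
  set.seed(207)
  m <- random_init(5, 8)
  self <- match_states(m, m)
  expect_equal(self$mapping, 1:5)
  expect_equal(self$distances, rep(0, 5))
  perm <- c(4, 2, 5, 1, 3)
  mp <- hmm_params(m$A[perm, perm], m$B[perm, ], m$pi[perm])
  mm <- match_states(m, mp)
  expect_equal(mm$distances, rep(0, 5))
  # mapping[k] gives the position of state k inside the permuted model
  expect_equal(perm[mm$mapping], 1:5)
  expect_error(match_states(m, random_init(5, 9)), "alphabet")
})

test_that("optimal assignment never exceeds any greedy assignment", {
  set.seed(208)
  for (r in 1:20) {
    a <- random_init(4, 6)
    b <- random_init(4, 6)
    opt <- match_states(a, b)
    # greedy: best remaining column per row, in row order
    cost <- outer(1:4, 1:4, Vectorize(function(i, j)
      0.5 * sum(abs(a$B[i, ] - b$B[j, ]))))
    used <- integer(0); g <- 0
    for (i in 1:4) {
      j <- setdiff(order(cost[i, ]), used)[1]
      used <- c(used, j); g <- g + cost[i, j]
    }
    expect_lte(opt$total, g + 1e-12)
  }
})

test_that("align_states permutes a model onto its reference", {
  set.seed(209)
  m <- random_init(4, 7)
  perm <- c(3, 1, 4, 2)
  mp <- hmm_params(m$A[perm, perm], m$B[perm, ], m$pi[perm])
  al <- align_states(mp, m)
  expect_equal(al$A, m$A, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(al$B, m$B, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("adding a random probe state keeps the model valid", {
  set.seed(210)
  m <- random_init(3, 6)
  m8 <- add_random_state(m)
  expect_equal(m8$N, 4)
  expect_equal(rowSums(m8$A), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(rowSums(m8$B), rep(1, 4), tolerance = 1e-10,
               ignore_attr = TRUE)
  expect_equal(sum(m8$pi), 1, tolerance = 1e-10)
})
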