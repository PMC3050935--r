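#' Viterbi-label every sequence of a set
#'
#' Decodes each hour-long sequence independently with [viterbi()]. Fully
#' deterministic (Viterbi ties break toward the lower state index).
#'
#' @param model An `hmm_params`.
#' @param seqset A `seq_set` over the same symbol alphabet.
#' @return A list of integer state-label vectors, aligned one-to-one with
#'   `seqset$obs`.
#' @export
label_all <- function(model, seqset) {
  if (n_symbols(seqset$ethogram) != model$M)
    stop("model and sequence set must share one symbol alphabet")
  lapply(seqset$obs, function(o) viterbi(model, o)$path)
}

# run-length bouts of a single label vector: data.frame(state, length)
label_bouts <- function(labels) {
  r <- rle(labels)
  data.frame(state = r$values, length = r$lengths)
}

#' Per-group summary of labeled state sequences
#'
#' Computes, for one group, the descriptive statistics of its decoded state
#' sequences: per-subject and pooled state frequencies (fraction of
#' minutes), bout counts and mean bout durations (a bout is a maximal run
#' of one state within an hour block; bouts never span blocks), state
#' compositions (empirical behavior frequencies within minutes labeled with
#' each state), and transition statistics over consecutive minute pairs
#' within a block: raw counts, row-normalized conditional probabilities
#' (self-transitions included) and absolute cross-state rates in
#' transitions per observed minute.
#'
#' @param labels List of state-label vectors from [label_all()], aligned to
#'   `seqset`.
#' @param seqset The labeled `seq_set`.
#' @param group Group name to summarize.
#' @param n_states Number of model states the labels refer to.
#' @param state_names Optional state names.
#' @return Object of class `group_stats`: list with `group`, `n_subjects`,
#'   `total_minutes`, `subject_freq` (subjects x states), `pooled_freq`,
#'   `state_minutes` (pooled minute counts), `n_bouts`, `mean_bout`
#'   (minutes; NA for unvisited states), `composition_counts` /
#'   `composition` (states x behaviors), `transition_counts` (states x
#'   states), `transition_prob` (conditional, rows sum to 1 over visited
#'   states) and `transition_rate` (absolute cross-state transitions per
#'   minute).
#' @export
summarize_group <- function(labels, seqset, group,
                            n_states = 7, state_names = NULL) {
  if (length(labels) != length(seqset$obs))
    stop("labels must align one-to-one with sequences")
  rows <- which(seqset$meta$group == group)
  if (length(rows) == 0L) stop("group not present: ", group)
  if (is.null(state_names))
    state_names <- if (n_states == 7) default_state_names()
                   else paste0("S", seq_len(n_states))
  M <- n_symbols(seqset$ethogram)
  subjects <- unique(seqset$meta$subject_id[rows])

  state_minutes <- integer(n_states)
  comp <- matrix(0L, n_states, M,
                 dimnames = list(state_names, seqset$ethogram$code))
  trans <- matrix(0L, n_states, n_states,
                  dimnames = list(state_names, state_names))
  n_bouts <- integer(n_states)
  subj_minutes <- matrix(0L, length(subjects), n_states,
                         dimnames = list(subjects, state_names))
  subj_total <- setNames(integer(length(subjects)), subjects)
  total_minutes <- 0L

  for (r in rows) {
    lab <- labels[[r]]
    obs <- seqset$obs[[r]]
    if (length(lab) != length(obs))
      stop("label length mismatch at sequence ", r)
    sid <- seqset$meta$subject_id[r]
    total_minutes <- total_minutes + length(lab)
    subj_total[sid] <- subj_total[sid] + length(lab)
    tab <- tabulate(lab, nbins = n_states)
    state_minutes <- state_minutes + tab
    subj_minutes[sid, ] <- subj_minutes[sid, ] + tab
    for (k in seq_along(lab))
      comp[lab[k], obs[k]] <- comp[lab[k], obs[k]] + 1L
    if (length(lab) > 1L) {
      from <- lab[-length(lab)]
      to <- lab[-1L]
      for (k in seq_along(from))
        trans[from[k], to[k]] <- trans[from[k], to[k]] + 1L
    }
    b <- rle(lab)
    n_bouts <- n_bouts + tabulate(b$values, nbins = n_states)
  }

  pooled_freq <- state_minutes / total_minutes
  subject_freq <- subj_minutes / subj_total
  composition <- comp / ifelse(state_minutes > 0, state_minutes, 1)
  row_tot <- rowSums(trans)
  transition_prob <- trans / ifelse(row_tot > 0, row_tot, 1)
  rate <- trans / total_minutes
  diag(rate) <- 0
  mean_bout <- ifelse(n_bouts > 0, state_minutes / n_bouts, NA_real_)

  structure(list(group = group, n_subjects = length(subjects),
                 total_minutes = total_minutes,
                 subject_freq = subject_freq,
                 pooled_freq = setNames(pooled_freq, state_names),
                 state_minutes = setNames(state_minutes, state_names),
                 n_bouts = setNames(n_bouts, state_names),
                 mean_bout = setNames(mean_bout, state_names),
                 composition_counts = comp, composition = composition,
                 transition_counts = trans,
                 transition_prob = transition_prob,
                 transition_rate = rate,
                 state_names = state_names,
                 behavior_codes = seqset$ethogram$code),
            class = "group_stats")
}

#' @export
print.group_stats <- function(x, ...) {
  cat(sprintf("group_stats for %s: %d subjects, %d minutes\n",
              x$group, x$n_subjects, x$total_minutes))
  cat("state frequencies:\n")
  print(round(x$pooled_freq, 3))
  cat("mean bout durations (min):\n")
  print(round(x$mean_bout, 2))
  invisible(x)
}

#' Pooled two-proportion z test
#'
#' Tests equality of two proportions x1/n1 and x2/n2 with the pooled
#' estimator phat = (x1+x2)/(n1+n2) and statistic
#' z = (x1/n1 - x2/n2) / sqrt(phat (1-phat) (1/n1 + 1/n2)),
#' which is standard normal under the null; the two-sided p-value follows.
#' The normal approximation is flagged valid only when x1, x2, n1-x1 and
#' n2-x2 all exceed 5. A degenerate pooled proportion (0 or 1) leaves z
#' undefined; then z = NA, p = 1 and valid = FALSE.
#'
#' @param x1,x2 Success counts.
#' @param n1,n2 Trial counts (>= 1).
#' @return List with `z`, `p` (two-sided) and `valid`.
#' @examples
#' two_proportion_test(50, 100, 30, 100)
#' @export
two_proportion_test <- function(x1, n1, x2, n2) {
  stopifnot(n1 >= 1, n2 >= 1, x1 >= 0, x2 >= 0, x1 <= n1, x2 <= n2)
  valid <- x1 > 5 && x2 > 5 && (n1 - x1) > 5 && (n2 - x2) > 5
  phat <- (x1 + x2) / (n1 + n2)
  if (phat <= 0 || phat >= 1)
    return(list(z = NA_real_, p = 1, valid = FALSE))
  z <- (x1 / n1 - x2 / n2) / sqrt(phat * (1 - phat) * (1 / n1 + 1 / n2))
  list(z = z, p = 2 * stats::pnorm(-abs(z)), valid = valid)
}

#' Two-sample t test on per-subject state frequencies
#'
#' Pooled-variance (Student) two-sample t test by default; Welch's
#' unequal-variance form on request. Two identical degenerate groups (zero
#' variance, equal means) give t = 0, p = 1.
#'
#' @param freqs_a,freqs_b Numeric vectors of per-subject values (>= 2 per
#'   group).
#' @param var_equal Pooled-variance Student t (default TRUE); FALSE gives
#'   Welch.
#' @return List with `t`, `df` and two-sided `p`.
#' @export
freq_ttest <- function(freqs_a, freqs_b, var_equal = TRUE) {
  stopifnot(length(freqs_a) >= 2, length(freqs_b) >= 2)
  if (stats::var(freqs_a) == 0 && stats::var(freqs_b) == 0) {
    if (mean(freqs_a) == mean(freqs_b))
      return(list(t = 0, df = length(freqs_a) + length(freqs_b) - 2, p = 1))
    return(list(t = sign(mean(freqs_a) - mean(freqs_b)) * Inf,
                df = length(freqs_a) + length(freqs_b) - 2, p = 0))
  }
  ht <- stats::t.test(freqs_a, freqs_b, var.equal = var_equal)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = unname(ht$p.value))
}

#' Benjamini-Hochberg step-up procedure
#'
#' Orders the m p-values, finds the largest i with p_(i) <= (i/m) q, and
#' calls the i smallest significant, controlling the false discovery rate
#' at level q.
#'
#' @param pvals Numeric vector of p-values in \[0, 1\].
#' @param q FDR level in (0, 1), default 0.05.
#' @return List with `significant` (logical, original order) and `k`
#'   (number of rejections).
#' @examples
#' benjamini_hochberg(c(0.001, 0.02, 0.04, 0.2), q = 0.05)
#' @export
benjamini_hochberg <- function(pvals, q = 0.05) {
  stopifnot(q > 0, q < 1)
  m <- length(pvals)
  if (m == 0L) return(list(significant = logical(0), k = 0L))
  if (any(pvals < 0 | pvals > 1, na.rm = TRUE) || anyNA(pvals))
    stop("p-values must lie in [0, 1]")
  ord <- order(pvals)
  ok <- which(pvals[ord] <= seq_len(m) / m * q)
  k <- if (length(ok)) max(ok) else 0L
  sig <- logical(m)
  if (k > 0L) sig[ord[seq_len(k)]] <- TRUE
  list(significant = sig, k = as.integer(k))
}

#' Compare two groups on state frequencies, compositions and transitions
#'
#' Runs the full battery of between-group tests on two [summarize_group()]
#' summaries: one pooled-variance t test per state on per-subject
#' frequencies; one pooled two-proportion z test per (state, behavior)
#' composition cell, using within-state minute counts pooled over subjects;
#' and one z test per ordered cross-state transition, using transition
#' counts over total observed minutes. Benjamini-Hochberg correction is
#' applied separately within each of the three families; z tests failing
#' the >5 count rule are reported with `valid = FALSE` and excluded from
#' the correction.
#'
#' @param stats_a,stats_b `group_stats` built on the same model and
#'   ethogram.
#' @param q FDR level (default 0.05).
#' @param welch Use Welch instead of pooled-variance t tests.
#' @return A data frame of class `comparison_result` with columns `family`
#'   (`frequencies`, `compositions`, `transitions`), `hypothesis`,
#'   `statistic`, `p`, `valid`, `bh_significant`.
#' @export
compare_groups <- function(stats_a, stats_b, q = 0.05, welch = FALSE) {
  if (!identical(stats_a$state_names, stats_b$state_names) ||
      !identical(stats_a$behavior_codes, stats_b$behavior_codes))
    stop("group summaries must share state set and ethogram")
  sn <- stats_a$state_names
  out <- list()

  # frequencies: per-state t test on per-subject fractions
  for (s in seq_along(sn)) {
    tt <- freq_ttest(stats_a$subject_freq[, s], stats_b$subject_freq[, s],
                     var_equal = !welch)
    out[[length(out) + 1L]] <- data.frame(
      family = "frequencies", hypothesis = sn[s],
      statistic = tt$t, p = tt$p, valid = TRUE,
      stringsAsFactors = FALSE)
  }

  # compositions: per (state, behavior) cell with pooled within-state counts
  codes <- stats_a$behavior_codes
  for (s in seq_along(sn)) {
    n1 <- stats_a$state_minutes[s]
    n2 <- stats_b$state_minutes[s]
    if (n1 == 0 || n2 == 0) next
    for (b in seq_along(codes)) {
      x1 <- stats_a$composition_counts[s, b]
      x2 <- stats_b$composition_counts[s, b]
      if (x1 == 0 && x2 == 0) next
      zt <- two_proportion_test(x1, n1, x2, n2)
      out[[length(out) + 1L]] <- data.frame(
        family = "compositions",
        hypothesis = paste0(sn[s], ":", codes[b]),
        statistic = zt$z, p = zt$p, valid = zt$valid,
        stringsAsFactors = FALSE)
    }
  }

  # transitions: ordered cross-state pairs, counts over total minutes
  for (i in seq_along(sn)) for (j in seq_along(sn)) {
    if (i == j) next
    x1 <- stats_a$transition_counts[i, j]
    x2 <- stats_b$transition_counts[i, j]
    if (x1 == 0 && x2 == 0) next
    zt <- two_proportion_test(x1, stats_a$total_minutes,
                              x2, stats_b$total_minutes)
    out[[length(out) + 1L]] <- data.frame(
      family = "transitions",
      hypothesis = paste0(sn[i], "->", sn[j]),
      statistic = zt$z, p = zt$p, valid = zt$valid,
      stringsAsFactors = FALSE)
  }

  res <- do.call(rbind, out)
  res$bh_significant <- FALSE
  for (fam in unique(res$family)) {
    idx <- which(res$family == fam & res$valid)
    if (length(idx))
      res$bh_significant[idx] <- benjamini_hochberg(res$p[idx], q)$significant
  }
  rownames(res) <- NULL
  class(res) <- c("comparison_result", "data.frame")
  attr(res, "q") <- q
  res
}

#' Export a state-graph edge list
#'
#' Edge list (source, target, rate) of absolute cross-state transition
#' rates with per-state frequency and mean bout duration, the data behind
#' circle-and-arrow state-diagram figures.
#'
#' @param stats A `group_stats`.
#' @param min_rate Drop edges below this rate (transitions/minute).
#' @return Data frame with columns `source`, `target`, `rate`, plus
#'   attribute `nodes`: data frame of `state`, `frequency`,
#'   `mean_bout_min`.
#' @export
state_graph <- function(stats, min_rate = 0) {
  sn <- stats$state_names
  idx <- which(stats$transition_rate > min_rate, arr.ind = TRUE)
  edges <- data.frame(source = sn[idx[, 1]], target = sn[idx[, 2]],
                      rate = stats$transition_rate[idx],
                      stringsAsFactors = FALSE)
  edges <- edges[order(-edges$rate), ]
  rownames(edges) <- NULL
  attr(edges, "nodes") <- data.frame(state = sn,
                                     frequency = as.numeric(stats$pooled_freq),
                                     mean_bout_min = as.numeric(stats$mean_bout),
                                     stringsAsFactors = FALSE)
  edges
}
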