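#' Observation design of a synthetic maternal-behavior study
#'
#' Defaults mirror a four-strain mouse maternal-observation design: inbred
#' C57BL/6 (26 dams) and BALB/c (26), reciprocal hybrids B6xC (36) and
#' CxB6 (39), scored once a minute for two separate hours per day over
#' postnatal days 1-7.
#'
#' @param groups Named integer vector: subjects per group.
#' @param days Observed postnatal days.
#' @param hours_per_day Hour blocks per day.
#' @param minutes_per_hour Observations per hour block.
#' @param seed Master seed for dataset generation.
#' @return Object of class `study_design`.
#' @export
study_design <- function(groups = c("C57BL/6" = 26, "BALB/c" = 26,
                                    "B6xC" = 36, "CxB6" = 39),
                         days = 1:7, hours_per_day = 2,
                         minutes_per_hour = 60, seed = 1) {
  stopifnot(all(groups >= 1), length(names(groups)) == length(groups),
            hours_per_day >= 1, minutes_per_hour >= 1)
  structure(list(groups = groups, days = as.integer(days),
                 hours_per_day = as.integer(hours_per_day),
                 minutes_per_hour = as.integer(minutes_per_hour),
                 seed = as.integer(seed)),
            class = "study_design")
}

#' @export
print.study_design <- function(x, ...) {
  cat(sprintf("study_design: %d subjects in %d groups, %d days x %d h x %d min (seed %d)\n",
              sum(x$groups), length(x$groups), length(x$days),
              x$hours_per_day, x$minutes_per_hour, x$seed))
  invisible(x)
}

#' Base 7-state ground-truth model over the default ethogram
#'
#' A hand-specified generating model whose states reproduce the
#' qualitative structure of rodent maternal behavior: two persistent
#' nursing states (BLN, ABN; self-transitions give ~12.5-minute expected
#' bouts), a short licking/grooming state (LG, ~4 min) positioned as the
#' dominant gateway between nursing and out-of-nest activity, a
#' heterogeneous self-grooming transition state (GRO, ~3.3 min), brief
#' interchanging EAT and ACT states (~4 min) with EAT emitting almost only
#' eating, and a sleeping state (SLP). Emission rows concentrate most mass
#' on each state's namesake behavior with the remainder on its typical
#' minor behaviors; GRO is deliberately the most mixed state. All numbers
#' are design targets for a plausible generating process, not estimates
#' from any real dataset.
#'
#' @return An `hmm_params` with 7 states over the 21-symbol default
#'   ethogram.
#' @export
base_ground_truth <- function() {
  eth <- default_ethogram()
  M <- n_symbols(eth)
  sn <- default_state_names()
  B <- matrix(0, 7, M, dimnames = list(sn, eth$code))
  set_row <- function(state, ...) {
    v <- c(...)
    B[state, names(v)] <<- v
  }
  set_row("BLN", N = .76, A = .13, P = .05, `N+` = .02, G = .02, U = .02)
  set_row("ABN", A = .79, P = .08, N = .07, `A+` = .02, U = .02, G = .02)
  set_row("LG",  P = .66, G = .10, A = .08, N = .05, U = .04, V = .03,
          `P+` = .02, W = .02)
  set_row("GRO", V = .34, W = .21, B = .12, P = .09, S = .08, G = .08,
          U = .04, Z = .04)
  set_row("EAT", E = .93, V = .03, D = .02, S = .02)
  set_row("ACT", S = .37, Z = .13, D = .12, R = .08, C = .07, M = .06,
          V = .06, E = .05, K = .03, T = .03)
  set_row("SLP", X = .88, S = .05, V = .04, Z = .03)

  A <- matrix(0, 7, 7, dimnames = list(sn, sn))
  A["BLN", ] <- c(BLN = .92, ABN = .035, LG = .035, GRO = .01, EAT = 0,
                  ACT = 0, SLP = 0)
  A["ABN", ] <- c(.035, .92, .035, .01, 0, 0, 0)
  A["LG", ]  <- c(.08, .08, .75, .03, .01, .05, 0)
  A["GRO", ] <- c(.05, .03, .08, .70, .04, .10, 0)
  A["EAT", ] <- c(0, 0, .03, .03, .75, .17, .02)
  A["ACT", ] <- c(0, 0, .04, .05, .13, .75, .03)
  A["SLP", ] <- c(0, 0, 0, .03, .05, .12, .80)

  pi <- c(BLN = .25, ABN = .25, LG = .15, GRO = .05, EAT = .08,
          ACT = .17, SLP = .05)
  hmm_params(A, B, pi, state_names = sn)
}

# raise (or lower) one row entry by delta and rescale the rest of the row
# so it stays on the simplex
perturb_row <- function(row, col, delta) {
  old <- row[col]
  new <- old + delta
  if (new < 0 || new >= 1)
    stop(sprintf("perturbation drives entry to %.3f, outside [0, 1)", new))
  row[-col] <- row[-col] * (1 - new) / (1 - old)
  row[col] <- new
  row
}

apply_contrasts <- function(base, contrasts) {
  m <- base
  for (k in seq_len(nrow(contrasts))) {
    cn <- contrasts[k, ]
    if (cn$matrix == "A") {
      i <- match(cn$row, m$state_names)
      j <- match(cn$col, m$state_names)
      if (is.na(i) || is.na(j)) stop("unknown state in contrast")
      m$A[i, ] <- perturb_row(m$A[i, ], j, cn$delta)
    } else if (cn$matrix == "B") {
      i <- match(cn$row, m$state_names)
      j <- which(colnames(m$B) == cn$col)
      if (is.na(i) || length(j) != 1L) stop("unknown state/behavior in contrast")
      m$B[i, ] <- perturb_row(m$B[i, ], j, cn$delta)
    } else if (cn$matrix == "pi") {
      i <- match(cn$row, m$state_names)
      if (is.na(i)) stop("unknown state in contrast")
      m$pi <- perturb_row(m$pi, i, cn$delta)
    } else stop("contrast matrix must be 'A', 'B' or 'pi'")
  }
  hmm_params(m$A, m$B, m$pi, state_names = m$state_names, tol = 1e-8)
}

#' Build per-group ground-truth models from a base model and contrasts
#'
#' Each contrast raises (or lowers) one named entry of one group's A, B or
#' pi by `delta`, rescaling the rest of the row so it stays a probability
#' distribution. The contrast table is retained as the perturbation log;
#' re-applying it to the base model reconstructs each group model exactly.
#'
#' @param base The shared base `hmm_params`.
#' @param contrasts Data frame with columns `group`, `matrix` (`"A"`,
#'   `"B"` or `"pi"`), `row` (state name), `col` (state name for A,
#'   behavior code for B, ignored for pi) and `delta`. An empty (0-row)
#'   table gives every group the base model.
#' @param groups Character vector of group names to build models for.
#' @return Object of class `ground_truth_spec`: list with `base`, `models`
#'   (named list of per-group `hmm_params`) and `contrasts` (the log).
#' @export
make_group_models <- function(base, contrasts, groups) {
  stopifnot(inherits(base, "hmm_params"))
  if (is.null(contrasts) || nrow(contrasts) == 0L) {
    contrasts <- data.frame(group = character(0), matrix = character(0),
                            row = character(0), col = character(0),
                            delta = numeric(0), stringsAsFactors = FALSE)
  }
  models <- lapply(setNames(groups, groups), function(g)
    apply_contrasts(base, contrasts[contrasts$group == g, , drop = FALSE]))
  structure(list(base = base, models = models, contrasts = contrasts),
            class = "ground_truth_spec")
}

#' Default strain-style contrasts for the four-group design
#'
#' Encodes the qualitative strain differences the generator emulates: the
#' BALB/c-like group gets more persistent blanket nursing at the expense of
#' arched-back nursing (ABN decays into BLN more often), frequent direct
#' GRO-to-BLN transitions bypassing LG, more self-grooming inside the LG
#' state, and non-negligible out-of-nest sleeping; the hybrid groups stay
#' close to the base with a small LG-frequency contrast between them.
#'
#' @return Contrast data frame suitable for [make_group_models()].
#' @export
default_contrasts <- function() {
  data.frame(
    group  = c("BALB/c", "BALB/c", "BALB/c", "BALB/c", "BALB/c",
               "CxB6"),
    matrix = c("A",      "A",      "A",      "B",      "pi",
               "A"),
    row    = c("ABN",    "GRO",    "LG",     "LG",     "SLP",
               "LG"),
    col    = c("BLN",    "BLN",    "ABN",    "G",      "",
               "ABN"),
    delta  = c(0.03,     0.10,     -0.04,    0.20,     0.04,
               -0.02),
    stringsAsFactors = FALSE)
}

#' Default ground-truth specification for the four-group study
#' @return A `ground_truth_spec` combining [base_ground_truth()] with
#'   [default_contrasts()].
#' @export
default_ground_truth_spec <- function() {
  make_group_models(base_ground_truth(), default_contrasts(),
                    groups = c("C57BL/6", "BALB/c", "B6xC", "CxB6"))
}

#' Simulate a full synthetic study
#'
#' Draws, for every subject, `days x hours_per_day` independent hour-long
#' sequences from the subject's group model. Each subject has its own RNG
#' stream derived from the design's master seed, so the dataset is
#' reproducible and stable under subject-level parallel generation. The
#' hidden state paths are retained as an evaluation oracle.
#'
#' @param spec A `ground_truth_spec` covering the design's groups.
#' @param design A `study_design`.
#' @return Object of class `sim_study`: list with `seqset` (a `seq_set`),
#'   `paths` (list of hidden-state vectors aligned to `seqset$obs`),
#'   `spec`, `design`.
#' @export
simulate_study <- function(spec = default_ground_truth_spec(),
                           design = study_design()) {
  stopifnot(inherits(spec, "ground_truth_spec"),
            inherits(design, "study_design"))
  groups <- names(design$groups)
  if (!all(groups %in% names(spec$models)))
    stop("spec lacks models for: ",
         paste(setdiff(groups, names(spec$models)), collapse = ", "))
  eth <- default_ethogram()
  n_subj <- sum(design$groups)
  set.seed(design$seed)
  subj_seeds <- sample.int(.Machine$integer.max - 1L, n_subj)

  meta <- list(); obs <- list(); paths <- list()
  s_idx <- 0L
  for (g in groups) {
    model <- spec$models[[g]]
    for (i in seq_len(design$groups[[g]])) {
      s_idx <- s_idx + 1L
      sid <- sprintf("%s_%02d", g, i)
      set.seed(subj_seeds[s_idx])
      for (d in design$days) for (h in seq_len(design$hours_per_day)) {
        draw <- sample_sequence(model, design$minutes_per_hour)
        meta[[length(meta) + 1L]] <- data.frame(
          subject_id = sid, group = g, day = d,
          hour_block = paste0("H", h), stringsAsFactors = FALSE)
        obs[[length(obs) + 1L]] <- draw$obs
        paths[[length(paths) + 1L]] <- draw$path
      }
    }
  }
  seqset <- seq_set(do.call(rbind, meta), obs, eth)
  structure(list(seqset = seqset, paths = paths, spec = spec,
                 design = design),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("synthetic study\n")
  print(x$design)
  print(x$seqset)
  invisible(x)
}

#' Structured initial model for Baum-Welch
#'
#' A deterministic (or mildly jittered) initializer standing in for
#' expert-chosen starting matrices: each state's emission row puts half its
#' mass on the state's namesake behavior and spreads the rest uniformly,
#' transitions are mildly sticky (0.6 self), and the initial distribution
#' is uniform. With `noise > 0`, uniform jitter of that relative magnitude
#' is mixed into every row (reproducible under `set.seed()`).
#'
#' @param ethogram The `ethogram` defining the symbol alphabet.
#' @param noise Jitter magnitude in \[0, 1); 0 gives a deterministic model.
#' @param anchors Named character vector mapping state names to their
#'   namesake behavior codes.
#' @return An `hmm_params`.
#' @export
structured_init <- function(ethogram = default_ethogram(), noise = 0,
                            anchors = c(BLN = "N", ABN = "A", LG = "P",
                                        GRO = "V", EAT = "E", ACT = "S",
                                        SLP = "X")) {
  stopifnot(noise >= 0, noise < 1)
  M <- n_symbols(ethogram)
  N <- length(anchors)
  sn <- names(anchors)
  B <- matrix(0.5 / (M - 1), N, M, dimnames = list(sn, ethogram$code))
  for (s in seq_len(N))
    B[s, code_to_index(anchors[[s]], ethogram)] <- 0.5
  A <- matrix(0.4 / (N - 1), N, N, dimnames = list(sn, sn))
  diag(A) <- 0.6
  pi <- rep(1 / N, N)
  if (noise > 0) {
    jit <- function(x) {
      x <- x * (1 - noise) + noise * stats::runif(length(x)) / length(x) * 2
      x / sum(x)
    }
    A <- t(apply(A, 1, jit))
    B <- t(apply(B, 1, jit))
    pi <- jit(pi)
    dimnames(B) <- list(sn, ethogram$code)
    dimnames(A) <- list(sn, sn)
  }
  hmm_params(A, B, pi, state_names = sn, tol = 1e-8)
}

#' Stationary distribution of a transition matrix
#'
#' Left eigenvector of A for eigenvalue 1, normalized to sum to 1.
#'
#' @param A Row-stochastic matrix.
#' @return Numeric stationary probability vector.
#' @export
stationary_distribution <- function(A) {
  e <- eigen(t(A))
  k <- which.min(abs(e$values - 1))
  v <- Re(e$vectors[, k])
  v <- v / sum(v)
  setNames(v, rownames(A))
}
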