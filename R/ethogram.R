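#' The default 21-behavior maternal ethogram
#'
#' Builds the catalogue of discrete behaviors scored once a minute during
#' maternal observation sessions, each with a stable single-symbol code and a
#' nest / out-of-nest context flag. Fourteen codes follow the conventional
#' single-letter scoring abbreviations (e.g. `A` = arched-back nursing,
#' `N` = blanket nursing, `P` = licking/grooming pups); the remaining seven
#' behaviors have no conventional letter and carry documented codes chosen
#' here: `K` carrying pup, `T` carrying tail, `C` climbing, `X` sleeping, and
#' `A+`, `N+`, `P+` for the nursing/grooming variants with more than half the
#' litter outside the nest.
#'
#' Behavior order (and therefore the integer coding of observation vectors)
#' is fixed: nest behaviors first, then out-of-nest behaviors, each in the
#' order listed below. The order never depends on locale or hashing.
#'
#' @return An object of class `ethogram`: a data frame with columns `code`,
#'   `label` and `context` (one of `"nest"`, `"out-of-nest"`), one row per
#'   behavior, with attribute `M` giving the symbol count (21).
#' @examples
#' eth <- default_ethogram()
#' nrow(eth)            # 21
#' subset(eth, code == "A")
#' @export
default_ethogram <- function() {
  nest <- rbind(
    c("A",  "arched-back nursing"),
    c("A+", "arched-back nursing (<half litter)"),
    c("N",  "blanket nursing"),
    c("N+", "blanket nursing (<half litter)"),
    c("P",  "licking/grooming pups"),
    c("P+", "licking/grooming pups (<half litter)"),
    c("B",  "nest building"),
    c("G",  "self-grooming in nest"),
    c("U",  "sniffing pups"),
    c("W",  "sniffing nest")
  )
  out <- rbind(
    c("K", "carrying pup"),
    c("T", "carrying tail"),
    c("C", "climbing"),
    c("Z", "digging"),
    c("D", "drinking"),
    c("E", "eating"),
    c("M", "moving pups"),
    c("R", "rearing"),
    c("V", "self-grooming out of nest"),
    c("S", "sniffing cage"),
    c("X", "sleeping")
  )
  eth <- data.frame(
    code = c(nest[, 1], out[, 1]),
    label = c(nest[, 2], out[, 2]),
    context = rep(c("nest", "out-of-nest"), c(nrow(nest), nrow(out))),
    stringsAsFactors = FALSE
  )
  ethogram(eth)
}

#' Construct an ethogram from a code table
#'
#' @param behaviors Data frame with columns `code`, `label`, `context`.
#' @return An `ethogram` object.
#' @export
ethogram <- function(behaviors) {
  stopifnot(is.data.frame(behaviors),
            all(c("code", "label", "context") %in% names(behaviors)))
  behaviors <- behaviors[, c("code", "label", "context")]
  if (anyDuplicated(behaviors$code))
    stop("ethogram codes must be unique")
  if (!all(behaviors$context %in% c("nest", "out-of-nest")))
    stop("context must be 'nest' or 'out-of-nest'")
  rownames(behaviors) <- NULL
  structure(behaviors, M = nrow(behaviors), class = c("ethogram", "data.frame"))
}

#' @export
print.ethogram <- function(x, ...) {
  cat("ethogram with", attr(x, "M"), "behaviors\n")
  print.data.frame(x, ...)
  invisible(x)
}

#' Number of symbols in an ethogram
#' @param ethogram An `ethogram` object.
#' @return Integer symbol count M.
#' @export
n_symbols <- function(ethogram) attr(ethogram, "M")

# map codes to 1-based indices; error names the offending codes
code_to_index <- function(codes, ethogram, where = NULL) {
  idx <- match(codes, ethogram$code)
  if (anyNA(idx)) {
    bad <- unique(codes[is.na(idx)])
    stop(sprintf("unknown behavior code%s %s%s",
                 if (length(bad) > 1) "s" else "",
                 paste(sQuote(bad), collapse = ", "),
                 if (is.null(where)) "" else paste0(" in ", where)))
  }
  idx
}

#' Bundle observation sequences with their ethogram
#'
#' A `seq_set` holds one hour-long observation sequence per row of `meta`
#' (columns `subject_id`, `group`, `day`, `hour_block`), with the coded
#' observations as 1-based indices into the shared ethogram.
#'
#' @param meta Data frame with columns `subject_id`, `group`, `day`,
#'   `hour_block`, one row per sequence.
#' @param obs List of integer vectors, one per row of `meta`; entries are
#'   indices into `ethogram`.
#' @param ethogram The shared `ethogram`.
#' @return An object of class `seq_set`.
#' @export
seq_set <- function(meta, obs, ethogram) {
  stopifnot(is.data.frame(meta), is.list(obs), nrow(meta) == length(obs))
  need <- c("subject_id", "group", "day", "hour_block")
  if (!all(need %in% names(meta)))
    stop("meta must have columns ", paste(need, collapse = ", "))
  M <- n_symbols(ethogram)
  obs <- lapply(obs, function(o) {
    o <- as.integer(o)
    if (length(o) < 1L || anyNA(o) || any(o < 1L) || any(o > M))
      stop("observations must be indices in 1..", M)
    o
  })
  grp_of <- tapply(as.character(meta$group), meta$subject_id,
                   function(g) length(unique(g)))
  if (any(grp_of > 1L))
    stop("each subject must belong to exactly one group")
  meta <- meta[, need]
  rownames(meta) <- NULL
  structure(list(meta = meta, obs = obs, ethogram = ethogram),
            class = "seq_set")
}

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d sequences, %d subjects, %d groups, %d total observations\n",
              length(x$obs), length(unique(x$meta$subject_id)),
              length(unique(x$meta$group)), n_obs(x)))
  invisible(x)
}

#' Total observation count of a sequence set
#' @param seqset A `seq_set`.
#' @return Integer: summed sequence lengths.
#' @export
n_obs <- function(seqset) sum(lengths(seqset$obs))

#' Subset a sequence set by group and/or postnatal day
#'
#' @param seqset A `seq_set`.
#' @param groups Optional character vector of groups to keep.
#' @param days Optional integer vector of days to keep (the default analysis
#'   window is postnatal days 1-7; later days are read but excluded from
#'   model training unless requested).
#' @return A `seq_set` with the selected sequences.
#' @export
filter_sequences <- function(seqset, groups = NULL, days = NULL) {
  keep <- rep(TRUE, nrow(seqset$meta))
  if (!is.null(groups)) keep <- keep & seqset$meta$group %in% groups
  if (!is.null(days)) keep <- keep & seqset$meta$day %in% days
  if (!any(keep)) stop("no sequences left after filtering")
  seq_set(seqset$meta[keep, , drop = FALSE], seqset$obs[keep],
          seqset$ethogram)
}

#' Read minute-sampled observation sequences from CSV
#'
#' Expects a wide CSV: header `subject_id, group, day, hour_block,
#' minute_1, ..., minute_T`, one row per subject-hour, each minute cell a
#' behavior code from the ethogram. Row order is preserved.
#'
#' @param path CSV file path.
#' @param ethogram The `ethogram` the codes must belong to (default
#'   [default_ethogram()]).
#' @return A `seq_set`.
#' @export
read_sequences <- function(path, ethogram = default_ethogram()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        check.names = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty sequence file: ", path)
  need <- c("subject_id", "group", "day", "hour_block")
  if (!all(need %in% names(df)))
    stop("sequence file must have columns ", paste(need, collapse = ", "))
  mcols <- grep("^minute_", names(df), value = TRUE)
  if (length(mcols) == 0L) stop("no minute_* columns in ", path)
  mcols <- mcols[order(as.integer(sub("^minute_", "", mcols)))]
  codes <- as.matrix(df[, mcols, drop = FALSE])
  if (any(is.na(codes) | codes == ""))
    stop("ragged rows: every minute_* cell must hold a behavior code")
  obs <- lapply(seq_len(nrow(df)), function(r)
    code_to_index(codes[r, ], ethogram, where = paste0("row ", r)))
  meta <- data.frame(subject_id = df$subject_id, group = df$group,
                     day = as.integer(df$day), hour_block = df$hour_block,
                     stringsAsFactors = FALSE)
  seq_set(meta, obs, ethogram)
}

#' Write a sequence set to CSV
#'
#' Inverse of [read_sequences()]: one wide row per subject-hour. All
#' sequences must share one length.
#'
#' @param seqset A `seq_set`.
#' @param path Output CSV path.
#' @return Invisibly, `path`.
#' @export
write_sequences <- function(seqset, path) {
  T_len <- unique(lengths(seqset$obs))
  if (length(T_len) != 1L)
    stop("wide CSV export requires equal-length sequences")
  codes <- t(vapply(seqset$obs, function(o) seqset$ethogram$code[o],
                    character(T_len)))
  colnames(codes) <- paste0("minute_", seq_len(T_len))
  out <- cbind(seqset$meta, as.data.frame(codes, stringsAsFactors = FALSE))
  utils::write.csv(out, path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Write sequences with their decoded state labels
#'
#' Serializes the pairing of observed behavior codes and decoded HMM state
#' names in long form: one row per minute with columns `subject_id`, `group`,
#' `day`, `hour_block`, `minute`, `code`, `state`.
#'
#' @param path Output CSV path.
#' @param seqset A `seq_set`.
#' @param labels A list of integer state-label vectors aligned one-to-one
#'   with `seqset$obs` (as returned by [label_all()]).
#' @param state_names Character vector naming the states the label indices
#'   refer to.
#' @return Invisibly, `path`.
#' @export
write_labeled_sequences <- function(path, seqset, labels,
                                    state_names = default_state_names()) {
  if (length(labels) != length(seqset$obs))
    stop("labels must align one-to-one with sequences")
  ok <- mapply(function(l, o) length(l) == length(o), labels, seqset$obs)
  if (!all(ok))
    stop("label length mismatch at sequence ", which(!ok)[1])
  rows <- lapply(seq_along(labels), function(r) {
    T_len <- length(labels[[r]])
    data.frame(seqset$meta[r, , drop = FALSE],
               minute = seq_len(T_len),
               code = seqset$ethogram$code[seqset$obs[[r]]],
               state = state_names[labels[[r]]],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' Read back a labeled-sequence CSV
#'
#' @param path CSV written by [write_labeled_sequences()].
#' @param ethogram The `ethogram` for the behavior codes.
#' @param state_names State names used when writing.
#' @return List with the reconstructed `seq_set` and `labels` (list of
#'   integer vectors).
#' @export
read_labeled_sequences <- function(path, ethogram = default_ethogram(),
                                   state_names = default_state_names()) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
  if (nrow(df) == 0L) stop("empty labeled-sequence file: ", path)
  key <- interaction(df$subject_id, df$day, df$hour_block, drop = TRUE,
                     lex.order = TRUE)
  key <- factor(key, levels = unique(key))  # preserve file order
  parts <- split(df, key)
  meta <- do.call(rbind, lapply(parts, function(p)
    data.frame(subject_id = p$subject_id[1], group = p$group[1],
               day = as.integer(p$day[1]), hour_block = p$hour_block[1],
               stringsAsFactors = FALSE)))
  obs <- unname(lapply(parts, function(p)
    code_to_index(p$code[order(as.integer(p$minute))], ethogram)))
  labels <- lapply(parts, function(p) {
    s <- match(p$state[order(as.integer(p$minute))], state_names)
    if (anyNA(s)) stop("unknown state name in ", path)
    s
  })
  names(labels) <- NULL
  list(seqset = seq_set(meta, obs, ethogram), labels = labels)
}
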