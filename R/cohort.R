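#' Column dialect for counting-process trial files
#'
#' Maps the package's canonical episode fields to the column names used in a
#' delimited file. The defaults are the names used by the deposited asthma
#' prevention trial export (`id.w`, `trt.w`, `start.w`, `stop.w`, `st.w`,
#' `nn`, `fevent`).
#'
#' @param id,treatment,start,stop,status Required columns: subject identifier,
#'   arm indicator (0 = placebo, 1 = medication), interval start and stop in
#'   days since study entry, and event status at `stop` (1 = attack,
#'   0 = censored).
#' @param n_episodes,first_event Optional bookkeeping columns (number of rows
#'   per subject; first-event flag). Stored when present, always re-derived.
#' @return A named list of class `cohort_dialect`.
#' @export
cohort_dialect <- function(id = "id.w", treatment = "trt.w",
                           start = "start.w", stop = "stop.w",
                           status = "st.w", n_episodes = "nn",
                           first_event = "fevent") {
  structure(list(id = id, treatment = treatment, start = start,
                 stop = stop, status = status, n_episodes = n_episodes,
                 first_event = first_event),
            class = "cohort_dialect")
}

#' Read a recurrent-event cohort from a delimited counting-process file
#'
#' Each row is one episode of one subject: the half-open interval
#' `(start, stop]` during which the subject was at risk for the next attack,
#' with `status = 1` if the attack occurred at `stop` and 0 if the interval
#' ended by censoring. Rows are validated, grouped by subject and sorted by
#' `start`; the derived variables `gap = stop - start` and `event_order`
#' (1-based episode rank within subject, the sequence number of the awaited
#' attack) are added.
#'
#' @param source Path to a delimited text file (or a `data.frame` already in
#'   the dialect's column names).
#' @param dialect A [cohort_dialect()] mapping canonical fields to columns.
#' @param sep Field separator (default comma).
#' @param strict If `TRUE`, censored episodes that are not a subject's final
#'   episode (gaps in follow-up) are an error; the default accepts them with
#'   a warning.
#' @return A `cohort`: a `data.frame` with columns `id`, `treatment`,
#'   `start`, `stop`, `status`, `gap`, `event_order` (plus `nn`/`fevent`
#'   when present in the source).
#' @export
read_cohort <- function(source, dialect = cohort_dialect(), sep = ",",
                        strict = FALSE) {
  df <- if (is.data.frame(source)) source else
    utils::read.table(source, header = TRUE, sep = sep,
                      check.names = FALSE, stringsAsFactors = FALSE)
  required <- c("id", "treatment", "start", "stop", "status")
  for (f in required) {
    col <- dialect[[f]]
    if (!col %in% names(df))
      stop("column '", col, "' (", f, ") not found in input", call. = FALSE)
  }
  out <- data.frame(
    id = df[[dialect$id]],
    treatment = as.numeric(df[[dialect$treatment]]),
    start = as.numeric(df[[dialect$start]]),
    stop = as.numeric(df[[dialect$stop]]),
    status = as.numeric(df[[dialect$status]]),
    stringsAsFactors = FALSE
  )
  for (f in c("n_episodes", "first_event")) {
    col <- dialect[[f]]
    if (!is.null(col) && col %in% names(df))
      out[[c(n_episodes = "nn", first_event = "fevent")[[f]]]] <-
        as.numeric(df[[col]])
  }
  bad <- !stats::complete.cases(out[required])
  if (any(bad)) {
    warning(sum(bad), " row(s) with missing values dropped", call. = FALSE)
    out <- out[!bad, , drop = FALSE]
  }
  as_cohort(out, strict = strict)
}

#' Construct and validate a cohort from episode vectors
#'
#' @param id,treatment,start,stop,status Parallel episode vectors (see
#'   [read_cohort()] for their meaning).
#' @param strict Passed to [as_cohort()].
#' @return A validated `cohort`.
#' @export
cohort <- function(id, treatment, start, stop, status, strict = FALSE) {
  as_cohort(data.frame(id = id, treatment = treatment, start = start,
                       stop = stop, status = status,
                       stringsAsFactors = FALSE),
            strict = strict)
}

#' Validate a counting-process data frame and derive gap/event order
#'
#' @param df A `data.frame` with columns `id`, `treatment`, `start`, `stop`,
#'   `status` (canonical names).
#' @param strict Reject non-final censored episodes instead of warning.
#' @return A `cohort`.
#' @export
as_cohort <- function(df, strict = FALSE) {
  stopifnot(is.data.frame(df),
            all(c("id", "treatment", "start", "stop", "status") %in% names(df)))
  if (any(df$stop <= df$start)) {
    bad <- which(df$stop <= df$start)[1]
    stop("stop <= start at row ", bad, " (id ", df$id[bad], ")",
         call. = FALSE)
  }
  if (!all(df$status %in% c(0, 1)))
    stop("status must be 0 or 1", call. = FALSE)
  if (!all(df$treatment %in% c(0, 1)))
    stop("treatment must be 0 (placebo) or 1 (medication)", call. = FALSE)
  if (any(df$start < 0))
    stop("negative start time", call. = FALSE)
  df <- df[order(match(df$id, unique(df$id)), df$start), , drop = FALSE]
  rownames(df) <- NULL
  sp <- split(seq_len(nrow(df)), match(df$id, unique(df$id)))
  order_vec <- integer(nrow(df))
  for (idx in sp) {
    if (length(unique(df$treatment[idx])) != 1L)
      stop("treatment varies within subject ", df$id[idx[1]], call. = FALSE)
    if (length(idx) > 1L) {
      if (any(df$start[idx][-1] < df$stop[idx][-length(idx)] - 1e-9))
        stop("overlapping episodes for subject ", df$id[idx[1]],
             call. = FALSE)
      cens_nonfinal <- df$status[idx][-length(idx)] == 0
      if (any(cens_nonfinal)) {
        msg <- paste0("subject ", df$id[idx[1]],
                      " has a censored non-final episode (gap in follow-up)")
        if (strict) stop(msg, call. = FALSE) else warning(msg, call. = FALSE)
      }
    }
    order_vec[idx] <- seq_along(idx)
  }
  df$gap <- df$stop - df$start
  df$event_order <- order_vec
  class(df) <- c("cohort", "data.frame")
  df
}

#' Recompute the derived variables of a cohort
#'
#' Recomputes `gap = stop - start` and `event_order` (1-based rank of each
#' episode within its subject). Idempotent; applied automatically by
#' [read_cohort()] and [as_cohort()].
#'
#' @param x A `cohort`.
#' @return The cohort with `gap` and `event_order` refreshed.
#' @export
derive_gap_and_order <- function(x) {
  stopifnot(inherits(x, "cohort"))
  as_cohort(as.data.frame(x)[c("id", "treatment", "start", "stop", "status",
                               intersect(c("nn", "fevent"), names(x)))])
}

#' Restrict a cohort to each subject's first episode
#'
#' Keeps exactly the `event_order == 1` episode of every subject (time to
#' first attack; all later attacks discarded). The subject count is
#' unchanged.
#'
#' @param x A `cohort`.
#' @return A `cohort` with one episode per subject, all of order 1.
#' @export
first_event_subset <- function(x) {
  stopifnot(inherits(x, "cohort"))
  out <- x[x$event_order == 1L, , drop = FALSE]
  if (length(unique(out$id)) != length(unique(x$id)))
    stop("some subject lacks an order-1 episode", call. = FALSE)
  rownames(out) <- NULL
  class(out) <- c("cohort", "data.frame")
  out
}

#' Tabulate how many children reached each attack count
#'
#' For each attack order k, counts the subjects with at least k observed
#' attacks (episodes of order k ending in an event) — the reverse cumulative
#' distribution of per-subject attack counts — together with the percentage
#' of all subjects. The count column sums to the total number of attacks.
#'
#' @param x A `cohort`.
#' @return A `data.frame` with columns `order` (k), `n_children`
#'   (subjects with >= k attacks) and `percent` (100 * n_children /
#'   number of subjects), one row per k up to the maximum observed count.
#' @export
attack_count_table <- function(x) {
  stopifnot(inherits(x, "cohort"))
  n_subjects <- length(unique(x$id))
  counts <- tapply(x$status, x$id, sum)
  kmax <- max(counts)
  if (kmax == 0)
    return(data.frame(order = integer(0), n_children = integer(0),
                      percent = numeric(0)))
  k <- seq_len(kmax)
  n_ge_k <- vapply(k, function(kk) sum(counts >= kk), integer(1))
  data.frame(order = k, n_children = n_ge_k,
             percent = 100 * n_ge_k / n_subjects)
}

#' Per-cohort summary counts
#'
#' @param x A `cohort`.
#' @return A list: subjects, episodes, total attacks, mean attacks per
#'   subject, and arm sizes (medication / placebo).
#' @export
cohort_summary <- function(x) {
  stopifnot(inherits(x, "cohort"))
  arm <- tapply(x$treatment, x$id, function(v) v[1])
  list(n_subjects = length(unique(x$id)),
       n_episodes = nrow(x),
       n_events = sum(x$status),
       mean_events = sum(x$status) / length(unique(x$id)),
       n_medication = sum(arm == 1),
       n_placebo = sum(arm == 0))
}

#' Write a cohort back to delimited text
#'
#' Emits the dialect's columns plus the derived `gap` and `event_order`.
#'
#' @param x A `cohort`.
#' @param path Output file path.
#' @param dialect A [cohort_dialect()]; controls the emitted column names.
#' @param sep Field separator.
#' @return `path`, invisibly.
#' @export
write_cohort <- function(x, path, dialect = cohort_dialect(), sep = ",") {
  stopifnot(inherits(x, "cohort"))
  out <- data.frame(x$id, x$treatment, x$start, x$stop, x$status,
                    check.names = FALSE)
  names(out) <- unlist(dialect[c("id", "treatment", "start", "stop",
                                 "status")])
  if ("nn" %in% names(x)) out[[dialect$n_episodes]] <- x$nn
  if ("fevent" %in% names(x)) out[[dialect$first_event]] <- x$fevent
  out$gap <- x$gap
  out$event_order <- x$event_order
  utils::write.table(out, path, sep = sep, row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' @export
print.cohort <- function(x, ...) {
  s <- cohort_summary(x)
  cat(sprintf(
    "Recurrent-event cohort: %d subjects (%d medication / %d placebo), %d episodes, %d attacks (mean %.2f/subject)\n",
    s$n_subjects, s$n_medication, s$n_placebo, s$n_episodes, s$n_events,
    s$mean_events))
  print(utils::head(as.data.frame(x), 6))
  if (nrow(x) > 6) cat("... ", nrow(x) - 6, " more episodes\n", sep = "")
  invisible(x)
}
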