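#' Kaplan-Meier survival curves with Greenwood standard errors
#'
#' Product-limit estimation of the survivor function of a duration, overall
#' or per group. Events precede censorings at tied times (the usual
#' convention).
#'
#' @param time Positive durations.
#' @param status Event indicator (1 = event, 0 = censored).
#' @param group Optional group labels (e.g. treatment arm); one curve per
#'   group.
#' @return A `survival_curve`: `data.frame` with columns `group`, `time`,
#'   `n_risk`, `n_event`, `n_censor`, `surv` and `se` (Greenwood standard
#'   error of the survival estimate).
#' @export
km_estimate <- function(time, status, group = NULL) {
  stopifnot(length(time) > 0, length(time) == length(status),
            all(time > 0), all(status %in% c(0, 1)))
  df <- data.frame(time = time, status = status,
                   group = if (is.null(group)) "all" else as.character(group))
  sf <- survival::survfit(survival::Surv(time, status) ~ group, data = df,
                          conf.type = "none")
  grp <- if (is.null(sf$strata)) rep(unique(df$group), length(sf$time))
    else rep(sub("^group=", "", names(sf$strata)), sf$strata)
  out <- data.frame(group = grp, time = sf$time, n_risk = sf$n.risk,
                    n_event = sf$n.event, n_censor = sf$n.censor,
                    surv = sf$surv,
                    se = sf$surv * sf$std.err)
  rownames(out) <- NULL
  class(out) <- c("survival_curve", "data.frame")
  out
}

#' Kaplan-Meier curves on the gap timescale for the k-th attack
#'
#' The risk set is every subject possessing an episode of order k — i.e.
#' every subject who experienced at least k-1 attacks and was then followed
#' for attack k (whether it occurred or the subject was censored waiting for
#' it). Time is that episode's gap (days since the previous attack, or since
#' entry for k = 1) and the event is that episode's status. One curve per
#' treatment arm by default.
#'
#' @param x A `cohort`.
#' @param k Attack order (k = 1 uses the whole cohort).
#' @param by_arm Split curves by treatment arm (default) or pool.
#' @return A `survival_curve` (groups `"medication"` / `"placebo"`, or
#'   `"all"`).
#' @export
km_by_event_order <- function(x, k, by_arm = TRUE) {
  stopifnot(inherits(x, "cohort"), k >= 1)
  ep <- x[x$event_order == k, , drop = FALSE]
  if (nrow(ep) == 0)
    stop("no episode of order ", k, " in the cohort", call. = FALSE)
  grp <- if (by_arm) ifelse(ep$treatment == 1, "medication", "placebo")
    else NULL
  km_estimate(ep$gap, ep$status, grp)
}

#' Naive all-episode Kaplan-Meier curve
#'
#' Treats every episode of the cohort as an independent individual on the
#' gap timescale — a deliberately naive description that ignores the
#' repeated-measures structure. The result is flagged via the `naive`
#' attribute so reports can label it.
#'
#' @param x A `cohort`.
#' @param by_arm Split by treatment arm.
#' @return A `survival_curve` with `attr(, "naive") = TRUE`.
#' @export
km_all_episodes <- function(x, by_arm = TRUE) {
  stopifnot(inherits(x, "cohort"))
  grp <- if (by_arm) ifelse(x$treatment == 1, "medication", "placebo")
    else NULL
  out <- km_estimate(x$gap, x$status, grp)
  attr(out, "naive") <- TRUE
  out
}

#' @export
plot.survival_curve <- function(x, main = "Kaplan-Meier survival", ...) {
  groups <- unique(x$group)
  cols <- stats::setNames(
    grDevices::hcl.colors(max(2, length(groups)), "Dark 3")[
      seq_along(groups)], groups)
  graphics::plot(NA, xlim = c(0, max(x$time)), ylim = c(0, 1),
                 xlab = "time (days)", ylab = "survival probability",
                 main = main, ...)
  for (g in groups) {
    cx <- x[x$group == g, ]
    graphics::lines(stats::stepfun(cx$time, c(1, cx$surv)),
                    do.points = FALSE, col = cols[[g]])
  }
  graphics::legend("topright", legend = groups, col = cols, lty = 1,
                   bty = "n")
  invisible(x)
}
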