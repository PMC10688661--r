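#' Build a counting-process model frame from a cohort
#'
#' Three standard constructions for recurrent-event Cox models:
#' \describe{
#'   \item{`calendar`}{Andersen-Gill: `entry = start`, `exit = stop`, all
#'     episodes, common baseline on the calendar timescale.}
#'   \item{`gap`}{renewal timescale: `entry = 0`, `exit = gap`, all
#'     episodes.}
#'   \item{`first_event`}{time to first attack only: `entry = 0`,
#'     `exit = gap` on [first_event_subset()].}
#' }
#' The cluster id is the subject in all three.
#'
#' @param x A `cohort`.
#' @param timescale One of `"calendar"`, `"gap"`, `"first_event"`.
#' @param covariates Covariate columns to carry (default treatment only).
#' @return A `data.frame` with columns `entry`, `exit`, `status`, `cluster`
#'   and the covariates.
#' @export
cox_frame <- function(x, timescale = c("calendar", "gap", "first_event"),
                      covariates = "treatment") {
  stopifnot(inherits(x, "cohort"))
  timescale <- match.arg(timescale)
  if (timescale == "first_event") x <- first_event_subset(x)
  out <- data.frame(
    entry = if (timescale == "calendar") x$start else 0,
    exit = if (timescale == "calendar") x$stop else x$gap,
    status = x$status,
    cluster = x$id)
  for (v in covariates) out[[v]] <- x[[v]]
  out
}

#' Fit a Cox proportional-hazards model on a counting-process frame
#'
#' Maximizes the (optionally stratified) partial likelihood over the
#' `(entry, exit]` risk sets, with Efron (default) or Breslow handling of
#' tied event times. When the frame carries a `cluster` column and
#' `robust = TRUE`, the cluster-robust sandwich covariance is attached.
#' Covariates that are constant over the frame carry no information and are
#' dropped with an `NA` coefficient and a flag rather than an error, so that
#' sliding-landmark fits at degenerate landmarks degrade gracefully.
#'
#' @param frame A `data.frame` with columns `entry`, `exit`, `status`,
#'   optional `stratum`, `cluster`, `weight`, and covariate columns.
#' @param covariates Character vector of covariate columns; default: every
#'   column not among the reserved ones.
#' @param ties `"efron"` or `"breslow"`.
#' @param robust Attach a cluster-robust covariance (requires `cluster`).
#' @return An object of class `cox_fit`: coefficients (with `NA` for dropped
#'   terms), model and robust covariances and standard errors, log partial
#'   likelihood at 0 and at the maximum, convergence info (including a
#'   `divergent` flag for monotone-likelihood fits, whose capped estimates
#'   should not be interpreted), and the frame.
#' @export
fit_cox <- function(frame, covariates = NULL,
                    ties = c("efron", "breslow"), robust = FALSE) {
  ties <- match.arg(ties)
  reserved <- c("entry", "exit", "status", "stratum", "cluster", "weight",
                "id", "s")
  if (is.null(covariates))
    covariates <- setdiff(names(frame), reserved)
  stopifnot(length(covariates) >= 1,
            all(c("entry", "exit", "status") %in% names(frame)),
            all(frame$exit > frame$entry))
  if (sum(frame$status) < 1) stop("no events in frame", call. = FALSE)
  if (!is.null(frame$weight)) {
    frame <- frame[frame$weight > 0, , drop = FALSE]
  }
  keep <- covariates[vapply(covariates,
                            function(v) isTRUE(stats::var(frame[[v]]) > 0),
                            logical(1))]
  dropped <- setdiff(covariates, keep)
  if (length(keep) == 0)
    stop("all covariates are constant in this frame", call. = FALSE)
  rhs <- keep
  if (!is.null(frame$stratum)) rhs <- c(rhs, "strata(stratum)")
  fml <- stats::as.formula(
    paste("survival::Surv(entry, exit, status) ~", paste(rhs, collapse = "+")))
  args <- list(formula = fml, data = frame, ties = ties,
               control = survival::coxph.control(eps = 1e-11,
                                                 iter.max = 100),
               x = TRUE)
  if (!is.null(frame$weight)) args$weights <- frame$weight
  if (robust) {
    if (is.null(frame$cluster)) stop("robust = TRUE needs a cluster column",
                                     call. = FALSE)
    args$cluster <- frame$cluster
  }
  divergent <- FALSE
  cf <- withCallingHandlers(
    do.call(survival::coxph, args),
    warning = function(w) {
      # monotone likelihood: coxph warns and caps the estimate; keep the
      # warning visible but flag the fit
      if (grepl("beta may be infinite", conditionMessage(w)))
        divergent <<- TRUE
    })
  beta <- stats::setNames(rep(NA_real_, length(covariates)), covariates)
  se <- vse <- beta
  bhat <- stats::coef(cf)
  beta[names(bhat)] <- bhat
  # model-based covariance; with a cluster term coxph stores the robust one
  # in $var and the model one in $naive.var
  mvar <- if (robust) cf$naive.var else cf$var
  rvar <- if (robust) cf$var else NULL
  se[names(bhat)] <- sqrt(diag(as.matrix(mvar)))
  if (robust) vse[names(bhat)] <- sqrt(diag(as.matrix(rvar)))
  structure(list(
    coefficients = beta,
    var = mvar, robust_var = rvar,
    se = se, robust_se = if (robust) vse else NULL,
    loglik = cf$loglik, ties = ties,
    n = cf$n, nevent = cf$nevent,
    covariates = covariates, fitted_covariates = names(bhat),
    dropped = dropped,
    divergent = divergent,
    iter = cf$iter,
    frame = frame,
    coxph = cf), class = "cox_fit")
}

#' @export
print.cox_fit <- function(x, ...) {
  cat("Cox fit (", x$ties, " ties): ", x$n, " rows, ", x$nevent,
      " events\n", sep = "")
  print(fit_table(x))
  if (length(x$dropped))
    cat("dropped (constant):", paste(x$dropped, collapse = ", "), "\n")
  invisible(x)
}

#' Coefficient table in the layout used for reporting
#'
#' @param x A `cox_fit`.
#' @return A `data.frame` with columns `coef`, `exp(coef)`, `se(coef)`,
#'   `robust se` (if available), `z`, `p` — z uses the robust SE when one is
#'   attached, the model SE otherwise.
#' @export
fit_table <- function(x) {
  stopifnot(inherits(x, "cox_fit"))
  use_se <- if (!is.null(x$robust_se)) x$robust_se else x$se
  z <- x$coefficients / use_se
  out <- data.frame(
    coef = x$coefficients, `exp(coef)` = exp(x$coefficients),
    `se(coef)` = x$se, check.names = FALSE)
  if (!is.null(x$robust_se)) out$`robust se` <- x$robust_se
  out$z <- z
  out$p <- 2 * stats::pnorm(-abs(z))
  out
}

# Linear predictor of a cox_fit on a frame (dropped covariates contribute 0).
.linear_predictor <- function(fit, frame) {
  b <- fit$coefficients
  b[is.na(b)] <- 0
  as.vector(as.matrix(frame[fit$covariates]) %*% b)
}

#' Landmark-specific (Breslow) baseline hazard
#'
#' At each distinct event time t within each stratum, the baseline hazard
#' increment is (number of events at t) divided by the sum of
#' exp(X beta-hat) over the rows at risk at t (entry < t <= exit), with case
#' weights applied to both numerator and denominator. The Breslow form is
#' used for the baseline regardless of the tie method used for the
#' coefficients.
#'
#' @param fit A `cox_fit`.
#' @param frame Frame to compute the baseline on; defaults to the fitted
#'   frame.
#' @return A `baseline_hazard`: `data.frame` with columns `stratum`, `time`,
#'   `n_event`, `hazard` (increment) and `cumhaz` (running sum within
#'   stratum).
#' @export
breslow_baseline <- function(fit, frame = fit$frame) {
  stopifnot(inherits(fit, "cox_fit"))
  lp <- .linear_predictor(fit, frame)
  w <- if (!is.null(frame$weight)) frame$weight else rep(1, nrow(frame))
  strat <- if (!is.null(frame$stratum)) frame$stratum else
    rep("all", nrow(frame))
  res <- lapply(split(seq_len(nrow(frame)), strat), function(idx) {
    ev_times <- sort(unique(frame$exit[idx][frame$status[idx] == 1]))
    if (length(ev_times) == 0) return(NULL)
    haz <- vapply(ev_times, function(t) {
      at_risk <- idx[frame$entry[idx] < t & frame$exit[idx] >= t]
      if (length(at_risk) == 0)
        stop("empty risk set at event time ", t, call. = FALSE)
      d <- sum(w[idx][frame$exit[idx] == t & frame$status[idx] == 1])
      d / sum(w[at_risk] * exp(lp[at_risk]))
    }, numeric(1))
    nev <- vapply(ev_times, function(t)
      sum(frame$exit[idx] == t & frame$status[idx] == 1), numeric(1))
    data.frame(stratum = strat[idx[1]], time = ev_times, n_event = nev,
               hazard = haz, cumhaz = cumsum(haz))
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  class(out) <- c("baseline_hazard", "data.frame")
  out
}

#' Cluster-robust sandwich covariance of a Cox fit
#'
#' Computes I^-1 (sum_c g_c g_c') I^-1 where g_c is the score residual
#' summed within cluster c — equivalently the cross-product of
#' cluster-collapsed dfbeta residuals.
#'
#' @param fit A `cox_fit`.
#' @param cluster Cluster ids, one per frame row; defaults to the frame's
#'   `cluster` column.
#' @return The robust covariance matrix.
#' @export
robust_variance <- function(fit, cluster = fit$frame$cluster) {
  stopifnot(inherits(fit, "cox_fit"))
  if (is.null(cluster)) stop("no cluster ids available", call. = FALSE)
  if (length(unique(cluster)) < 2)
    stop("robust variance is degenerate with a single cluster",
         call. = FALSE)
  D <- stats::residuals(fit$coxph, type = "dfbeta",
                        collapse = cluster, weighted = TRUE)
  D <- as.matrix(D)
  V <- crossprod(D)
  dimnames(V) <- list(fit$fitted_covariates, fit$fitted_covariates)
  V
}

#' The recurrent-event model comparison suite
#'
#' Fits, on one cohort, the five standard treatment-effect models for this
#' trial design: Andersen-Gill Cox on calendar time, Cox on time to first
#' attack, shared gamma-frailty Cox on calendar time, Cox on gap time, and
#' shared gamma-frailty Cox on gap time.
#'
#' @param x A `cohort`.
#' @param ties Tie method for the plain Cox fits.
#' @return A `data.frame` with one row per model: `coef`, `exp(coef)`,
#'   `se(coef)`, `z`, `p` (blank for frailty rows, which add `theta`, the
#'   estimated frailty variance).
#' @export
model_comparison <- function(x, ties = "efron") {
  stopifnot(inherits(x, "cohort"))
  row_of <- function(fit) {
    b <- fit$coefficients[["treatment"]]
    s <- fit$se[["treatment"]]
    c(coef = b, `exp(coef)` = exp(b), `se(coef)` = s, z = b / s,
      p = 2 * stats::pnorm(-abs(b / s)))
  }
  frow <- function(ff) c(coef = ff$coefficients[["treatment"]],
                         `exp(coef)` = exp(ff$coefficients[["treatment"]]),
                         `se(coef)` = ff$se[["treatment"]],
                         z = NA, p = NA)
  m <- rbind(
    `Cox-calendar` = row_of(fit_cox(cox_frame(x, "calendar"), ties = ties)),
    `Cox-first event` = row_of(fit_cox(cox_frame(x, "first_event"),
                                       ties = ties)),
    `Cox frailty-calendar` = frow(ffc <- fit_gamma_frailty(
      cox_frame(x, "calendar"))),
    `Cox-gap` = row_of(fit_cox(cox_frame(x, "gap"), ties = ties)),
    `Cox frailty-gap` = frow(ffg <- fit_gamma_frailty(cox_frame(x, "gap"))))
  out <- as.data.frame(m)
  out$theta <- c(NA, NA, ffc$theta, NA, ffg$theta)
  out
}
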