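#' Grid of landmark prediction times
#'
#' @param from,to,by Landmark times in days; defaults 0 to 400 by 5 (81
#'   points).
#' @param window Prediction window w in days (horizon = s + w); default 120.
#' @param weights Non-negative weights psi(s), one per landmark point,
#'   controlling how landmarks are weighted when fitting supermodels;
#'   default 1 everywhere.
#' @return A `landmark_grid`: list with `s` (ascending landmark times),
#'   `window` and `weights`.
#' @export
landmark_grid <- function(from = 0, to = 400, by = 5, window = 120,
                          weights = NULL) {
  s <- seq(from, to, by = by)
  if (is.null(weights)) weights <- rep(1, length(s))
  stopifnot(!is.unsorted(s, strictly = TRUE), window > 0,
            length(weights) == length(s), all(weights >= 0))
  structure(list(s = s, window = window, weights = weights),
            class = "landmark_grid")
}

# First event time after s for one subject, walking contiguous episodes.
# Returns c(time, status) where status 1 means an event at `time`, 0 means
# follow-up ended (censored) at `time`.
.first_event_after <- function(starts, stops, statuses, s) {
  k <- which(starts <= s & s < stops)[1]
  repeat {
    if (statuses[k] == 1) return(c(stops[k], 1))
    if (k == length(stops) || starts[k + 1] > stops[k] + 1e-9)
      return(c(stops[k], 0))
    k <- k + 1
  }
}

#' Build the sliding landmark dataset at landmark time s
#'
#' Selects the subjects at risk at s (an episode with start <= s < stop),
#' truncates their follow-up at s, administratively censors it at the
#' horizon s + w, and freezes the covariates at s: the treatment arm and
#' `cnts`, the order of the attack awaited at s (equivalently one plus the
#' number of attacks already experienced). The default outcome is the time
#' to the first attack after s: `exit` is the first event time after s, the
#' horizon, or the end of follow-up, whichever comes first, with `status = 1`
#' only for an attack at `exit <= s + w`. An attack at exactly the horizon
#' counts as an event; reaching the horizon attack-free is administrative
#' censoring. An `"all_episodes"` outcome mode instead keeps every episode
#' overlapping `(s, s + w]` (covariates still frozen at s).
#'
#' @param x A `cohort`.
#' @param s Landmark time (days).
#' @param window Prediction window w (days).
#' @param outcome `"first_event"` (default) or `"all_episodes"`.
#' @param cnts One of `"order"` (the awaited attack's order, default) or
#'   `"previous"` (number of attacks already experienced = order - 1).
#' @param cnts_cap Cap applied to `cnts` to limit the leverage of extreme
#'   attack histories.
#' @return A `landmark_dataset`: `data.frame` with columns `id`, `entry`
#'   (= s), `exit`, `status`, `treatment`, `cnts`, `stratum` (= s),
#'   `cluster`; attributes `s`, `window`. Zero rows (nobody at risk) is a
#'   valid result, not an error.
#' @export
make_sliding_dataset <- function(x, s, window = 120,
                                 outcome = c("first_event", "all_episodes"),
                                 cnts = c("order", "previous"),
                                 cnts_cap = 20) {
  stopifnot(inherits(x, "cohort"), s >= 0, window > 0)
  outcome <- match.arg(outcome)
  cnts <- match.arg(cnts)
  horizon <- s + window
  active_idx <- which(x$start <= s & s < x$stop)
  sp <- split(seq_len(nrow(x)), match(x$id, unique(x$id)))
  sub_of <- match(x$id, unique(x$id))
  if (length(active_idx) > 0) {
    cn <- pmin(x$event_order[active_idx] - (cnts == "previous"), cnts_cap)
    if (outcome == "first_event") {
      fe <- vapply(active_idx, function(r) {
        idx <- sp[[sub_of[r]]]
        .first_event_after(x$start[idx], x$stop[idx], x$status[idx], s)
      }, numeric(2))
      out <- data.frame(
        id = x$id[active_idx], entry = s,
        exit = pmin(fe[1, ], horizon),
        status = ifelse(fe[1, ] <= horizon, fe[2, ], 0),
        treatment = x$treatment[active_idx], cnts = cn)
    } else {
      rows <- lapply(seq_along(active_idx), function(r) {
        idx <- sp[[sub_of[active_idx[r]]]]
        keep <- idx[x$stop[idx] > s & x$start[idx] < horizon]
        data.frame(
          id = x$id[keep], entry = pmax(x$start[keep], s),
          exit = pmin(x$stop[keep], horizon),
          status = ifelse(x$stop[keep] <= horizon, x$status[keep], 0),
          treatment = x$treatment[keep], cnts = cn[r])
      })
      out <- do.call(rbind, rows)
    }
  } else {
    out <- data.frame(id = character(0), entry = numeric(0),
                      exit = numeric(0), status = numeric(0),
                      treatment = numeric(0), cnts = numeric(0))
  }
  out$stratum <- rep(s, nrow(out))
  out$cluster <- out$id
  rownames(out) <- NULL
  structure(out, s = s, window = window, outcome = outcome,
            class = c("landmark_dataset", "data.frame"))
}

#' Fit the simple landmark Cox model at one landmark point
#'
#' A Cox model for the windowed outcome on the frozen covariates
#' (`treatment`, `cnts`), left-truncated at s. A covariate that is constant
#' in the landmark dataset (e.g. `cnts` at s = 0) is flagged and dropped
#' with an `NA` coefficient; a dataset with no events yields `NULL` (a
#' skipped point, recorded by [landmark_coefficient_path()]).
#'
#' @param dataset A `landmark_dataset`.
#' @param ties Tie method.
#' @param robust Attach cluster-robust covariance.
#' @return A `cox_fit`, or `NULL` when no events fall in the window.
#' @export
fit_simple_landmark <- function(dataset, ties = "efron", robust = FALSE) {
  stopifnot(inherits(dataset, "landmark_dataset"))
  if (nrow(dataset) == 0 || sum(dataset$status) == 0) return(NULL)
  fr <- as.data.frame(dataset)
  fr$stratum <- NULL
  fit <- fit_cox(fr, covariates = c("treatment", "cnts"), ties = ties,
                 robust = robust)
  fit$s <- attr(dataset, "s")
  fit$window <- attr(dataset, "window")
  fit
}

#' Per-landmark coefficient path
#'
#' Fits the simple landmark model at every grid point and collects the
#' coefficient estimates and standard errors of `treatment` and `cnts` as
#' functions of the landmark time (the dynamic treatment-effect and
#' attack-burden paths). Points with no events, or where a covariate is
#' constant, are recorded with a reason rather than raised.
#'
#' @param x A `cohort`.
#' @param grid A [landmark_grid()].
#' @param ... Passed to [make_sliding_dataset()].
#' @return A `coefficient_path`: `data.frame` with columns `s`, `term`,
#'   `coef`, `se`, `n`, `n_event`; attribute `skipped` lists grid points
#'   without a fit and why.
#' @export
landmark_coefficient_path <- function(x, grid = landmark_grid(), ...) {
  stopifnot(inherits(x, "cohort"), inherits(grid, "landmark_grid"))
  rows <- list()
  skipped <- list()
  for (s in grid$s) {
    ld <- make_sliding_dataset(x, s, grid$window, ...)
    if (nrow(ld) == 0) {
      skipped[[length(skipped) + 1]] <-
        data.frame(s = s, reason = "no subject at risk")
      next
    }
    fit <- fit_simple_landmark(ld)
    if (is.null(fit)) {
      skipped[[length(skipped) + 1]] <-
        data.frame(s = s, reason = "no event in window")
      next
    }
    rows[[length(rows) + 1]] <- data.frame(
      s = s, term = names(fit$coefficients),
      coef = unname(fit$coefficients), se = unname(fit$se),
      n = nrow(ld), n_event = sum(ld$status))
  }
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  attr(out, "skipped") <- if (length(skipped)) do.call(rbind, skipped) else
    data.frame(s = numeric(0), reason = character(0))
  attr(out, "grid") <- grid
  class(out) <- c("coefficient_path", "data.frame")
  out
}

#' @export
plot.coefficient_path <- function(x, ...) {
  terms <- unique(x$term)
  op <- graphics::par(mfrow = c(1, length(terms)))
  on.exit(graphics::par(op))
  for (tm in terms) {
    cx <- x[x$term == tm & !is.na(x$coef), ]
    graphics::plot(cx$s, cx$coef, type = "l",
                   xlab = "landmark time s (days)", ylab = "coefficient",
                   main = tm, ...)
    graphics::lines(cx$s, cx$coef + 1.96 * cx$se, lty = 2)
    graphics::lines(cx$s, cx$coef - 1.96 * cx$se, lty = 2)
    graphics::abline(h = 0, col = "grey")
  }
  invisible(x)
}

#' Stack sliding landmark datasets into the super prediction dataset
#'
#' Concatenates the landmark datasets of every grid point, labelling each
#' row with its landmark stratum s, its subject as cluster id, the
#' polynomial basis covariates `LM1 = s/scale`, `LM2 = (s/scale)^2`, and the
#' grid weight psi(s).
#'
#' @param x A `cohort`.
#' @param grid A [landmark_grid()].
#' @param scale Basis scale (the default 150 gives LM1 = s/150,
#'   LM2 = (s/150)^2).
#' @param ... Passed to [make_sliding_dataset()].
#' @return A `super_dataset`: `data.frame` with columns `id`, `entry`,
#'   `exit`, `status`, `treatment`, `cnts`, `stratum`, `cluster`, `LM1`,
#'   `LM2`, `weight`; attributes `grid` and `scale`.
#' @export
make_super_dataset <- function(x, grid = landmark_grid(), scale = 150, ...) {
  stopifnot(inherits(x, "cohort"), inherits(grid, "landmark_grid"))
  parts <- lapply(seq_along(grid$s), function(l) {
    ld <- make_sliding_dataset(x, grid$s[l], grid$window, ...)
    if (nrow(ld) == 0) return(NULL)
    ld <- as.data.frame(ld)
    ld$LM1 <- grid$s[l] / scale
    ld$LM2 <- (grid$s[l] / scale)^2
    ld$weight <- grid$weights[l]
    ld
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  structure(out, grid = grid, scale = scale,
            class = c("super_dataset", "data.frame"))
}

#' Supermodel 1: stratified landmark supermodel
#'
#' Maximizes the stacked pseudo partial likelihood: a Cox model on the super
#' prediction dataset with one baseline hazard stratum per landmark point s,
#' common coefficients for `treatment` and `cnts` across strata, row weights
#' psi(s), and a sandwich covariance clustered on subject (the same subject
#' appears in many overlapping landmark datasets).
#'
#' With `interactions = TRUE` each stratum gets its own coefficient pair
#' (treatment and cnts interacted with the stratum factor); the stacked
#' partial likelihood then separates and reproduces the independent
#' per-landmark fits exactly.
#'
#' @param super A `super_dataset`.
#' @param ties Tie method.
#' @param interactions Per-stratum coefficients instead of common ones.
#' @return A `supermodel_fit` wrapping the underlying `cox_fit`, with the
#'   basis specification and a [beta_lm()] reconstruction.
#' @export
fit_supermodel_stratified <- function(super, ties = "efron",
                                      interactions = FALSE) {
  stopifnot(inherits(super, "super_dataset"))
  fr <- as.data.frame(super)
  fr <- fr[fr$weight > 0, , drop = FALSE]
  ev <- tapply(fr$status, fr$stratum, sum)
  empty <- names(ev)[ev == 0]
  if (length(empty)) {
    message("dropping ", length(empty), " event-free strata: s = ",
            paste(empty, collapse = ", "))
    fr <- fr[!fr$stratum %in% as.numeric(empty), , drop = FALSE]
  }
  if (!interactions) {
    fit <- fit_cox(fr, covariates = c("treatment", "cnts"), ties = ties,
                   robust = TRUE)
  } else {
    fr$sf <- factor(fr$stratum)
    fml <- survival::Surv(entry, exit, status) ~ sf:treatment + sf:cnts +
      strata(sf)
    cf <- survival::coxph(fml, data = fr, ties = ties, weights = fr$weight,
                          cluster = fr$cluster,
                          control = survival::coxph.control(eps = 1e-11,
                                                            iter.max = 100))
    fit <- structure(list(coefficients = stats::coef(cf),
                          var = cf$naive.var, robust_var = cf$var,
                          se = sqrt(diag(as.matrix(cf$naive.var))),
                          robust_se = sqrt(diag(as.matrix(cf$var))),
                          loglik = cf$loglik, ties = ties, n = cf$n,
                          nevent = cf$nevent,
                          covariates = names(stats::coef(cf)),
                          fitted_covariates = names(stats::coef(cf)),
                          dropped = character(0), frame = fr, coxph = cf),
                     class = "cox_fit")
  }
  structure(list(fit = fit, model = "stratified",
                 interactions = interactions,
                 scale = attr(super, "scale"), grid = attr(super, "grid"),
                 basis = FALSE), class = "supermodel_fit")
}

#' Supermodel 2: unstratified landmark supermodel with landmark terms
#'
#' A single-baseline Cox model on the super prediction dataset with
#' covariates `treatment`, `cnts` and the landmark basis terms `LM1`, `LM2`
#' entering as main effects (standing in for the s-dependence of the
#' baseline hazard), clustered on subject. With
#' `treatment_interactions = TRUE` the treatment effect itself is expanded
#' on the basis, beta(s) = theta1 + theta2 LM1 + theta3 LM2.
#'
#' @param super A `super_dataset`.
#' @param ties Tie method.
#' @param treatment_interactions Expand the treatment coefficient on the
#'   landmark basis.
#' @return A `supermodel_fit`.
#' @export
fit_supermodel_unstratified <- function(super, ties = "efron",
                                        treatment_interactions = FALSE) {
  stopifnot(inherits(super, "super_dataset"))
  fr <- as.data.frame(super)
  fr <- fr[fr$weight > 0, , drop = FALSE]
  fr$stratum <- NULL
  for (v in c("LM1", "LM2"))
    if (stats::var(fr[[v]]) == 0)
      stop("landmark basis column ", v,
           " is constant on this grid (single landmark point?)",
           call. = FALSE)
  if (treatment_interactions) {
    fr$trt_LM1 <- fr$treatment * fr$LM1
    fr$trt_LM2 <- fr$treatment * fr$LM2
    covs <- c("treatment", "cnts", "LM1", "LM2", "trt_LM1", "trt_LM2")
  } else covs <- c("treatment", "cnts", "LM1", "LM2")
  fit <- fit_cox(fr, covariates = covs, ties = ties, robust = TRUE)
  structure(list(fit = fit, model = "unstratified",
                 interactions = treatment_interactions,
                 scale = attr(super, "scale"), grid = attr(super, "grid"),
                 basis = treatment_interactions), class = "supermodel_fit")
}

#' Landmark-dependent coefficient beta_LM(s) of a supermodel
#'
#' Reconstructs the treatment coefficient at landmark s from the fitted
#' basis expansion f(s) theta. For models without a treatment-basis
#' expansion the coefficient is constant in s.
#'
#' @param fit A `supermodel_fit`.
#' @param s Landmark time(s).
#' @param term Covariate (default `"treatment"`).
#' @return Numeric vector of coefficients, one per `s`.
#' @export
beta_lm <- function(fit, s, term = "treatment") {
  stopifnot(inherits(fit, "supermodel_fit"))
  b <- fit$fit$coefficients
  if (!fit$basis) return(rep(unname(b[[term]]), length(s)))
  f1 <- s / fit$scale
  unname(b[[term]] + b[["trt_LM1"]] * f1 + b[["trt_LM2"]] * f1^2)
}

#' @export
print.supermodel_fit <- function(x, ...) {
  cat("Landmark supermodel (", x$model, "), grid of ",
      length(x$grid$s), " landmark points, window ", x$grid$window,
      " days\n", sep = "")
  print(fit_table(x$fit))
  invisible(x)
}

#' Dynamic conditional event-free probability
#'
#' The probability of remaining attack-free through the horizon s + w given
#' at-risk status and covariates X at landmark s:
#' exp(-sum over event times t in (s, s + w] of h0(t | s) exp(X beta_LM(s))),
#' using the landmark-specific Breslow baseline increments.
#'
#' @param fit A `cox_fit` (simple landmark fit) or `supermodel_fit`.
#' @param baseline A [breslow_baseline()] for the fit; for stratified
#'   supermodels the stratum labelled `s` is used, otherwise the single
#'   stratum.
#' @param X Named covariate vector on the fit's covariate scale (e.g.
#'   `c(treatment = 1, cnts = 2)`); basis columns are filled in from `s`
#'   automatically for supermodels.
#' @param s Landmark time.
#' @param w Prediction window; `w = 0` returns 1.
#' @return A probability in [0, 1].
#' @export
predict_dynamic <- function(fit, baseline, X, s, w) {
  stopifnot(inherits(baseline, "baseline_hazard"), w >= 0)
  if (w == 0) return(1)
  if (inherits(fit, "supermodel_fit")) {
    scale <- fit$scale
    cfit <- fit$fit
    extra <- c(LM1 = s / scale, LM2 = (s / scale)^2)
    if (fit$basis)
      extra <- c(extra, trt_LM1 = unname(X[["treatment"]]) * s / scale,
                 trt_LM2 = unname(X[["treatment"]]) * (s / scale)^2)
    X <- c(X, extra[setdiff(names(extra), names(X))])
  } else cfit <- fit
  stopifnot(inherits(cfit, "cox_fit"))
  b <- cfit$coefficients
  b[is.na(b)] <- 0
  miss <- setdiff(cfit$covariates, names(X))
  if (length(miss))
    stop("covariate values missing for: ", paste(miss, collapse = ", "),
         call. = FALSE)
  lp <- sum(b[cfit$covariates] * X[cfit$covariates])
  strat <- unique(baseline$stratum)
  bl <- if (length(strat) > 1) baseline[baseline$stratum == s, ] else baseline
  inc <- bl$hazard[bl$time > s & bl$time <= s + w]
  exp(-sum(inc) * exp(lp))
}
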