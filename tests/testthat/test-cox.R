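# Four rows, two events, one binary covariate: the partial-likelihood score
# U(b) = (1 - 2e^b/(2e^b + 2)) + (0 - e^b/(e^b + 2)) can be solved
# independently by bisection.
test_that("the fitted coefficient solves the analytic score equation", {
  fr <- data.frame(entry = 0, exit = c(1, 2, 3, 4),
                   status = c(1, 1, 0, 0), x = c(1, 0, 1, 0))
  fit <- fit_cox(fr, covariates = "x")
  score <- function(b)
    (1 - 2 * exp(b) / (2 * exp(b) + 2)) + (0 - exp(b) / (exp(b) + 2))
  b_oracle <- stats::uniroot(score, c(-5, 5), tol = 1e-12)$root
  expect_equal(unname(fit$coefficients[["x"]]), b_oracle, tolerance = 1e-7)
  # partial likelihood at the maximum is never below its value at 0
  expect_gte(fit$loglik[2], fit$loglik[1])
})

test_that("constant covariates are flagged and dropped, not fatal", {
  fr <- data.frame(entry = 0, exit = c(1, 2, 3, 4),
                   status = c(1, 1, 0, 0), x = c(1, 0, 1, 0), z = 0)
  fit <- fit_cox(fr, covariates = c("x", "z"))
  expect_true("z" %in% fit$dropped)
  expect_true(is.na(fit$coefficients[["z"]]))
  expect_false(is.na(fit$coefficients[["x"]]))
  expect_error(fit_cox(data.frame(entry = 0, exit = 1:2, status = c(1, 0),
                                  z = 1), covariates = "z"),
               "constant")
})

test_that("Breslow and Efron agree without ties; strata and time shifts behave", {
  fr <- random_frame(n = 30, seed = 2)
  fb <- fit_cox(fr, covariates = "x", ties = "breslow")
  fe <- fit_cox(fr, covariates = "x", ties = "efron")
  expect_equal(fb$coefficients, fe$coefficients, tolerance = 1e-9)

  fr1 <- fr; fr1$stratum <- "only"
  fs <- fit_cox(fr1, covariates = "x")
  expect_equal(fs$coefficients, fe$coefficients, tolerance = 1e-9)

  fr2 <- fr; fr2$entry <- fr2$entry + 100; fr2$exit <- fr2$exit + 100
  fshift <- fit_cox(fr2, covariates = "x")
  expect_equal(fshift$coefficients, fe$coefficients, tolerance = 1e-9)
})

test_that("baseline hazard increments follow the risk-set reciprocal rule", {
  # symmetric design: beta-hat = 0 exactly, so each increment is d/n
  fr <- data.frame(entry = 0, exit = c(1, 3, 4, 2),
                   status = c(1, 1, 0, 0), x = c(1, 0, 1, 0))
  fit <- fit_cox(fr, covariates = "x", ties = "breslow")
  expect_equal(unname(fit$coefficients[["x"]]), 0, tolerance = 1e-8)
  bl <- breslow_baseline(fit)
  expect_equal(bl$time, c(1, 3))
  expect_equal(bl$hazard, c(1 / 4, 1 / 2), tolerance = 1e-8)
  expect_equal(bl$cumhaz, cumsum(bl$hazard))

  # two strata are computed independently
  fr2 <- rbind(cbind(fr, stratum = "a"),
               cbind(random_frame(10, seed = 5)[
                 c("entry", "exit", "status", "x")], stratum = "b"))
  fit2 <- fit_cox(fr2, covariates = "x", ties = "breslow")
  bl2 <- breslow_baseline(fit2)
  fit_b <- fit_cox(fr2[fr2$stratum == "b", ], covariates = "x")
  fit_b$coefficients <- fit2$coefficients  # same beta, stratum-b rows only
  bl_b <- breslow_baseline(fit_b, fr2[fr2$stratum == "b", ])
  expect_equal(bl2$hazard[bl2$stratum == "b"], bl_b$hazard,
               tolerance = 1e-10)
})

test_that("cumulative baseline hazard matches a naive O(n^2) oracle", {
  fr <- random_frame(n = 25, seed = 9)
  fr$entry <- round(stats::runif(25, 0, 2), 2)  # staggered entry
  fr <- fr[fr$exit > fr$entry, ]
  fit <- fit_cox(fr, covariates = "x", ties = "breslow")
  bl <- breslow_baseline(fit)
  b <- fit$coefficients[["x"]]
  ev <- sort(fr$exit[fr$status == 1])
  oracle <- 0
  for (t in ev) {
    denom <- 0
    for (j in seq_len(nrow(fr)))
      if (fr$entry[j] < t && fr$exit[j] >= t)
        denom <- denom + exp(fr$x[j] * b)
    oracle <- oracle + sum(fr$exit == t & fr$status == 1) / denom
  }
  expect_equal(max(bl$cumhaz), oracle, tolerance = 1e-10)
})

test_that("cluster-robust variance matches a hand-built sandwich", {
  # untied data, Breslow form, single covariate: build score residuals,
  # information and the sandwich from first principles
  fr <- random_frame(n = 15, seed = 3)
  fr$cluster <- rep(1:5, each = 3)
  fit <- fit_cox(fr, covariates = "x", ties = "breslow", robust = TRUE)
  b <- fit$coefficients[["x"]]
  ev <- sort(fr$exit[fr$status == 1])
  risk <- function(t) which(fr$entry < t & fr$exit >= t)
  xbar <- vapply(ev, function(t) {
    r <- risk(t); sum(fr$x[r] * exp(b * fr$x[r])) / sum(exp(b * fr$x[r]))
  }, numeric(1))
  h0 <- vapply(ev, function(t) {
    r <- risk(t); 1 / sum(exp(b * fr$x[r]))
  }, numeric(1))
  info <- sum(vapply(seq_along(ev), function(k) {
    r <- risk(ev[k])
    w <- exp(b * fr$x[r]) / sum(exp(b * fr$x[r]))
    sum(w * (fr$x[r] - xbar[k])^2)
  }, numeric(1)))
  sc <- vapply(seq_len(nrow(fr)), function(i) {
    out <- if (fr$status[i] == 1)
      fr$x[i] - xbar[which(ev == fr$exit[i])] else 0
    for (k in seq_along(ev))
      if (fr$entry[i] < ev[k] && fr$exit[i] >= ev[k])
        out <- out - exp(b * fr$x[i]) * (fr$x[i] - xbar[k]) * h0[k]
    out
  }, numeric(1))
  g <- tapply(sc, fr$cluster, sum)
  v_oracle <- sum(g^2) / info^2
  expect_equal(unname(robust_variance(fit)[1, 1]), unname(v_oracle),
               tolerance = 1e-8)
  expect_equal(unname(fit$robust_var[1, 1]), unname(v_oracle),
               tolerance = 1e-8)
  expect_error(robust_variance(fit, cluster = rep(1, nrow(fr))),
               "single cluster")
})

test_that("duplicating every row leaves beta and the robust SE unchanged", {
  fr <- random_frame(n = 20, seed = 12)
  fr$cluster <- rep(1:10, each = 2)
  f1 <- fit_cox(fr, covariates = "x", ties = "breslow", robust = TRUE)
  fr2 <- rbind(fr, fr)
  f2 <- fit_cox(fr2, covariates = "x", ties = "breslow", robust = TRUE)
  expect_equal(f2$coefficients, f1$coefficients, tolerance = 1e-8)
  expect_equal(f2$robust_se, f1$robust_se, tolerance = 1e-6)
  expect_equal(f2$se[["x"]], f1$se[["x"]] / sqrt(2), tolerance = 1e-6)
})

test_that("gap-time fits recover the simulated effect on renewal data", {
  co <- sim_fixture(n = 800, theta = 0, beta = -0.3,
                    process = "renewal_gap", seed = 31)
  fit <- fit_cox(cox_frame(co, "gap"))
  expect_lt(abs(fit$coefficients[["treatment"]] + 0.3),
            2 * fit$se[["treatment"]])
})

test_that("the model comparison table has the five standard rows", {
  co <- sim_fixture(n = 100, seed = 55)
  tab <- model_comparison(co)
  expect_equal(rownames(tab),
               c("Cox-calendar", "Cox-first event", "Cox frailty-calendar",
                 "Cox-gap", "Cox frailty-gap"))
  expect_true(all(is.finite(tab$coef)))
  expect_true(all(is.na(tab$z[c(3, 5)])))
  expect_equal(tab$`exp(coef)`, exp(tab$coef))
})
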