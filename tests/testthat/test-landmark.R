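test_that("sliding datasets truncate, censor and freeze covariates correctly", {
  co <- cohort(id = c(1, 1, 2, 3),
               treatment = c(0, 0, 1, 1),
               start = c(0, 100, 0, 0),
               stop = c(100, 540, 30, 170),
               status = c(1, 0, 0, 1))
  # event inside the window
  ld <- make_sliding_dataset(co, s = 50, window = 120)
  r1 <- ld[ld$id == 1, ]
  expect_equal(c(r1$entry, r1$exit, r1$status, r1$cnts), c(50, 100, 1, 1))
  # administrative censoring at the horizon s + w
  ld2 <- make_sliding_dataset(co, s = 150, window = 120)
  r2 <- ld2[ld2$id == 1, ]
  expect_equal(c(r2$entry, r2$exit, r2$status, r2$cnts), c(150, 270, 0, 2))
  # subject 2 was censored before s = 50: excluded from the risk set
  expect_false(2 %in% ld$id)
  # an attack at exactly the horizon counts as an event (subject 3 at 170)
  r3 <- ld[ld$id == 3, ]
  expect_equal(c(r3$exit, r3$status), c(170, 1))
  # every row's exit lies in (s, s + w] and its subject covers s
  expect_true(all(ld$exit > 50 & ld$exit <= 170))
  for (i in seq_len(nrow(ld))) {
    sub <- co[co$id == ld$id[i], ]
    expect_true(any(sub$start <= 50 & 50 < sub$stop))
  }
  # cnts switch: number of previous attacks instead of awaited order
  ldp <- make_sliding_dataset(co, s = 150, window = 120, cnts = "previous")
  expect_equal(ldp$cnts[ldp$id == 1], 1)
  # nobody at risk: empty dataset, not an error
  expect_equal(nrow(make_sliding_dataset(co, s = 539.5, window = 10)), 1)
  expect_equal(nrow(make_sliding_dataset(co, s = 1000, window = 10)), 0)
})

test_that("cnts is capped to bound the leverage of extreme histories", {
  heavy <- as_cohort(data.frame(
    id = 1, treatment = 1, start = 0:29, stop = c(1:29, 540),
    status = c(rep(1, 29), 0)))
  ld <- make_sliding_dataset(heavy, s = 28.5, window = 100, cnts_cap = 20)
  expect_equal(ld$cnts, 20)
})

test_that("landmarking at s = 0 over the full span equals the first-event Cox", {
  co <- sim_fixture(n = 150, seed = 41)
  ld <- make_sliding_dataset(co, s = 0, window = 600)
  fit <- fit_simple_landmark(ld)
  expect_true("cnts" %in% fit$dropped)  # everyone awaits attack 1 at s = 0
  plain <- fit_cox(cox_frame(co, "first_event"))
  expect_equal(fit$coefficients[["treatment"]],
               plain$coefficients[["treatment"]], tolerance = 1e-8)
})

test_that("the landmark grid and coefficient path have the expected shape", {
  expect_equal(length(landmark_grid()$s), 81)
  expect_equal(length(landmark_grid(0, 0, by = 5)$s), 1)
  co <- sim_fixture(n = 150, seed = 41)
  g <- landmark_grid(0, 100, by = 50)
  path <- landmark_coefficient_path(co, g)
  expect_s3_class(path, "coefficient_path")
  expect_setequal(unique(path$term), c("treatment", "cnts"))
  expect_true(all(path$s %in% g$s))
  expect_true(all(path$n_event[!is.na(path$coef)] > 0))
})

test_that("the super dataset stacks landmark datasets with basis covariates", {
  co <- sim_fixture(n = 60, seed = 47)
  g <- landmark_grid(from = 150, to = 300, by = 150)
  sd <- make_super_dataset(co, g)
  n1 <- nrow(make_sliding_dataset(co, 150, g$window))
  n2 <- nrow(make_sliding_dataset(co, 300, g$window))
  expect_equal(nrow(sd), n1 + n2)
  expect_equal(as.vector(table(sd$stratum)), c(n1, n2))
  expect_equal(unique(sd$LM1[sd$stratum == 150]), 1)
  expect_equal(unique(sd$LM2[sd$stratum == 150]), 1)
  expect_equal(unique(sd$LM1[sd$stratum == 300]), 2)
  expect_equal(unique(sd$LM2[sd$stratum == 300]), 4)
  # row count = sum of at-risk counts over the grid
  at_risk <- vapply(g$s, function(s) sum(co$start <= s & s < co$stop),
                    numeric(1))
  expect_equal(nrow(sd), sum(at_risk))
})

test_that("a single-landmark supermodel equals the simple landmark fit", {
  co <- sim_fixture(n = 150, seed = 41)
  g <- landmark_grid(from = 100, to = 100, by = 5)
  sm <- fit_supermodel_stratified(make_super_dataset(co, g))
  simple <- fit_simple_landmark(make_sliding_dataset(co, 100, g$window))
  expect_equal(sm$fit$coefficients, simple$coefficients, tolerance = 1e-8)
  expect_error(fit_supermodel_unstratified(make_super_dataset(co, g)),
               "LM1")
})

test_that("per-stratum interactions reproduce the independent per-landmark fits", {
  co <- sim_fixture(n = 200, seed = 42)
  g <- landmark_grid(from = 30, to = 210, by = 60)
  smi <- fit_supermodel_stratified(make_super_dataset(co, g),
                                   interactions = TRUE)
  for (s in g$s) {
    simple <- fit_simple_landmark(make_sliding_dataset(co, s, g$window))
    expect_equal(smi$fit$coefficients[[paste0("sf", s, ":treatment")]],
                 simple$coefficients[["treatment"]], tolerance = 1e-6)
    expect_equal(smi$fit$coefficients[[paste0("sf", s, ":cnts")]],
                 simple$coefficients[["cnts"]], tolerance = 1e-6)
  }
})

test_that("listing every landmark twice changes neither beta nor robust SE", {
  co <- sim_fixture(n = 120, seed = 53)
  g <- landmark_grid(from = 50, to = 150, by = 50)
  sd1 <- make_super_dataset(co, g)
  sd2 <- rbind(as.data.frame(sd1), as.data.frame(sd1))
  attr(sd2, "grid") <- g
  attr(sd2, "scale") <- 150
  class(sd2) <- class(sd1)
  # Breslow ties: duplication creates tied event times, under which the
  # Efron correction intentionally differs
  f1 <- fit_supermodel_stratified(sd1, ties = "breslow")
  f2 <- fit_supermodel_stratified(sd2, ties = "breslow")
  expect_equal(f2$fit$coefficients, f1$fit$coefficients, tolerance = 1e-7)
  expect_equal(f2$fit$robust_se, f1$fit$robust_se, tolerance = 1e-6)
  expect_lt(f2$fit$se[["treatment"]], f1$fit$se[["treatment"]])
})

test_that("zero-weight landmarks contribute nothing to the supermodel", {
  co <- sim_fixture(n = 120, seed = 53)
  g_full <- landmark_grid(from = 0, to = 200, by = 50,
                          weights = c(1, 0, 1, 0, 1))
  g_red <- landmark_grid(from = 0, to = 200, by = 100)
  f_full <- fit_supermodel_stratified(make_super_dataset(co, g_full))
  f_red <- fit_supermodel_stratified(make_super_dataset(co, g_red))
  expect_equal(f_full$fit$coefficients, f_red$fit$coefficients,
               tolerance = 1e-9)
})

test_that("supermodel 2 carries landmark terms and a basis-expanded variant", {
  co <- sim_fixture(n = 200, seed = 42)
  g <- landmark_grid(from = 0, to = 200, by = 25)
  sd <- make_super_dataset(co, g)
  sm2 <- fit_supermodel_unstratified(sd)
  expect_setequal(sm2$fit$fitted_covariates,
                  c("treatment", "cnts", "LM1", "LM2"))
  expect_equal(beta_lm(sm2, c(0, 100, 200)),
               rep(sm2$fit$coefficients[["treatment"]], 3))
  smx <- fit_supermodel_unstratified(sd, treatment_interactions = TRUE)
  b <- smx$fit$coefficients
  expect_equal(beta_lm(smx, 150),
               unname(b[["treatment"]] + b[["trt_LM1"]] + b[["trt_LM2"]]))
})

test_that("dynamic predictions equal a brute-force product integral", {
  for (seed in 1:20) {
    fr <- random_frame(n = 14, seed = seed)
    fr$entry <- round(stats::runif(14, 0, 1), 2)
    fr <- fr[fr$exit > fr$entry, ]
    if (sum(fr$status) == 0 || stats::var(fr$x) == 0) next
    fit <- fit_cox(fr, covariates = "x", ties = "breslow")
    bl <- breslow_baseline(fit)
    s <- 1; w <- 5; xv <- c(x = 1)
    p <- predict_dynamic(fit, bl, xv, s, w)
    # independent enumeration straight from the frame
    b <- fit$coefficients[["x"]]
    ev <- sort(unique(fr$exit[fr$status == 1]))
    ev <- ev[ev > s & ev <= s + w]
    ch <- 0
    for (t in ev) {
      denom <- sum(exp(b * fr$x[fr$entry < t & fr$exit >= t]))
      ch <- ch + sum(fr$exit == t & fr$status == 1) / denom
    }
    expect_equal(p, exp(-ch * exp(b)), tolerance = 1e-10)
    # monotone in the window, 1 at w = 0, always a probability
    expect_equal(predict_dynamic(fit, bl, xv, s, 0), 1)
    probs <- vapply(c(1, 3, 5, 8), function(wi)
      predict_dynamic(fit, bl, xv, s, wi), numeric(1))
    expect_true(all(diff(probs) <= 1e-12))
    expect_true(all(probs >= 0 & probs <= 1))
  }
})

test_that("supermodel predictions use the landmark-specific stratum baseline", {
  co <- sim_fixture(n = 150, seed = 41)
  g <- landmark_grid(from = 50, to = 150, by = 50)
  sd <- make_super_dataset(co, g)
  sm1 <- fit_supermodel_stratified(sd)
  bl <- breslow_baseline(sm1$fit)
  p_med <- predict_dynamic(sm1, bl, c(treatment = 1, cnts = 1), 100, 120)
  p_pla <- predict_dynamic(sm1, bl, c(treatment = 0, cnts = 1), 100, 120)
  expect_true(p_med > 0 && p_med < 1)
  # protective simulated effect: medication arm has higher event-free odds
  expect_gt(p_med, p_pla)
  expect_error(predict_dynamic(sm1, bl, c(treatment = 1), 100, 120),
               "cnts")
})
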