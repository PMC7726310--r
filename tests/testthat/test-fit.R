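# helper: intercept-only single-block designs assembled by hand
manual_design <- function(blkA, blkB) {
  structure(list(pairA = blkA, pairB = blkB, spec = model_spec("1"),
                 knots = list(), n_pairs = length(blkA$exit),
                 n_dropped_na = 0L), class = "msm_design")
}

blk_rates <- function(blk) {
  exposed <- blk$X[, "exposed"] == 1
  c(n = sum(blk$event[!exposed]) / sum((blk$exit - blk$entry)[!exposed]),
    e = sum(blk$event[exposed]) / sum((blk$exit - blk$entry)[exposed]))
}

test_that("exponential special case: fitted rates equal events / risk time", {
  h <- small_recovery()
  d <- build_design(h, model_spec("1"))
  fit <- fit_msm(d, fix_shape = 1)
  co <- coef(fit)
  rA <- blk_rates(d$pairA)
  rB <- blk_rates(d$pairB)
  expect_equal(exp(co[["A:(Intercept)"]]), rA[["n"]], tolerance = 1e-7)
  expect_equal(exp(co[["A:(Intercept)"]] + co[["A:exposed"]]), rA[["e"]],
               tolerance = 1e-7)
  expect_equal(exp(co[["B:(Intercept)"]]), rB[["n"]], tolerance = 1e-7)
  expect_equal(exp(co[["B:(Intercept)"]] + co[["B:exposed"]]), rB[["e"]],
               tolerance = 1e-7)
  expect_equal(co[["A:log_shape"]], 0)
  # single-record exponential algebra: one event at t = 2 from entry 0
  d1 <- manual_design(
    list(entry = 0, exit = 2, event = 1,
         X = cbind(`(Intercept)` = 1, exposed = 0), cluster = "c1",
         pair_id = "p1"),
    list(entry = 0, exit = 1, event = 1,
         X = cbind(`(Intercept)` = 1, exposed = 0), cluster = "c2",
         pair_id = "p2"))
  eta <- 0.3
  par <- c(0, eta, 0, 0, log(2), 0)   # gamma_A = 1, eta_A = 0.3; B arbitrary
  expect_equal(neg_log_likelihood(par, d1),
               -((eta - 2 * exp(eta)) + (log(2) - exp(log(2)))))
})

test_that("likelihood agrees with adaptive quadrature of the hazard", {
  h <- toy_histories()
  d <- build_design(h, model_spec("2a"))
  set.seed(8)
  for (rep in 1:4) {
    par <- c(runif(1, -0.3, 0.3), rnorm(ncol(d$pairA$X), 0, 0.2),
             runif(1, -0.3, 0.3), rnorm(ncol(d$pairB$X), 0, 0.2))
    # scale age columns' coefficients down to keep hazards sane
    oracle <- 0
    idx <- 0
    for (pr in c("pairA", "pairB")) {
      blk <- d[[pr]]
      lg <- par[idx + 1]
      beta <- par[idx + 1 + seq_len(ncol(blk$X))]
      g <- exp(lg)
      eta <- drop(blk$X %*% beta)
      for (i in seq_along(blk$exit)) {
        hfun <- function(t) g * t^(g - 1) * exp(eta[i])
        H <- integrate(hfun, blk$entry[i], blk$exit[i], rel.tol = 1e-10)$value
        oracle <- oracle + blk$event[i] * log(hfun(blk$exit[i])) - H
      }
      idx <- idx + 1 + ncol(blk$X)
    }
    expect_equal(neg_log_likelihood(par, d), -oracle, tolerance = 1e-6)
  }
})

test_that("delayed-entry records contribute H(exit) - H(entry)", {
  blk <- function(entry) list(entry = entry, exit = 3, event = 1,
                              X = cbind(`(Intercept)` = 1, exposed = 0),
                              cluster = "c", pair_id = "p")
  d0 <- manual_design(blk(0), blk(0))
  d1 <- manual_design(blk(1.2), blk(0))
  par <- c(log(1.7), -0.4, 0, log(1.7), -0.4, 0)
  g <- 1.7; eta <- -0.4
  diff_expected <- exp(eta) * 1.2^g     # the entry interval's hazard mass
  expect_equal(neg_log_likelihood(par, d1) - neg_log_likelihood(par, d0),
               -diff_expected, tolerance = 1e-10)
})

test_that("Weibull MLE agrees with survreg on a single-transition sample", {
  skip_if_not_installed("survival")
  set.seed(77)
  n <- 600
  t_ev <- inverse_transform_event_time(1.4, log(0.2), runif(n))
  cens <- rexp(n, 0.15)
  time <- pmin(t_ev, cens, 6)
  ev <- as.numeric(t_ev <= pmin(cens, 6))
  mk <- function(time, ev) list(entry = rep(0, length(time)), exit = time,
                                event = ev,
                                X = cbind(`(Intercept)` = rep(1, length(time))),
                                cluster = as.character(seq_along(time)),
                                pair_id = as.character(seq_along(time)))
  # pair B gets an independent nuisance sample
  t2 <- inverse_transform_event_time(1, log(0.3), runif(200))
  time2 <- pmin(t2, 4); ev2 <- as.numeric(t2 <= 4)
  fit <- fit_msm(manual_design(mk(time, ev), mk(time2, ev2)))
  sr <- survival::survreg(survival::Surv(time, ev) ~ 1, dist = "weibull")
  gamma_sr <- 1 / sr$scale
  b0_sr <- -coef(sr)[[1]] / sr$scale
  expect_equal(exp(coef(fit)[["A:log_shape"]]), gamma_sr, tolerance = 1e-4)
  expect_equal(coef(fit)[["A:(Intercept)"]], b0_sr, tolerance = 1e-4)
  sr2 <- survival::survreg(survival::Surv(time2, ev2) ~ 1, dist = "weibull")
  expect_equal(fit$logLik, as.numeric(logLik(sr) + logLik(sr2)),
               tolerance = 1e-6)
})

test_that("the optimum is unique across perturbed starts", {
  h <- small_recovery()
  h <- h[seq_len(600), ]
  d <- build_design(h, model_spec("1"))
  fit0 <- fit_msm(d)
  set.seed(99)
  for (i in 1:5) {
    init <- coef(fit0) + rnorm(length(coef(fit0)), 0, 0.7)
    fit1 <- fit_msm(d, init = init)
    expect_equal(fit1$logLik, fit0$logLik, tolerance = 1e-6)
    expect_equal(coef(fit1)[["A:exposed"]], coef(fit0)[["A:exposed"]],
                 tolerance = 1e-4)
  }
})

test_that("time rescaling changes only the intercepts, by c^-gamma", {
  h <- small_recovery()[seq_len(2000), ]
  cc <- 2.5
  hs <- h
  for (col in c("owner_event_time", "pet_event_time", "censor_time",
                "pet_death_time"))
    hs[[col]] <- hs[[col]] * cc
  f1 <- fit_msm(build_design(h, model_spec("1")))
  f2 <- fit_msm(build_design(hs, model_spec("1")))
  expect_equal(coef(f2)[["A:exposed"]], coef(f1)[["A:exposed"]], tolerance = 1e-5)
  expect_equal(coef(f2)[["B:exposed"]], coef(f1)[["B:exposed"]], tolerance = 1e-5)
  expect_equal(coef(f2)[["A:log_shape"]], coef(f1)[["A:log_shape"]], tolerance = 1e-4)
  gA <- exp(coef(f1)[["A:log_shape"]])
  expect_equal(exp(coef(f2)[["A:(Intercept)"]]),
               exp(coef(f1)[["A:(Intercept)"]]) * cc^(-gA), tolerance = 1e-3)
  expect_equal(f2$hazard_ratios$HR, f1$hazard_ratios$HR, tolerance = 1e-4)
})

test_that("Wald p < alpha exactly when the CI excludes 1", {
  h <- small_recovery()
  fit <- fit_msm(build_design(h, model_spec("1")))
  hr <- fit$hazard_ratios
  expect_true(any(hr$p < 0.05) && any(hr$p > 0.05))  # one signal, one null
  for (i in seq_len(nrow(hr)))
    expect_equal(hr$p[i] < 0.05, hr$lower[i] > 1 || hr$upper[i] < 1)
})

test_that("duplicating records within two-member clusters follows the sandwich algebra", {
  h <- small_recovery()[seq_len(1500), ]
  d <- build_design(h, model_spec("1"))
  fit1 <- fit_msm(d)
  v_hc <- cluster_robust_vcov(fit1, cluster_ids = seq_len(nrow(fit1$scores)))
  dup <- function(blk) list(entry = rep(blk$entry, 2), exit = rep(blk$exit, 2),
                            event = rep(blk$event, 2),
                            X = rbind(blk$X, blk$X),
                            cluster = rep(blk$cluster, 2),
                            pair_id = rep(blk$pair_id, 2))
  d2 <- d
  d2$pairA <- dup(d$pairA)
  d2$pairB <- dup(d$pairB)
  fit2 <- fit_msm(d2)
  expect_equal(coef(fit2), coef(fit1), tolerance = 1e-5)
  # each duplicated record pair as its own 2-member cluster: the sandwich
  # equals the singleton sandwich of the original fit ...
  nA <- length(d$pairA$exit); nB <- length(d$pairB$exit)
  twin <- c(seq_len(nA), seq_len(nA), nA + seq_len(nB), nA + seq_len(nB))
  v_twin <- cluster_robust_vcov(fit2, cluster_ids = twin)
  expect_equal(v_twin, v_hc, tolerance = 1e-3)
  # ... while treating the copies as independent singletons halves it
  v_single <- cluster_robust_vcov(fit2,
                                  cluster_ids = seq_len(nrow(fit2$scores)))
  expect_equal(v_single, v_hc / 2, tolerance = 1e-3)
})

test_that("cluster-robust SE agrees with a cluster bootstrap", {
  cfg <- demo_truth_config("dog_crude", n_households = 900, seed = 55)
  res <- run_pipeline(cfg, models = character(0), verbose = FALSE)
  d <- build_design(res$histories, model_spec("1"))
  fit <- fit_msm(d)
  se_sand <- fit$hazard_ratios$se[1]

  # resample households with replacement, refit, SD of theta_A
  recs <- list(A = d$pairA, B = d$pairB)
  clusters <- sort(unique(c(d$pairA$cluster, d$pairB$cluster)))
  idxA <- split(seq_along(d$pairA$cluster), d$pairA$cluster)
  idxB <- split(seq_along(d$pairB$cluster), d$pairB$cluster)
  set.seed(56)
  boot <- replicate(200, {
    cl <- sample(clusters, length(clusters), replace = TRUE)
    take <- function(blk, idx) {
      ii <- unlist(idx[cl], use.names = FALSE)
      list(entry = blk$entry[ii], exit = blk$exit[ii], event = blk$event[ii],
           X = blk$X[ii, , drop = FALSE], cluster = blk$cluster[ii],
           pair_id = blk$pair_id[ii])
    }
    db <- d
    db$pairA <- take(d$pairA, idxA)
    db$pairB <- take(d$pairB, idxB)
    fb <- fit_msm(db, init = coef(fit))
    coef(fb)[["A:exposed"]]
  })
  expect_equal(se_sand, sd(boot), tolerance = 0.2)
})

test_that("a transition pair without events fails informatively", {
  h <- toy_histories()
  h$pet_event_time <- NA
  d <- build_design(h, model_spec("1"))
  expect_error(fit_msm(d), "no events.*pairB")
})
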