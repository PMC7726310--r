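# Maximum-likelihood fitting of the constrained Weibull-Markov multistate
# model, with model-based and household-cluster robust (sandwich)
# covariances.
#
# Each transition pair p has hazard h(t) = gamma_p t^(gamma_p - 1) exp(eta)
# with eta = intercept + theta_p * exposed + x' beta_p, so the cumulative
# hazard over a delayed-entry interval (u, t] is exp(eta) (t^gamma -
# u^gamma). The Weibull shape is shared within a pair, which makes
# exp(theta_p) a single time-constant hazard ratio. Shapes enter as
# log(gamma) for unconstrained optimisation.

# parameter indexing for one pair block: c(log_shape, coef(X))
pair_par_names <- function(prefix, X) c(paste0(prefix, ":log_shape"),
                                        paste0(prefix, ":", colnames(X)))

# log-likelihood, gradient and per-record scores for one pair block
pair_loglik <- function(lg, beta, blk, want_scores = FALSE) {
  g <- exp(lg)
  eta <- drop(blk$X %*% beta)
  lt <- log(blk$exit)
  tg <- blk$exit^g
  ug <- ifelse(blk$entry > 0, blk$entry^g, 0)
  lu_ug <- ifelse(blk$entry > 0, blk$entry^g * log(blk$entry), 0)
  du <- tg - ug
  ee <- exp(eta)
  ev <- blk$event
  ll <- sum(ev * (lg + (g - 1) * lt + eta) - ee * du)
  resid <- ev - ee * du                       # d(ll)/d(eta) per record
  sc_lg <- ev * (1 + g * lt) - ee * g * (tg * lt - lu_ug)
  out <- list(
    ll = ll,
    grad = c(sum(sc_lg), drop(crossprod(blk$X, resid))))
  if (want_scores) out$scores <- cbind(sc_lg, blk$X * resid)
  out
}

split_par <- function(par, design) {
  pA <- ncol(design$pairA$X)
  pB <- ncol(design$pairB$X)
  stopifnot(length(par) == pA + pB + 2L)
  list(lgA = par[1L], betaA = par[1L + seq_len(pA)],
       lgB = par[pA + 2L], betaB = par[pA + 2L + seq_len(pB)])
}

#' Negative log-likelihood of the Weibull-Markov multistate model
#'
#' @param params parameter vector laid out as
#'   `c(A:log_shape, A:coefficients, B:log_shape, B:coefficients)` in the
#'   column order of the design matrices.
#' @param design an [build_design()] object.
#' @return scalar negative log-likelihood (may be non-finite at extreme
#'   parameter values; the optimiser wrapper penalises such points).
#' @export
neg_log_likelihood <- function(params, design) {
  p <- split_par(params, design)
  -(pair_loglik(p$lgA, p$betaA, design$pairA)$ll +
      pair_loglik(p$lgB, p$betaB, design$pairB)$ll)
}

neg_ll_grad <- function(params, design) {
  p <- split_par(params, design)
  -c(pair_loglik(p$lgA, p$betaA, design$pairA)$grad,
     pair_loglik(p$lgB, p$betaB, design$pairB)$grad)
}

msm_scores <- function(params, design) {
  p <- split_par(params, design)
  a <- pair_loglik(p$lgA, p$betaA, design$pairA, want_scores = TRUE)
  b <- pair_loglik(p$lgB, p$betaB, design$pairB, want_scores = TRUE)
  nA <- nrow(a$scores); nB <- nrow(b$scores)
  sc <- matrix(0, nA + nB, length(params))
  sc[seq_len(nA), seq_len(ncol(a$scores))] <- a$scores
  sc[nA + seq_len(nB), ncol(a$scores) + seq_len(ncol(b$scores))] <- b$scores
  list(scores = sc, cluster = c(design$pairA$cluster, design$pairB$cluster))
}

default_init <- function(design, fix_shape = NULL) {
  init_pair <- function(blk, lg0) {
    risk <- sum(blk$exit - blk$entry)
    b0 <- log(max(sum(blk$event), 0.5) / max(risk, 1e-8))
    c(lg0, b0, rep(0, ncol(blk$X) - 1L))
  }
  lg0 <- if (is.null(fix_shape)) c(0, 0) else log(rep_len(fix_shape, 2L))
  c(init_pair(design$pairA, lg0[1]), init_pair(design$pairB, lg0[2]))
}

#' Fit the Weibull-Markov multistate model by maximum likelihood
#'
#' Maximises the interval likelihood of the stacked risk records by
#' quasi-Newton (BFGS) with an analytic gradient, falling back on a small
#' set of deterministic alternative starts if the first run does not
#' converge. The model-based covariance comes from the observed
#' information; the household-cluster robust covariance is the sandwich
#' of [cluster_robust_vcov()] and is used for the reported confidence
#' intervals and Wald tests of the two hazard ratios
#' `HR_A = exp(theta_A)` (owner type 2 diabetes, pet-diabetic vs
#' pet-nondiabetic origin) and `HR_B = exp(theta_B)` (pet diabetes,
#' owner-diabetic vs owner-nondiabetic origin).
#'
#' @param design an [build_design()] object.
#' @param init optional start values (full parameter vector).
#' @param fix_shape optionally fix the Weibull shapes instead of estimating
#'   them: a scalar or length-2 vector (pair A, pair B); `fix_shape = 1`
#'   gives exponential (constant-intensity) transitions.
#' @param control passed to [stats::optim()] (defaults: BFGS, `maxit` 500,
#'   `reltol` 1e-12).
#' @return object of class `petmsm_fit`.
#' @export
fit_msm <- function(design, init = NULL, fix_shape = NULL, control = list()) {
  stopifnot(inherits(design, "msm_design"))
  for (pr in c("pairA", "pairB")) {
    if (sum(design[[pr]]$event) < 1)
      stopf("no events in transition %s: the pair's parameters are not estimable",
            pr)
  }
  pA <- ncol(design$pairA$X)
  par_names <- c(pair_par_names("A", design$pairA$X),
                 pair_par_names("B", design$pairB$X))
  npar <- length(par_names)
  free <- rep(TRUE, npar)
  full0 <- default_init(design, fix_shape)
  if (!is.null(fix_shape)) free[c(1L, pA + 2L)] <- FALSE
  if (is.null(init)) init <- full0
  stopifnot(length(init) == npar)

  expand <- function(fp) { full <- full0; full[free] <- fp; full }
  fn <- function(fp) {
    v <- neg_log_likelihood(expand(fp), design)
    if (!is.finite(v)) 1e12 else v
  }
  gr <- function(fp) {
    gv <- neg_ll_grad(expand(fp), design)[free]
    gv[!is.finite(gv)] <- 0
    gv
  }
  ctrl <- utils::modifyList(list(maxit = 500L, reltol = 1e-12), control)

  starts <- list(init[free])
  # deterministic fallback starts: shift intercepts / shapes
  shift <- function(d_lg, d_b0) {
    s <- init
    s[c(1L, pA + 2L)] <- s[c(1L, pA + 2L)] + d_lg
    s[c(2L, pA + 3L)] <- s[c(2L, pA + 3L)] + d_b0
    s[free]
  }
  starts <- c(starts, list(shift(0.5, -0.5), shift(-0.5, 0.5), shift(0, 1),
                           shift(0, -1)))
  best <- NULL
  tried <- 0L
  for (s in starts) {
    tried <- tried + 1L
    o <- tryCatch(optim(s, fn, gr, method = "BFGS", control = ctrl),
                  error = function(e) NULL)
    if (is.null(o)) next
    ok <- o$convergence == 0 && max(abs(gr(o$par))) < 1e-3 * max(1, abs(o$value))
    if (is.null(best) || o$value < best$value - 1e-9) best <- c(o, list(ok = ok))
    if (!is.null(best) && best$ok) break
  }
  if (is.null(best))
    stopf("optimisation failed from all starts")
  converged <- isTRUE(best$ok) || best$convergence == 0
  if (!converged)
    warnf("fit_msm did not report convergence (optim code %d after %d starts)",
          best$convergence, tried)

  par <- expand(best$par)
  names(par) <- par_names

  info <- optimHess(best$par, fn, gr)     # observed information (free params)
  vcov_model <- matrix(NA_real_, npar, npar,
                       dimnames = list(par_names, par_names))
  kap <- kappa(info, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stopf("observed information is numerically singular (condition number %.3g); check for separation or constant covariates", kap)
  vcov_model[free, free] <- solve(info)

  sc <- msm_scores(par, design)
  sc$scores <- sc$scores[, free, drop = FALSE]

  fit <- structure(list(
    coefficients = par,
    logLik = -best$value,
    vcov = vcov_model,
    free = free,
    information = info,
    scores = sc$scores,
    record_cluster = sc$cluster,
    convergence = list(converged = converged, optim_code = best$convergence,
                       starts_tried = tried,
                       max_gradient = max(abs(gr(best$par)))),
    n = c(pairs = design$n_pairs,
          records = length(design$pairA$exit) + length(design$pairB$exit),
          events_A = sum(design$pairA$event), events_B = sum(design$pairB$event),
          clusters = length(unique(sc$cluster))),
    knots = design$knots,
    spec = design$spec), class = "petmsm_fit")
  fit$vcov_cluster <- cluster_robust_vcov(fit)
  fit$hazard_ratios <- hazard_ratios(fit)
  fit
}

#' Household-cluster robust (sandwich) covariance
#'
#' Computes `A^-1 B A^-1` where `A` is the observed information and
#' `B = sum_c s_c s_c'` over the per-cluster sums `s_c` of the record-level
#' score contributions. With every record its own cluster this reduces to
#' the heteroscedasticity-robust sandwich.
#'
#' @param fit a [fit_msm()] object.
#' @param cluster_ids optional alternative clustering of the stacked
#'   records (defaults to the household ids carried by the design).
#' @return covariance matrix for the full parameter vector (rows/columns
#'   of fixed parameters are NA).
#' @export
cluster_robust_vcov <- function(fit, cluster_ids = NULL) {
  cl <- cluster_ids %||% fit$record_cluster
  if (length(cl) != nrow(fit$scores))
    stopf("cluster_ids must have one entry per stacked record (%d)",
          nrow(fit$scores))
  G <- rowsum(fit$scores, group = cl)
  B <- crossprod(as.matrix(G))
  kap <- kappa(fit$information, exact = TRUE)
  if (!is.finite(kap) || kap > 1e12)
    stopf("observed information is numerically singular (condition number %.3g)", kap)
  Ainv <- solve(fit$information)
  V <- Ainv %*% B %*% Ainv
  V <- (V + t(V)) / 2
  out <- matrix(NA_real_, length(fit$coefficients), length(fit$coefficients),
                dimnames = dimnames(fit$vcov))
  out[fit$free, fit$free] <- V
  out
}

#' Hazard ratios with cluster-robust confidence intervals
#'
#' @param fit a [fit_msm()] object.
#' @param vcov which covariance to use: `"cluster"` (default) or `"model"`.
#' @return data.frame with one row per transition pair: `theta`, `HR`,
#'   confidence limits, cluster-robust SE and Wald p-value.
#' @export
hazard_ratios <- function(fit, vcov = c("cluster", "model")) {
  vcov <- match.arg(vcov)
  V <- if (vcov == "cluster") fit$vcov_cluster %||% cluster_robust_vcov(fit)
       else fit$vcov
  alpha <- fit$spec$alpha %||% 0.05
  zq <- qnorm(1 - alpha / 2)
  idx <- match(c("A:exposed", "B:exposed"), names(fit$coefficients))
  theta <- fit$coefficients[idx]
  se <- sqrt(diag(V)[idx])
  z <- theta / se
  data.frame(pair = c("A (owner T2D)", "B (pet diabetes)"),
             theta = unname(theta), se = unname(se),
             HR = unname(exp(theta)),
             lower = unname(exp(theta - zq * se)),
             upper = unname(exp(theta + zq * se)),
             p = unname(2 * pnorm(-abs(z))),
             stringsAsFactors = FALSE)
}

#' @export
print.petmsm_fit <- function(x, digits = 3, ...) {
  cat(sprintf("Weibull-Markov multistate fit (model %s)\n", x$spec$label))
  cat(sprintf("  %d pairs, %d records, %d clusters; logLik %.2f; %s\n",
              x$n["pairs"], x$n["records"], x$n["clusters"], x$logLik,
              if (x$convergence$converged) "converged" else "NOT converged"))
  hr <- x$hazard_ratios
  for (i in seq_len(nrow(hr)))
    cat(sprintf("  %-18s HR %.*f (%.*f to %.*f), p = %.3g\n", hr$pair[i],
                digits, hr$HR[i], digits, hr$lower[i], digits, hr$upper[i],
                hr$p[i]))
  invisible(x)
}

#' @export
logLik.petmsm_fit <- function(object, ...) {
  structure(object$logLik, df = sum(object$free), class = "logLik")
}

#' @export
coef.petmsm_fit <- function(object, ...) object$coefficients

#' @export
vcov.petmsm_fit <- function(object, cluster = TRUE, ...)
  if (cluster) object$vcov_cluster else object$vcov
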