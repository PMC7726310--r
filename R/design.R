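# Expand pair histories into stacked at-risk interval records with
# per-transition-pair design matrices.

# build the covariate matrix for one pair's term set
build_term_matrix <- function(h, terms, knots) {
  if (!length(terms)) return(matrix(0, nrow(h), 0))
  cols <- list()
  for (tm in terms) {
    info <- MSM_TERMS[[tm]]
    if (is.null(info)) stopf("unknown model term '%s'", tm)
    if (!info$column %in% names(h))
      stopf("model term '%s' needs history column '%s', which is missing",
            tm, info$column)
    v <- h[[info$column]]
    if (info$type == "rcs") {
      B <- rcs_basis(v, knots = knots[[tm]])
      colnames(B) <- paste0(tm, c("", "'"))
      cols[[tm]] <- B
    } else if (info$type == "binary") {
      m <- matrix(as.numeric(v != info$ref), ncol = 1)
      colnames(m) <- paste0(tm, ":", info$alt)
      cols[[tm]] <- m
    } else if (info$type == "factor") {
      lev <- setdiff(sort(unique(v)), info$ref)
      m <- vapply(lev, function(l) as.numeric(v == l), numeric(nrow(h)))
      if (length(lev) == 1L) m <- matrix(m, ncol = 1)
      colnames(m) <- paste0(tm, ":", lev)
      cols[[tm]] <- m
    } else if (info$type == "log") {
      m <- matrix(log(v), ncol = 1)
      colnames(m) <- paste0("log_", info$column)
      cols[[tm]] <- m
    } else { # numeric
      m <- matrix(as.numeric(v), ncol = 1)
      colnames(m) <- tm
      cols[[tm]] <- m
    }
  }
  do.call(cbind, cols)
}

#' Build the stacked risk-interval design for the multistate model
#'
#' Expands each pair history into one record per transition the pair is at
#' risk for, under the clock-forward Markov time scale: a baseline-N pair
#' contributes competing records for the owner and pet transitions from 0
#' until its first event or censoring, and, after a first transition, a
#' delayed-entry record for the remaining transition; baseline-O and
#' baseline-D pairs enter their single outgoing transition at time 0.
#' Records carry the partner-state (`exposed`) indicator that defines the
#' hazard ratios, and covariate columns shared between the two transitions
#' of each pair (the equality constraints). Covariates absent from a pair's
#' set are zero-constrained by omission.
#'
#' Pairs with a missing value in any covariate used by the model are
#' dropped (complete-case); the count is recorded in the result.
#'
#' @param histories output of [build_histories()].
#' @param spec a [model_spec()].
#' @return object of class `msm_design`: per-pair record blocks (entry and
#'   exit times, event flags, design matrix, cluster ids), spline knots,
#'   and bookkeeping counts.
#' @export
build_design <- function(histories, spec = model_spec("1")) {
  stopifnot(inherits(spec, "model_spec"))
  h <- histories
  used_terms <- unique(c(spec$pairA, spec$pairB))
  used_cols <- vapply(used_terms, function(tm) MSM_TERMS[[tm]]$column, character(1))
  miss <- setdiff(used_cols, names(h))
  if (length(miss)) stopf("histories lack covariate column(s): %s",
                          paste(miss, collapse = ", "))
  n0 <- nrow(h)
  if (length(used_cols)) {
    cc <- rowSums(is.na(h[, used_cols, drop = FALSE])) == 0
    h <- h[cc, , drop = FALSE]
  }
  n_dropped <- n0 - nrow(h)

  # spline knots at the 10/50/90 centiles of the analysed pairs
  knots <- list()
  for (tm in used_terms)
    if (MSM_TERMS[[tm]]$type == "rcs")
      knots[[tm]] <- unname(quantile(h[[MSM_TERMS[[tm]]$column]],
                                     c(0.1, 0.5, 0.9), na.rm = TRUE))

  C <- h$censor_time
  to <- ifelse(is.na(h$owner_event_time), Inf, h$owner_event_time)
  tp <- ifelse(is.na(h$pet_event_time), Inf, h$pet_event_time)
  st <- h$baseline_state

  blocks <- function(terms) {
    covmat <- build_term_matrix(h, terms, knots)
    function(entry, exit, event, rows, exposed) {
      keep <- exit > entry
      if (any(event & !keep))
        stopf("event record with non-positive interval length")
      X <- cbind(`(Intercept)` = rep(1, length(entry)),
                 exposed = rep_len(as.numeric(exposed), length(entry)),
                 covmat[rows, , drop = FALSE])[keep, , drop = FALSE]
      list(entry = entry[keep], exit = exit[keep],
           event = as.numeric(event[keep]), X = X,
           cluster = h$cluster_id[rows][keep],
           pair_id = h$pair_id[rows][keep])
    }
  }

  isN <- st == "N"; isO <- st == "O"; isD <- st == "D"
  exit1 <- pmin(to, tp, C)

  ## pair A: owner incidence (origin N unexposed, origin D exposed)
  mkA <- blocks(spec$pairA)
  rN <- which(isN)
  a1 <- mkA(entry = rep(0, length(rN)), exit = exit1[rN],
            event = is.finite(to[rN]) & to[rN] == exit1[rN],
            rows = rN, exposed = FALSE)
  rD0 <- which(isD)
  rDn <- which(isN & is.finite(tp) & tp < to)   # entered D during follow-up
  a2 <- mkA(entry = c(rep(0, length(rD0)), tp[rDn]),
            exit = pmin(to, C)[c(rD0, rDn)],
            event = is.finite(to[c(rD0, rDn)]),
            rows = c(rD0, rDn), exposed = TRUE)

  ## pair B: pet incidence (origin N unexposed, origin O exposed)
  mkB <- blocks(spec$pairB)
  b1 <- mkB(entry = rep(0, length(rN)), exit = exit1[rN],
            event = is.finite(tp[rN]) & tp[rN] == exit1[rN],
            rows = rN, exposed = FALSE)
  rO0 <- which(isO)
  rOn <- which(isN & is.finite(to) & to < tp)   # entered O during follow-up
  b2 <- mkB(entry = c(rep(0, length(rO0)), to[rOn]),
            exit = pmin(tp, C)[c(rO0, rOn)],
            event = is.finite(tp[c(rO0, rOn)]),
            rows = c(rO0, rOn), exposed = TRUE)

  cat_block <- function(x, y) list(
    entry = c(x$entry, y$entry), exit = c(x$exit, y$exit),
    event = c(x$event, y$event), X = rbind(x$X, y$X),
    cluster = c(x$cluster, y$cluster), pair_id = c(x$pair_id, y$pair_id))

  structure(list(pairA = cat_block(a1, a2), pairB = cat_block(b1, b2),
                 spec = spec, knots = knots,
                 n_pairs = nrow(h), n_dropped_na = n_dropped),
            class = "msm_design")
}

#' @export
print.msm_design <- function(x, ...) {
  cat(sprintf("msm_design (model %s): %d pairs (%d dropped incomplete)\n",
              x$spec$label, x$n_pairs, x$n_dropped_na))
  cat(sprintf("  pair A: %d records, %d events, %d columns\n",
              length(x$pairA$exit), sum(x$pairA$event), ncol(x$pairA$X)))
  cat(sprintf("  pair B: %d records, %d events, %d columns\n",
              length(x$pairB$exit), sum(x$pairB$event), ncol(x$pairB$X)))
  invisible(x)
}
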