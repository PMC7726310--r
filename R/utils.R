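# Internal helpers shared across modules.

#' @importFrom data.table data.table as.data.table setDT setDF := .N .SD .I
#' @importFrom stats optim optimHess pnorm qnorm quantile rbinom rexp rnorm
#'   runif plogis qlogis integrate ks.test rlnorm
NULL

# silence R CMD check notes for data.table NSE column names
utils::globalVariables(c(
  "person_id", "pet_id", "household_id", "pair_id", "cluster_id",
  "subject_id", "event_date", "stream", "code", "diabetic", "diagnosis_date",
  "insurance_start", "insurance_end", "death_date", "emigration_date",
  "birth_date", "n_pets", "owner_dx", "pet_dx", "is_index_owner",
  "onset", "recorded", "exposure"
))

years_between <- function(from, to) {
  as.numeric(as.Date(to) - as.Date(from)) / DAYS_PER_YEAR
}

date_plus_years <- function(date, years) {
  as.Date(date) + floor(years * DAYS_PER_YEAR)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# evaluate expr with a private RNG stream; restores global .Random.seed
with_local_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = env) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  expr
}

# pmin/pmax that treat NA as +Inf (absent censoring dates)
pmin_na_inf <- function(...) {
  args <- lapply(list(...), function(x) ifelse(is.na(x), Inf, x))
  do.call(pmin, args)
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
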