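# Covariate ladders for the multistate model.
#
# Every covariate effect is shared ("equality constrained") between the two
# transitions of its pair: pair A (owner incidence: no-diabetes -> owner
# T2D and pet-diabetic -> both) and pair B (pet incidence: no-diabetes ->
# pet diabetes and owner-T2D -> both). A covariate absent from a pair's set
# has its effect fixed at zero for that pair. Model 2a zeroes the pet's age
# and sex in pair A and the owner's age and sex in pair B; model 2b zeroes
# only the cross sexes; models 3-7 add covariate blocks without zero
# constraints, model 7 being the fully adjusted model.

MODEL_LABELS <- c("1", "2a", "2b", "3", "4", "5", "6", "7")

# term vocabulary -> columns in the history table; "rcs" terms expand to a
# restricted cubic spline basis with knots at the 10/50/90 centiles
MSM_TERMS <- list(
  owner_age = list(column = "owner_age", type = "rcs"),
  owner_sex = list(column = "owner_sex", type = "binary", ref = "female",
                   alt = "male"),
  pet_age = list(column = "pet_age", type = "rcs"),
  pet_sex = list(column = "pet_sex", type = "binary", ref = "female",
                 alt = "male"),
  breed_group = list(column = "breed_risk_group", type = "factor",
                     ref = "moderate"),
  country = list(column = "country_of_birth", type = "factor", ref = "Sweden"),
  log_density = list(column = "population_density", type = "log"),
  region = list(column = "region", type = "factor", ref = "Gotaland"),
  education = list(column = "education", type = "factor", ref = "secondary"),
  marital = list(column = "marital_status", type = "binary",
                 ref = "married/cohabiting", alt = "not"),
  income_decile = list(column = "income_decile", type = "numeric")
)

#' Covariate specification for one model of the adjustment ladder
#'
#' @param label one of `"1"`, `"2a"`, `"2b"`, `"3"`, `"4"`, `"5"`, `"6"`,
#'   `"7"`: the crude model, the two constrained age/sex models, the
#'   unconstrained age/sex model, and the sequential additions of breed
#'   group, country of birth, population density and region, and
#'   socioeconomic covariates (the fully adjusted model).
#' @param n_knots number of restricted-cubic-spline knots for the age terms.
#' @param alpha two-sided significance level used for Wald tests and
#'   confidence intervals.
#' @return object of class `model_spec`: the per-pair covariate term sets.
#' @export
model_spec <- function(label = "1", n_knots = 3L, alpha = 0.05) {
  label <- as.character(label)
  if (!label %in% MODEL_LABELS)
    stopf("unknown model label '%s' (use one of %s)", label,
          paste(MODEL_LABELS, collapse = ", "))
  base3 <- c("owner_age", "owner_sex", "pet_age", "pet_sex")
  lad <- list(
    "4" = "breed_group", "5" = "country",
    "6" = c("log_density", "region"),
    "7" = c("education", "marital", "income_decile"))
  sets <- switch(label,
    "1" = list(pairA = character(0), pairB = character(0)),
    "2a" = list(pairA = c("owner_age", "owner_sex"),
                pairB = c("pet_age", "pet_sex")),
    "2b" = list(pairA = c("owner_age", "pet_age", "owner_sex"),
                pairB = c("owner_age", "pet_age", "pet_sex")),
    { # models 3-7: cumulative ladder on top of unconstrained age/sex
      upto <- MODEL_LABELS[seq_len(match(label, MODEL_LABELS))]
      extra <- unlist(lad[intersect(names(lad), upto)], use.names = FALSE)
      list(pairA = c(base3, extra), pairB = c(base3, extra))
    })
  structure(list(label = label, pairA = sets$pairA, pairB = sets$pairB,
                 n_knots = as.integer(n_knots), alpha = alpha),
            class = "model_spec")
}

#' @export
print.model_spec <- function(x, ...) {
  cat(sprintf("model %s\n  pair A (owner incidence): %s\n  pair B (pet incidence): %s\n",
              x$label,
              if (length(x$pairA)) paste(x$pairA, collapse = ", ") else "(crude)",
              if (length(x$pairB)) paste(x$pairB, collapse = ", ") else "(crude)"))
  invisible(x)
}
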