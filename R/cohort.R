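# Owner-pet pair assembly: candidate pairs, exclusion cascade, baseline
# state classification, follow-up histories and crude incidence rates.

#' Build candidate owner-pet pairs from the ownership links
#'
#' One pair per (person, pet) link; spouses and cohabiting partners are
#' owners in their own right, so a two-person household with one pet
#' yields two pairs sharing the household as cluster.
#'
#' @param persons,pets,links registry tables (see [generate_cohort()]).
#' @return data.frame with `pair_id`, `person_id`, `pet_id`, `cluster_id`.
#' @export
build_pairs <- function(persons, pets, links) {
  dangling_p <- setdiff(links$person_id, persons$person_id)
  dangling_a <- setdiff(links$pet_id, pets$pet_id)
  if (length(dangling_p) || length(dangling_a))
    stopf("ownership links reference unknown ids: %s",
          paste(utils::head(c(dangling_p, dangling_a), 5), collapse = ", "))
  pairs <- data.frame(
    person_id = links$person_id,
    pet_id = links$pet_id,
    cluster_id = persons$household_id[match(links$person_id, persons$person_id)],
    stringsAsFactors = FALSE)
  pairs <- pairs[order(pairs$person_id, pairs$pet_id), , drop = FALSE]
  pairs <- cbind(pair_id = sprintf("PR%07d", seq_len(nrow(pairs))), pairs,
                 stringsAsFactors = FALSE)
  rownames(pairs) <- NULL
  pairs
}

#' Classify the combined baseline diabetes state of a pair
#'
#' @param owner_dx_date,pet_dx_date diagnosis dates (NA when never
#'   diagnosed), recycled to a common length.
#' @param fu_start first day of follow-up; diagnoses strictly before this
#'   date count as baseline.
#' @return character vector over `{"N","O","D","B"}`: no diabetes, owner
#'   type 2 diabetes only, pet diabetes only, both.
#' @export
classify_baseline <- function(owner_dx_date, pet_dx_date,
                              fu_start = as.Date("2007-01-01")) {
  fu_start <- as.Date(fu_start)
  o <- !is.na(owner_dx_date) & owner_dx_date < fu_start
  p <- !is.na(pet_dx_date) & pet_dx_date < fu_start
  ifelse(o & p, "B", ifelse(o, "O", ifelse(p, "D", "N")))
}

required_owner_covariates <- c("birth_date", "sex", "country_of_birth",
                               "region", "population_density", "education",
                               "marital_status", "disposable_income")

#' Apply the eligibility exclusion cascade
#'
#' Applies, in order: owners dead or emigrated before follow-up start;
#' incomplete baseline or follow-up data (any missing required owner
#' covariate); owners with more than 10 insured pets (presumed breeders);
#' invalid pet birth date or incomplete pet follow-up; pets without
#' diabetes whose insurance terminated before follow-up start; and pairs
#' in which both owner and pet were diagnosed before follow-up start. The
#' returned report telescopes exactly (each remaining count equals the
#' previous one minus the pairs removed).
#'
#' @param pairs candidate pairs from [build_pairs()].
#' @param persons,pets registry tables.
#' @param owner_status,pet_status phenotyping output ([phenotype_owners()],
#'   [phenotype_pets()]).
#' @param fu_start first day of follow-up.
#' @return list with `pairs` (eligible pairs) and `report` (data.frame
#'   `rule`, `removed`, `remaining`).
#' @export
apply_exclusions <- function(pairs, persons, pets, owner_status, pet_status,
                             fu_start = as.Date("2007-01-01")) {
  fu_start <- as.Date(fu_start)
  pi <- match(pairs$person_id, persons$person_id)
  ai <- match(pairs$pet_id, pets$pet_id)
  odx <- owner_status$diagnosis_date[match(pairs$person_id, owner_status$person_id)]
  pdx <- pet_status$diagnosis_date[match(pairs$pet_id, pet_status$pet_id)]

  report <- data.frame(rule = "candidate owner-pet pairs", removed = 0L,
                       remaining = nrow(pairs), stringsAsFactors = FALSE)
  drop_rule <- function(keep, label) {
    removed <- sum(!keep)
    pairs <<- pairs[keep, , drop = FALSE]
    pi <<- pi[keep]; ai <<- ai[keep]; odx <<- odx[keep]; pdx <<- pdx[keep]
    report <<- rbind(report, data.frame(rule = label, removed = removed,
                                        remaining = nrow(pairs),
                                        stringsAsFactors = FALSE))
  }

  dead <- !is.na(persons$death_date[pi]) & persons$death_date[pi] < fu_start
  gone <- !is.na(persons$emigration_date[pi]) & persons$emigration_date[pi] < fu_start
  drop_rule(!(dead | gone), "owner died or emigrated before follow-up start")

  cov <- persons[pi, required_owner_covariates, drop = FALSE]
  incomplete <- rowSums(is.na(cov)) > 0
  drop_rule(!incomplete, "incomplete baseline or follow-up data")

  n_per_owner <- table(pairs$person_id)
  breeder <- n_per_owner[pairs$person_id] > 10
  drop_rule(!as.vector(breeder), "owner with more than 10 insured pets")

  bad_pet <- is.na(pets$birth_date[ai]) | pets$birth_date[ai] > fu_start |
    is.na(pets$insurance_start[ai])
  drop_rule(!bad_pet, "invalid pet birth date or incomplete pet follow-up")

  pet_diab_bl <- !is.na(pdx) & pdx < fu_start
  terminated <- !is.na(pets$insurance_end[ai]) &
    pets$insurance_end[ai] < fu_start & !pet_diab_bl
  drop_rule(!terminated,
            "pet without diabetes with insurance terminated before follow-up start")

  both <- classify_baseline(odx, pdx, fu_start) == "B"
  drop_rule(!both, "owner and pet both diagnosed before follow-up start")

  rownames(pairs) <- NULL
  list(pairs = pairs, report = report)
}

#' Build per-pair follow-up histories
#'
#' Converts diagnosis and administrative dates into follow-up times in
#' years since the start of follow-up (days / 365.25). Each pair is
#' censored at the earliest of owner death, owner emigration, pet death
#' (only while the pet is free of diabetes), termination of pet insurance
#' (unless it merely reflects the death of an already diabetic pet) and
#' the administrative end of follow-up. Diagnoses after the censoring time
#' are dropped. Same-day owner and pet diagnoses are ordered owner-first
#' with the second transition given a half-day interval, and an event on
#' the first follow-up day is moved half a day in, so no at-risk interval
#' has zero length.
#'
#' @param pairs eligible pairs (from [apply_exclusions()]).
#' @param persons,pets registry tables.
#' @param owner_status,pet_status phenotyping output.
#' @param baseline_start,fu_start,fu_end calendar frame; diagnoses outside
#'   `[baseline_start, fu_end]` signal an assembly inconsistency and error.
#' @return data.frame of pair histories: identifiers and cluster, baseline
#'   state, event and censoring times (years), censoring reason, pet death
#'   time, and baseline-frozen covariates including the within-cohort
#'   income decile.
#' @export
build_histories <- function(pairs, persons, pets, owner_status, pet_status,
                            baseline_start = as.Date("2004-01-01"),
                            fu_start = as.Date("2007-01-01"),
                            fu_end = as.Date("2012-12-31")) {
  baseline_start <- as.Date(baseline_start)
  fu_start <- as.Date(fu_start)
  fu_end <- as.Date(fu_end)
  horizon <- years_between(fu_start, fu_end)
  pi <- match(pairs$person_id, persons$person_id)
  ai <- match(pairs$pet_id, pets$pet_id)
  odx <- owner_status$diagnosis_date[match(pairs$person_id, owner_status$person_id)]
  pdx <- pet_status$diagnosis_date[match(pairs$pet_id, pet_status$pet_id)]

  out_of_window <- function(d) !is.na(d) & (d < baseline_start | d > fu_end)
  if (any(out_of_window(odx)) || any(out_of_window(pdx)))
    stopf("diagnosis dates outside both the baseline and follow-up windows: phenotyping/assembly inconsistency")

  state <- classify_baseline(odx, pdx, fu_start)
  if (any(state == "B"))
    stopf("pairs in baseline state B must be excluded before building histories")

  ydate <- function(d) ifelse(is.na(d), NA_real_, years_between(fu_start, d))
  t_o <- ydate(odx); t_o[state %in% c("O")] <- NA  # baseline dx is not an event
  t_p <- ydate(pdx); t_p[state %in% c("D")] <- NA
  t_o[!is.na(t_o) & t_o < 0] <- NA  # defensive; states already encode baseline
  t_p[!is.na(t_p) & t_p < 0] <- NA

  death_o <- ydate(persons$death_date[pi])
  emig_o <- ydate(persons$emigration_date[pi])
  death_p <- ydate(pets$death_date[ai])
  ins_end <- ydate(pets$insurance_end[ai])

  pet_ever_diabetic <- !is.na(pdx)
  # pet death censors only while the pet is diabetes-free
  death_p_cens <- ifelse(pet_ever_diabetic, Inf, ifelse(is.na(death_p), Inf, death_p))
  # a death-driven insurance end of a diabetic pet does not censor
  death_driven <- !is.na(ins_end) & !is.na(death_p) & ins_end == death_p
  ins_cens <- ifelse(is.na(ins_end) | (pet_ever_diabetic & death_driven),
                     Inf, ins_end)
  comp <- cbind(`owner death` = ifelse(is.na(death_o), Inf, death_o),
                `pet death` = death_p_cens,
                emigration = ifelse(is.na(emig_o), Inf, emig_o),
                `insurance termination` = ins_cens,
                `admin end` = horizon)
  censor_time <- pmax(apply(comp, 1L, min), 0)
  censor_reason <- colnames(comp)[apply(comp, 1L, which.min)]

  # drop events after censoring; order same-day events owner-first
  t_o[!is.na(t_o) & t_o > censor_time] <- NA
  t_p[!is.na(t_p) & t_p > censor_time] <- NA
  t_o[!is.na(t_o) & t_o == 0] <- HALF_DAY
  t_p[!is.na(t_p) & t_p == 0] <- HALF_DAY
  tie <- !is.na(t_o) & !is.na(t_p) & t_o == t_p
  t_p[tie] <- t_p[tie] + HALF_DAY
  # a half-day shift applied to an event on the censoring day must not push
  # it outside observation: extend the pair's censoring time to cover it
  censor_time <- pmax(censor_time,
                      ifelse(is.na(t_o), -Inf, t_o),
                      ifelse(is.na(t_p), -Inf, t_p))

  owner_age <- years_between(persons$birth_date[pi], fu_start)
  pet_age <- years_between(pets$birth_date[ai], fu_start)

  # within-cohort income deciles on unique owners
  upers <- !duplicated(pairs$person_id)
  inc <- persons$disposable_income[pi]
  br <- unique(quantile(inc[upers], probs = seq(0, 1, 0.1), na.rm = TRUE,
                        names = FALSE))
  income_decile <- as.integer(cut(inc, breaks = br, include.lowest = TRUE,
                                  labels = FALSE))
  if (length(br) < 11L)  # degenerate income distribution: rescale bins
    income_decile <- as.integer(round(1 + (income_decile - 1) *
                                        9 / max(1L, length(br) - 2L)))

  hist <- data.frame(
    pair_id = pairs$pair_id,
    person_id = pairs$person_id,
    pet_id = pairs$pet_id,
    cluster_id = pairs$cluster_id,
    baseline_state = state,
    owner_event_time = t_o,
    pet_event_time = t_p,
    censor_time = censor_time,
    censor_reason = censor_reason,
    pet_death_time = death_p,
    owner_age = owner_age,
    owner_sex = persons$sex[pi],
    pet_age = pet_age,
    pet_sex = pets$sex[ai],
    breed_risk_group = pets$breed_risk_group[ai],
    country_of_birth = persons$country_of_birth[pi],
    region = persons$region[pi],
    population_density = persons$population_density[pi],
    education = persons$education[pi],
    marital_status = persons$marital_status[pi],
    income_decile = income_decile,
    stringsAsFactors = FALSE)
  rownames(hist) <- NULL
  hist
}

#' Dead-pet sensitivity filter
#'
#' Re-creates the sensitivity cohort: pairs whose pet died before the
#' start of follow-up are dropped regardless of the pet's diabetes status,
#' and follow-up time contributed after the death of a diabetic pet is
#' removed (the pair is censored at the pet's death).
#'
#' @param histories output of [build_histories()].
#' @return filtered and truncated histories.
#' @export
sensitivity_filter <- function(histories) {
  dead_before <- !is.na(histories$pet_death_time) & histories$pet_death_time < 0
  h <- histories[!dead_before, , drop = FALSE]
  trunc <- !is.na(h$pet_death_time) & h$pet_death_time < h$censor_time
  h$censor_reason[trunc] <- "pet death"
  h$censor_time[trunc] <- h$pet_death_time[trunc]
  h$owner_event_time[!is.na(h$owner_event_time) &
                       h$owner_event_time > h$censor_time] <- NA
  h$pet_event_time[!is.na(h$pet_event_time) &
                     h$pet_event_time > h$censor_time] <- NA
  rownames(h) <- NULL
  h
}

#' Crude incidence rates per 1000 subject-years
#'
#' Owner incidence counts first type 2 diabetes events among owners free of
#' diabetes at baseline, per 1000 person-years at risk, on deduplicated
#' persons (an owner contributing several pairs counts once, with risk time
#' the union of the pair intervals). Pet incidence is computed analogously
#' on deduplicated pets.
#'
#' @param histories output of [build_histories()].
#' @return data.frame with one row per subject type: `events`, `years` and
#'   `rate_per_1000` (NA with a message when no risk time accrued).
#' @export
incidence_rates <- function(histories) {
  one_side <- function(id, event_time, censor_time, keep) {
    dt <- data.table(id = id[keep],
                     ev = event_time[keep],
                     cens = censor_time[keep])
    if (nrow(dt) == 0L)
      return(c(events = 0, years = 0))
    agg <- dt[, .(event = any(!is.na(ev)),
                  risk = max(pmin(ifelse(is.na(ev), Inf, ev), cens))), by = id]
    c(events = sum(agg$event), years = sum(agg$risk))
  }
  o <- one_side(histories$person_id, histories$owner_event_time,
                histories$censor_time,
                histories$baseline_state %in% c("N", "D"))
  p <- one_side(histories$pet_id, histories$pet_event_time,
                histories$censor_time,
                histories$baseline_state %in% c("N", "O"))
  out <- data.frame(subject = c("owner", "pet"),
                    events = c(o["events"], p["events"]),
                    years = c(o["years"], p["years"]),
                    stringsAsFactors = FALSE)
  out$rate_per_1000 <- ifelse(out$years > 0, 1000 * out$events / out$years, NA)
  if (any(out$years == 0))
    message("no subject-years at risk for some subject type; rate undefined")
  rownames(out) <- NULL
  out
}
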