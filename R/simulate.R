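#' Invert a Weibull cumulative hazard at a uniform deviate
#'
#' Returns the event time `t` whose cumulative hazard
#' `H(t) = exp(log_rate) * t^shape` equals `-log(1 - u)`, i.e. the
#' inverse-transform draw from a Weibull intensity.
#'
#' @param shape positive Weibull shape.
#' @param log_rate log rate (log scale of the cumulative hazard).
#' @param u uniform(0,1) deviate(s), strictly inside the unit interval.
#' @return event time(s), same length as `u`.
#' @examples
#' inverse_transform_event_time(1, 0, 1 - exp(-1))  # unit exponential: 1
#' inverse_transform_event_time(2, 0, 1 - exp(-4))  # H(t) = t^2: 2
#' @export
inverse_transform_event_time <- function(shape, log_rate, u) {
  if (any(!is.finite(shape)) || any(shape <= 0))
    stopf("shape must be positive")
  if (any(!is.finite(u)) || any(u <= 0) || any(u >= 1))
    stopf("u must lie strictly inside (0, 1)")
  (-log1p(-u) * exp(-log_rate))^(1 / shape)
}

# truncated normal via inverse CDF (vectorised)
rtnorm <- function(n, mean, sd, lo, hi) {
  plo <- pnorm((lo - mean) / sd)
  phi <- pnorm((hi - mean) / sd)
  mean + sd * qnorm(runif(n, plo, phi))
}

sample_cat <- function(n, margins) {
  if (n == 0L) return(character(0))
  sample(names(margins), n, replace = TRUE, prob = margins)
}

#' Breed to diabetes-risk-group fixture mapping
#'
#' Deterministic mapping from breed label to a high / moderate / low
#' diabetes-risk group, following the breed groupings used in large Swedish
#' cohort studies of canine and feline diabetes incidence. Shipped as a
#' plain-text fixture under `extdata`.
#'
#' @param species "dog" or "cat".
#' @return data.frame with columns `breed`, `risk_group`.
#' @export
breed_risk_map <- function(species = c("dog", "cat")) {
  species <- match.arg(species)
  path <- system.file("extdata", paste0("breed_risk_", species, ".csv"),
                      package = "petmsm", mustWork = TRUE)
  utils::read.csv(path, stringsAsFactors = FALSE)
}

# solve onset time for one subject given Exp(1) target E and an exposure
# flip at time s: baseline hazard (g1, e1) before s, exposed hazard (g2, e2)
# after. s = Inf means never exposed, s = 0 exposed from entry.
solve_onset <- function(E, s, g1, e1, g2, e2) {
  H_s <- ifelse(is.finite(s), exp(e1) * pmax(s, 0)^g1, Inf)
  ifelse(E <= H_s,
         (E * exp(-e1))^(1 / g1),
         (pmax(s, 0)^g2 + (E - H_s) * exp(-e2))^(1 / g2))
}

empty_registry <- function() {
  persons <- data.frame(
    person_id = character(0), household_id = character(0),
    birth_date = as.Date(character(0)), sex = character(0),
    country_of_birth = character(0), region = character(0),
    population_density = numeric(0), education = character(0),
    marital_status = character(0), disposable_income = numeric(0),
    death_date = as.Date(character(0)), emigration_date = as.Date(character(0)),
    is_index_owner = logical(0), stringsAsFactors = FALSE)
  pets <- data.frame(
    pet_id = character(0), species = character(0),
    birth_date = as.Date(character(0)), sex = character(0),
    breed = character(0), breed_risk_group = character(0),
    death_date = as.Date(character(0)),
    insurance_start = as.Date(character(0)),
    insurance_end = as.Date(character(0)), stringsAsFactors = FALSE)
  links <- data.frame(person_id = character(0), pet_id = character(0),
                      stringsAsFactors = FALSE)
  ev <- data.frame(subject_id = character(0), stream = character(0),
                   code = character(0), event_date = as.Date(character(0)),
                   stringsAsFactors = FALSE)
  truth_owners <- data.frame(person_id = character(0), diabetic = logical(0),
                             diagnosis_date = as.Date(character(0)),
                             stringsAsFactors = FALSE)
  truth_pets <- data.frame(pet_id = character(0), diabetic = logical(0),
                           diagnosis_date = as.Date(character(0)),
                           stringsAsFactors = FALSE)
  list(persons = persons, pets = pets, links = links,
       diagnoses = ev, dispensations = ev, claims = ev,
       truth = list(owners = truth_owners, pets = truth_pets))
}

#' Generate a synthetic owner-pet registry with known ground truth
#'
#' Simulates the six registry extracts of a register-linkage study of
#' shared diabetes risk in owner-pet pairs: persons (index policyholders
#' born before 1961 plus spouses/cohabitants), insured pets, ownership
#' links, human diagnosis records (ICD-10), drug dispensations (ATC) and
#' veterinary claims (standardised EA codes). Diabetes onsets are drawn
#' from Weibull transition intensities whose hazard jumps by the
#' partner-state offset when the other member of a household pair is
#' diagnosed, so the generated data follow exactly the four-state
#' Weibull-Markov model fitted by [fit_msm()]. The four censoring
#' processes (owner death, emigration, pet death, insurance termination)
#' run as independent exponential clocks.
#'
#' Every diagnosed subject receives a first qualifying register record at
#' the diagnosis date (plus `detection_delay_days`), so phenotyping can
#' recover the planted truth exactly under the default zero delay.
#' Non-qualifying noise records (type 1 diabetes codes, insulin
#' dispensations, unrelated claims) are sprinkled to exercise the
#' phenotyping filters.
#'
#' @param config a [truth_config()].
#' @return a list with elements `persons`, `pets`, `links`, `diagnoses`,
#'   `dispensations`, `claims` (data.frames) and `truth` (the planted
#'   per-subject diabetes status used by recovery tests).
#' @export
generate_cohort <- function(config) {
  validate_truth_config(config)
  with_local_seed(config$seed, generate_cohort_impl(config))
}

generate_cohort_impl <- function(cfg) {
  if (cfg$n_households == 0L) return(empty_registry())
  n_h <- cfg$n_households
  horizon <- years_between(cfg$fu_start, cfg$fu_end)
  delay_y <- cfg$detection_delay_days / DAYS_PER_YEAR

  ## ---- households & persons -------------------------------------------
  hh_id <- sprintf("H%07d", seq_len(n_h))
  has_spouse <- runif(n_h) < cfg$spouse_prob
  idx_age <- rtnorm(n_h, cfg$owner_age_mean, cfg$owner_age_sd,
                    cfg$owner_age_min, cfg$owner_age_max)
  sp_age <- pmax(idx_age[has_spouse] + rnorm(sum(has_spouse), 0, cfg$spouse_age_sd),
                 cfg$spouse_age_min)
  n_sp <- sum(has_spouse)
  n_pers <- n_h + n_sp

  per <- data.table(
    person_id = sprintf("P%07d", seq_len(n_pers)),
    household_id = c(hh_id, hh_id[has_spouse]),
    hh_idx = c(seq_len(n_h), which(has_spouse)),
    age = c(idx_age, sp_age),
    is_index_owner = rep(c(TRUE, FALSE), c(n_h, n_sp))
  )
  idx_female <- runif(n_h) < cfg$p_owner_female
  sp_female <- ifelse(runif(n_sp) < 0.95, !idx_female[has_spouse],
                      idx_female[has_spouse])
  per$sex <- ifelse(c(idx_female, sp_female), "female", "male")
  per$birth_date <- date_plus_years(cfg$fu_start, -per$age)
  per$country_of_birth <- sample_cat(n_pers, cfg$country_margins)
  hh_region <- sample_cat(n_h, cfg$region_margins)
  hh_density <- rlnorm(n_h, cfg$density_meanlog, cfg$density_sdlog)
  per$region <- hh_region[per$hh_idx]
  per$population_density <- round(hh_density[per$hh_idx], 1)
  per$education <- sample_cat(n_pers, cfg$education_margins)
  hh_married <- has_spouse | (runif(n_h) < cfg$p_married_nospouse)
  per$marital_status <- ifelse(hh_married[per$hh_idx],
                               "married/cohabiting", "not")
  per$disposable_income <- round(rlnorm(n_pers, cfg$income_meanlog,
                                        cfg$income_sdlog), 1)
  per$education[runif(n_pers) < cfg$missing_cov_prob] <- NA_character_

  # censoring clocks, in years from baseline start (death, emigration)
  base_to_fu <- years_between(cfg$baseline_start, cfg$fu_start)
  death_y <- rexp(n_pers, cfg$rate_owner_death) - base_to_fu  # years from fu_start
  emig_y <- rexp(n_pers, cfg$rate_emigration) - base_to_fu

  ## ---- pets ------------------------------------------------------------
  extra <- sample(0:2, n_h, replace = TRUE,
                  prob = c(1 - sum(cfg$extra_pet_probs), cfg$extra_pet_probs))
  n_per_hh <- 1L + extra
  breeder <- runif(n_h) < cfg$breeder_prob
  n_per_hh[breeder] <- cfg$breeder_n_pets
  n_pets <- sum(n_per_hh)
  pet_hh <- rep(seq_len(n_h), n_per_hh)

  pet <- data.table(
    pet_id = sprintf("A%07d", seq_len(n_pets)),
    hh_idx = pet_hh,
    household_id = hh_id[pet_hh],
    species = cfg$species
  )
  pet$age <- pmin(pmax(rlnorm(n_pets, cfg$pet_age_meanlog, cfg$pet_age_sdlog),
                       cfg$pet_age_min), cfg$pet_age_max)
  pet$sex <- ifelse(runif(n_pets) < cfg$p_pet_female, "female", "male")
  bmap <- breed_risk_map(cfg$species)
  pet$breed_risk_group <- sample_cat(n_pets, cfg$breed_margins)
  pet$breed <- vapply(pet$breed_risk_group, function(g)
    sample(bmap$breed[bmap$risk_group == g], 1L), character(1))
  pet$birth_date <- date_plus_years(cfg$fu_start, -pet$age)
  pet$birth_date[runif(n_pets) < cfg$invalid_birth_prob] <- as.Date(NA)

  ins_start <- date_plus_years(cfg$fu_start, -runif(n_pets, 0.1, 7))
  born <- date_plus_years(cfg$fu_start, -pet$age) + 60  # real birth + 60d
  pet$insurance_start <- pmax(ins_start, born)

  term_baseline <- runif(n_pets) < cfg$p_term_baseline
  lo <- pmax(as.numeric(pet$insurance_start),
             as.numeric(cfg$baseline_start)) + 1
  hi <- as.numeric(cfg$baseline_end)
  term_date_bl <- as.Date(floor(runif(n_pets, pmin(lo, hi - 1), hi)),
                          origin = "1970-01-01")
  term_y <- ifelse(term_baseline,
                   years_between(cfg$fu_start, term_date_bl),
                   rexp(n_pets, cfg$rate_insurance_term))

  pdeath_baseline <- runif(n_pets) < cfg$p_pet_death_baseline
  pdeath_date_bl <- as.Date(floor(runif(n_pets, pmin(lo, hi - 1), hi)),
                            origin = "1970-01-01")
  pet_death_y <- ifelse(pdeath_baseline,
                        years_between(cfg$fu_start, pdeath_date_bl),
                        rexp(n_pets, cfg$rate_pet_death))

  ## ---- links: every person in a household owns all its pets ------------
  links <- merge(per[, c("person_id", "hh_idx")], pet[, c("pet_id", "hh_idx")],
                 by = "hh_idx", allow.cartesian = TRUE)
  setDT(links)

  ## ---- linear predictors ------------------------------------------------
  z_owner <- (per$age - cfg$age_center) / cfg$age_scale
  z_pet <- (pet$age - cfg$pet_age_center) / cfg$pet_age_scale
  z_owner_idx <- z_owner[match(pet$household_id,
                               per$household_id[per$is_index_owner])]

  bA <- cfg$beta_pairA
  eta1 <- cfg$log_rate_owner +
    (if ("owner_age" %in% names(bA)) bA[["owner_age"]] * z_owner else 0) +
    (if ("owner_male" %in% names(bA)) bA[["owner_male"]] * (per$sex == "male") else 0)
  eta4 <- eta1 + cfg$theta_A
  bB <- cfg$beta_pairB
  eta2 <- cfg$log_rate_pet +
    (if ("owner_age" %in% names(bB)) bB[["owner_age"]] * z_owner_idx else 0) +
    (if ("pet_age" %in% names(bB)) bB[["pet_age"]] * z_pet else 0) +
    (if ("pet_male" %in% names(bB)) bB[["pet_male"]] * (pet$sex == "male") else 0)
  eta3 <- eta2 + cfg$theta_B

  ## ---- baseline-period prevalence ---------------------------------------
  p_own <- plogis(qlogis(cfg$p_owner_baseline) + cfg$prev_age_coef * z_owner)
  own_bl <- runif(n_pers) < p_own
  own_bl_date <- as.Date(floor(runif(n_pers, as.numeric(cfg$baseline_start),
                                     as.numeric(cfg$baseline_end))),
                         origin = "1970-01-01")
  own_bl_ok <- own_bl &
    years_between(cfg$fu_start, own_bl_date) <= pmin(death_y, emig_y)

  p_petbl <- plogis(qlogis(cfg$p_pet_baseline) + cfg$pet_prev_age_coef * z_owner_idx)
  pet_bl <- runif(n_pets) < p_petbl
  pet_bl_date <- as.Date(floor(runif(n_pets,
                                     pmin(lo, hi - 1), hi)),
                         origin = "1970-01-01")
  pet_bl_ok <- pet_bl &
    years_between(cfg$fu_start, pet_bl_date) <= pmin(term_y, pet_death_y) &
    pet_bl_date >= pet$insurance_start

  ## ---- follow-up onset engine -------------------------------------------
  E_pers <- rexp(n_pers)
  E_pets <- rexp(n_pets)
  pers_limit <- pmin(death_y, emig_y, horizon)       # diagnosis validity
  pets_limit <- pmin(term_y, pet_death_y, horizon)

  pers_diag <- ifelse(own_bl_ok, 0, Inf)   # diagnosis times (0 = prevalent)
  pets_diag <- ifelse(pet_bl_ok, 0, Inf)
  g <- cfg$shape

  for (iter in seq_len(25L)) {
    # exposure-flip times: earliest partner diagnosis over household links
    s_per <- rep(Inf, n_pers)
    r_pet <- rep(Inf, n_pets)
    lk <- links[, .(person_id, pet_id)]
    pd <- pets_diag[match(lk$pet_id, pet$pet_id)]
    od <- pers_diag[match(lk$person_id, per$person_id)]
    agg_p <- lk[, .(s = min(pd[.I])), by = person_id]
    agg_q <- lk[, .(s = min(od[.I])), by = pet_id]
    s_per[match(agg_p$person_id, per$person_id)] <- agg_p$s
    r_pet[match(agg_q$pet_id, pet$pet_id)] <- agg_q$s

    t_per <- solve_onset(E_pers, s_per, g[1], eta1, g[4], eta4)
    t_pet <- solve_onset(E_pets, r_pet, g[2], eta2, g[3], eta3)
    new_pers <- ifelse(own_bl_ok, 0,
                       ifelse(t_per + delay_y <= pers_limit, t_per + delay_y, Inf))
    new_pets <- ifelse(pet_bl_ok, 0,
                       ifelse(t_pet + delay_y <= pets_limit, t_pet + delay_y, Inf))
    if (identical(new_pers, pers_diag) && identical(new_pets, pets_diag)) break
    pers_diag <- new_pers
    pets_diag <- new_pets
  }

  ## ---- dates & registry tables ------------------------------------------
  cap_date <- function(y) {
    d <- date_plus_years(cfg$fu_start, y)
    d[!is.finite(y) | d > cfg$fu_end] <- NA
    d
  }
  per$death_date <- cap_date(death_y)
  # emigration only meaningful while alive in Sweden
  emig_y2 <- ifelse(emig_y < death_y, emig_y, Inf)
  per$emigration_date <- cap_date(emig_y2)

  death_first <- pet_death_y <= term_y
  pet$death_date <- cap_date(ifelse(death_first, pet_death_y, Inf))
  pet$insurance_end <- cap_date(pmin(term_y, pet_death_y))

  own_dx_date <- as.Date(rep(NA_integer_, n_pers), origin = "1970-01-01")
  own_dx_date[own_bl_ok] <- own_bl_date[own_bl_ok]
  fu_own <- !own_bl_ok & is.finite(pers_diag)
  own_dx_date[fu_own] <- date_plus_years(cfg$fu_start, pers_diag[fu_own])

  pet_dx_date <- as.Date(rep(NA_integer_, n_pets), origin = "1970-01-01")
  pet_dx_date[pet_bl_ok] <- pet_bl_date[pet_bl_ok]
  fu_pet <- !pet_bl_ok & is.finite(pets_diag)
  pet_dx_date[fu_pet] <- date_plus_years(cfg$fu_start, pets_diag[fu_pet])

  events <- build_coded_events(cfg, per, pet, own_dx_date, pet_dx_date,
                               death_y, emig_y2, term_y, pet_death_y)

  persons_out <- setDF(per[, c("person_id", "household_id", "birth_date", "sex",
                               "country_of_birth", "region", "population_density",
                               "education", "marital_status", "disposable_income",
                               "death_date", "emigration_date", "is_index_owner")])
  pets_out <- setDF(pet[, c("pet_id", "species", "birth_date", "sex", "breed",
                            "breed_risk_group", "death_date", "insurance_start",
                            "insurance_end")])
  links_out <- setDF(links[order(person_id, pet_id), c("person_id", "pet_id")])

  truth_owners <- data.frame(person_id = per$person_id,
                             diabetic = !is.na(own_dx_date),
                             diagnosis_date = own_dx_date,
                             stringsAsFactors = FALSE)
  truth_pets <- data.frame(pet_id = pet$pet_id,
                           diabetic = !is.na(pet_dx_date),
                           diagnosis_date = pet_dx_date,
                           stringsAsFactors = FALSE)

  list(persons = persons_out, pets = pets_out, links = links_out,
       diagnoses = events$diagnoses, dispensations = events$dispensations,
       claims = events$claims,
       truth = list(owners = truth_owners, pets = truth_pets))
}

# qualifying + noise code streams for all subjects
build_coded_events <- function(cfg, per, pet, own_dx_date, pet_dx_date,
                               death_y, emig_y, term_y, pet_death_y) {
  n_pers <- nrow(per)
  n_pets <- nrow(pet)
  icd_codes <- c("E11", "E118", "E119")
  atc_codes <- c("A10BA02", "A10BB01", "A10BH01", "A10XA01")
  ea_codes <- c("EA234", "EA2341", "EA2342", "EA23421")

  ev <- list()
  add <- function(subject, stream, code, date) {
    keep <- !is.na(date)
    if (!any(keep)) return(invisible(NULL))
    ev[[length(ev) + 1L]] <<- data.frame(
      subject_id = subject[keep], stream = stream[keep], code = code[keep],
      event_date = date[keep], stringsAsFactors = FALSE)
    invisible(NULL)
  }

  ## owners: first qualifying record at diagnosis date
  has_dx <- !is.na(own_dx_date)
  if (any(has_dx)) {
    dxd <- own_dx_date[has_dx]
    use_drug <- dxd >= cfg$drug_register_start & runif(sum(has_dx)) < 0.6
    stream <- ifelse(use_drug, "drug_register", "patient_register")
    code <- ifelse(use_drug,
                   sample(atc_codes, sum(has_dx), replace = TRUE),
                   sample(icd_codes, sum(has_dx), replace = TRUE))
    add(per$person_id[has_dx], stream, code, dxd)
    # refill / revisit 90 days later when still observable
    lim <- date_plus_years(cfg$fu_start, pmin(death_y, emig_y)[has_dx])
    lim <- pmin(lim, cfg$fu_end, na.rm = TRUE)
    refill <- dxd + 90
    refill[refill > lim | runif(sum(has_dx)) > 0.5] <- NA
    refill[refill < cfg$drug_register_start] <- NA
    add(per$person_id[has_dx], rep("drug_register", sum(has_dx)),
        sample(atc_codes, sum(has_dx), replace = TRUE), refill)
    # cause-of-death mention for diabetic decedents
    dth <- per$death_date[has_dx]
    cod <- ifelse(!is.na(dth) & dth >= dxd & runif(sum(has_dx)) < 0.3, dth, NA)
    add(per$person_id[has_dx], rep("cause_of_death", sum(has_dx)),
        rep("E119", sum(has_dx)), as.Date(cod, origin = "1970-01-01"))
  }

  ## owner noise: non-qualifying diagnoses and dispensations
  noise_icd <- c("I10", "E10", "E109", "M545", "J459")
  noise_atc <- c("A10A", "A10AB01", "C07AB02", "A02BC01")
  pick <- runif(n_pers) < 0.25
  if (any(pick)) {
    d <- as.Date(floor(runif(sum(pick), as.numeric(cfg$baseline_start),
                             as.numeric(cfg$fu_end))), origin = "1970-01-01")
    lim <- date_plus_years(cfg$fu_start, pmin(death_y, emig_y)[pick])
    d[!is.na(lim) & d > lim] <- NA
    add(per$person_id[pick], rep("patient_register", sum(pick)),
        sample(noise_icd, sum(pick), replace = TRUE), d)
  }
  pick <- runif(n_pers) < 0.15
  if (any(pick)) {
    d <- as.Date(floor(runif(sum(pick), as.numeric(cfg$drug_register_start),
                             as.numeric(cfg$fu_end))), origin = "1970-01-01")
    lim <- date_plus_years(cfg$fu_start, pmin(death_y, emig_y)[pick])
    d[!is.na(lim) & d > lim] <- NA
    add(per$person_id[pick], rep("drug_register", sum(pick)),
        sample(noise_atc, sum(pick), replace = TRUE), d)
  }

  ## pets: qualifying claims at diagnosis, bounded by the insured interval
  has_pdx <- !is.na(pet_dx_date)
  ins_lim <- date_plus_years(cfg$fu_start, pmin(term_y, pet_death_y))
  ins_lim <- pmin(ins_lim, cfg$fu_end)
  if (any(has_pdx)) {
    dxd <- pet_dx_date[has_pdx]
    add(pet$pet_id[has_pdx], rep("vet_claim", sum(has_pdx)),
        sample(ea_codes, sum(has_pdx), replace = TRUE, prob = c(.3, .4, .2, .1)),
        dxd)
    fup <- dxd + 120
    fup[fup > ins_lim[has_pdx] | runif(sum(has_pdx)) > 0.4] <- NA
    add(pet$pet_id[has_pdx], rep("vet_claim", sum(has_pdx)),
        sample(ea_codes, sum(has_pdx), replace = TRUE), fup)
  }
  ## pet noise claims inside the insured interval
  noise_ea <- c("EA230", "EA111", "QZ100", "EA2")
  pick <- runif(n_pets) < 0.3
  if (any(pick)) {
    lo <- pmax(as.numeric(pet$insurance_start[pick]),
               as.numeric(cfg$baseline_start))
    hi <- as.numeric(ins_lim[pick])
    ok <- hi > lo + 1
    d <- rep(NA_real_, sum(pick))
    d[ok] <- floor(runif(sum(ok), lo[ok], hi[ok]))
    add(pet$pet_id[pick], rep("vet_claim", sum(pick)),
        sample(noise_ea, sum(pick), replace = TRUE),
        as.Date(d, origin = "1970-01-01"))
  }

  all_ev <- if (length(ev)) do.call(rbind, ev) else
    data.frame(subject_id = character(0), stream = character(0),
               code = character(0), event_date = as.Date(character(0)),
               stringsAsFactors = FALSE)
  all_ev <- all_ev[order(all_ev$subject_id, all_ev$event_date, all_ev$code), ]
  rownames(all_ev) <- NULL
  list(
    diagnoses = all_ev[all_ev$stream %in% c("patient_register", "cause_of_death"), ],
    dispensations = all_ev[all_ev$stream == "drug_register", ],
    claims = all_ev[all_ev$stream == "vet_claim", ]
  )
}

#' Write / read a registry bundle as delimited text
#'
#' Writes the six registry tables (and, optionally, the ground-truth
#' status tables) as CSV files with ISO-8601 dates, or reads them back.
#'
#' @param cohort a registry bundle from [generate_cohort()].
#' @param dir output directory (created if needed).
#' @param truth also write `truth_owners.csv` / `truth_pets.csv`.
#' @return `write_registry` returns `dir` invisibly; `read_registry`
#'   returns a registry bundle (without truth unless present on disk).
#' @export
write_registry <- function(cohort, dir, truth = TRUE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tabs <- c("persons", "pets", "links", "diagnoses", "dispensations", "claims")
  for (tb in tabs)
    utils::write.csv(cohort[[tb]], file.path(dir, paste0(tb, ".csv")),
                     row.names = FALSE, na = "")
  if (truth && !is.null(cohort$truth)) {
    utils::write.csv(cohort$truth$owners, file.path(dir, "truth_owners.csv"),
                     row.names = FALSE, na = "")
    utils::write.csv(cohort$truth$pets, file.path(dir, "truth_pets.csv"),
                     row.names = FALSE, na = "")
  }
  invisible(dir)
}

#' @rdname write_registry
#' @export
read_registry <- function(dir) {
  rd <- function(f) utils::read.csv(file.path(dir, f), stringsAsFactors = FALSE,
                                    na.strings = "")
  date_cols <- function(df, cols) {
    for (cl in intersect(cols, names(df))) df[[cl]] <- as.Date(df[[cl]])
    df
  }
  out <- list(
    persons = date_cols(rd("persons.csv"),
                        c("birth_date", "death_date", "emigration_date")),
    pets = date_cols(rd("pets.csv"),
                     c("birth_date", "death_date", "insurance_start", "insurance_end")),
    links = rd("links.csv"),
    diagnoses = date_cols(rd("diagnoses.csv"), "event_date"),
    dispensations = date_cols(rd("dispensations.csv"), "event_date"),
    claims = date_cols(rd("claims.csv"), "event_date")
  )
  to <- file.path(dir, "truth_owners.csv")
  if (file.exists(to)) {
    out$truth <- list(
      owners = date_cols(rd("truth_owners.csv"), "diagnosis_date"),
      pets = date_cols(rd("truth_pets.csv"), "diagnosis_date"))
  }
  out
}
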