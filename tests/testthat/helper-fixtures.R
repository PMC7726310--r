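# shared fixtures, built once per test run

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, build(), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

# a small registry-calibrated dog cohort with phenotyping and assembly done
small_study <- function() fixture("small_study", function() {
  cfg <- demo_truth_config("dog", n_households = 1500, seed = 101)
  cohort <- generate_cohort(cfg)
  owner_status <- suppressWarnings(phenotype_owners(
    rbind(cohort$diagnoses, cohort$dispensations),
    subject_ids = cohort$persons$person_id))
  pet_status <- phenotype_pets(cohort$claims, subject_ids = cohort$pets$pet_id)
  pairs <- build_pairs(cohort$persons, cohort$pets, cohort$links)
  excl <- apply_exclusions(pairs, cohort$persons, cohort$pets,
                           owner_status, pet_status)
  histories <- build_histories(excl$pairs, cohort$persons, cohort$pets,
                               owner_status, pet_status)
  list(cfg = cfg, cohort = cohort, owner_status = owner_status,
       pet_status = pet_status, pairs = pairs, excl = excl,
       histories = histories)
})

# an enriched recovery cohort large enough to fit reliably, small enough
# for unit tests
small_recovery <- function() fixture("small_recovery", function() {
  cfg <- demo_truth_config("dog_crude", n_households = 4000, seed = 202)
  res <- run_pipeline(cfg, models = character(0), verbose = FALSE)
  res$histories
})

# hand-rolled minimal histories: two clusters, all covariates present
toy_histories <- function() {
  data.frame(
    pair_id = paste0("PR", 1:6),
    person_id = c("p1", "p1", "p2", "p3", "p4", "p5"),
    pet_id = c("a1", "a2", "a3", "a4", "a5", "a6"),
    cluster_id = c("h1", "h1", "h1", "h2", "h2", "h3"),
    baseline_state = c("N", "N", "O", "D", "N", "N"),
    owner_event_time = c(1.5, 1.5, NA, 2.0, NA, NA),
    pet_event_time = c(NA, 3.0, 2.5, NA, NA, 0.5),
    censor_time = c(4, 6, 5, 6, 3, 2),
    censor_reason = c("owner death", "admin end", "admin end", "admin end",
                      "insurance termination", "pet death"),
    pet_death_time = c(NA, NA, NA, -0.5, NA, NA),
    owner_age = c(55, 55, 62, 49, 70, 58),
    owner_sex = c("female", "female", "male", "male", "female", "male"),
    pet_age = c(4, 7, 2, 11, 6, 5),
    pet_sex = c("male", "female", "female", "female", "male", "male"),
    breed_risk_group = c("moderate", "high", "low", "moderate", "moderate", "high"),
    country_of_birth = c("Sweden", "Sweden", "other Nordic", "Sweden",
                         "non-Nordic", "Sweden"),
    region = c("Gotaland", "Gotaland", "Svealand", "Norrland", "Gotaland",
               "Svealand"),
    population_density = c(500, 500, 1200, 40, 800, 300),
    education = c("secondary", "secondary", "university", "compulsory",
                  "secondary", "university"),
    marital_status = c("married/cohabiting", "married/cohabiting", "not",
                       "married/cohabiting", "not", "not"),
    income_decile = c(4L, 4L, 8L, 2L, 6L, 5L),
    stringsAsFactors = FALSE)
}

# independent record enumeration: per-pair state walk, used as oracle for
# build_design (kept deliberately naive and separate from the implementation)
enumerate_records <- function(h) {
  out <- list()
  for (i in seq_len(nrow(h))) {
    C <- h$censor_time[i]
    to <- h$owner_event_time[i]
    tp <- h$pet_event_time[i]
    st <- h$baseline_state[i]
    add <- function(k, entry, exit, ev) {
      if (exit > entry)
        out[[length(out) + 1L]] <<- data.frame(pair = h$pair_id[i], k = k,
                                               entry = entry, exit = exit,
                                               event = ev)
    }
    if (st == "N") {
      first <- min(to, tp, C, na.rm = TRUE)
      add("k1", 0, first, !is.na(to) && to == first)
      add("k2", 0, first, !is.na(tp) && tp == first)
      if (!is.na(to) && to == first)        # entered O
        add("k3", to, min(tp, C, na.rm = TRUE), !is.na(tp))
      if (!is.na(tp) && tp == first)        # entered D
        add("k4", tp, min(to, C, na.rm = TRUE), !is.na(to))
    } else if (st == "O") {
      add("k3", 0, min(tp, C, na.rm = TRUE), !is.na(tp))
    } else if (st == "D") {
      add("k4", 0, min(to, C, na.rm = TRUE), !is.na(to))
    }
  }
  do.call(rbind, out)
}
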