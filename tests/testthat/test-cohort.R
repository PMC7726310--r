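mk_persons <- function(ids, hh, ...) {
  n <- length(ids)
  defaults <- data.frame(
    person_id = ids, household_id = hh,
    birth_date = as.Date("1950-06-01"), sex = "female",
    country_of_birth = "Sweden", region = "Gotaland",
    population_density = 500, education = "secondary",
    marital_status = "married/cohabiting", disposable_income = 1600,
    death_date = as.Date(NA), emigration_date = as.Date(NA),
    is_index_owner = c(TRUE, rep(FALSE, n - 1L)), stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

mk_pets <- function(ids, ...) {
  defaults <- data.frame(
    pet_id = ids, species = "dog", birth_date = as.Date("2003-05-01"),
    sex = "male", breed = "Beagle", breed_risk_group = "moderate",
    death_date = as.Date(NA), insurance_start = as.Date("2004-02-01"),
    insurance_end = as.Date(NA), stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) defaults[[nm]] <- overrides[[nm]]
  defaults
}

no_dx <- function(person_ids = character(0), pet_ids = character(0)) {
  list(owners = data.frame(person_id = person_ids, diabetic = FALSE,
                           diagnosis_date = as.Date(NA), source = NA,
                           stringsAsFactors = FALSE),
       pets = data.frame(pet_id = pet_ids, diabetic = FALSE,
                         diagnosis_date = as.Date(NA), source = NA,
                         stringsAsFactors = FALSE))
}

test_that("spouses are owners: two-person household with one dog gives two pairs", {
  persons <- mk_persons(c("p1", "p2"), "h1")
  pets <- mk_pets("a1")
  links <- data.frame(person_id = c("p1", "p2"), pet_id = "a1",
                      stringsAsFactors = FALSE)
  pairs <- build_pairs(persons, pets, links)
  expect_equal(nrow(pairs), 2L)
  expect_equal(unique(pairs$cluster_id), "h1")
})

test_that("one person with three dogs forms three pairs", {
  persons <- mk_persons("p1", "h1")
  pets <- mk_pets(c("a1", "a2", "a3"))
  links <- data.frame(person_id = "p1", pet_id = c("a1", "a2", "a3"),
                      stringsAsFactors = FALSE)
  expect_equal(nrow(build_pairs(persons, pets, links)), 3L)
})

test_that("dangling link ids raise a hard error naming them", {
  persons <- mk_persons("p1", "h1")
  pets <- mk_pets("a1")
  links <- data.frame(person_id = c("p1", "pX"), pet_id = c("a1", "a1"),
                      stringsAsFactors = FALSE)
  expect_error(build_pairs(persons, pets, links), "pX")
})

test_that("pair count equals the brute-force join on generated tables", {
  s <- small_study()
  coh <- s$cohort
  brute <- merge(merge(coh$links, coh$persons, by = "person_id"),
                 coh$pets, by = "pet_id")
  expect_equal(nrow(s$pairs), nrow(brute))
  expect_setequal(paste(s$pairs$person_id, s$pairs$pet_id),
                  paste(brute$person_id, brute$pet_id))
})

test_that("baseline state classification follows the diagnosis dates", {
  fu <- as.Date("2007-01-01")
  expect_equal(classify_baseline(as.Date("2006-05-01"), as.Date(NA), fu), "O")
  expect_equal(classify_baseline(as.Date(NA), as.Date(NA), fu), "N")
  expect_equal(classify_baseline(as.Date(NA), as.Date("2004-02-02"), fu), "D")
  expect_equal(classify_baseline(as.Date("2005-01-01"), as.Date("2006-01-01"), fu), "B")
  # diagnosis on the first follow-up day is follow-up, not baseline
  expect_equal(classify_baseline(as.Date("2007-01-01"), as.Date(NA), fu), "N")
})

test_that("exclusion cascade applies the rules in order and telescopes", {
  persons <- mk_persons(c("p1", "p2", "p3"), c("h1", "h2", "h3"),
                        is_index_owner = TRUE)
  persons$death_date[1] <- as.Date("2006-10-10")      # dead before follow-up
  pets <- mk_pets(c("a1", "a2", "a3"))
  pets$insurance_end[2] <- as.Date("2006-06-30")      # terminated, non-diabetic
  links <- data.frame(person_id = c("p1", "p2", "p3"),
                      pet_id = c("a1", "a2", "a3"), stringsAsFactors = FALSE)
  st <- no_dx(persons$person_id, pets$pet_id)
  pairs <- build_pairs(persons, pets, links)
  res <- apply_exclusions(pairs, persons, pets, st$owners, st$pets)
  expect_equal(res$report$removed,   c(0L, 1L, 0L, 0L, 0L, 1L, 0L))
  expect_equal(res$report$remaining, c(3L, 2L, 2L, 2L, 2L, 1L, 1L))
  expect_equal(res$pairs$person_id, "p3")

  # both diabetic at baseline: excluded at the final rule
  st$owners$diabetic[3] <- TRUE
  st$owners$diagnosis_date[3] <- as.Date("2005-03-03")
  st$pets$diabetic[3] <- TRUE
  st$pets$diagnosis_date[3] <- as.Date("2006-03-03")
  res2 <- apply_exclusions(pairs, persons, pets, st$owners, st$pets)
  expect_equal(utils::tail(res2$report$removed, 1), 1L)
  expect_equal(nrow(res2$pairs), 0L)

  # a terminated pet that IS diabetic at baseline is retained
  st3 <- no_dx(persons$person_id, pets$pet_id)
  st3$pets$diabetic[2] <- TRUE
  st3$pets$diagnosis_date[2] <- as.Date("2005-05-05")
  res3 <- apply_exclusions(pairs, persons, pets, st3$owners, st3$pets)
  expect_true("p2" %in% res3$pairs$person_id)
})

test_that("a planted zero-exclusion fixture removes nothing", {
  persons <- mk_persons(c("p1", "p2"), c("h1", "h2"), is_index_owner = TRUE)
  pets <- mk_pets(c("a1", "a2"))
  links <- data.frame(person_id = c("p1", "p2"), pet_id = c("a1", "a2"),
                      stringsAsFactors = FALSE)
  st <- no_dx(persons$person_id, pets$pet_id)
  res <- apply_exclusions(build_pairs(persons, pets, links), persons, pets,
                          st$owners, st$pets)
  expect_true(all(res$report$removed == 0L))
})

test_that("owners with more than 10 insured pets are excluded as breeders", {
  ids <- sprintf("a%02d", 1:11)
  persons <- mk_persons("p1", "h1")
  pets <- mk_pets(ids)
  links <- data.frame(person_id = "p1", pet_id = ids, stringsAsFactors = FALSE)
  st <- no_dx("p1", ids)
  res <- apply_exclusions(build_pairs(persons, pets, links), persons, pets,
                          st$owners, st$pets)
  expect_equal(res$report$removed[4], 11L)
  expect_equal(nrow(res$pairs), 0L)
})

test_that("telescoping holds exactly on a generated registry", {
  s <- small_study()
  rep <- s$excl$report
  expect_equal(rep$remaining[1], nrow(s$pairs))
  for (i in 2:nrow(rep))
    expect_equal(rep$remaining[i], rep$remaining[i - 1] - rep$removed[i])
  expect_equal(utils::tail(rep$remaining, 1), nrow(s$excl$pairs))
})

test_that("histories convert dates to years and respect censoring rules", {
  persons <- mk_persons(c("p1", "p2"), c("h1", "h2"), is_index_owner = TRUE)
  pets <- mk_pets(c("a1", "a2"))
  pets$death_date[2] <- as.Date("2009-06-01")
  pets$insurance_end[2] <- as.Date("2009-06-01")      # death-driven end
  links <- data.frame(person_id = c("p1", "p2"), pet_id = c("a1", "a2"),
                      stringsAsFactors = FALSE)
  st <- no_dx(persons$person_id, pets$pet_id)
  # pair 1: baseline N, owner dx 2008-07-01 then pet dx 2010-01-01
  st$owners$diabetic[1] <- TRUE
  st$owners$diagnosis_date[1] <- as.Date("2008-07-01")
  st$pets$diabetic[1] <- TRUE
  st$pets$diagnosis_date[1] <- as.Date("2010-01-01")
  # pair 2: baseline D (pet dx 2005), pet dies 2009, owner dx 2011
  st$pets$diabetic[2] <- TRUE
  st$pets$diagnosis_date[2] <- as.Date("2005-04-04")
  st$owners$diabetic[2] <- TRUE
  st$owners$diagnosis_date[2] <- as.Date("2011-03-01")

  pairs <- build_pairs(persons, pets, links)
  h <- build_histories(pairs, persons, pets, st$owners, st$pets)
  h1 <- h[h$person_id == "p1", ]
  expect_equal(h1$baseline_state, "N")
  expect_equal(h1$owner_event_time,
               as.numeric(as.Date("2008-07-01") - as.Date("2007-01-01")) / 365.25)
  expect_equal(h1$pet_event_time,
               as.numeric(as.Date("2010-01-01") - as.Date("2007-01-01")) / 365.25)

  h2 <- h[h$person_id == "p2", ]
  expect_equal(h2$baseline_state, "D")
  # no censoring at the death of an already diabetic pet
  expect_equal(h2$censor_reason, "admin end")
  expect_false(is.na(h2$owner_event_time))
  # follow-up times stay within the six-year horizon (plus at most the
  # half-day shifts applied to boundary events)
  expect_true(all(h$censor_time >= 0 & h$censor_time <= 6 + 1.5 / 365.25))

  # sensitivity variant: censor at the diabetic pet's death, owner event gone
  hs <- sensitivity_filter(h)
  hs2 <- hs[hs$person_id == "p2", ]
  expect_equal(hs2$censor_time,
               as.numeric(as.Date("2009-06-01") - as.Date("2007-01-01")) / 365.25)
  expect_true(is.na(hs2$owner_event_time))
  expect_equal(hs2$censor_reason, "pet death")
})

test_that("sensitivity filter drops pets dead before follow-up, else idempotent", {
  h <- toy_histories()
  hs <- sensitivity_filter(h)
  expect_false(any(hs$person_id == "p3"))   # pet died during baseline
  h_no_death <- h[is.na(h$pet_death_time), ]
  expect_equal(sensitivity_filter(h_no_death), h_no_death, ignore_attr = TRUE)
})

test_that("diagnoses outside both study windows are a hard error", {
  persons <- mk_persons("p1", "h1")
  pets <- mk_pets("a1")
  links <- data.frame(person_id = "p1", pet_id = "a1", stringsAsFactors = FALSE)
  st <- no_dx("p1", "a1")
  st$owners$diagnosis_date[1] <- as.Date("2013-06-01")
  pairs <- build_pairs(persons, pets, links)
  expect_error(build_histories(pairs, persons, pets, st$owners, st$pets),
               "inconsistency")
})

test_that("same-day and day-one diagnoses get half-day intervals, owner first", {
  persons <- mk_persons("p1", "h1")
  pets <- mk_pets("a1")
  links <- data.frame(person_id = "p1", pet_id = "a1", stringsAsFactors = FALSE)
  st <- no_dx("p1", "a1")
  st$owners$diagnosis_date[1] <- as.Date("2008-05-05")
  st$pets$diagnosis_date[1] <- as.Date("2008-05-05")
  h <- build_histories(build_pairs(persons, pets, links), persons, pets,
                       st$owners, st$pets)
  expect_equal(h$pet_event_time - h$owner_event_time, 0.5 / 365.25)

  st$owners$diagnosis_date[1] <- as.Date("2007-01-01")
  st$pets$diagnosis_date[1] <- as.Date(NA)
  h <- build_histories(build_pairs(persons, pets, links), persons, pets,
                       st$owners, st$pets)
  expect_equal(h$owner_event_time, 0.5 / 365.25)
})

test_that("incidence rates count deduplicated subjects", {
  # 1 event in 100 subject-years -> 10 per 1000
  h <- toy_histories()[5, ]
  h$censor_time <- 100
  h$owner_event_time <- 100
  expect_equal(incidence_rates(h)$rate_per_1000[1], 10)
  h$owner_event_time <- NA
  expect_equal(incidence_rates(h)$rate_per_1000[1], 0)

  # an owner with two dogs and one T2D event counts once, with union risk time
  h2 <- toy_histories()[1:2, ]           # same person p1, events at 1.5
  inc <- incidence_rates(h2)
  expect_equal(inc$events[1], 1)
  expect_equal(inc$years[1], 1.5)

  # owners diabetic at baseline (state O) are excluded from owner incidence
  h3 <- toy_histories()
  inc3 <- incidence_rates(h3)
  expect_false("p2" %in% h3$person_id[h3$baseline_state %in% c("N", "D")])
  # zero risk time reported as undefined
  h0 <- toy_histories()[0, ]
  expect_message(inc0 <- incidence_rates(h0), "undefined")
  expect_true(all(is.na(inc0$rate_per_1000)))
})

test_that("state-partitioned person-time equals total censor time per pair", {
  s <- small_study()
  h <- s$histories
  d <- build_design(h, model_spec("1"))
  dur_by_pair <- function(blk, exposed) {
    keep <- blk$X[, "exposed"] == as.numeric(exposed)
    v <- tapply((blk$exit - blk$entry)[keep], blk$pair_id[keep], sum)
    out <- setNames(rep(0, nrow(h)), h$pair_id)
    out[names(v)] <- v
    out
  }
  tN_A <- dur_by_pair(d$pairA, FALSE)   # time in state N seen by pair A
  tN_B <- dur_by_pair(d$pairB, FALSE)   # ... and by pair B: must agree
  expect_equal(tN_A, tN_B, tolerance = 1e-10)
  tD <- dur_by_pair(d$pairA, TRUE)
  tO <- dur_by_pair(d$pairB, TRUE)
  # absorbing-state time: censoring after the second diagnosis
  to <- ifelse(is.na(h$owner_event_time), Inf, h$owner_event_time)
  tp <- ifelse(is.na(h$pet_event_time), Inf, h$pet_event_time)
  both <- is.finite(to) & is.finite(tp)
  tB <- ifelse(both, h$censor_time - pmax(to, tp),
               ifelse(h$baseline_state == "O" & is.finite(tp),
                      h$censor_time - tp,
               ifelse(h$baseline_state == "D" & is.finite(to),
                      h$censor_time - to, 0)))
  expect_equal(unname(tN_A + tO + tD + tB), h$censor_time, tolerance = 1e-8)
})
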