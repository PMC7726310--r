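# Diabetes phenotyping from register code streams.
#
# Owner type 2 diabetes: any main or secondary ICD-10 E11 diagnosis in the
# patient register or cause-of-death register, or any dispensation of an
# oral / non-insulin injectable diabetes drug (ATC A10B, A10X). Type 1
# codes (E10) and insulin (A10A) never qualify. Pet diabetes: a veterinary
# claim with one of the enumerated EA codes. The first qualifying record
# dates the diagnosis.

OWNER_ICD_STREAMS <- c("patient_register", "cause_of_death")
PET_DIABETES_CODES <- c("EA234", "EA2341", "EA2342", "EA23421")

# drop malformed codes with a warning; never let them qualify silently
clean_events <- function(events) {
  stopifnot(all(c("subject_id", "stream", "code", "event_date") %in% names(events)))
  code <- as.character(events$code)
  bad <- is.na(code) | !nzchar(trimws(code)) | is.na(events$event_date)
  if (any(bad)) {
    warnf("skipping %d malformed coded event(s) (missing/empty code or date)",
          sum(bad))
    events <- events[!bad, , drop = FALSE]
  }
  events$code <- trimws(as.character(events$code))
  events
}

summarise_status <- function(events, qualifies, id_col, all_ids = NULL) {
  ev <- events[qualifies, , drop = FALSE]
  if (nrow(ev)) {
    dt <- as.data.table(ev)
    st <- dt[, {
      d <- min(event_date)
      list(diagnosis_date = d,
           source = paste(sort(unique(stream[event_date == d])), collapse = ";"))
    }, by = subject_id]
  } else {
    st <- data.table(subject_id = character(0),
                     diagnosis_date = as.Date(character(0)),
                     source = character(0))
  }
  out <- data.frame(subject_id = st$subject_id,
                    diabetic = rep(TRUE, nrow(st)),
                    diagnosis_date = st$diagnosis_date, source = st$source,
                    stringsAsFactors = FALSE)
  if (!is.null(all_ids)) {
    missing <- setdiff(all_ids, out$subject_id)
    if (length(missing))
      out <- rbind(out, data.frame(subject_id = missing, diabetic = FALSE,
                                   diagnosis_date = as.Date(NA),
                                   source = NA_character_,
                                   stringsAsFactors = FALSE))
    out <- out[match(all_ids, out$subject_id), ]
    rownames(out) <- NULL
  } else {
    out <- out[order(out$subject_id), ]
    rownames(out) <- NULL
  }
  names(out)[1] <- id_col
  out
}

#' Phenotype owners for type 2 diabetes from their code streams
#'
#' Scans diagnosis and dispensation records and classifies each person as
#' having type 2 diabetes if any record qualifies: an ICD-10 code starting
#' `E11` in the patient register or cause-of-death register, or an ATC code
#' starting `A10B` or `A10X` in the prescribed drug register. Insulin
#' (`A10A`) and type 1 diabetes (`E10`) records never qualify. The
#' diagnosis date is the earliest qualifying record; `source` lists all
#' streams contributing a qualifying record on that date. Malformed codes
#' are skipped with a warning.
#'
#' @param events data.frame of coded events with columns `subject_id`,
#'   `stream` (`patient_register`, `cause_of_death`, `drug_register`),
#'   `code`, `event_date`. Typically `rbind` of the diagnoses and
#'   dispensations registry tables.
#' @param subject_ids optional character vector of persons that must appear
#'   in the output; subjects without qualifying events are returned as
#'   non-diabetic.
#' @return data.frame with columns `person_id`, `diabetic`,
#'   `diagnosis_date`, `source`.
#' @export
phenotype_owners <- function(events, subject_ids = NULL) {
  events <- clean_events(events)
  icd_ok <- events$stream %in% OWNER_ICD_STREAMS & startsWith(events$code, "E11")
  atc_ok <- events$stream == "drug_register" &
    (startsWith(events$code, "A10B") | startsWith(events$code, "A10X"))
  summarise_status(events, icd_ok | atc_ok, "person_id", subject_ids)
}

#' Phenotype pets for diabetes from veterinary claims
#'
#' A pet is diabetic if any claim carries exactly one of the standardised
#' veterinary diagnostic codes `EA234` (diabetes), `EA2341` (without
#' complications), `EA2342` (with complications) or `EA23421` (with
#' ketoacidosis); the earliest such claim dates the diagnosis.
#'
#' @param claims data.frame of claims with columns `subject_id`, `stream`,
#'   `code`, `event_date`.
#' @param subject_ids optional character vector of pets that must appear in
#'   the output.
#' @return data.frame with columns `pet_id`, `diabetic`, `diagnosis_date`,
#'   `source`.
#' @export
phenotype_pets <- function(claims, subject_ids = NULL) {
  claims <- clean_events(claims)
  ok <- claims$stream == "vet_claim" & claims$code %in% PET_DIABETES_CODES
  summarise_status(claims, ok, "pet_id", subject_ids)
}
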