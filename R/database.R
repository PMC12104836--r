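# Cohort document database: seven validated classes over three levels
# (Subject / {EpilepsyStatus, Exam, Treatment} / {Channel, Segment,
# Seizure}), backed by one JSON collection per class in a directory.
# Only file locations are stored for raw data, never the data itself.

db_vocab <- function(hospitals = c("UCLH", "GOSH", "SYNH")) {
  list(
    hospital = hospitals,
    sex = c("M", "F"),
    handedness = c("L", "R", "A"),
    exam_type = c("icEEG", "MRI", "CT"),
    treatment_type = c("epilepsy surgery"),
    electrode_type = c("grid", "strip", "depth"),
    reference = c("referential", "bipolar"),
    wake_status = c("W", "N1", "N2", "N3", "R", "NA"),
    seizure_type = c("focal", "subclin", "sg"),
    hemisphere = c("left", "right")
  )
}

# Per-class schema: required fields, optional fields, vocabulary bindings,
# parent references and uniqueness rules ("unique key within scope").
db_schema <- function(hospitals = c("UCLH", "GOSH", "SYNH")) {
  v <- db_vocab(hospitals)
  list(
    subject = list(
      required = c("hospital", "subject_id"),
      optional = c("dob", "sex_at_birth", "handedness", "age_of_epilepsy_onset"),
      vocab = list(hospital = v$hospital, sex_at_birth = v$sex,
                   handedness = v$handedness),
      parent = NULL,
      unique = list(list(key = "subject_id", scope = character(),
                         rule = "subject_id unique"))
    ),
    epilepsy_status = list(
      required = c("subject_id", "date_of_status"),
      optional = c("status_epilepticus", "complex_partial_seizures",
                   "cps_monthly_frequency", "secondary_generalised_seizures",
                   "sgs_monthly_frequency"),
      vocab = list(),
      parent = "subject",
      unique = list(list(key = "date_of_status", scope = "subject_id",
                         rule = "date_of_status unique within subject_id"))
    ),
    exam = list(
      required = c("subject_id", "exam_id", "exam_type", "exam_date"),
      optional = c("iceeg_report_file_location", "raw_iceeg_folder_location",
                   "pre_implantation_mri_file_location",
                   "post_surgery_mri_file_location",
                   "post_implantation_ct_file_location"),
      vocab = list(exam_type = v$exam_type),
      parent = "subject",
      unique = list(list(key = "exam_id", scope = "subject_id",
                         rule = "exam_id unique within subject_id"))
    ),
    treatment = list(
      required = c("subject_id", "treatment_type", "treatment_date"),
      optional = c("outcome_ilae", "outcome_engel", "outcome_date",
                   "surgery_type", "surgery_pathology", "surgery_hemisphere"),
      vocab = list(treatment_type = v$treatment_type,
                   surgery_hemisphere = v$hemisphere),
      parent = "subject",
      unique = list(list(key = "treatment_date",
                         scope = c("subject_id", "treatment_type"),
                         rule = "treatment_date unique within subject_id + treatment_type"))
    ),
    channel = list(
      required = c("subject_id", "exam_id", "channel_name"),
      optional = c("channel_hemisphere", "electrode_type", "location",
                   "roi_ids", "roi_names", "is_resected", "is_spiking",
                   "is_structurally_abnormal", "is_within_soz"),
      vocab = list(channel_hemisphere = v$hemisphere,
                   electrode_type = v$electrode_type),
      parent = "exam",
      unique = list(list(key = "channel_name", scope = "exam_id",
                         rule = "channel_name unique within exam_id"))
    ),
    iceeg_segment = list(
      required = c("subject_id", "exam_id", "datetime", "duration",
                   "sampling_frequency", "reference", "wake_status",
                   "file_location"),
      optional = c("segment_number", "unsuitable_channels", "spiking_channels"),
      vocab = list(reference = v$reference, wake_status = v$wake_status),
      parent = "exam",
      unique = list(list(key = "datetime", scope = "exam_id",
                         rule = "segment datetime unique within exam_id"))
    ),
    seizure = list(
      required = c("subject_id", "exam_id", "seizure_datetime"),
      optional = c("seizure_duration", "seizure_type", "seizure_onset_channels"),
      vocab = list(seizure_type = v$seizure_type),
      parent = "exam",
      unique = list(list(key = "seizure_datetime", scope = "exam_id",
                         rule = "seizure datetime unique within exam_id"))
    )
  )
}

#' Create or open a cohort database
#'
#' @param dir backing directory (one JSON collection per class).
#' @param hospitals allowed hospital codes (vocabulary is extensible).
#' @return a database handle (environment of class `normkit_db`).
#' @export
db_create <- function(dir, hospitals = c("UCLH", "GOSH", "SYNH")) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  db <- new.env(parent = emptyenv())
  db$dir <- dir
  db$schema <- db_schema(hospitals)
  db$docs <- stats::setNames(vector("list", length(db$schema)),
                             names(db$schema))
  for (cl in names(db$docs)) db$docs[[cl]] <- list()
  class(db) <- "normkit_db"
  db_flush(db)
  db
}

#' @rdname db_create
#' @export
db_open <- function(dir, hospitals = c("UCLH", "GOSH", "SYNH")) {
  assert_that(file.exists(file.path(dir, "subject.json")),
              sprintf("'%s' is not a normkit database", dir))
  db <- new.env(parent = emptyenv())
  db$dir <- dir
  db$schema <- db_schema(hospitals)
  db$docs <- list()
  for (cl in names(db$schema)) {
    path <- file.path(dir, paste0(cl, ".json"))
    docs <- if (file.exists(path))
      jsonlite::read_json(path, simplifyVector = FALSE) else list()
    db$docs[[cl]] <- docs
  }
  class(db) <- "normkit_db"
  db
}

db_flush <- function(db, classes = names(db$schema)) {
  for (cl in classes) {
    jsonlite::write_json(db$docs[[cl]],
                         file.path(db$dir, paste0(cl, ".json")),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         pretty = TRUE)
  }
  invisible(db)
}

#' @export
print.normkit_db <- function(x, ...) {
  counts <- vapply(x$docs, length, integer(1))
  cat("<normkit_db>", x$dir, "\n ",
      paste(sprintf("%s: %d", names(counts), counts), collapse = ", "), "\n")
  invisible(x)
}

# Canonicalise a datetime-bearing value to second precision for uniqueness.
canon_datetime <- function(x) {
  if (inherits(x, "POSIXct")) format_datetime(x) else as.character(x)
}

#' Validate a document against its class schema
#'
#' Checks required fields, constrained vocabularies and (against the current
#' database content) uniqueness rules and parent references. Never mutates.
#'
#' @param db a database handle.
#' @param doc named list.
#' @param class one of the seven schema classes.
#' @return character vector of violations (length 0 when valid).
#' @export
validate_document <- function(db, doc, class) {
  if (!class %in% names(db$schema))
    abort_normkit(sprintf("unknown document class '%s'", class),
                  "normkit_unknown_class")
  sc <- db$schema[[class]]
  v <- character()
  for (f in sc$required) {
    val <- doc[[f]]
    if (is.null(val) || (length(val) == 1 && is.na(val)) || identical(val, ""))
      v <- c(v, sprintf("required field '%s' absent", f))
  }
  known <- c(sc$required, sc$optional)
  extra <- setdiff(names(doc), known)
  if (length(extra))
    v <- c(v, sprintf("unknown field(s): %s", paste(extra, collapse = ", ")))
  for (f in names(sc$vocab)) {
    val <- doc[[f]]
    if (!is.null(val) && !all(val %in% sc$vocab[[f]]))
      v <- c(v, sprintf("field '%s' value '%s' outside vocabulary {%s}",
                        f, paste(val, collapse = ","),
                        paste(sc$vocab[[f]], collapse = ", ")))
  }
  # subject id format: HOSP_###
  if (class == "subject" && !is.null(doc$subject_id) &&
      !is.null(doc$hospital) &&
      !grepl(paste0("^", doc$hospital, "_\\d{3,}$"), doc$subject_id))
    v <- c(v, "subject_id must be '<hospital>_<zero-padded index>'")
  # parent references
  if (!is.null(sc$parent)) {
    if (!is.null(doc$subject_id)) {
      subj_ids <- vapply(db$docs$subject, function(d) d$subject_id %||% "",
                         character(1))
      if (!doc$subject_id %in% subj_ids)
        v <- c(v, sprintf("dangling reference: subject '%s' not in database",
                          doc$subject_id))
    }
    if (sc$parent == "exam" && !is.null(doc$exam_id)) {
      ok <- any(vapply(db$docs$exam, function(d)
        identical(d$exam_id, doc$exam_id) &&
          identical(d$subject_id, doc$subject_id), logical(1)))
      if (!ok)
        v <- c(v, sprintf("dangling reference: exam '%s' of subject '%s' not in database",
                          doc$exam_id, doc$subject_id %||% "?"))
    }
  }
  # uniqueness
  for (u in sc$unique) {
    val <- doc[[u$key]]
    if (is.null(val)) next
    clash <- any(vapply(db$docs[[class]], function(d) {
      same_scope <- all(vapply(u$scope, function(s)
        identical(d[[s]], doc[[s]]), logical(1)))
      same_scope && identical(canon_datetime(d[[u$key]]), canon_datetime(val))
    }, logical(1)))
    if (clash) v <- c(v, sprintf("uniqueness violation: %s", u$rule))
  }
  v
}

#' Insert a validated document
#'
#' @param db a database handle.
#' @param doc named list.
#' @param class schema class name.
#' @param flush write the collection to disk immediately (default TRUE).
#' @return the document id (content hash of class + required fields),
#'   invisibly.
#' @export
db_insert <- function(db, doc, class, flush = TRUE) {
  v <- validate_document(db, doc, class)
  if (length(v))
    abort_normkit(sprintf("invalid %s document: %s", class,
                          paste(v, collapse = "; ")), "normkit_invalid_doc")
  sc <- db$schema[[class]]
  key <- lapply(doc[sc$required], function(x)
    if (inherits(x, "POSIXct")) format_datetime(x) else x)
  id <- md5_string(canonical_json(c(list(.class = class), key)))
  doc$.id <- id
  doc <- lapply(doc, function(x) if (inherits(x, "POSIXct")) format_datetime(x) else x)
  db$docs[[class]][[length(db$docs[[class]]) + 1L]] <- doc
  if (flush) db_flush(db, class)
  invisible(id)
}

#' Insert several documents of one class, flushing once
#'
#' @param db database handle.
#' @param docs list of named lists.
#' @param class schema class name.
#' @return character vector of document ids, invisibly.
#' @export
db_insert_many <- function(db, docs, class) {
  ids <- vapply(docs, function(d) db_insert(db, d, class, flush = FALSE),
                character(1))
  db_flush(db, class)
  invisible(ids)
}

#' Fetch a document by id
#'
#' @param db database handle.
#' @param id document id from [db_insert()].
#' @return the document (named list) or NULL.
#' @export
db_get <- function(db, id) {
  for (cl in names(db$docs))
    for (d in db$docs[[cl]])
      if (identical(d$.id, id)) return(d[setdiff(names(d), ".id")])
  NULL
}

#' Query documents of a class
#'
#' Equality predicates over schema fields; scalar criteria match scalar
#' fields, and a criterion value with several entries matches any of them.
#'
#' @param db database handle.
#' @param class schema class name.
#' @param criteria named list of field = value predicates (empty = all).
#' @return list of matching documents.
#' @export
db_query <- function(db, class, criteria = list()) {
  if (!class %in% names(db$schema))
    abort_normkit(sprintf("unknown document class '%s'", class),
                  "normkit_unknown_class")
  sc <- db$schema[[class]]
  known <- c(sc$required, sc$optional)
  bad <- setdiff(names(criteria), known)
  if (length(bad))
    abort_normkit(sprintf("unknown field(s) in criteria: %s",
                          paste(bad, collapse = ", ")), "normkit_unknown_field")
  Filter(function(d) {
    all(vapply(names(criteria), function(f) {
      val <- d[[f]]
      if (is.null(val)) return(FALSE)
      any(unlist(val) %in% unlist(criteria[[f]]))
    }, logical(1)))
  }, db$docs[[class]])
}

#' Query interictal segments with subject/exam context
#'
#' @param db database handle.
#' @param criteria predicates over icEEG-segment fields.
#' @return list of segment documents, each with `hospital` joined in from
#'   the subject document.
#' @export
query_segments <- function(db, criteria = list()) {
  segs <- db_query(db, "iceeg_segment", criteria)
  subj <- db$docs$subject
  lapply(segs, function(s) {
    hit <- Filter(function(d) identical(d$subject_id, s$subject_id), subj)
    s$hospital <- if (length(hit)) hit[[1]]$hospital else NA_character_
    s
  })
}

#' Query channel documents
#'
#' @param db database handle.
#' @param criteria predicates over channel fields.
#' @return list of channel documents.
#' @export
query_channels <- function(db, criteria = list()) {
  db_query(db, "channel", criteria)
}
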