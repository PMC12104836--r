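fresh_db <- function() db_create(tempfile("db"))

seed_subject_exam <- function(db, id = "SYNH_001") {
  db_insert(db, list(hospital = "SYNH", subject_id = id), "subject")
  db_insert(db, list(subject_id = id, exam_id = paste0(id, "_icEEG_1"),
                     exam_type = "icEEG", exam_date = "2024-03-04"), "exam")
  paste0(id, "_icEEG_1")
}

test_that("documents validate against required fields and vocabularies", {
  db <- fresh_db()
  expect_length(validate_document(db, list(hospital = "UCLH",
                                           subject_id = "UCLH_001"),
                                  "subject"), 0)
  v <- validate_document(db, list(subject_id = "UCLH_001"), "subject")
  expect_match(v, "required field 'hospital'", all = FALSE)

  db_insert(db, list(hospital = "UCLH", subject_id = "UCLH_001"), "subject")
  ex <- db_insert(db, list(subject_id = "UCLH_001", exam_id = "E1",
                           exam_type = "icEEG", exam_date = "2010-11-28"),
                  "exam")
  v2 <- validate_document(db, list(subject_id = "UCLH_001", exam_id = "E1"),
                          "channel")
  expect_match(v2, "channel_name", all = FALSE)
  v3 <- validate_document(db, list(subject_id = "UCLH_001", exam_id = "E1",
                                   datetime = "2010-11-29T10:00:00",
                                   duration = 70, sampling_frequency = 512,
                                   reference = "referential",
                                   wake_status = "awake-ish",
                                   file_location = "x/y.mat"),
                          "iceeg_segment")
  expect_match(v3, "wake_status.*vocabulary", all = FALSE)
  expect_error(validate_document(db, list(), "potato"), "unknown document class")
})

test_that("uniqueness rules are enforced and named", {
  db <- fresh_db()
  seed_subject_exam(db)
  db_insert(db, list(subject_id = "SYNH_001", date_of_status = "2024-01-01"),
            "epilepsy_status")
  expect_error(db_insert(db, list(subject_id = "SYNH_001",
                                  date_of_status = "2024-01-01"),
                         "epilepsy_status"),
               "date_of_status unique within subject_id")

  db_insert(db, list(subject_id = "SYNH_001", exam_id = "SYNH_001_icEEG_1",
                     channel_name = "LHIP1"), "channel")
  expect_error(db_insert(db, list(subject_id = "SYNH_001",
                                  exam_id = "SYNH_001_icEEG_1",
                                  channel_name = "LHIP1"), "channel"),
               "channel_name unique within exam_id")

  db_insert(db, list(subject_id = "SYNH_001",
                     treatment_type = "epilepsy surgery",
                     treatment_date = "2024-06-01"), "treatment")
  expect_error(db_insert(db, list(subject_id = "SYNH_001",
                                  treatment_type = "epilepsy surgery",
                                  treatment_date = "2024-06-01"), "treatment"),
               "treatment_date unique")
})

test_that("dangling parent references are rejected", {
  db <- fresh_db()
  expect_error(db_insert(db, list(subject_id = "SYNH_009",
                                  date_of_status = "2024-01-01"),
                         "epilepsy_status"), "dangling")
  seed_subject_exam(db)
  expect_error(db_insert(db, list(subject_id = "SYNH_001", exam_id = "nope",
                                  channel_name = "A1"), "channel"),
               "dangling")
})

test_that("insert round-trips by id and reload is content-identical", {
  dir <- tempfile("db")
  db <- db_create(dir)
  seed_subject_exam(db)
  id <- db_insert(db, list(subject_id = "SYNH_001",
                           exam_id = "SYNH_001_icEEG_1",
                           channel_name = "LHIP1",
                           channel_hemisphere = "left",
                           electrode_type = "depth",
                           location = c(-29.83, -15.10, -9.69)), "channel")
  doc <- db_get(db, id)
  expect_identical(doc$channel_name, "LHIP1")
  expect_equal(unlist(doc$location), c(-29.83, -15.10, -9.69))

  db2 <- db_open(dir)
  for (cl in names(db$docs))
    expect_identical(normkit:::canonical_json(db2$docs[[cl]]),
                     normkit:::canonical_json(db$docs[[cl]]))
  unlink(dir, recursive = TRUE)
})

test_that("queries match a linear-scan oracle and reject unknown fields", {
  db <- fresh_db()
  ex <- seed_subject_exam(db)
  set.seed(3)
  for (i in 1:12) {
    db_insert(db, list(subject_id = "SYNH_001", exam_id = ex,
                       datetime = sprintf("2024-03-05T%02d:00:00", i),
                       duration = sample(c(70, 120), 1),
                       sampling_frequency = 512,
                       reference = "referential",
                       wake_status = sample(c("W", "N2"), 1),
                       file_location = sprintf("seg%d", i)), "iceeg_segment")
  }
  got <- query_segments(db, list(wake_status = "W", duration = 70))
  oracle <- Filter(function(d) d$wake_status == "W" && d$duration == 70,
                   db$docs$iceeg_segment)
  expect_identical(vapply(got, `[[`, "", "file_location"),
                   vapply(oracle, `[[`, "", "file_location"))
  expect_true(all(vapply(got, `[[`, "", "hospital") == "SYNH"))
  expect_length(query_segments(db, list(wake_status = "N3")), 0)
  expect_length(query_segments(db), 12)
  expect_error(db_query(db, "iceeg_segment", list(nonsense = 1)),
               "unknown field")
})

test_that("the printed flag table answers the documented queries", {
  db <- fresh_db()
  ex <- seed_subject_exam(db)
  t1 <- table1_fixture(); t2 <- table2_fixture()
  docs <- lapply(seq_len(nrow(t1)), function(i)
    list(subject_id = "SYNH_001", exam_id = ex, channel_name = t1$name[i],
         channel_hemisphere = t1$hemisphere[i],
         electrode_type = t1$electrode_type[i],
         roi_ids = t1$roi_id[i], roi_names = t1$roi_name[i],
         is_resected = t2$is_resected[i], is_spiking = t2$is_spiking[i],
         is_structurally_abnormal = t2$is_structurally_abnormal[i],
         is_within_soz = t2$is_within_soz[i]))
  db_insert_many(db, docs, "channel")
  expect_length(query_channels(db, list(is_resected = TRUE)), 0)
  spiking <- vapply(query_channels(db, list(is_spiking = TRUE)),
                    `[[`, "", "channel_name")
  expect_identical(spiking, paste0("LHIPP", 1:5))
  depth_left <- query_channels(db, list(electrode_type = "depth",
                                        channel_hemisphere = "left"))
  expect_length(depth_left, 10)
})
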