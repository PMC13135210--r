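reg <- code_registry()

test_that("visit classification follows code-set membership", {
  v <- data.frame(
    visit_id = c("a", "b", "c", "d"),
    diagnosis_codes = c("ARTI-V1", "", "ARTI-S1|EXC-PNEU", "ZZZ|CDX-UTI"),
    visit_type = c("problem", "problem", "problem", "well_child"),
    stringsAsFactors = FALSE)
  cl <- classify_visits(v, reg)
  expect_equal(cl$is_arti, c(TRUE, FALSE, TRUE, FALSE))
  expect_true(cl$dx_viral[1] && !cl$dx_strep[1])
  # an excluded codiagnosis does not undo ARTI membership
  expect_true(cl$is_arti[3] && cl$has_excluded_dx[3])
  expect_true(cl$has_abx_warranting_codx[4] && cl$is_well_visit[4])
  expect_identical(attr(cl, "n_unknown_codes"), 1L)
})

test_that("exposure flagging is an OR over the three evidence channels", {
  grid <- expand.grid(billing_modifier = c("", "GT", "95"),
                      place_of_service = c("11", "02"),
                      video_flag = c(0L, 1L), stringsAsFactors = FALSE)
  got <- flag_exposure(grid)
  want <- ifelse(grid$billing_modifier %in% c("GT", "95") |
                   grid$place_of_service == "02" |
                   grid$video_flag == 1L, "telemedicine", "inperson")
  expect_identical(got, want)
})

test_that("index-visit rule uses an inclusive 21-day lookback", {
  expect_identical(find_index_visits(c(0, 10, 40)), c(TRUE, FALSE, TRUE))
  expect_identical(find_index_visits(7), TRUE)
  # day 21 sits inside [t-21, t-1] of day 0; day 43 is 22 days after day 21
  expect_identical(find_index_visits(c(0, 21, 43)), c(TRUE, FALSE, TRUE))
  expect_error(find_index_visits(c(5, 3)), "sorted")
})

test_that("follow-up and antibiotic linkage windows are inclusive", {
  expect_identical(link_followups(0, c(3, 14, 15)), c(TRUE, TRUE, FALSE))
  expect_identical(link_followups(0, numeric(0)), logical(0))
  expect_identical(
    link_antibiotics(10, c(10, 12, 13, 9), systemic_flag = c(1, 1, 1, 1)),
    c(TRUE, TRUE, FALSE, FALSE))
  expect_identical(link_antibiotics(10, 11, systemic_flag = 0), FALSE)
})

test_that("toy stream builds the expected episodes", {
  tt <- toy_tables()
  cohort <- build_episodes(tt$patients, tt$visits, tt$prescriptions, reg)
  ep <- cohort$episodes
  expect_identical(sort(ep$index_visit_id), c("V01", "V04", "V06"))
  a <- ep[ep$index_visit_id == "V01", ]
  # day-13 and day-24 visits attach to the day-10 index (offsets 3 and 14)
  expect_identical(a$followup_visit_ids, "V02|V03")
  expect_identical(a$followup_offsets, "3|14")
  # same-day tie-break: V04 is the index, V05 its day-0 follow-up
  b <- ep[ep$index_visit_id == "V04", ]
  expect_identical(b$followup_visit_ids, "V05")
  expect_identical(b$followup_offsets, "0")
  # linked antibiotics: day-10 amoxicillin at offset 0; the offset-3
  # azithromycin is subsequent, not index-linked
  expect_identical(a$linked_rx_drugs, "amoxicillin")
  expect_identical(a$subsequent_rx_offsets, "3")
  # topical prescriptions never link
  expect_identical(ep$linked_rx_ids[ep$index_visit_id == "V06"], "")
  expect_identical(cohort$orphans, character(0))
})

test_that("episode construction is idempotent", {
  ehr <- generate_ehr(synth_config(n_practices = 10,
                                   mean_patients_per_practice = 40,
                                   seed = 14))
  c1 <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions, reg)
  c2 <- build_episodes(ehr$patients, ehr$visits, ehr$prescriptions, reg)
  expect_identical(c1, c2)
})

test_that("every ARTI visit is an index, a follow-up of one index, or an orphan", {
  set.seed(421)
  for (rep in 1:20) {
    n <- sample(30:120, 1)
    visits <- data.frame(
      visit_id = sprintf("V%03d", seq_len(n)),
      patient_id = sample(sprintf("p%02d", 1:12), n, replace = TRUE),
      practice_id = "P1",
      day = sample(1:150, n, replace = TRUE),
      visit_type = "problem",
      diagnosis_codes = sample(c(reg$arti_viral, reg$arti_strep), n,
                               replace = TRUE),
      billing_modifier = "", place_of_service = "11", video_flag = 0L,
      clinician_specialty = "pediatrics", stringsAsFactors = FALSE)
    patients <- data.frame(
      patient_id = unique(visits$patient_id), practice_id = "P1",
      age_years = 5, race_ethnicity = "White", census_division = "pacific",
      payer = "medicaid", language = "english", rurality = "urban",
      medical_complexity_flag = 0L, prior_well_visits = 0L,
      prior_problem_visits = 0L, prior_telemedicine = 0L,
      prior_antibiotics = 0L, stringsAsFactors = FALSE)
    rx <- data.frame(rx_id = character(0), patient_id = character(0),
                     day = integer(0), drug_name = character(0),
                     systemic_flag = integer(0))
    cohort <- build_episodes(patients, visits, rx, reg)
    ep <- cohort$episodes
    fu <- unlist(split_ids <- strsplit(ep$followup_visit_ids, "|",
                                       fixed = TRUE))
    fu <- fu[nzchar(fu)]
    groups <- list(index = ep$index_visit_id, followup = fu,
                   orphan = cohort$orphans)
    all_ids <- unname(unlist(groups))
    # partition: each ARTI visit appears in exactly one role
    expect_identical(sort(all_ids), sort(visits$visit_id))
    expect_identical(anyDuplicated(all_ids), 0L)
    # follow-up offsets always in 0..14, linked rx offsets in 0..2
    off <- as.numeric(unlist(strsplit(ep$followup_offsets, "|",
                                      fixed = TRUE)))
    expect_true(all(off >= 0 & off <= 14))
  }
})

test_that("exclusion filters drop seeded episodes in fixed order", {
  base <- toy_tables()
  ep <- build_episodes(base$patients, base$visits, base$prescriptions,
                       reg)$episodes
  ep10 <- ep[rep(1, 10), ]
  ep10$index_visit_id <- sprintf("E%02d", 1:10)
  ep10$has_excluded_dx <- c(TRUE, TRUE, rep(FALSE, 8))
  ep10$is_well_visit <- c(TRUE, FALSE, TRUE, rep(FALSE, 7))
  ep10$has_abx_warranting_codx <- c(rep(FALSE, 3), TRUE, rep(FALSE, 6))
  res <- apply_exclusions(ep10)
  expect_identical(nrow(res$episodes), 6L)
  # first-triggered reason wins: E01 counts as excluded_dx, not well visit
  expect_identical(res$tally,
                   c(excluded_dx = 2L, well_visit = 1L,
                     abx_warranting_codx = 1L))
})

test_that("complete-case filtering reports the missing fraction", {
  tt <- toy_tables()
  ep <- build_episodes(tt$patients, tt$visits, tt$prescriptions,
                       reg)$episodes
  expect_identical(complete_case_filter(ep)$excluded_fraction, 0)
  ep20 <- ep[rep(1, 20), ]
  ep20$census_division[1:2] <- NA
  res <- complete_case_filter(ep20)
  expect_identical(res$excluded_fraction, 0.1)
  expect_identical(nrow(res$episodes), 18L)
  expect_error(complete_case_filter(ep, required = "nope"), "nope")
})
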