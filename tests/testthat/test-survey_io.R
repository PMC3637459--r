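example_dir <- system.file("extdata", "worked_example", package = "shiftnet")

test_that("rosters read with canonical order, roles validated, duplicates rejected", {
  roster <- read_roster(file.path(example_dir, "roster.csv"))
  expect_equal(nrow(roster), 4)
  expect_equal(roster$person_id, c("A", "B", "C", "D"))
  expect_equal(roster$shift, rep("day", 4))

  bad_role <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,date,shift,person_id,role",
               "S1,2009-05-06,AM,X,SRN",
               "S1,2009-05-06,AM,Y,NURSE"), bad_role)
  expect_error(read_roster(bad_role), "Row 2.*NURSE")

  dup <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,date,shift,person_id,role",
               "S1,2009-05-06,AM,X,SRN",
               "S1,2009-05-06,AM,X,PCT"), dup)
  expect_error(read_roster(dup), "Row 2.*duplicate person_id")
})

test_that("AM/PM shift labels map onto day/night", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,date,shift,person_id,role",
               "S1,2009-05-06,AM,X,SRN",
               "S2,2009-05-05,PM,Y,PCT"), f)
  roster <- read_roster(f)
  expect_equal(roster$shift, c("day", "night"))
})

test_that("survey parsing accepts the 10+ category and rejects malformed rows", {
  roster <- read_roster(file.path(example_dir, "roster.csv"))
  f <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,respondent,relation,target,frequency",
               "W08_day,A,socializing,B,10+",
               "W08_day,A,socializing,C,0"), f)
  s <- read_surveys(f, roster)
  expect_equal(s$frequency, c(10L, 0L))

  bad <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,respondent,relation,target,frequency",
               "W08_day,A,socializing,B,11"), bad)
  expect_error(read_surveys(bad, roster), "0\\.\\.10")

  self <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,respondent,relation,target,frequency",
               "W08_day,A,socializing,A,3"), self)
  expect_error(read_surveys(self, roster), "same person")

  stranger <- tempfile(fileext = ".csv")
  writeLines(c("shift_id,respondent,relation,target,frequency",
               "W08_day,Z,socializing,A,3"), stranger)
  expect_error(read_surveys(stranger, roster), "not on the roster")
})

test_that("an empty survey file makes every rostered member a nonrespondent", {
  roster <- read_roster(file.path(example_dir, "roster.csv"))
  f <- tempfile(fileext = ".csv")
  writeLines("shift_id,respondent,relation,target,frequency", f)
  s <- read_surveys(f, roster)
  expect_equal(nrow(s), 0)
  nset <- build_networks(s, roster)
  expect_equal(nset$missing$problem_solving, roster$person_id)
  expect_error(dichotomize_symmetrize(nset, "problem_solving"), "all rows missing")
})

test_that("build_networks fills rows from respondents and marks nonrespondents missing", {
  roster <- tibble::tibble(shift_id = "S1", person_id = c("A", "B"),
                           role = c("SRN", "PCT"))
  resp <- tibble::tibble(shift_id = "S1", respondent = "A",
                         relation = "problem_solving", target = "B",
                         frequency = 5L)
  nset <- build_networks(resp, roster)
  W <- nset$matrices$problem_solving
  expect_equal(W["A", "B"], 5L, ignore_attr = TRUE)
  expect_true(all(is.na(W["B", ])))
  expect_equal(nset$missing$problem_solving, "B")
  # relations with no responses at all are produced as all-missing
  expect_equal(nset$missing$socializing, c("A", "B"))

  dup <- dplyr::bind_rows(resp, dplyr::mutate(resp, frequency = 7L))
  expect_error(build_networks(dup, roster), "Duplicate survey rows")
})

test_that("dichotomization applies the union rule and tracks unobservable dyads", {
  ids <- c("A", "B", "C")
  W <- matrix(0L, 3, 3, dimnames = list(ids, ids))
  W["A", "B"] <- 3L  # B never reciprocates, still a dyad tie
  diag(W) <- NA_integer_
  nset <- nset_from_matrix(W)
  dn <- dichotomize_symmetrize(nset, "problem_solving")
  expect_true(dn$adj["A", "B"])
  expect_true(dn$adj["B", "A"])
  expect_false(dn$adj["A", "C"])
  expect_equal(dn$excluded_dyads, 0L)

  # one observed direction (even a zero) keeps a dyad observable; only dyads
  # with both directions missing are excluded
  nset2 <- nset_from_matrix(W, missing = "B")
  dn2 <- dichotomize_symmetrize(nset2, "problem_solving")
  expect_true(dn2$adj["A", "B"])         # A's report survives B's nonresponse
  expect_false(dn2$adj["B", "C"])        # observable through C's zero report
  expect_equal(dn2$excluded_dyads, 0L)

  nset3 <- nset_from_matrix(W, missing = c("B", "C"))
  dn3m <- dichotomize_symmetrize(nset3, "problem_solving")
  expect_true(is.na(dn3m$adj["B", "C"])) # both directions missing
  expect_equal(dn3m$excluded_dyads, 1L)

  # idempotence: dichotomizing an already binary matrix changes nothing
  B <- (W >= 1L) * 1L
  diag(B) <- NA_integer_
  storage.mode(B) <- "integer"
  dn3 <- dichotomize_symmetrize(nset_from_matrix(B), "problem_solving")
  expect_identical(dn3$adj, dn$adj)
})

test_that("the worked-example shift yields 5 of 6 dyads present", {
  roster <- read_roster(file.path(example_dir, "roster.csv"))
  surveys <- read_surveys(file.path(example_dir, "surveys.csv"), roster)
  nset <- build_networks(surveys, roster)
  dn <- dichotomize_symmetrize(nset, "medication_advice")
  up <- dn$adj[upper.tri(dn$adj)]
  expect_equal(sum(up, na.rm = TRUE), 5)
  expect_equal(sum(!is.na(up)), 6)
  expect_false(dn$adj["A", "B"])
})

test_that("response rates reproduce the per-shift and pooled accounting", {
  rates <- response_rates(tibble::tibble(
    shift_id = c("May 6 AM", "May 27 AM", "May 13 PM"),
    completed = c(10, 13, 11),
    refused = c(1, 0, 4),
    not_located = c(3, 0, 3)
  ))
  expect_equal(rates$rate[1:3], c(71.4, 100, 61.1))
  expect_equal(rates$shift_id[4], "overall")

  # pooled rate is total/total, not the mean of the per-shift rates
  acct <- readr::read_csv(
    system.file("extdata", "response_accounting.csv", package = "shiftnet"),
    show_col_types = FALSE
  )
  all_rates <- response_rates(acct)
  pooled <- all_rates[all_rates$shift_id == "overall", ]
  expect_equal(pooled$completed, 336)
  expect_equal(pooled$rate, 82.0)
  expect_false(isTRUE(all.equal(pooled$rate,
                                mean(all_rates$rate[all_rates$shift_id != "overall"]))))

  expect_error(
    response_rates(tibble::tibble(shift_id = "x", completed = 0,
                                  refused = 0, not_located = 0)),
    "zero eligible"
  )
  expect_error(
    response_rates(tibble::tibble(shift_id = "x", completed = -1,
                                  refused = 2, not_located = 0)),
    "nonnegative"
  )
})

test_that("percentage rounding is half away from zero at one decimal", {
  # 11/18 = 61.111 -> 61.1; 19/22 = 86.3636 -> 86.4; 13/19 = 68.421 -> 68.4
  rates <- response_rates(tibble::tibble(
    shift_id = c("a", "b", "c"),
    completed = c(11, 19, 13), refused = c(4, 3, 4), not_located = c(3, 0, 2)
  ))
  expect_equal(rates$rate[1:3], c(61.1, 86.4, 68.4))
})

test_that("a generated panel round-trips exactly through write and read", {
  cfg <- synthetic_config(n_weeks = 2, seed = 404)
  ds <- generate_dataset(cfg)
  dir <- tempfile()
  write_dataset(ds, dir)
  nets <- read_dataset(dir)
  expect_setequal(names(nets), names(ds$networks))
  for (id in names(nets)) {
    expect_identical(nets[[id]]$matrices, ds$networks[[id]]$matrices)
    expect_setequal(nets[[id]]$missing$problem_solving,
                    ds$nonrespondents[[id]])
    expect_equal(nets[[id]]$roster$person_id, ds$rosters[[id]]$person_id)
    expect_equal(nets[[id]]$week, ds$networks[[id]]$week)
  }
})
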