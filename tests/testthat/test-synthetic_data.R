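test_that("rosters have the configured size, roles and deterministic membership", {
  cfg <- synthetic_config(seed = 11)
  roster <- generate_roster(cfg, week = 1, shift = "day")
  expect_equal(nrow(roster), 19)
  expect_setequal(unique(roster$role), role_types())
  expect_equal(unname(table(roster$role)[names(cfg$role_counts)]),
               unname(cfg$role_counts), ignore_attr = TRUE)

  small <- synthetic_config(role_counts = c(SRN = 2L), seed = 11)
  expect_equal(nrow(generate_roster(small, 1, "day")), 2)

  expect_identical(generate_roster(cfg, 3, "night"),
                   generate_roster(cfg, 3, "night"))
  expect_false(identical(generate_roster(cfg, 3, "night")$person_id,
                         generate_roster(cfg, 4, "night")$person_id) &&
                 identical(generate_roster(cfg, 3, "night")$person_id,
                           generate_roster(cfg, 5, "night")$person_id))

  expect_error(synthetic_config(role_counts = c(NURSE = 3L)), "Unknown role")
  expect_error(synthetic_config(nonresponse_rate = 1.4), "\\[0, 1\\]")
})

test_that("members persist across weeks (repeat-respondent structure)", {
  cfg <- synthetic_config(seed = 21)
  ids <- lapply(1:6, function(w) generate_roster(cfg, w, "day")$person_id)
  overlaps <- mapply(function(a, b) length(intersect(a, b)), ids[-6], ids[-1])
  expect_true(all(overlaps > 0))
  pool_size <- length(unique(unlist(ids)))
  expect_lte(pool_size, sum(ceiling(2.5 * cfg$role_counts)))
})

test_that("identical configs give bit-identical datasets and different seeds differ", {
  cfg <- synthetic_config(n_weeks = 2, seed = 303)
  expect_identical(generate_dataset(cfg), generate_dataset(cfg))
  cfg2 <- synthetic_config(n_weeks = 2, seed = 304)
  expect_false(identical(generate_dataset(cfg)$networks,
                         generate_dataset(cfg2)$networks))
})

test_that("generator limits: empty networks at very negative base logit, roster floor enforced", {
  cfg <- synthetic_config(base_logit = -30, overlap_lambda = 0,
                          sociability_sd = 0, seed = 5)
  roster <- generate_roster(cfg, 1, "day")
  nset <- generate_networks(cfg, roster, "day")
  for (W in nset$matrices) expect_equal(sum(W, na.rm = TRUE), 0)
  dn <- dichotomize_symmetrize(nset, "socializing")
  expect_equal(network_density(dn), 0)
  expect_error(generate_networks(cfg, roster[1, ], "day"), ">= 2 members")
})

test_that("expected density increases with base_logit", {
  dens_at <- function(bl) {
    cfg <- synthetic_config(base_logit = bl, overlap_lambda = 0, seed = 17,
                            nonresponse_rate = 0)
    mean(sapply(1:30, function(i) {
      cfg$seed <- 1000L + i
      nset <- generate_networks(cfg, generate_roster(cfg, i %% 5 + 1, "day"), "day")
      network_density(dichotomize_symmetrize(nset, "problem_solving"))
    }))
  }
  d <- sapply(c(-3, -1.5, 0), dens_at)
  expect_true(all(diff(d) > 0))
})

test_that("with zero overlap loading the relations are uncorrelated on average", {
  cfg <- synthetic_config(overlap_lambda = 0, seed = 23, nonresponse_rate = 0)
  rs <- sapply(1:200, function(i) {
    cfg$seed <- 2000L + i
    nset <- generate_networks(cfg, generate_roster(cfg, 1, "day"), "day")
    matrix_correlation(nset$matrices$problem_solving, nset$matrices$socializing)
  })
  expect_lt(abs(mean(rs)), 0.03)
})

test_that("day and night densities coincide when the night offset is zero", {
  cfg <- synthetic_config(night_density_offset = 0, overlap_lambda = 0,
                          seed = 29, nonresponse_rate = 0)
  dens <- function(shift, i) {
    cfg$seed <- 3000L + i
    nset <- generate_networks(cfg, generate_roster(cfg, 1, shift), shift)
    network_density(dichotomize_symmetrize(nset, "socializing"))
  }
  day <- sapply(1:200, function(i) dens("day", i))
  night <- sapply(1:200, function(i) dens("night", 7000 + i))
  se <- sqrt(var(day) / length(day) + var(night) / length(night))
  expect_lt(abs(mean(day) - mean(night)), 4 * se)
})

test_that("night offset raises night density when positive", {
  cfg <- synthetic_config(n_weeks = 4, night_density_offset = 1.0, seed = 31,
                          nonresponse_rate = 0)
  ds <- generate_dataset(cfg)
  m <- dataset_metrics(ds)
  byshift <- tapply(m$density_pct, m$shift, mean)
  expect_gt(byshift[["night"]], byshift[["day"]])
})

test_that("nonresponse marking is Bernoulli at the configured rate", {
  cfg0 <- synthetic_config(n_weeks = 2, nonresponse_rate = 0, seed = 37)
  ds0 <- generate_dataset(cfg0)
  expect_equal(sum(lengths(ds0$nonrespondents)), 0)

  cfg1 <- synthetic_config(n_weeks = 1, nonresponse_rate = 1, seed = 37)
  ds1 <- generate_dataset(cfg1)
  expect_equal(lengths(ds1$nonrespondents),
               sapply(ds1$rosters, nrow), ignore_attr = TRUE)
  expect_error(dichotomize_symmetrize(ds1$networks[[1]], "socializing"),
               "all rows missing")

  cfg <- synthetic_config(n_weeks = 12, nonresponse_rate = 0.18, seed = 41)
  ds <- generate_dataset(cfg)
  trials <- sum(sapply(ds$rosters, nrow))
  hits <- sum(lengths(ds$nonrespondents))
  ci <- qbinom(c(0.005, 0.995), trials, 0.18)
  expect_gte(hits, ci[1])
  expect_lte(hits, ci[2])
  # nonrespondent rows are missing, not zero; incoming columns retained
  id1 <- names(ds$nonrespondents)[lengths(ds$nonrespondents) > 0][1]
  nr <- ds$nonrespondents[[id1]][1]
  W <- ds$networks[[id1]]$matrices$problem_solving
  expect_true(all(is.na(W[nr, ])))
  respondents <- setdiff(rownames(W), ds$nonrespondents[[id1]])
  expect_false(anyNA(W[respondents, nr]))
})

test_that("inter-relation correlation rises with the overlap loading product", {
  mean_r <- function(lam) {
    cfg <- synthetic_config(overlap_lambda = lam, seed = 43, nonresponse_rate = 0)
    mean(sapply(1:40, function(i) {
      cfg$seed <- 4000L + i
      nset <- generate_networks(cfg, generate_roster(cfg, 1, "day"), "day")
      matrix_correlation(nset$matrices$problem_solving,
                         nset$matrices$socializing)
    }))
  }
  rs <- sapply(c(0, 1, 2.5), mean_r)
  expect_true(all(diff(rs) > 0))
})

test_that("calibration tunes the loading to the requested correlation", {
  cal <- calibrate_overlap(synthetic_config(seed = 47), target_r = 0.25,
                           lambda_grid = c(0, 1, 2, 3), n_shifts = 30)
  tab <- attr(cal, "calibration")
  expect_true(all(diff(tab$mean_r) > 0))
  # simulate at the calibrated loading and recover the target
  cfg <- cal
  rs <- sapply(1:60, function(i) {
    cfg$seed <- 5000L + i
    nset <- generate_networks(cfg, generate_roster(cfg, 1, "day"), "day")
    matrix_correlation(nset$matrices$problem_solving, nset$matrices$socializing)
  })
  expect_lt(abs(mean(rs) - 0.25), 0.05)
  expect_error(
    calibrate_overlap(synthetic_config(seed = 47), target_r = 0.99,
                      lambda_grid = c(0, 1), n_shifts = 10),
    "achievable range"
  )
})
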