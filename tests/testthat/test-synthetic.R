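test_that("invalid configurations are rejected with the field named", {
  expect_error(simulation_config(latent_corr = c(community_dwelling = 1.2,
                                                 institutionalized = 0.8)),
               "latent_corr")
  expect_error(simulation_config(srgh_cutpoints = c(0, -1, 1, 2)),
               "srgh_cutpoints")
  expect_error(simulation_config(prop_conditions = rbind(
    community_dwelling = c(0.5, 0.1, 0.1),
    institutionalized = c(0.3, 0.3, 0.4))), "prop_conditions")
  expect_error(simulation_config(prop_old = c(community_dwelling = 0.5)),
               "prop_old")
})

test_that("n = 0 yields an empty dataset with a complete schema", {
  bank <- default_item_bank()
  d <- simulate_survey(bank, simulation_config(n_community = 0L,
                                               n_institutionalized = 0L))
  expect_s3_class(d, "survey_dataset")
  expect_identical(nrow(d$respondents), 0L)
  expect_identical(ncol(d$responses), nrow(bank))
  expect_true(all(c("id", "population", "age_group", "gender", "conditions",
                    "education", "assisted", "weight", "srgh", "theta_bio",
                    "theta_lived") %in% colnames(d$respondents)))
})

test_that("same seed gives identical datasets; different seed differs", {
  bank <- default_item_bank()
  d1 <- simulate_survey(bank, small_sim_config(seed = 5L))
  d2 <- simulate_survey(bank, small_sim_config(seed = 5L))
  d3 <- simulate_survey(bank, small_sim_config(seed = 6L))
  expect_identical(d1$respondents, d2$respondents)
  expect_identical(d1$responses, d2$responses)
  expect_false(identical(d1$responses, d3$responses))
})

test_that("latent correlation matches the configured value at large n", {
  bank <- default_item_bank()
  cfg <- simulation_config(
    n_community = 50000L, n_institutionalized = 0L,
    latent_corr = c(community_dwelling = 0.80, institutionalized = 0.85),
    seed = 11L)
  d <- simulate_survey(bank, cfg)
  r <- cor(d$respondents$theta_bio, d$respondents$theta_lived)
  expect_lt(abs(r - 0.80), 0.02)
  expect_lt(abs(mean(d$respondents$theta_bio)), 0.02)
  expect_lt(abs(sd(d$respondents$theta_lived) - 1), 0.02)
})

test_that("dataset invariants hold: codes, weights, lived missingness", {
  bank <- default_item_bank()
  d <- simulate_survey(bank, small_sim_config(seed = 2L))
  expect_true(all(d$responses %in% c(1:4, NA)))
  expect_true(all(d$respondents$weight > 0))
  expect_true(all(d$respondents$srgh %in% 1:5))
  lived_cols <- bank$item_id[bank$form == "lived"]
  any_lived <- rowSums(!is.na(d$responses[, lived_cols])) > 0
  expect_true(all(!any_lived[!d$respondents$assisted]))
})

test_that("assistance fraction tracks the configured probability", {
  bank <- default_item_bank()
  cfg <- simulation_config(
    n_community = 20000L, n_institutionalized = 0L,
    assist_intercept = c(community_dwelling = qlogis(0.6),
                         institutionalized = 0),
    assist_slope = 0, seed = 3L)
  d <- simulate_survey(bank, cfg)
  lived_always <- bank$item_id[bank$form == "lived" &
                                 bank$administration_rule == "assisted_only"]
  frac <- mean(rowSums(!is.na(d$responses[, lived_always])) > 0)
  expect_lt(abs(frac - 0.6), 3 * sqrt(0.6 * 0.4 / 20000) + 1e-9)
})

test_that("generate_srgh marginals match the closed-form logistic model", {
  set.seed(9)
  cuts <- c(-1.5, -0.3, 0.8, 2.0)
  s <- generate_srgh(rnorm(100000), slope = 0, cutpoints = cuts)
  expect_true(all(s %in% 1:5))
  expected <- diff(c(0, plogis(cuts), 1))
  observed <- tabulate(s, 5) / 100000
  expect_true(all(abs(observed - expected) < 0.01))
  # degenerate cutpoints concentrate the mass
  set.seed(9)
  s2 <- generate_srgh(rnorm(2000), slope = 0,
                      cutpoints = c(-30, -10, 10, 30))
  expect_gt(mean(s2 == 3L), 0.999)
  expect_error(generate_srgh(0, 1, c(0, 0, 1, 2)), "cutpoints")
})

test_that("srgh orientation: more lived difficulty means worse srgh", {
  set.seed(4)
  theta <- rnorm(20000)
  s <- generate_srgh(theta, slope = 1.5, cutpoints = c(-4.2, -1.5, 0.8, 3))
  expect_gt(cor(theta, s, method = "spearman"), 0.3)
})

test_that("dif overrides replace baseline rows and shift behaviour", {
  bank <- default_item_bank()
  dif <- data.frame(form = "biological", item_id = "AUT_28_2",
                    cell = c("Young", "Old"), a = c(2, 2),
                    b1 = c(-2, 2), b2 = c(-1, 3), stringsAsFactors = FALSE)
  expect_error(simulate_survey(bank, small_sim_config(),
                               dif = transform(dif, item_id = "NOPE")),
               "dif")
  cfg <- simulation_config(n_community = 4000L, n_institutionalized = 0L,
                           seed = 8L)
  d <- simulate_survey(bank, cfg, dif = dif)
  r <- d$responses[, "AUT_28_2"]
  young <- d$respondents$age_group == "young"
  # b1 = -2 for young makes difficulty far more prevalent than b1 = +2 (old)
  expect_gt(mean(r[young] >= 2, na.rm = TRUE),
            mean(r[!young] >= 2, na.rm = TRUE) + 0.3)
})

test_that("survey dataset round-trips through CSV + sidecar", {
  bank <- default_item_bank()
  d <- simulate_survey(bank, small_sim_config(seed = 12L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_survey_csv(d, path)
  back <- read_survey_csv(path, bank)
  expect_identical(back$responses, d$responses)
  expect_equal(back$respondents$weight, d$respondents$weight)
  expect_identical(back$respondents$srgh, d$respondents$srgh)
  expect_false(back$collapsed)
})
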