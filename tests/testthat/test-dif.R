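test_that("intercept-only fit matches the multinomial closed form", {
  y <- rep(1:3, c(30, 50, 20))
  f <- fit_proportional_odds(y)
  expect_equal(f$loglik, sum(c(30, 50, 20) * log(c(30, 50, 20) / 100)),
               tolerance = 1e-6)
  expect_equal(f$mcfadden, 0, tolerance = 1e-6)
  expect_true(all(diff(f$intercepts) > 0))
})

test_that("30-observation fixture matches the grid-search oracle", {
  set.seed(61)
  x <- rnorm(30)
  u <- runif(30)
  cum <- cbind(plogis(-0.5 - 0.9 * x), plogis(0.7 - 0.9 * x))
  y <- 1L + rowSums(u > cum)
  f <- fit_proportional_odds(y, cbind(x = x))
  o <- po_grid_oracle(as.integer(factor(y)), x)
  expect_lt(abs(f$beta - o$beta), 1e-3)
  expect_lt(max(abs(f$intercepts - o$cuts)), 1e-3)
  expect_gte(f$loglik, o$loglik - 1e-6)
})

test_that("null covariate has a near-zero slope at large n", {
  set.seed(67)
  n <- 20000
  y <- sample(1:3, n, TRUE, prob = c(0.5, 0.3, 0.2))
  x <- rnorm(n)
  f <- fit_proportional_odds(y, cbind(x = x))
  expect_lt(abs(f$beta), 0.05)
  expect_error(fit_proportional_odds(y, cbind(k = rep(1, n))), "constant")
})

test_that("dif_scan flags strictly above the criterion and nests R2", {
  set.seed(71)
  n <- 4000
  theta <- rnorm(n)
  g <- rep(c("a", "b"), each = n / 2)
  pars <- data.frame(item_id = "i", a = 1.8, b1 = 0, b2 = 1)
  null_item <- simulate_grm_responses(theta, pars)[, 1]
  dif_item <- integer(n)
  sel <- g == "b"
  shifted <- pars; shifted$b1 <- shifted$b1 + 1 / 1.8
  shifted$b2 <- shifted$b2 + 1 / 1.8
  dif_item[!sel] <- simulate_grm_responses(theta[!sel], pars)[, 1]
  dif_item[sel] <- simulate_grm_responses(theta[sel], shifted)[, 1]
  scan <- dif_scan(cbind(null_item = null_item, dif_item = dif_item),
                   theta, g)
  expect_identical(scan$flag, scan$delta_r2 > 0.02)
  expect_true(scan$flag[scan$item == "dif_item"])
  expect_false(scan$flag[scan$item == "null_item"])
  expect_true(all(scan$r2_m3 >= scan$r2_m1 - 1e-9))
  expect_true(all(scan$r2_m2 >= scan$r2_m1 - 1e-9))
  # permuted labels kill the signal
  set.seed(72)
  scan_perm <- dif_scan(cbind(dif_item = dif_item), theta, sample(g))
  expect_lt(scan_perm$delta_r2, 0.005)
  # custom criterion boundary: strictly greater than
  expect_identical(
    dif_scan(cbind(dif_item = dif_item), theta, g,
             criterion = scan$delta_r2[scan$item == "dif_item"])$flag,
    FALSE)
})

test_that("dif_scan skips items constant within a group level", {
  set.seed(73)
  theta <- rnorm(500)
  g <- rep(c("a", "b"), each = 250)
  item <- simulate_grm_responses(theta, toy_params(1))[, 1]
  item[g == "b"] <- 1L
  expect_warning(scan <- dif_scan(item, theta, g, min_level_n = 10L),
                 "constant within")
  expect_true(is.na(scan$flag))
})

test_that("purification: DIF-free data yields an empty split in <= 2 rounds", {
  dat <- toy_grm_data(1500, toy_params(6), seed = 79L)
  bank <- default_item_bank()[1:6, ]
  bank$item_id <- colnames(dat$resp)
  bank$form <- "biological"; bank$domain <- "Communication"
  bank$counterpart_id <- NA_character_
  class(bank) <- c("item_bank", "data.frame")
  set.seed(80)
  rdf <- data.frame(
    id = sprintf("r%d", 1:1500),
    population = sample(c("community_dwelling", "institutionalized"),
                        1500, TRUE),
    age_group = sample(c("young", "old"), 1500, TRUE),
    gender = sample(c("female", "male"), 1500, TRUE),
    conditions = "0", education = "no_school", assisted = TRUE, weight = 1,
    srgh = 3L, stringsAsFactors = FALSE)
  d <- healthscales:::new_survey_dataset(rdf, dat$resp, bank,
                                         collapsed = TRUE)
  spec <- purify(d, "biological",
                 group_vars = c("population", "age_group", "gender"))
  expect_identical(length(spec$items), 0L)
  expect_lte(attr(spec, "iterations"), 2L)
  expect_true(attr(spec, "converged"))
})

test_that("purification splits an item with population and age DIF into
           crossed cells", {
  set.seed(83)
  n <- 4000
  rdf <- data.frame(
    id = sprintf("r%d", 1:n),
    population = sample(c("community_dwelling", "institutionalized"), n, TRUE),
    age_group = sample(c("young", "old"), n, TRUE),
    gender = "female", conditions = "0", education = "no_school",
    assisted = TRUE, weight = 1, srgh = 3L, stringsAsFactors = FALSE)
  theta <- rnorm(n)
  params <- toy_params(8)
  resp <- simulate_grm_responses(theta, params)
  # strong uniform DIF on item 1 for both population and age
  shift <- 1.2 * (rdf$population == "institutionalized") +
    1.2 * (rdf$age_group == "old")
  p2 <- plogis(params$a[1] * (theta - shift / params$a[1] - params$b2[1]))
  p12 <- plogis(params$a[1] * (theta - shift / params$a[1] - params$b1[1]))
  u <- runif(n)
  resp[, 1] <- ifelse(u < p2, 2L, ifelse(u < p12, 1L, 0L))
  bank <- default_item_bank()[1:8, ]
  bank$item_id <- colnames(resp)
  bank$form <- "biological"; bank$domain <- "Communication"
  bank$counterpart_id <- NA_character_
  class(bank) <- c("item_bank", "data.frame")
  d <- healthscales:::new_survey_dataset(rdf, resp, bank, collapsed = TRUE)
  spec <- suppressWarnings(purify(d, "biological",
                                  group_vars = c("population", "age_group")))
  expect_setequal(spec$items[["it01"]], c("age_group", "population"))
  fit <- fit_grm_em(d, "biological", split = spec)
  expect_identical(nrow(fit$params[fit$params$item_id == "it01", ]), 4L)
  # round-trip of the spec consumed by the calibrator
  path <- withr::local_tempfile(fileext = ".json")
  write_split_spec(spec, path)
  expect_identical(read_split_spec(path)$items[["it01"]],
                   spec$items[["it01"]])
})
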