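test_that("category probabilities match the logistic closed form", {
  # published parameter row: a=2.106, b=(0.690, 1.698) at theta = 0
  p <- category_probabilities(0, 2.106, c(0.690, 1.698))
  expect_equal(as.numeric(p), c(0.810, 0.163, 0.027), tolerance = 1e-2)
  expect_equal(as.numeric(p),
               c(1 - plogis(2.106 * -0.690),
                 plogis(2.106 * -0.690) - plogis(2.106 * -1.698),
                 plogis(2.106 * -1.698)), tolerance = 1e-12)
  # normalization and limits across random parameter draws
  set.seed(5)
  for (k in 1:20) {
    a <- runif(1, 0.3, 4)
    b1 <- runif(1, -2, 1.5)
    b <- c(b1, b1 + runif(1, 0.1, 2))
    th <- runif(5, -4, 4)
    pr <- category_probabilities(th, a, b)
    expect_equal(rowSums(pr), rep(1, 5), tolerance = 1e-12)
    expect_true(all(pr >= 0))
    expect_equal(as.numeric(category_probabilities(-50, a, b)), c(1, 0, 0),
                 tolerance = 1e-10)
    expect_equal(as.numeric(category_probabilities(50, a, b)), c(0, 0, 1),
                 tolerance = 1e-10)
  }
  expect_error(category_probabilities(0, 1, c(1, 0.5)), "increasing")
})

test_that("quadrature grid is a valid normal-prior discretization", {
  g <- quadrature_grid()
  expect_identical(length(g$nodes), 61L)
  expect_lt(abs(sum(g$weights) - 1), 1e-10)
  expect_true(all(diff(g$nodes) > 0))
  expect_lt(abs(sum(g$nodes * g$weights)), 1e-10)  # symmetric prior
})

test_that("EM recovers generating parameters and keeps loglik monotone", {
  dat <- toy_grm_data(5000, toy_params(10), seed = 17L)
  fit <- fit_grm_em(dat$resp)
  expect_true(fit$converged)
  expect_true(all(diff(fit$loglik_trace) > -1e-8))
  est <- fit$params[match(dat$params$item_id, fit$params$item_id), ]
  expect_true(all(abs(est$a - dat$params$a) <
                    pmax(0.15, 0.10 * dat$params$a)))
  mid <- abs(dat$params$b1) < 1.5
  expect_true(all(abs(est$b1 - dat$params$b1)[mid] < 0.1))
  expect_true(all(abs(est$b2 - dat$params$b2)[abs(dat$params$b2) < 1.5] < 0.1))
  # determinism of the deterministic fitter
  fit2 <- fit_grm_em(dat$resp)
  expect_identical(fit$params, fit2$params)
})

test_that("quadrature refinement changes fitted parameters by < 0.01", {
  dat <- toy_grm_data(2000, toy_params(8), seed = 19L)
  f1 <- fit_grm_em(dat$resp, grid = quadrature_grid(61), tol = 1e-4)
  f2 <- fit_grm_em(dat$resp, grid = quadrature_grid(122), tol = 1e-4)
  expect_lt(max(abs(f1$params$a - f2$params$a),
                abs(f1$params$b1 - f2$params$b1),
                abs(f1$params$b2 - f2$params$b2)), 0.01)
})

test_that("split items get one parameter row per cell, anchors one", {
  set.seed(23)
  n <- 3000
  rdf <- data.frame(
    id = sprintf("r%d", 1:n),
    population = sample(c("community_dwelling", "institutionalized"), n, TRUE),
    age_group = sample(c("young", "old"), n, TRUE),
    stringsAsFactors = FALSE)
  theta <- rnorm(n)
  params <- toy_params(6)
  resp <- simulate_grm_responses(theta, params)
  # item 1 behaves differently for institutionalized respondents
  inst <- rdf$population == "institutionalized"
  shifted <- params[1, ]; shifted$b1 <- shifted$b1 - 1; shifted$b2 <- shifted$b2 - 1
  resp[inst, 1] <- simulate_grm_responses(theta[inst], shifted)[, 1]
  bank <- default_item_bank()[1:6, ]
  bank$item_id <- colnames(resp); bank$form <- "biological"
  bank$domain <- "Communication"; bank$counterpart_id <- NA_character_
  class(bank) <- c("item_bank", "data.frame")
  rdf$gender <- "female"; rdf$conditions <- "0"; rdf$education <- "no_school"
  rdf$assisted <- TRUE; rdf$weight <- 1; rdf$srgh <- 3L
  d <- healthscales:::new_survey_dataset(rdf, resp, bank, collapsed = TRUE)
  spec <- split_spec(list(it01 = "population"))
  fit <- fit_grm_em(d, "biological", split = spec)
  rows1 <- fit$params[fit$params$item_id == "it01", ]
  expect_identical(nrow(rows1), 2L)
  expect_setequal(rows1$cell, c("community_dwelling", "institutionalized"))
  expect_true(all(table(fit$params$item_id[fit$params$item_id != "it01"]) == 1))
  # the institutionalized cell recovered the shifted thresholds (direction
  # and rough size; few anchor items make this a noisy constructed case)
  b1_cd <- rows1$b1[rows1$cell == "community_dwelling"]
  b1_in <- rows1$b1[rows1$cell == "institutionalized"]
  expect_lt(abs((b1_cd - b1_in) - 1), 0.4)
})

test_that("degenerate items are excluded or collapsed with a warning", {
  dat <- toy_grm_data(1000, toy_params(5), seed = 29L)
  resp <- dat$resp
  resp[, 2] <- 1L
  expect_warning(fit <- fit_grm_em(resp), "degenerate")
  expect_false("it02" %in% fit$params$item_id)
  # unobserved top category collapses the item to 2 categories
  resp2 <- dat$resp
  resp2[resp2[, 3] == 2L, 3] <- 1L
  expect_warning(fit2 <- fit_grm_em(resp2), "top category")
  expect_identical(fit2$params$n_cat[fit2$params$item_id == "it03"], 2L)
  expect_true(is.na(fit2$params$b2[fit2$params$item_id == "it03"]))
})

test_that("EAP scoring: symmetry, monotone ordering, oracle agreement", {
  grid <- quadrature_grid(301, -8, 8)
  one <- grm_fit_from_params(
    data.frame(item_id = "x", a = 1.7, b1 = -0.8, b2 = 0.8), grid)
  expect_lt(abs(eap_score(one, matrix(1L, 1, 1,
                                      dimnames = list(NULL, "x")))$theta),
            1e-10)
  # elementwise-larger patterns cannot decrease the EAP
  fitp <- grm_fit_from_params(toy_params(4), quadrature_grid())
  pats <- rbind(c(0L, 0L, 0L, 0L), c(0L, 1L, 0L, 0L), c(1L, 1L, 0L, 1L),
                c(2L, 1L, 1L, 1L), c(2L, 2L, 2L, 2L))
  colnames(pats) <- fitp$items
  th <- eap_score(fitp, pats)$theta
  expect_true(all(diff(th) >= -1e-12))
  # fine-grid EAP vs adaptive-integration oracle
  for (x in 0:2) {
    pat <- matrix(as.integer(x), 1, 1, dimnames = list(NULL, "x"))
    got <- eap_score(one, pat)
    lik <- function(t) {
      p2 <- plogis(1.7 * (t - 0.8)); p1 <- plogis(1.7 * (t + 0.8))
      c(1 - p1, p1 - p2, p2)[x + 1]
    }
    num <- integrate(function(t) t * dnorm(t) * vapply(t, lik, 1), -9, 9,
                     rel.tol = 1e-10)$value
    den <- integrate(function(t) dnorm(t) * vapply(t, lik, 1), -9, 9,
                     rel.tol = 1e-10)$value
    expect_lt(abs(got$theta - num / den), 1e-4)
  }
  # all-missing pattern cannot be scored
  expect_error(eap_score(fitp, matrix(NA_integer_, 1, 4,
                                      dimnames = list(NULL, fitp$items))),
               "no observed response")
})

test_that("EAP recovers the generating trait on model-true data", {
  dat <- toy_grm_data(2000, toy_params(20), seed = 37L)
  fit <- fit_grm_em(dat$resp)
  sc <- eap_score(fit, dat$resp)
  expect_gte(cor(sc$theta, dat$theta), 0.9)
  expect_true(all(sc$se > 0))
})

test_that("rescaling hits the 0/100 endpoints and preserves order", {
  expect_equal(rescale_scores(c(-2, 0, 2)), c(0, 50, 100))
  set.seed(41)
  x <- rnorm(50)
  s <- rescale_scores(x)
  expect_equal(range(s), c(0, 100))
  expect_identical(order(s), order(x))
  expect_error(rescale_scores(rep(1, 5)), "distinct")
  expect_error(rescale_scores(c(1, NA)), "finite")
})

test_that("fitted score correlation mirrors the configured latent
           correlation after disattenuation", {
  # classical attenuation: cor(EAP_b, EAP_l) ~ rho * sqrt(rel_b * rel_l);
  # the correction uses model-internal reliabilities only
  cfg <- simulation_config(
    n_community = 5000L, n_institutionalized = 0L,
    latent_corr = c(community_dwelling = 0.80, institutionalized = 0.85),
    assist_intercept = c(community_dwelling = 50, institutionalized = 50),
    seed = 21L)
  bank <- default_item_bank()
  d <- simulate_survey(bank, cfg)
  d <- suppressMessages(apply_eligibility_filter(
    collapse_categories(drop_sensory_items(d))))
  fb <- suppressWarnings(fit_grm_em(d, "biological"))
  fl <- suppressWarnings(fit_grm_em(d, "lived"))
  eb <- eap_score(fb, d)
  el <- eap_score(fl, d)
  rel <- function(e) var(e$theta) / (var(e$theta) + mean(e$se^2))
  raw <- cor(eb$theta, el$theta)
  corrected <- raw / sqrt(rel(eb) * rel(el))
  expect_lt(abs(corrected - 0.80), 0.05)
  # raw correlation sits at the attenuation-predicted value
  expect_lt(abs(raw - 0.80 * sqrt(rel(eb) * rel(el))), 0.05)
})
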