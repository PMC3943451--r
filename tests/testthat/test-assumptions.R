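test_that("polychoric estimator recovers known correlations", {
  set.seed(3)
  n <- 50000
  z1 <- rnorm(n)
  z2 <- 0.5 * z1 + sqrt(0.75) * rnorm(n)
  x <- findInterval(z1, 0)
  y <- findInterval(z2, c(-0.5, 0.7))
  expect_lt(abs(healthscales:::polychoric_pair(x, y) - 0.5), 0.03)
  y_ind <- findInterval(rnorm(n), c(-0.5, 0.7))
  expect_lt(abs(healthscales:::polychoric_pair(x, y_ind)), 0.02)
  # perfect concordance clips at the boundary
  expect_gte(healthscales:::polychoric_pair(x, x), 0.998)
})

test_that("pbvnorm matches the product rule and symmetry", {
  # rho = 0 factorizes; the estimator's likelihood rests on this primitive
  expect_equal(healthscales:::pbvnorm(0.3, -0.2, 0), pnorm(0.3) * pnorm(-0.2),
               tolerance = 1e-10)
  expect_equal(healthscales:::pbvnorm(0.5, 1.1, 0.6),
               healthscales:::pbvnorm(1.1, 0.5, 0.6), tolerance = 1e-10)
  # against a fine Monte Carlo check
  set.seed(1)
  z1 <- rnorm(2e5); z2 <- 0.6 * z1 + 0.8 * rnorm(2e5)
  mc <- mean(z1 <= 0.5 & z2 <= 1.1)
  expect_lt(abs(healthscales:::pbvnorm(0.5, 1.1, 0.6) - mc), 0.005)
})

test_that("one-factor loadings reproduce closed forms", {
  p <- 10
  R <- matrix(0.49, p, p); diag(R) <- 1
  expect_equal(unname(one_factor_loadings(R)), rep(0.7, p), tolerance = 1e-6)
  R3 <- diag(3)
  R3[1, 2] <- R3[2, 1] <- 0.72
  R3[1, 3] <- R3[3, 1] <- 0.63
  R3[2, 3] <- R3[3, 2] <- 0.56
  expect_equal(unname(one_factor_loadings(R3)), c(0.9, 0.8, 0.7),
               tolerance = 1e-6)
  expect_error(one_factor_loadings(diag(5)), "degenerate")
})

test_that("eigenvalue ratio: identity, equicorrelation, reorder invariance", {
  expect_equal(eigenvalue_ratio(diag(7)), 1)
  p <- 10
  R <- matrix(0.5, p, p); diag(R) <- 1
  expect_equal(eigenvalue_ratio(R), 11, tolerance = 1e-8)
  set.seed(2)
  lam <- runif(6, 0.4, 0.9)
  R2 <- tcrossprod(lam); diag(R2) <- 1
  perm <- sample(6)
  expect_equal(eigenvalue_ratio(R2), eigenvalue_ratio(R2[perm, perm]),
               tolerance = 1e-10)
})

test_that("local dependence flags follow the strict threshold and symmetry", {
  lam <- c(0.7, 0.7, 0.7, 0.7)
  R <- tcrossprod(lam); diag(R) <- 1
  R[1, 2] <- R[2, 1] <- lam[1] * lam[2] + 0.25  # residual 0.25
  R[3, 4] <- R[4, 3] <- lam[3] * lam[4] + 0.20  # residual exactly 0.20
  colnames(R) <- rownames(R) <- paste0("i", 1:4)
  flags <- flag_local_dependence(R, loadings = stats::setNames(lam, colnames(R)))
  expect_identical(nrow(flags), 1L)
  expect_setequal(c(flags$item_i, flags$item_j), c("i1", "i2"))
  expect_equal(flags$residual, 0.25)
  # symmetric under item reordering
  perm <- c(2, 1, 4, 3)
  f2 <- flag_local_dependence(R[perm, perm],
                              loadings = stats::setNames(lam, colnames(R))[perm])
  expect_setequal(c(f2$item_i, f2$item_j), c("i1", "i2"))
  # exact one-factor structure: no flags
  R0 <- tcrossprod(lam); diag(R0) <- 1
  colnames(R0) <- rownames(R0) <- paste0("i", 1:4)
  expect_identical(nrow(flag_local_dependence(
    R0, stats::setNames(lam, colnames(R0)))), 0L)
  # retain override flips the proposed drop
  lam2 <- stats::setNames(c(0.8, 0.6, 0.7, 0.7), colnames(R))
  f3 <- flag_local_dependence(R, lam2)
  expect_identical(f3$drop, "i2")
  f4 <- flag_local_dependence(R, lam2, retain = "i2")
  expect_identical(f4$drop, "i1")
})

test_that("unidimensional locally-independent data rarely gets flagged", {
  dat <- toy_grm_data(5000, toy_params(12), seed = 7L)
  pc <- polychoric_matrix(dat$resp)
  lam <- one_factor_loadings(pc)
  flags <- flag_local_dependence(pc, lam)
  expect_lte(nrow(flags), ceiling(0.05 * choose(12, 2)))
  expect_gt(eigenvalue_ratio(pc), 3)
  verdicts <- vapply(colnames(dat$resp), function(it)
    monotonicity_check(dat$resp, it)$verdict, character(1))
  expect_lte(sum(verdicts == "non-monotone"), ceiling(0.05 * 12))
})

test_that("a shared nuisance factor is caught by the residual screen", {
  # loadings live on the latent-response (polychoric) scale, where the 0.2
  # residual criterion is defined: items are discretized normal propensities
  # with a 0.7 general loading; items 1-2 additionally share a 0.6 nuisance
  # loading, so their model residual is 0.36
  cuts <- c(-0.2, 0.9)
  for (seed in c(31L, 32L, 33L)) {
    set.seed(seed)
    n <- 5000
    theta <- rnorm(n)
    nuis <- rnorm(n)
    resp <- sapply(1:8, function(j) {
      ystar <- if (j <= 2)
        0.7 * theta + 0.6 * nuis + sqrt(1 - 0.49 - 0.36) * rnorm(n)
      else 0.7 * theta + sqrt(1 - 0.49) * rnorm(n)
      findInterval(ystar, cuts)
    })
    colnames(resp) <- sprintf("it%02d", 1:8)
    pc <- polychoric_matrix(resp)
    flags <- flag_local_dependence(pc, one_factor_loadings(pc))
    hit <- any(flags$item_i == "it01" & flags$item_j == "it02")
    expect_true(hit, label = sprintf("nuisance pair flagged (seed %d)", seed))
  }
})

test_that("monotonicity check flags constructed violations only", {
  dat <- toy_grm_data(10000, toy_params(10), seed = 9L)
  ok <- monotonicity_check(dat$resp, "it05")
  expect_identical(ok$verdict, "monotone")
  expect_identical(ok$n_bins, 10L)
  # an item anticorrelated with the rest-score
  bad <- dat$resp
  bad[, "it05"] <- simulate_grm_responses(-dat$theta, dat$params[5, ])[, 1]
  expect_identical(monotonicity_check(bad, "it05")$verdict, "non-monotone")
  # constant rest-score cannot be evaluated
  const <- cbind(itA = dat$resp[, 1], itB = rep(1L, 10000))
  expect_identical(monotonicity_check(const, "itA")$verdict,
                   "cannot-evaluate")
  # small samples reduce the bin count with a log line
  expect_message(
    res <- monotonicity_check(dat$resp[1:90, ], "it05"), "reduced")
  expect_lt(res$n_bins, 10L)
})

test_that("check_assumptions assembles a coherent report", {
  dat <- toy_grm_data(2000, toy_params(8), seed = 13L)
  bank <- default_item_bank()
  small_bank <- bank[1:8, ]
  small_bank$item_id <- colnames(dat$resp)
  small_bank$form <- "biological"
  small_bank$domain <- "Communication"
  small_bank$counterpart_id <- NA_character_
  class(small_bank) <- c("item_bank", "data.frame")
  rdf <- data.frame(id = sprintf("r%d", 1:2000),
                    population = "community_dwelling", age_group = "young",
                    gender = "female", conditions = "0",
                    education = "university", assisted = TRUE, weight = 1,
                    srgh = 3L, stringsAsFactors = FALSE)
  d <- healthscales:::new_survey_dataset(rdf, dat$resp, small_bank,
                                         collapsed = TRUE)
  rep <- suppressMessages(check_assumptions(d, "biological"))
  expect_s3_class(rep, "assumption_report")
  expect_setequal(c(rep$retained, rep$excluded), colnames(dat$resp))
  expect_true(rep$unidimensional)
  path <- withr::local_tempfile(fileext = ".json")
  write_assumption_report(rep, path)
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(obj$eigenvalue_ratio, rep$eigenvalue_ratio)
})
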