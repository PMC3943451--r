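# Synthetic survey generator: emulates the structure of the 2008 Spanish
# disability survey (two residence populations, correlated biological and
# lived latent traits, assistance-dependent administration of lived items,
# SRGH driven by lived health) with fully known ground truth.

#' Configuration of the synthetic survey generator
#'
#' The defaults state the emulated world: population sizes, the
#' latent-trait correlation per population (0.79 community-dwelling / 0.85
#' institutionalized), demographic mixing proportions taken from the
#' published sample description, an assistance-probability model (more
#' lived-health difficulty makes assistance more likely, institutionalized
#' respondents almost always receive it), and a proportional-odds SRGH model
#' driven by the lived trait.
#'
#' @param n_community,n_institutionalized respondents per population.
#' @param latent_corr named vector: Pearson correlation of the biological
#'   and lived latent traits, per population; each in (-1, 1).
#' @param prop_old,prop_female named vectors of mixing proportions per
#'   population (age > 65; female).
#' @param prop_conditions 2 x 3 matrix of health-condition-count mixing
#'   proportions (rows `community_dwelling`, `institutionalized`; columns
#'   `"0"`, `"1-2"`, `">2"`), rows summing to 1.
#' @param assist_intercept named vector, logit of assistance probability at
#'   average lived difficulty, per population.
#' @param assist_slope logit increase in assistance probability per unit of
#'   lived-trait difficulty.
#' @param srgh_slope slope of SRGH on the lived trait (logits per theta
#'   unit); `srgh_bio_mix` mixes in the biological trait (0 = lived only).
#' @param srgh_cutpoints 4 strictly increasing proportional-odds cutpoints
#'   on the scale of `plogis(c_k - slope * theta)`.
#' @param moderate_share when a collapsed response is "moderate/severe",
#'   probability that the raw code is 2 (moderate) rather than 3 (severe).
#' @param subgroup_admin_prob administration probability of subgroup-only
#'   items (driving, menstrual care).
#' @param weight_sdlog log-normal sd of the positive sampling weights.
#' @param seed integer seed; every stochastic output of the generator is a
#'   pure function of (config, seed).
#' @return A validated list of class `simulation_config`.
#' @export
simulation_config <- function(
    n_community = 1000L, n_institutionalized = 500L,
    latent_corr = c(community_dwelling = 0.79, institutionalized = 0.85),
    prop_old = c(community_dwelling = 0.585, institutionalized = 0.82),
    prop_female = c(community_dwelling = 0.633, institutionalized = 0.655),
    prop_conditions = rbind(community_dwelling = c(0.124, 0.501, 0.375),
                            institutionalized = c(0.123, 0.686, 0.191)),
    assist_intercept = c(community_dwelling = -0.2, institutionalized = 2.0),
    assist_slope = 1.0,
    srgh_slope = 1.5, srgh_bio_mix = 0,
    srgh_cutpoints = c(-4.2, -1.5, 0.8, 3.0),
    moderate_share = 0.7,
    subgroup_admin_prob = 0.4,
    weight_sdlog = 0.5,
    seed = 1L) {
  check_count(n_community, "n_community")
  check_count(n_institutionalized, "n_institutionalized")
  pops <- c("community_dwelling", "institutionalized")
  for (nm in c("latent_corr", "prop_old", "prop_female", "assist_intercept")) {
    v <- get(nm)
    if (!all(pops %in% names(v)))
      stop_invalid(nm, "must be named for both populations")
  }
  if (any(abs(latent_corr) >= 1))
    stop_invalid("latent_corr", "must lie strictly inside (-1, 1)")
  check_prob(prop_old, "prop_old")
  check_prob(prop_female, "prop_female")
  if (!all(abs(rowSums(prop_conditions) - 1) < 1e-8))
    stop_invalid("prop_conditions", "rows must sum to 1")
  if (any(diff(srgh_cutpoints) <= 0))
    stop_invalid("srgh_cutpoints", "must be strictly increasing")
  check_number(srgh_slope, "srgh_slope")
  check_number(srgh_bio_mix, "srgh_bio_mix", lower = 0, upper = 1)
  check_prob(moderate_share, "moderate_share")
  check_prob(subgroup_admin_prob, "subgroup_admin_prob")
  check_number(weight_sdlog, "weight_sdlog", lower = 0)
  check_count(seed, "seed")
  structure(list(
    n_community = as.integer(n_community),
    n_institutionalized = as.integer(n_institutionalized),
    latent_corr = latent_corr, prop_old = prop_old,
    prop_female = prop_female, prop_conditions = prop_conditions,
    assist_intercept = assist_intercept, assist_slope = assist_slope,
    srgh_slope = srgh_slope, srgh_bio_mix = srgh_bio_mix,
    srgh_cutpoints = srgh_cutpoints, moderate_share = moderate_share,
    subgroup_admin_prob = subgroup_admin_prob, weight_sdlog = weight_sdlog,
    seed = as.integer(seed)), class = "simulation_config")
}

# Table-1-style education mixing proportions (inert covariate downstream).
education_levels <- c("no_school", "primary_incomplete", "primary_complete",
                      "secondary_first", "secondary_finished",
                      "professional_medium", "professional_superior",
                      "university")
education_probs <- rbind(
  community_dwelling = c(0.119, 0.356, 0.288, 0.093, 0.053, 0.028, 0.017, 0.046),
  institutionalized = c(0.218, 0.453, 0.234, 0.030, 0.031, 0.013, 0.005, 0.015))

#' Ground-truth item parameters for every bank item
#'
#' Items present in [grm_reference_parameters()] take their published-style
#' values (including group-split cells); the remaining items (sensory
#' placeholders, subgroup-only items, and biological items outside the final
#' scale) receive deterministic plausible values: discrimination cycling
#' over \{1.2, 1.8, 2.4\} and thresholds spread over the usual difficulty
#' range.
#'
#' @param bank an [default_item_bank()] style `item_bank`.
#' @return data frame `form`, `item_id`, `cell`, `a`, `b1`, `b2`.
#' @export
default_item_parameters <- function(bank) {
  ref <- grm_reference_parameters()
  missing_ids <- setdiff(bank$item_id, ref$item_id)
  if (length(missing_ids) == 0L) return(ref)
  k <- seq_along(missing_ids)
  fill <- data.frame(
    form = bank$form[match(missing_ids, bank$item_id)],
    item_id = missing_ids, cell = "common",
    a = c(1.2, 1.8, 2.4)[(k %% 3L) + 1L],
    b1 = -0.5 + 1.5 * ((k %% 5L) / 4),
    b2 = NA_real_, stringsAsFactors = FALSE)
  fill$b2 <- fill$b1 + 1.0
  out <- rbind(ref, fill)
  rownames(out) <- NULL
  out
}

#' Draw SRGH from a proportional-odds model on the lived trait
#'
#' `P(SRGH <= k | theta) = plogis(cutpoints[k] - slope * theta)`, with SRGH
#' coded 1 (very good) ... 5 (very bad), so greater lived-health difficulty
#' implies worse SRGH on average when `slope > 0`.
#'
#' @param theta numeric vector of lived-trait (difficulty) values.
#' @param slope proportional-odds slope.
#' @param cutpoints 4 strictly increasing cutpoints.
#' @return integer vector in 1..5; uses the current RNG state.
#' @export
generate_srgh <- function(theta, slope, cutpoints) {
  if (length(cutpoints) != 4L || any(diff(cutpoints) <= 0))
    stop_invalid("cutpoints", "must be 4 strictly increasing values")
  check_number(slope, "slope")
  n <- length(theta)
  cum <- vapply(cutpoints, function(ck) plogis(ck - slope * theta),
                numeric(n))
  cum <- matrix(cum, nrow = n)
  u <- runif(n)
  as.integer(1L + rowSums(u > cum))
}

#' Simulate an EDAD-like survey dataset
#'
#' Draws respondents for both populations with bivariate-normal latent
#' traits (standard-normal margins, configured correlation), generates raw
#' 4-category item responses under the graded response model using each
#' respondent's demographic cell parameters, masks lived items for
#' respondents not using assistance, draws SRGH from the lived trait and
#' positive sampling weights, and keeps the latent truth block.
#'
#' @param bank an `item_bank`.
#' @param config a [simulation_config()].
#' @param dif optional data frame of per-cell parameter overrides (columns
#'   `form`, `item_id`, `cell`, `a`, `b1`, `b2`); rows replace the item's
#'   baseline rows. Every `item_id` must exist in the bank.
#' @param item_params baseline ground-truth parameters, default
#'   [default_item_parameters()] of the bank (which already includes the
#'   reference group-split cells).
#' @return A `survey_dataset`: list with `respondents` (covariates, weight,
#'   SRGH, assistance, latent truth), `responses` (raw 1-4 codes, `NA` when
#'   not administered), `bank`, and `collapsed = FALSE`.
#' @export
simulate_survey <- function(bank, config, dif = NULL,
                            item_params = default_item_parameters(bank)) {
  validate_item_bank(bank)
  stopifnot(inherits(config, "simulation_config"))
  truth <- item_params
  if (!is.null(dif)) {
    if (!all(dif$item_id %in% bank$item_id))
      stop_invalid("dif", "references item ids absent from the bank")
    drop <- truth$item_id %in% dif$item_id & truth$form %in% dif$form
    truth <- rbind(truth[!drop, ], dif[, colnames(truth)])
  }
  set.seed(config$seed)
  n <- config$n_community + config$n_institutionalized
  population <- rep(c("community_dwelling", "institutionalized"),
                    c(config$n_community, config$n_institutionalized))
  resp_df <- data.frame(
    id = if (n > 0L) sprintf("R%05d", seq_len(n)) else character(0),
    population = population, stringsAsFactors = FALSE)
  responses <- matrix(NA_integer_, n, nrow(bank),
                      dimnames = list(NULL, bank$item_id))
  if (n == 0L) {
    resp_df$age_group <- character(0)
    resp_df$gender <- character(0)
    resp_df$conditions <- character(0)
    resp_df$education <- character(0)
    resp_df$assisted <- logical(0)
    resp_df$weight <- numeric(0)
    resp_df$srgh <- integer(0)
    resp_df$theta_bio <- numeric(0)
    resp_df$theta_lived <- numeric(0)
    return(new_survey_dataset(resp_df, responses, bank, config))
  }
  resp_df$age_group <- ifelse(
    runif(n) < config$prop_old[population], "old", "young")
  resp_df$gender <- ifelse(
    runif(n) < config$prop_female[population], "female", "male")
  cond_lv <- c("0", "1-2", ">2")
  resp_df$conditions <- vapply(seq_len(n), function(i) {
    sample(cond_lv, 1L, prob = config$prop_conditions[population[i], ])
  }, character(1))
  resp_df$education <- vapply(seq_len(n), function(i) {
    sample(education_levels, 1L, prob = education_probs[population[i], ])
  }, character(1))
  # correlated standard-normal latent traits, per population
  rho <- config$latent_corr[population]
  z1 <- rnorm(n)
  z2 <- rnorm(n)
  resp_df$theta_bio <- z1
  resp_df$theta_lived <- rho * z1 + sqrt(1 - rho^2) * z2
  resp_df$assisted <- runif(n) < plogis(
    config$assist_intercept[population] +
      config$assist_slope * resp_df$theta_lived)

  for (j in seq_len(nrow(bank))) {
    id <- bank$item_id[j]
    form <- bank$form[j]
    theta <- if (form == "biological") resp_df$theta_bio else resp_df$theta_lived
    rows <- truth[truth$item_id == id & truth$form == form, , drop = FALSE]
    if (nrow(rows) == 0L)
      stop_invalid("item_params", sprintf("no parameters for item %s", id))
    collapsed <- integer(n)
    for (r in seq_len(nrow(rows))) {
      sel <- cell_applies(rows$cell[r], resp_df$population, resp_df$age_group)
      if (!any(sel)) next
      p2 <- plogis(rows$a[r] * (theta[sel] - rows$b2[r]))
      p12 <- plogis(rows$a[r] * (theta[sel] - rows$b1[r]))
      u <- runif(sum(sel))
      collapsed[sel] <- ifelse(u < p2, 2L, ifelse(u < p12, 1L, 0L))
    }
    # expand collapsed {0,1,2} to raw codes {1, 2/3, 4}
    raw <- ifelse(collapsed == 0L, 1L,
                  ifelse(collapsed == 2L, 4L,
                         ifelse(runif(n) < config$moderate_share, 2L, 3L)))
    administered <- rep(TRUE, n)
    if (bank$administration_rule[j] %in% c("assisted_only"))
      administered <- resp_df$assisted
    if (bank$administration_rule[j] == "subgroup_only") {
      administered <- runif(n) < config$subgroup_admin_prob
      if (grepl("^AUT_31", id)) administered <- administered &
          resp_df$gender == "female"
      if (form == "lived") administered <- administered & resp_df$assisted
    }
    raw[!administered] <- NA_integer_
    responses[, j] <- raw
  }
  resp_df$weight <- rlnorm(n, meanlog = 0, sdlog = config$weight_sdlog)
  srgh_driver <- (1 - config$srgh_bio_mix) * resp_df$theta_lived +
    config$srgh_bio_mix * resp_df$theta_bio
  resp_df$srgh <- generate_srgh(srgh_driver, config$srgh_slope,
                                config$srgh_cutpoints)
  new_survey_dataset(resp_df, responses, bank, config)
}

new_survey_dataset <- function(respondents, responses, bank, config = NULL,
                               collapsed = FALSE) {
  structure(list(respondents = respondents, responses = responses,
                 bank = bank, config = config, collapsed = collapsed),
            class = "survey_dataset")
}

#' @export
print.survey_dataset <- function(x, ...) {
  cat(sprintf("<survey_dataset> %d respondents x %d items (%s codes)\n",
              nrow(x$respondents), ncol(x$responses),
              if (x$collapsed) "collapsed 0-2" else "raw 1-4"))
  if (nrow(x$respondents) > 0)
    cat(sprintf("  populations: %s\n",
                paste(sprintf("%s=%d", names(table(x$respondents$population)),
                              table(x$respondents$population)),
                      collapse = ", ")))
  invisible(x)
}

#' Write / read a survey dataset as CSV plus a JSON sidecar
#'
#' One row per respondent; response columns named by `item_id`, missing
#' responses as empty fields. The sidecar records the generator
#' configuration, seed, collapse state and a truth summary.
#'
#' @param data a `survey_dataset`.
#' @param path CSV path; the sidecar is written to `paste0(path, ".json")`.
#' @param bank the `item_bank` to attach on reading.
#' @return `read_survey_csv()` returns the `survey_dataset`.
#' @export
write_survey_csv <- function(data, path) {
  stopifnot(inherits(data, "survey_dataset"))
  df <- cbind(data$respondents, as.data.frame(data$responses))
  write.csv(df, path, row.names = FALSE, na = "")
  sidecar <- list(
    collapsed = data$collapsed,
    n = nrow(data$respondents),
    config = if (!is.null(data$config)) unclass(data$config),
    truth_summary = if (nrow(data$respondents) > 0) list(
      mean_theta_bio = mean(data$respondents$theta_bio),
      mean_theta_lived = mean(data$respondents$theta_lived),
      cor_bio_lived = if (nrow(data$respondents) > 2)
        cor(data$respondents$theta_bio, data$respondents$theta_lived)))
  jsonlite::write_json(sidecar, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA, na = "null")
  invisible(path)
}

#' @rdname write_survey_csv
#' @export
read_survey_csv <- function(path, bank) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  sidecar_path <- paste0(path, ".json")
  collapsed <- FALSE
  if (file.exists(sidecar_path)) {
    sc <- jsonlite::read_json(sidecar_path, simplifyVector = TRUE)
    collapsed <- isTRUE(sc$collapsed)
  }
  item_cols <- intersect(bank$item_id, colnames(df))
  responses <- as.matrix(df[, item_cols, drop = FALSE])
  storage.mode(responses) <- "integer"
  respondents <- df[, setdiff(colnames(df), item_cols), drop = FALSE]
  bank <- bank[bank$item_id %in% item_cols, , drop = FALSE]
  class(bank) <- c("item_bank", "data.frame")
  new_survey_dataset(respondents, responses, bank, collapsed = collapsed)
}
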