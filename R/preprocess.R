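# Recoding and eligibility rules: sensory items out, 4 -> 3 category
# collapse, keep only respondents with at least one observed biological
# difficulty, weighted sample description.

#' Remove sensory-domain items
#'
#' Vision and hearing questions do not distinguish capacity from
#' performance and are excluded before any analysis. Column-only operation:
#' respondents are untouched. Idempotent.
#'
#' @param data a `survey_dataset`.
#' @param bank item bank matching the data columns (default: the bank
#'   stored in the dataset).
#' @return the dataset without Sensory-domain columns.
#' @export
drop_sensory_items <- function(data, bank = data$bank) {
  stopifnot(inherits(data, "survey_dataset"))
  if (!all(colnames(data$responses) %in% bank$item_id))
    stop_invalid("bank", "dataset has columns unknown to the bank")
  sensory <- bank$item_id[bank$domain == "Sensory"]
  keep <- !colnames(data$responses) %in% sensory
  data$responses <- data$responses[, keep, drop = FALSE]
  data$bank <- bank[bank$domain != "Sensory", , drop = FALSE]
  class(data$bank) <- c("item_bank", "data.frame")
  data
}

#' Collapse the raw 4-category responses to 3 categories
#'
#' The raw codes 2 ("moderate difficulty") and 3 ("severe difficulty") have
#' low frequency and are merged: mapping `1 -> 0` (none/little), `2,3 -> 1`
#' (moderate/severe), `4 -> 2` (cannot do). Missing stays missing. Applying
#' the collapse twice is rejected.
#'
#' @param data a `survey_dataset` with raw 1-4 codes.
#' @return the dataset with responses in `{0, 1, 2, NA}` and
#'   `collapsed = TRUE`.
#' @export
collapse_categories <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  if (isTRUE(data$collapsed))
    stop_invalid("data", "responses are already collapsed")
  x <- data$responses
  bad <- !(x %in% c(1L, 2L, 3L, 4L)) & !is.na(x)
  if (any(bad))
    stop_invalid("data", "raw responses must be 1, 2, 3, 4 or missing")
  map <- c(`1` = 0L, `2` = 1L, `3` = 1L, `4` = 2L)
  y <- matrix(map[as.character(x)], nrow = nrow(x),
              dimnames = dimnames(x))
  storage.mode(y) <- "integer"
  data$responses <- y
  data$collapsed <- TRUE
  data
}

#' Eligibility filter: at least one biological difficulty
#'
#' Retains exactly the respondents with at least one collapsed biological
#' response in `{1, 2}` (moderate/severe or cannot). Respondents whose
#' biological responses are all 0 or all missing are dropped: the rule
#' requires an observed difficulty.
#'
#' @param data a collapsed `survey_dataset` (sensory items already removed).
#' @return the filtered dataset; attribute `"retained"` holds the retained
#'   count per population.
#' @export
apply_eligibility_filter <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  if (!isTRUE(data$collapsed))
    stop_invalid("data", "apply the category collapse first")
  bio <- intersect(bank_items(data$bank, "biological"),
                   colnames(data$responses))
  has_diff <- rowSums(data$responses[, bio, drop = FALSE] >= 1L,
                      na.rm = TRUE) > 0
  data$respondents <- data$respondents[has_diff, , drop = FALSE]
  data$responses <- data$responses[has_diff, , drop = FALSE]
  rownames(data$respondents) <- NULL
  retained <- table(factor(data$respondents$population))
  message(sprintf("eligibility filter: retained %s",
                  paste(sprintf("%s=%d", names(retained), retained),
                        collapse = ", ")))
  attr(data, "retained") <- retained
  data
}

#' Weighted descriptive table of the two study populations
#'
#' Weighted percentages by population for gender, age group, education,
#' SRGH distribution and health-condition-count groups (the published
#' sample-description layout). Percentages within a categorical block sum
#' to 100 per population.
#'
#' @param data a `survey_dataset` with positive sampling weights.
#' @return data frame with columns `population`, `block`, `level`,
#'   `percent`, plus the weighted/unweighted N per population as attribute
#'   `"n"`.
#' @export
weighted_descriptives <- function(data) {
  stopifnot(inherits(data, "survey_dataset"))
  r <- data$respondents
  if (any(r$weight <= 0) || anyNA(r$weight))
    stop_invalid("weights", "sampling weights must be positive")
  blocks <- list(
    gender = factor(r$gender, c("female", "male")),
    age_group = factor(r$age_group, c("young", "old")),
    education = factor(r$education, education_levels),
    srgh = factor(r$srgh, 1:5,
                  labels = c("very good", "good", "fair", "bad", "very bad")),
    conditions = factor(r$conditions, c("0", "1-2", ">2")))
  out <- NULL
  for (pop in sort(unique(r$population))) {
    sel <- r$population == pop
    w <- r$weight[sel]
    for (bn in names(blocks)) {
      f <- blocks[[bn]][sel]
      tw <- tapply(w, f, sum, default = 0)
      pct <- 100 * tw / sum(w[!is.na(f)])
      out <- rbind(out, data.frame(
        population = pop, block = bn, level = names(pct),
        percent = as.numeric(pct), stringsAsFactors = FALSE))
    }
  }
  rownames(out) <- NULL
  attr(out, "n") <- table(r$population)
  out
}
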