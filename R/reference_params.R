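# Published-style reference calibration of the two scales, used as the
# default ground truth of the synthetic-data generator and for parameter
# recovery experiments. Parameters are on the collapsed 3-category scale
# (0 none/little, 1 moderate/severe, 2 cannot) in the logistic metric
# (D = 1): P(X >= k | theta) = plogis(a * (theta - b_k)).
#
# Items calibrated separately for demographic groups carry one row per
# calibration cell ("Split in"); all other items have a single "common" row.

#' Reference graded-response-model parameters for the two scales
#'
#' The package's built-in calibration of the biological health scale (26
#' items) and lived health scale (19 items): per item a discrimination `a`
#' and two thresholds `b1 < b2` on the latent (theta) scale, with separate
#' rows for the demographic cells in which an item showed differential item
#' functioning (study population and/or age group). These values serve as
#' the default ground truth for [simulate_survey()] and for
#' simulate-and-refit recovery experiments.
#'
#' @return A data frame with columns `form`, `item_id`, `cell`, `a`, `b1`,
#'   `b2`. `cell` is `"common"` for items without group-specific
#'   calibration, otherwise one of `"Young"`, `"Old"`, `"Institutionalized"`,
#'   `"Community-dwelling"`, or a population-by-age combination such as
#'   `"Institutionalized young"`.
#' @examples
#' ref <- grm_reference_parameters()
#' subset(ref, item_id == "MOV_21_2")
#' @export
grm_reference_parameters <- function() {
  b <- function(item_id, cell, a, b1, b2)
    data.frame(form = "biological", item_id = item_id, cell = cell,
               a = a, b1 = b1, b2 = b2, stringsAsFactors = FALSE)
  l <- function(item_id, cell, a, b1, b2)
    data.frame(form = "lived", item_id = item_id, cell = cell,
               a = a, b1 = b1, b2 = b2, stringsAsFactors = FALSE)
  out <- rbind(
    # --- biological health scale ---
    b("COM_8_2",  "Young", 2.106, 0.690, 1.698),
    b("COM_8_2",  "Old",   2.681, 1.011, 2.054),
    b("COM_9_2",  "common", 2.375, 1.025, 2.300),
    b("COM_10_2", "Young", 2.153, 0.521, 1.147),
    b("COM_10_2", "Old",   2.271, 0.871, 1.514),
    b("COM_11_2", "common", 2.276, 1.226, 2.010),
    b("COM_12_2", "Young", 3.357, 0.557, 1.422),
    b("COM_12_2", "Old",   4.291, 0.952, 1.772),
    b("COM_13_2", "common", 1.989, 0.649, 1.427),
    b("APR_14_2", "common", 2.066, 1.397, 2.558),
    b("APR_15_2", "common", 1.963, 1.043, 2.103),
    b("APR_16_2", "common", 2.328, 1.236, 1.940),
    b("APR_17_2", "common", 1.871, 0.799, 1.965),
    b("MOV_20_2", "Institutionalized young", 2.033, 1.433, 2.126),
    b("MOV_20_2", "Institutionalized old",   1.394, 0.148, 1.427),
    b("MOV_20_2", "Community-dwelling",      1.987, -0.447, 1.196),
    b("MOV_21_2", "common", 0.626, -2.691, 1.156),
    b("MOV_26_2", "Institutionalized",  1.895, 0.931, 1.708),
    b("MOV_26_2", "Community-dwelling", 2.122, -0.319, 1.212),
    b("AUT_27_2", "Young", 2.590, 0.019, 1.040),
    b("AUT_27_2", "Old",   2.475, -0.549, 0.908),
    b("AUT_28_2", "common", 1.922, -0.375, 0.994),
    b("AUT_29_2", "Institutionalized young", 3.571, 1.090, 1.542),
    b("AUT_29_2", "Institutionalized old",   1.728, 0.358, 1.352),
    b("AUT_29_2", "Community-dwelling",      3.129, -0.169, 0.893),
    b("AUT_30_2", "Young", 2.275, 0.902, 1.682),
    b("AUT_30_2", "Old",   2.247, 0.373, 1.144),
    b("AUT_32_2", "Institutionalized young", 3.591, 0.750, 1.545),
    b("AUT_32_2", "Institutionalized old",   2.057, 0.161, 0.923),
    b("AUT_32_2", "Community-dwelling",      3.294, -0.278, 0.723),
    b("AUT_33_2", "Institutionalized",  2.196, 1.128, 1.914),
    b("AUT_33_2", "Community-dwelling", 3.140, -0.043, 1.439),
    b("AUT_34_2", "common", 1.789, -0.220, 1.875),
    b("AUT_35_2", "common", 1.957, 0.113, 1.457),
    b("VDOM_38_2", "common", 1.152, -1.083, 0.645),
    b("INTER_39_2", "Young", 1.820, 1.224, 2.325),
    b("INTER_39_2", "Old",   2.374, 1.423, 2.221),
    b("INTER_40_2", "common", 1.837, 1.026, 1.969),
    b("INTER_42_2", "Young", 1.865, 0.952, 1.825),
    b("INTER_42_2", "Old",   2.917, 1.202, 1.806),
    b("INTER_44_2", "Institutionalized",        1.359, -0.175, 0.515),
    b("INTER_44_2", "Community-dwelling young", 1.920, 0.654, 1.325),
    b("INTER_44_2", "Community-dwelling old",   4.970, 1.151, 1.295),
    # --- lived health scale ---
    l("COM_8_3b", "Institutionalized young",  1.325, -0.001, 1.452),
    l("COM_8_3b", "Institutionalized old",    1.634, 0.906, 2.073),
    l("COM_8_3b", "Community-dwelling young", 0.914, 1.795, 3.807),
    l("COM_8_3b", "Community-dwelling old",   1.222, 2.110, 3.453),
    l("APR_16_3b", "Institutionalized",  2.440, 0.800, 1.486),
    l("APR_16_3b", "Community-dwelling", 1.867, 1.745, 2.383),
    l("APR_17_3b", "Institutionalized young", 1.180, -0.092, 1.091),
    l("APR_17_3b", "Institutionalized old",   2.018, 0.428, 1.067),
    l("APR_17_3b", "Community-dwelling",      1.346, 1.625, 2.475),
    l("MOV_20_3b", "Institutionalized young", 2.904, 1.025, 2.172),
    l("MOV_20_3b", "Institutionalized old",   1.957, 0.523, 2.191),
    l("MOV_20_3b", "Community-dwelling",      1.390, 0.083, 2.927),
    l("MOV_21_3b", "common", 1.813, -0.128, 2.097),
    l("MOV_24_3b", "Institutionalized",  1.938, 0.309, 1.005),
    l("MOV_24_3b", "Community-dwelling", 1.314, -0.416, 1.731),
    l("MOV_25_3b", "Institutionalized",  2.436, 0.800, 1.535),
    l("MOV_25_3b", "Community-dwelling", 1.463, -0.121, 2.178),
    l("MOV_26_3b", "Institutionalized",  2.407, 0.721, 1.576),
    l("MOV_26_3b", "Community-dwelling", 1.631, -0.034, 1.914),
    l("AUT_27_3b", "common", 2.760, 0.197, 1.695),
    l("AUT_28_3b", "common", 2.325, 0.159, 1.597),
    l("AUT_29_3b", "common", 2.562, 0.501, 1.720),
    l("AUT_30_3b", "common", 2.862, 0.541, 1.637),
    l("AUT_32_3b", "common", 3.445, 0.361, 1.565),
    l("AUT_33_3b", "common", 2.837, 0.913, 2.165),
    l("AUT_34_3b", "common", 1.967, 0.521, 1.648),
    l("AUT_35_3b", "common", 2.664, 0.290, 0.955),
    l("VDOM_36_3b", "common", 2.512, -0.062, 0.681),
    # "Carry out housework" is the most discriminating lived item (4.25);
    # "Prepare meals" takes the remaining Home Life row.
    l("VDOM_37_3b", "common", 2.462, -0.099, 0.595),
    l("VDOM_38_3b", "common", 4.251, 0.008, 0.543)
  )
  rownames(out) <- NULL
  out
}

# Does a calibration cell label apply to a respondent in (population, age)?
# population: "institutionalized" | "community_dwelling"; age: "young" | "old".
cell_applies <- function(cell, population, age) {
  pop_lab <- ifelse(population == "institutionalized",
                    "Institutionalized", "Community-dwelling")
  age_lab <- ifelse(age == "young", "young", "old")
  cell == "common" |
    cell == ifelse(age == "young", "Young", "Old") |
    cell == pop_lab |
    cell == paste(pop_lab, age_lab)
}

#' Simulate-and-refit recovery run against the reference calibration
#'
#' Draws `n` respondents of one demographic group with `theta ~ N(0,1)`,
#' generates collapsed 3-category responses to the scale's items from the
#' reference parameters applicable to that group, refits a single-group
#' graded response model by EM, and returns the estimates next to the
#' generating values.
#'
#' @param form `"biological"` or `"lived"`.
#' @param population,age the demographic group whose parameter cells apply.
#' @param n respondents (default 20000).
#' @param seed integer seed.
#' @param grid,tol,max_cycles EM settings, see [fit_grm_em()].
#' @return data frame with one row per item: generating (`a`, `b1`, `b2`)
#'   and estimated (`a_hat`, `b1_hat`, `b2_hat`) parameters.
#' @export
parameter_recovery_run <- function(form, population = "community_dwelling",
                                   age = "old", n = 20000L, seed = 1L,
                                   grid = quadrature_grid(), tol = 1e-3,
                                   max_cycles = 300L) {
  truth <- params_for_group(grm_reference_parameters(), form, population, age)
  set.seed(seed)
  theta <- rnorm(n)
  resp <- simulate_grm_responses(theta, truth)
  fit <- suppressWarnings(fit_grm_em(resp, grid = grid, tol = tol,
                                     max_cycles = max_cycles))
  est <- fit$params[match(truth$item_id, fit$params$item_id), ]
  data.frame(item_id = truth$item_id, cell = truth$cell,
             a = truth$a, b1 = truth$b1, b2 = truth$b2,
             a_hat = est$a, b1_hat = est$b1, b2_hat = est$b2,
             stringsAsFactors = FALSE)
}

#' Select the parameter row applicable to one demographic group
#'
#' For each item of a (possibly group-split) parameter table, picks the row
#' whose calibration cell covers the given population and age group, e.g.
#' the `"Old"` or `"Community-dwelling old"` row for community-dwelling
#' respondents older than 65.
#'
#' @param params data frame as returned by [grm_reference_parameters()].
#' @param form `"biological"` or `"lived"`.
#' @param population `"institutionalized"` or `"community_dwelling"`.
#' @param age `"young"` (<=65) or `"old"` (>65).
#' @return One row per item: columns `item_id`, `cell`, `a`, `b1`, `b2`.
#' @export
params_for_group <- function(params, form,
                             population = c("community_dwelling",
                                            "institutionalized"),
                             age = c("old", "young")) {
  population <- match.arg(population)
  age <- match.arg(age)
  p <- params[params$form == form, , drop = FALSE]
  keep <- cell_applies(p$cell, population, age)
  out <- p[keep, c("item_id", "cell", "a", "b1", "b2")]
  if (anyDuplicated(out$item_id))
    stop_invalid("params", "overlapping calibration cells for one item")
  rownames(out) <- NULL
  out
}
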