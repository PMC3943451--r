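# Samejima graded response model on the collapsed 3-category scale:
# marginal maximum likelihood via EM with fixed-node quadrature, EAP
# scoring, and the 0-100 rescaling of latent scores.
#
# Logistic metric with D = 1 throughout:
#   P(X >= k | theta) = plogis(a * (theta - b_k)),  k = 1, 2,  b1 < b2.

#' Quadrature grid for a standard-normal latent trait
#'
#' Equally spaced nodes with normal-density weights renormalized to sum to
#' one; used both for the EM calibration and for EAP scoring.
#'
#' @param n number of nodes (default 61).
#' @param lower,upper grid range on the theta scale (default \[-6, 6\]).
#' @return list with `nodes` and `weights` (class `quadrature_grid`).
#' @export
quadrature_grid <- function(n = 61L, lower = -6, upper = 6) {
  n <- check_count(n, "n", min = 2L)
  if (upper <= lower) stop_invalid("upper", "grid range must be increasing")
  nodes <- seq(lower, upper, length.out = n)
  w <- dnorm(nodes)
  structure(list(nodes = nodes, weights = w / sum(w)),
            class = "quadrature_grid")
}

#' Category probabilities under the graded response model
#'
#' @param theta latent trait value(s).
#' @param a discrimination (> 0), in logits per theta unit.
#' @param b numeric vector of increasing thresholds; length 2 for the
#'   collapsed 3-category items.
#' @return matrix `length(theta)` x `length(b) + 1` of category
#'   probabilities (columns = categories 0, 1, ..., K-1), rows sum to 1.
#' @examples
#' category_probabilities(0, a = 2.106, b = c(0.690, 1.698))
#' @export
category_probabilities <- function(theta, a, b) {
  check_number(a, "a", lower = 1e-12)
  if (any(diff(b) <= 0)) stop_invalid("b", "thresholds must be increasing")
  cum <- vapply(b, function(bk) plogis(a * (theta - bk)), numeric(length(theta)))
  cum <- matrix(cum, nrow = length(theta))
  star <- cbind(1, cum, 0)
  out <- star[, -ncol(star), drop = FALSE] - star[, -1, drop = FALSE]
  colnames(out) <- paste0("p", seq_len(ncol(out)) - 1L)
  out
}

# log category probabilities for a parameter table at the grid nodes:
# array R x 3 x Q. Rows with n_cat == 2 leave slot k=2 at -Inf.
grm_log_prob_array <- function(params, grid) {
  R <- nrow(params)
  Q <- length(grid$nodes)
  arr <- array(-Inf, dim = c(R, 3L, Q))
  for (r in seq_len(R)) {
    if (params$n_cat[r] == 3L) {
      p <- category_probabilities(grid$nodes, params$a[r],
                                  c(params$b1[r], params$b2[r]))
    } else {
      p <- category_probabilities(grid$nodes, params$a[r], params$b1[r])
      p <- cbind(p, 0)
    }
    arr[r, , ] <- t(log(pmax(p, 1e-300)))
  }
  arr
}

# M-step objective for one parameter row: expected counts r_kq (3 x Q).
mstep_optimize <- function(counts, grid, a0, b10, b20, n_cat) {
  th <- grid$nodes
  if (n_cat == 3L) {
    obj <- function(par) {
      a <- exp(par[1]); b1 <- par[2]; b2 <- b1 + exp(par[3])
      p <- t(category_probabilities(th, a, c(b1, b2)))  # 3 x Q
      -sum(counts * log(pmax(p, 1e-300)))
    }
    start <- c(log(a0), b10, log(max(b20 - b10, 1e-3)))
    fit <- nlminb(start, obj, control = list(iter.max = 200))
    c(a = exp(fit$par[1]), b1 = fit$par[2],
      b2 = fit$par[2] + exp(fit$par[3]))
  } else {
    obj <- function(par) {
      a <- exp(par[1]); b1 <- par[2]
      p <- t(category_probabilities(th, a, b1))  # 2 x Q
      -sum(counts[1:2, , drop = FALSE] * log(pmax(p, 1e-300)))
    }
    fit <- nlminb(c(log(a0), b10), obj, control = list(iter.max = 200))
    c(a = exp(fit$par[1]), b1 = fit$par[2], b2 = NA_real_)
  }
}

# Build the (param table, row-index matrix) pair for a response matrix and
# an optional split specification.
build_param_layout <- function(resp, split, covariates) {
  items <- colnames(resp)
  n <- nrow(resp)
  params <- NULL
  rowidx <- matrix(0L, n, length(items), dimnames = list(NULL, items))
  for (j in seq_along(items)) {
    id <- items[j]
    vars <- if (!is.null(split)) split_vars_for(split, id) else character(0)
    if (length(vars) == 0L) {
      params <- rbind(params, data.frame(item_id = id, cell = "common",
                                         stringsAsFactors = FALSE))
      rowidx[, j] <- nrow(params)
    } else {
      cell <- interaction(covariates[vars], sep = " ", drop = TRUE)
      for (lev in levels(cell)) {
        params <- rbind(params, data.frame(item_id = id, cell = lev,
                                           stringsAsFactors = FALSE))
        rowidx[cell == lev, j] <- nrow(params)
      }
    }
  }
  list(params = params, rowidx = rowidx)
}

#' Calibrate a graded response model by marginal maximum likelihood (EM)
#'
#' Fits Samejima's graded response model to collapsed 3-category responses
#' with a standard-normal latent trait and fixed-node quadrature. Items
#' listed in `split` get separate parameters per demographic cell while all
#' other items act as anchors shared across cells (one joint EM; the latent
#' distribution is N(0,1) in every cell). Missing responses are simply
#' omitted from each respondent's likelihood (missing at random).
#'
#' @param data a recoded [survey_dataset] (see [collapse_categories()]) or a
#'   plain integer matrix of responses in `{0, 1, 2, NA}` with item columns.
#' @param form `"biological"` or `"lived"`; ignored for matrix input.
#' @param items optional character vector restricting the item set
#'   (default: all non-sensory items of `form` present in the data).
#' @param split optional [split_spec] mapping items to the grouping
#'   variables requiring separate calibration.
#' @param grid a [quadrature_grid()].
#' @param tol convergence tolerance: maximum absolute parameter change
#'   between EM cycles (default 1e-3).
#' @param max_cycles maximum EM cycles (default 200). Non-convergence is
#'   flagged, not an error.
#' @param min_cell_n warn when a calibration cell has fewer respondents
#'   (default 200).
#' @return A `grm_fit`: parameter table (`item_id`, `cell`, `a`, `b1`,
#'   `b2`, `n_cat`, `n`), marginal log-likelihood and its per-cycle trace,
#'   cycle count, convergence flag, the grid and the split specification.
#' @export
fit_grm_em <- function(data, form = c("biological", "lived"), items = NULL,
                       split = NULL, grid = quadrature_grid(), tol = 1e-3,
                       max_cycles = 200L, min_cell_n = 200L) {
  if (inherits(data, "survey_dataset")) {
    form <- match.arg(form)
    if (!isTRUE(data$collapsed))
      stop_invalid("data", "responses must be collapsed to 0/1/2 first")
    if (is.null(items))
      items <- intersect(bank_items(data$bank, form, include_sensory = FALSE),
                         colnames(data$responses))
    resp <- data$responses[, items, drop = FALSE]
    covariates <- data$respondents
  } else {
    resp <- as.matrix(data)
    if (is.null(colnames(resp)))
      colnames(resp) <- paste0("item", seq_len(ncol(resp)))
    if (!is.null(items)) resp <- resp[, items, drop = FALSE]
    covariates <- NULL
    form <- if (identical(form, c("biological", "lived"))) "biological"
            else match.arg(form)
  }
  storage.mode(resp) <- "integer"
  ok <- resp %in% c(0L, 1L, 2L) | is.na(resp)
  if (!all(ok)) stop_invalid("data", "responses must be 0, 1, 2 or missing")

  # drop items with < 2 observed categories (no information)
  informative <- vapply(seq_len(ncol(resp)), function(j) {
    length(unique(resp[!is.na(resp[, j]), j])) >= 2L
  }, logical(1))
  if (any(!informative)) {
    warning("dropping degenerate constant-response item(s): ",
            paste(colnames(resp)[!informative], collapse = ", "))
    resp <- resp[, informative, drop = FALSE]
  }
  if (ncol(resp) < 2L) stop_invalid("data", "need at least 2 retained items")

  layout <- build_param_layout(resp, split, covariates)
  params <- layout$params
  rowidx <- layout$rowidx
  R <- nrow(params)
  Q <- length(grid$nodes)
  n <- nrow(resp)

  # per-row observed category counts -> n_cat, starting values
  params$n_cat <- 3L
  params$n <- 0L
  params$a <- 1.5
  params$b1 <- 0
  params$b2 <- 1
  for (r in seq_len(R)) {
    j <- match(params$item_id[r], colnames(resp))
    sel <- rowidx[, j] == r & !is.na(resp[, j])
    x <- resp[sel, j]
    params$n[r] <- length(x)
    if (params$n[r] < min_cell_n)
      warning(sprintf("calibration cell '%s' of item %s has only %d respondents",
                      params$cell[r], params$item_id[r], params$n[r]))
    p1 <- mean(x >= 1L)
    p2 <- mean(x >= 2L)
    if (p2 < 1e-12 || p1 - p2 < 1e-12) {
      # a category unobserved in this cell: collapse to 2 categories
      if (params$n_cat[r] == 3L && p2 < 1e-12) {
        warning(sprintf("item %s cell '%s': top category unobserved; %s",
                        params$item_id[r], params$cell[r],
                        "collapsing to 2 categories"))
        params$n_cat[r] <- 2L
      } else if (p1 - p2 < 1e-12) {
        warning(sprintf("item %s cell '%s': middle category unobserved; %s",
                        params$item_id[r], params$cell[r],
                        "collapsing to 2 categories"))
        params$n_cat[r] <- 2L
        resp[sel & resp[, j] == 2L, j] <- 1L
      }
    }
    p1 <- min(max(p1, 1e-4), 1 - 1e-4)
    p2 <- min(max(mean(resp[sel, j] >= 2L), 1e-4), p1 - 1e-4)
    params$b1[r] <- -qlogis(p1) / params$a[r]
    params$b2[r] <- if (params$n_cat[r] == 3L)
      max(-qlogis(p2) / params$a[r], params$b1[r] + 0.1) else NA_real_
  }

  logw <- log(grid$weights)
  trace <- numeric(0)
  converged <- FALSE
  cycles <- 0L
  for (cycle in seq_len(max_cycles)) {
    cycles <- cycle
    arr <- grm_log_prob_array(params, grid)
    logL <- grm_loglik_mat(resp, rowidx, as.numeric(arr), R, Q)
    logpost <- sweep(logL, 2L, logw, "+")
    mx <- apply(logpost, 1L, max)
    post <- exp(logpost - mx)
    rs <- rowSums(post)
    loglik <- sum(mx + log(rs))
    trace <- c(trace, loglik)
    post <- post / rs
    counts <- array(grm_expected_counts(resp, rowidx, post, R),
                    dim = c(R, 3L, Q))
    delta <- 0
    for (r in seq_len(R)) {
      new <- mstep_optimize(counts[r, , ], grid, params$a[r], params$b1[r],
                            params$b2[r] %||% NA_real_, params$n_cat[r])
      delta <- max(delta, abs(new[["a"]] - params$a[r]),
                   abs(new[["b1"]] - params$b1[r]),
                   if (params$n_cat[r] == 3L)
                     abs(new[["b2"]] - params$b2[r]) else 0)
      params$a[r] <- new[["a"]]
      params$b1[r] <- new[["b1"]]
      params$b2[r] <- new[["b2"]]
    }
    if (delta < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warning(sprintf("EM did not converge in %d cycles (last max change %.4g)",
                    max_cycles, delta))
  structure(list(params = params[, c("item_id", "cell", "a", "b1", "b2",
                                     "n_cat", "n")],
                 split = split, form = form, items = colnames(resp),
                 loglik = trace[length(trace)], loglik_trace = trace,
                 cycles = cycles, converged = converged, grid = grid),
            class = "grm_fit")
}

#' @export
print.grm_fit <- function(x, ...) {
  cat(sprintf("<grm_fit> %s scale: %d items, %d parameter rows\n",
              x$form, length(x$items), nrow(x$params)))
  cat(sprintf("  logLik %.2f after %d EM cycles (%s)\n", x$loglik, x$cycles,
              if (x$converged) "converged" else "NOT converged"))
  invisible(x)
}

# row-index matrix for scoring a response matrix under a fit
fit_rowidx <- function(fit, resp, covariates) {
  n <- nrow(resp)
  rowidx <- matrix(0L, n, length(fit$items))
  for (j in seq_along(fit$items)) {
    rows <- which(fit$params$item_id == fit$items[j])
    if (length(rows) == 1L) {
      rowidx[, j] <- rows
    } else {
      vars <- split_vars_for(fit$split, fit$items[j])
      cell <- interaction(covariates[vars], sep = " ", drop = FALSE)
      m <- match(as.character(cell), fit$params$cell[rows])
      if (anyNA(m))
        stop_invalid("data", sprintf("respondents in unseen cell for item %s",
                                     fit$items[j]))
      rowidx[, j] <- rows[m]
    }
  }
  rowidx
}

#' Expected a posteriori (EAP) latent scores
#'
#' Posterior mean and standard deviation of theta given each respondent's
#' response pattern, using the respondent's cell-specific item parameters
#' and the fit's quadrature grid.
#'
#' @param fit a [fit_grm_em()] result.
#' @param data a recoded [survey_dataset], or a response matrix/vector whose
#'   columns (elements) match `fit$items`.
#' @return data frame with columns `theta` and `se`; one row per respondent.
#'   Patterns with no observed response raise an error.
#' @export
eap_score <- function(fit, data) {
  if (inherits(data, "survey_dataset")) {
    resp <- data$responses[, fit$items, drop = FALSE]
    covariates <- data$respondents
  } else if (is.null(dim(data))) {
    resp <- matrix(as.integer(data), nrow = 1L,
                   dimnames = list(NULL, fit$items))
    covariates <- NULL
  } else {
    resp <- as.matrix(data)[, fit$items, drop = FALSE]
    covariates <- NULL
  }
  storage.mode(resp) <- "integer"
  if (any(rowSums(!is.na(resp)) == 0L))
    stop_invalid("data", "pattern with no observed response cannot be scored")
  rowidx <- fit_rowidx(fit, resp, covariates)
  R <- nrow(fit$params)
  Q <- length(fit$grid$nodes)
  arr <- grm_log_prob_array(fit$params, fit$grid)
  logL <- grm_loglik_mat(resp, rowidx, as.numeric(arr), R, Q)
  logpost <- sweep(logL, 2L, log(fit$grid$weights), "+")
  mx <- apply(logpost, 1L, max)
  post <- exp(logpost - mx)
  post <- post / rowSums(post)
  th <- fit$grid$nodes
  m1 <- as.numeric(post %*% th)
  m2 <- as.numeric(post %*% th^2)
  data.frame(theta = m1, se = sqrt(pmax(m2 - m1^2, 0)))
}

#' Rescale latent scores to the 0-100 metric
#'
#' Affine map sending the sample minimum to 0 and the sample maximum to 100.
#' Orientation follows the latent difficulty scale: higher theta (more
#' difficulty, worse health) maps to 100.
#'
#' @param thetas numeric vector with at least 2 distinct finite values.
#' @return numeric vector in \[0, 100\].
#' @export
rescale_scores <- function(thetas) {
  if (!is.numeric(thetas) || any(!is.finite(thetas)))
    stop_invalid("thetas", "must be finite numeric")
  rng <- range(thetas)
  if (diff(rng) <= 0)
    stop_invalid("thetas", "needs at least 2 distinct values to rescale")
  100 * (thetas - rng[1]) / diff(rng)
}

#' Build a scoring object from known item parameters
#'
#' Wraps a parameter table (for example [grm_reference_parameters()] rows,
#' or simulation ground truth) as a `grm_fit` so respondents can be
#' EAP-scored with [eap_score()] without re-calibrating. One row per item.
#'
#' @param params data frame with columns `item_id`, `a`, `b1`, `b2`.
#' @param grid a [quadrature_grid()].
#' @return a `grm_fit` with a single "common" cell per item.
#' @export
grm_fit_from_params <- function(params, grid = quadrature_grid()) {
  if (anyDuplicated(params$item_id))
    stop_invalid("params", "one row per item required")
  tab <- data.frame(item_id = params$item_id, cell = "common",
                    a = params$a, b1 = params$b1, b2 = params$b2,
                    n_cat = ifelse(is.na(params$b2), 2L, 3L),
                    n = NA_integer_, stringsAsFactors = FALSE)
  structure(list(params = tab, split = NULL, form = "biological",
                 items = tab$item_id, loglik = NA_real_,
                 loglik_trace = numeric(0), cycles = 0L, converged = TRUE,
                 grid = grid),
            class = "grm_fit")
}

#' Simulate graded responses for given latent trait values
#'
#' Draws 3-category responses under the graded response model for each
#' (respondent, item) pair, using one parameter row per item.
#'
#' @param theta numeric vector of latent trait values.
#' @param params data frame with columns `item_id`, `a`, `b1`, `b2` (one row
#'   per item).
#' @return integer matrix `length(theta)` x `nrow(params)` with values 0-2,
#'   columns named by `item_id`. Uses the current RNG state.
#' @export
simulate_grm_responses <- function(theta, params) {
  n <- length(theta)
  out <- matrix(NA_integer_, n, nrow(params),
                dimnames = list(NULL, params$item_id))
  for (j in seq_len(nrow(params))) {
    p2 <- plogis(params$a[j] * (theta - params$b2[j]))
    p12 <- plogis(params$a[j] * (theta - params$b1[j]))
    u <- runif(n)
    out[, j] <- ifelse(u < p2, 2L, ifelse(u < p12, 1L, 0L))
  }
  out
}
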