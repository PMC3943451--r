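# Differential item functioning by iterative hybrid ordinal logistic
# regression: nested proportional-odds models matched on the IRT score,
# McFadden pseudo-R-squared change > 0.02 as the flagging criterion,
# purification by re-calibrating and re-scoring until the flag set is
# stable. Flagged items are calibrated separately per group (split cells).

#' Split specification: which items need group-specific calibration
#'
#' @param items named list: item id -> character vector of grouping
#'   variables for which the item shows DIF. Items absent from the list are
#'   calibrated in a single "common" cell.
#' @return object of class `split_spec`.
#' @export
split_spec <- function(items = list()) {
  if (length(items) > 0 && is.null(names(items)))
    stop_invalid("items", "must be a named list (item id -> variables)")
  structure(list(items = items), class = "split_spec")
}

split_vars_for <- function(split, item_id) {
  if (is.null(split)) return(character(0))
  sort(unique(split$items[[item_id]] %||% character(0)))
}

#' @export
print.split_spec <- function(x, ...) {
  if (length(x$items) == 0) {
    cat("<split_spec> empty (all items common)\n")
  } else {
    cat(sprintf("<split_spec> %d split item(s)\n", length(x$items)))
    for (id in names(x$items))
      cat(sprintf("  %s: %s\n", id, paste(x$items[[id]], collapse = " x ")))
  }
  invisible(x)
}

#' Serialize / read a split specification as JSON
#' @param split a `split_spec`.
#' @param path file path.
#' @export
write_split_spec <- function(split, path) {
  jsonlite::write_json(split$items, path, auto_unbox = FALSE)
  invisible(path)
}

#' @rdname write_split_spec
#' @export
read_split_spec <- function(path) {
  items <- jsonlite::read_json(path, simplifyVector = TRUE)
  split_spec(as.list(items))
}

#' Proportional-odds (cumulative logit) maximum likelihood fit
#'
#' `P(y <= k) = plogis(c_k - X beta)` with strictly increasing intercepts
#' (enforced through a log-gap reparameterization). McFadden's pseudo
#' R-squared `1 - ll / ll_null` is computed against the intercept-only
#' model.
#'
#' @param y ordinal outcome (integer codes or factor), >= 2 observed
#'   categories.
#' @param X covariate matrix (or `NULL` for the intercept-only model);
#'   constant columns are rejected.
#' @return object of class `po_fit`: `intercepts`, `beta`, `loglik`,
#'   `null_loglik`, `mcfadden`, `converged`, `n`.
#' @export
fit_proportional_odds <- function(y, X = NULL) {
  y <- as.integer(factor(y))
  ok <- !is.na(y)
  if (!is.null(X)) {
    X <- as.matrix(X)
    ok <- ok & rowSums(is.na(X)) == 0
    X <- X[ok, , drop = FALSE]
  }
  y <- y[ok]
  K <- max(y)
  n <- length(y)
  if (K < 2L) stop_invalid("y", "needs at least 2 observed categories")
  if (!is.null(X)) {
    sds <- apply(X, 2L, sd)
    if (any(sds < 1e-12)) stop_invalid("X", "constant covariate column")
  }
  p <- if (is.null(X)) 0L else ncol(X)
  nk <- tabulate(y, K)
  null_ll <- sum(nk * log(nk / n))
  # parameters: c1, log gaps (K-2), beta (p)
  unpack <- function(par) {
    cuts <- cumsum(c(par[1], exp(par[seq_len(K - 2) + 1])))
    beta <- if (p > 0) par[(K - 1) + seq_len(p)] else numeric(0)
    list(cuts = cuts, beta = beta)
  }
  cum0 <- cumsum(nk / n)[-K]
  start <- c(qlogis(cum0)[1],
             if (K > 2) log(pmax(diff(qlogis(cum0)), 1e-3)),
             rep(0, p))
  upper_cut <- function(cuts) c(cuts, Inf)[y]            # c_{y}
  lower_cut <- function(cuts) c(-Inf, cuts)[y]           # c_{y-1}
  negll <- function(par) {
    u <- unpack(par)
    eta <- if (p > 0) as.numeric(X %*% u$beta) else numeric(n)
    pr <- plogis(upper_cut(u$cuts) - eta) - plogis(lower_cut(u$cuts) - eta)
    -sum(log(pmax(pr, 1e-300)))
  }
  negll_grad <- function(par) {
    u <- unpack(par)
    eta <- if (p > 0) as.numeric(X %*% u$beta) else numeric(n)
    a1 <- upper_cut(u$cuts) - eta
    a0 <- lower_cut(u$cuts) - eta
    pr <- pmax(plogis(a1) - plogis(a0), 1e-300)
    d1 <- ifelse(is.finite(a1), dlogis(a1), 0) / pr
    d0 <- ifelse(is.finite(a0), dlogis(a0), 0) / pr
    # dll/dc_k: +d1 where y == k, -d0 where y == k + 1
    gcut <- vapply(seq_len(K - 1), function(k)
      sum(d1[y == k]) - sum(d0[y == k + 1L]), numeric(1))
    # chain rule through (c1, log gaps): dc_k/dpar_1 = 1,
    # dc_k/dpar_m = exp(par_m) for k >= m (m = 2..K-1)
    gpar <- numeric(length(par))
    gpar[1] <- sum(gcut)
    if (K > 2)
      for (m in 2:(K - 1))
        gpar[m] <- exp(par[m]) * sum(gcut[m:(K - 1)])
    if (p > 0)
      gpar[(K - 1) + seq_len(p)] <- as.numeric(crossprod(X, d0 - d1))
    -gpar
  }
  fit <- nlminb(start, negll, gradient = negll_grad,
                control = list(iter.max = 300, eval.max = 600))
  u <- unpack(fit$par)
  converged <- fit$convergence == 0 && all(abs(u$beta) < 30)
  ll <- -fit$objective
  structure(list(intercepts = u$cuts, beta = u$beta, loglik = ll,
                 null_loglik = null_ll,
                 mcfadden = 1 - ll / null_ll,
                 converged = converged, n = n, K = K),
            class = "po_fit")
}

#' @export
print.po_fit <- function(x, ...) {
  cat(sprintf("<po_fit> n=%d, K=%d, logLik %.3f, McFadden R2 %.4f%s\n",
              x$n, x$K, x$loglik, x$mcfadden,
              if (x$converged) "" else " (NOT converged)"))
  invisible(x)
}

#' DIF scan of items against one or more grouping variables
#'
#' For each item and grouping variable, fits three nested proportional-odds
#' models on the (non-missing) item responses: M1 `item ~ score`, M2
#' `item ~ score + group`, M3 `item ~ score + group + group:score`
#' (multi-level groups via indicator coding). The DIF statistic is the
#' change in McFadden's pseudo R-squared between M3 and M1 (uniform plus
#' non-uniform DIF combined); items with a change strictly above
#' `criterion` are flagged. M2's R-squared is reported for diagnostics.
#'
#' @param responses item response vector, or matrix with item columns.
#' @param score matching score (latent scale score) per respondent.
#' @param group grouping factor, or a data frame of grouping variables.
#' @param criterion flag threshold on the R-squared change (default 0.02).
#' @param min_level_n warn when a group level has fewer respondents
#'   (default 100).
#' @return data frame with one row per item x variable: `item`, `variable`,
#'   `r2_m1`, `r2_m2`, `r2_m3`, `delta_r2`, `flag`. Items constant within
#'   a group level are skipped with a warning (`flag = NA`).
#' @export
dif_scan <- function(responses, score, group, criterion = 0.02,
                     min_level_n = 100L) {
  if (is.null(dim(responses))) {
    responses <- matrix(responses, ncol = 1L,
                        dimnames = list(NULL, "item"))
  }
  if (!is.data.frame(group)) group <- data.frame(group = group)
  out <- NULL
  for (v in colnames(group)) {
    g <- factor(group[[v]])
    if (nlevels(g) < 2L) stop_invalid("group", "needs >= 2 levels")
    if (any(table(g) < min_level_n))
      warning(sprintf("group '%s' has a level with < %d respondents",
                      v, min_level_n))
    G <- stats::model.matrix(~g)[, -1, drop = FALSE]
    for (item in colnames(responses)) {
      yi <- responses[, item]
      ok <- !is.na(yi) & !is.na(score)
      row <- data.frame(item = item, variable = v, r2_m1 = NA_real_,
                        r2_m2 = NA_real_, r2_m3 = NA_real_,
                        delta_r2 = NA_real_, flag = NA,
                        stringsAsFactors = FALSE)
      lvl_const <- vapply(levels(g), function(l)
        length(unique(yi[ok & g == l])) < 2L, logical(1))
      if (any(lvl_const)) {
        warning(sprintf("dif_scan: item %s constant within a level of %s; %s",
                        item, v, "scan skipped"))
        out <- rbind(out, row)
        next
      }
      s <- score[ok]
      Gi <- G[ok, , drop = FALSE]
      m1 <- fit_proportional_odds(yi[ok], cbind(score = s))
      m2 <- fit_proportional_odds(yi[ok], cbind(score = s, Gi))
      m3 <- fit_proportional_odds(yi[ok], cbind(score = s, Gi, Gi * s))
      row$r2_m1 <- m1$mcfadden
      row$r2_m2 <- m2$mcfadden
      row$r2_m3 <- m3$mcfadden
      row$delta_r2 <- max(m3$mcfadden - m1$mcfadden, 0)
      row$flag <- row$delta_r2 > criterion
      out <- rbind(out, row)
    }
  }
  rownames(out) <- NULL
  out
}

#' Purification: iterate calibration, scoring and DIF scanning
#'
#' Standard purification loop for the score-matched DIF method: (1)
#' calibrate the graded response model under the current split
#' specification, (2) EAP-score all respondents with it, (3) scan every
#' item against every grouping variable using these scores, (4) update the
#' split specification with the flagged item x variable pairs; repeat until
#' the flag set is unchanged or `max_iter` is reached (then the last
#' specification is returned with a warning).
#'
#' @param data collapsed, filtered `survey_dataset`.
#' @param form `"biological"` or `"lived"`.
#' @param group_vars grouping variables scanned (columns of
#'   `data$respondents`), default population, age group, gender, number of
#'   health conditions.
#' @param criterion McFadden R-squared change threshold (default 0.02).
#' @param max_iter maximum purification iterations (default 10).
#' @param items optional item subset (post assumption screening).
#' @param grid,tol,max_cycles settings passed to [fit_grm_em()].
#' @return a [split_spec()]; attributes `"iterations"`, `"converged"` and
#'   `"scan"` (the final DIF table).
#' @export
purify <- function(data, form = c("biological", "lived"),
                   group_vars = c("population", "age_group", "gender",
                                  "conditions"),
                   criterion = 0.02, max_iter = 10L, items = NULL,
                   grid = quadrature_grid(), tol = 1e-3, max_cycles = 200L) {
  form <- match.arg(form)
  group_vars <- group_vars[vapply(group_vars, function(v)
    length(unique(data$respondents[[v]])) > 1L, logical(1))]
  spec <- split_spec()
  prev_key <- ""
  converged <- FALSE
  scan <- NULL
  iterations <- 0L
  for (iter in seq_len(max_iter)) {
    iterations <- iter
    fit <- fit_grm_em(data, form, items = items, split = spec, grid = grid,
                      tol = tol, max_cycles = max_cycles)
    can_score <- rowSums(!is.na(data$responses[, fit$items, drop = FALSE])) > 0
    scores <- rep(NA_real_, nrow(data$respondents))
    sub <- data
    sub$respondents <- sub$respondents[can_score, , drop = FALSE]
    sub$responses <- sub$responses[can_score, , drop = FALSE]
    scores[can_score] <- eap_score(fit, sub)$theta
    scan <- dif_scan(data$responses[, fit$items, drop = FALSE], scores,
                     data$respondents[, group_vars, drop = FALSE],
                     criterion = criterion)
    flagged <- scan[!is.na(scan$flag) & scan$flag, , drop = FALSE]
    new_items <- lapply(split(flagged$variable, flagged$item), sort)
    new_items <- new_items[order(names(new_items))]
    spec <- split_spec(new_items)
    key <- paste(names(new_items),
                 vapply(new_items, paste, "", collapse = ","),
                 collapse = ";")
    if (identical(key, prev_key)) {
      converged <- TRUE
      break
    }
    prev_key <- key
  }
  if (!converged)
    warning(sprintf("purification did not stabilize within %d iterations",
                    max_iter))
  attr(spec, "iterations") <- iterations
  attr(spec, "converged") <- converged
  attr(spec, "scan") <- scan
  spec
}
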