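# IRT assumption screening: unidimensionality (eigenvalue ratio of the
# polychoric matrix + one-factor loadings), local independence (residual
# correlations), monotonicity (rest-score bin means).

# Bivariate standard normal CDF P(Z1 <= h, Z2 <= k) with correlation rho,
# via Phi(h)Phi(k) + integral_0^rho of the bivariate density at (h, k).
# Unit-interval Gauss-Legendre nodes are cached and rescaled per call.
.gl_cache <- new.env(parent = emptyenv())

gl_unit <- function(n) {
  key <- as.character(n)
  if (is.null(.gl_cache[[key]]))
    .gl_cache[[key]] <- gauss_legendre(n, 0, 1)
  .gl_cache[[key]]
}

pbvnorm <- function(h, k, rho, nodes = 32L) {
  if (!is.finite(h) && h > 0) return(pnorm(k))
  if (!is.finite(k) && k > 0) return(pnorm(h))
  if (!is.finite(h) || !is.finite(k)) {
    if (h == -Inf || k == -Inf) return(0)
  }
  gl <- gl_unit(nodes)
  x <- rho * gl$x
  w <- rho * gl$w
  dens <- exp(-(h^2 - 2 * x * h * k + k^2) / (2 * (1 - x^2))) /
    (2 * pi * sqrt(1 - x^2))
  pnorm(h) * pnorm(k) + sum(w * dens)
}

# Gauss-Legendre nodes/weights on [a, b] (golub-welsch via eigen)
gauss_legendre <- function(n, a, b) {
  i <- seq_len(n - 1)
  beta <- i / sqrt(4 * i^2 - 1)
  J <- matrix(0, n, n)
  J[cbind(i, i + 1)] <- beta
  J[cbind(i + 1, i)] <- beta
  e <- eigen(J, symmetric = TRUE)
  x <- e$values
  w <- 2 * e$vectors[1, ]^2
  list(x = (a + b) / 2 + (b - a) / 2 * x, w = (b - a) / 2 * w)
}

# two-step polychoric correlation for one pair of ordinal vectors
polychoric_pair <- function(x, y) {
  ok <- !is.na(x) & !is.na(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  tab <- table(factor(x, sort(unique(x))), factor(y, sort(unique(y))))
  if (nrow(tab) < 2L || ncol(tab) < 2L) return(NA_real_)
  tau_x <- qnorm(cumsum(rowSums(tab) / n))[-nrow(tab)]
  tau_y <- qnorm(cumsum(colSums(tab) / n))[-ncol(tab)]
  ax <- c(-Inf, tau_x, Inf)
  ay <- c(-Inf, tau_y, Inf)
  negll <- function(rho) {
    ll <- 0
    Phi <- matrix(0, length(ax), length(ay))
    for (i in seq_along(ax)) for (j in seq_along(ay))
      Phi[i, j] <- pbvnorm(ax[i], ay[j], rho)
    for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab))) {
      p <- Phi[i + 1, j + 1] - Phi[i, j + 1] - Phi[i + 1, j] + Phi[i, j]
      ll <- ll + tab[i, j] * log(max(p, 1e-12))
    }
    -ll
  }
  opt <- optimize(negll, c(-0.999, 0.999))
  clip_cor(opt$minimum)
}

#' Polychoric correlation matrix of a scale's items
#'
#' Two-step estimator: thresholds from the marginal cumulative proportions
#' via the inverse normal, then the correlation maximizing the
#' bivariate-normal cell likelihood, per item pair. Degenerate pairs (an
#' item constant within the pairwise-complete subset) are set to `NA` and
#' logged.
#'
#' @param data a collapsed `survey_dataset`, or an ordinal response matrix.
#' @param form scale to use for `survey_dataset` input.
#' @param min_pair_n minimum pairwise-complete sample size (default 30).
#' @return object of class `polychoric_matrix`: list with `rho` (symmetric,
#'   unit diagonal, entries clipped to ±0.999), `n` (pairwise sample
#'   sizes), `items`.
#' @export
polychoric_matrix <- function(data, form = c("biological", "lived"),
                              min_pair_n = 30L) {
  if (inherits(data, "survey_dataset")) {
    form <- match.arg(form)
    if (!isTRUE(data$collapsed))
      stop_invalid("data", "collapse responses first")
    items <- intersect(bank_items(data$bank, form, include_sensory = FALSE),
                       colnames(data$responses))
    x <- data$responses[, items, drop = FALSE]
  } else {
    x <- as.matrix(data)
    if (is.null(colnames(x))) colnames(x) <- paste0("item", seq_len(ncol(x)))
  }
  p <- ncol(x)
  rho <- diag(1, p)
  npair <- matrix(nrow(x), p, p)
  dimnames(rho) <- dimnames(npair) <- list(colnames(x), colnames(x))
  usable <- 0L
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    nij <- sum(!is.na(x[, i]) & !is.na(x[, j]))
    npair[i, j] <- npair[j, i] <- nij
    if (nij < min_pair_n) {
      rho[i, j] <- rho[j, i] <- NA_real_
      next
    }
    r <- polychoric_pair(x[, i], x[, j])
    if (is.na(r))
      message(sprintf("polychoric: degenerate pair (%s, %s) marked missing",
                      colnames(x)[i], colnames(x)[j]))
    rho[i, j] <- rho[j, i] <- r
    usable <- usable + 1L
  }
  if (usable < 1L)
    stop_invalid("data", "need >= 2 items with adequate pairwise n")
  structure(list(rho = rho, n = npair, items = colnames(x)),
            class = "polychoric_matrix")
}

as_cor_matrix <- function(r) {
  if (inherits(r, "polychoric_matrix")) r$rho else as.matrix(r)
}

# nearest-PSD correction by eigenvalue clipping (keeps unit diagonal)
smooth_psd <- function(R) {
  R[is.na(R)] <- 0
  diag(R) <- 1
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (all(e$values > 1e-10)) return(R)
  v <- pmax(e$values, 1e-8)
  S <- e$vectors %*% diag(v) %*% t(e$vectors)
  d <- sqrt(diag(S))
  S <- S / tcrossprod(d)
  diag(S) <- 1
  S
}

#' Minimum-residual one-factor loadings
#'
#' Loadings minimizing `sum_{i<j} (r_ij - l_i l_j)^2`, by alternating
#' updates from the leading-eigenvector start.
#'
#' @param r a [polychoric_matrix()] or plain correlation matrix.
#' @return named numeric vector of loadings.
#' @export
one_factor_loadings <- function(r) {
  R <- smooth_psd(as_cor_matrix(r))
  p <- ncol(R)
  off <- R
  diag(off) <- 0
  if (max(abs(off)) < 1e-8)
    stop_invalid("r", "degenerate structure: no common factor")
  e <- eigen(R, symmetric = TRUE)
  if (e$values[1] <= 0)
    stop_invalid("r", "degenerate structure: no positive eigenvalue")
  lam <- e$vectors[, 1] * sqrt(max(e$values[1] - 1 + mean(diag(R)), 0.1))
  if (sum(lam) < 0) lam <- -lam
  for (iter in 1:500) {
    old <- lam
    for (i in seq_len(p)) {
      denom <- sum(lam[-i]^2)
      if (denom < 1e-12) next
      lam[i] <- sum(R[i, -i] * lam[-i]) / denom
    }
    if (max(abs(lam - old)) < 1e-9) break
  }
  if (sum(lam^2) < 1e-8)
    stop_invalid("r", "degenerate structure: no common factor")
  names(lam) <- colnames(R)
  lam
}

#' Flag locally dependent item pairs
#'
#' Residual correlation `r_ij - l_i l_j`; pairs strictly above the
#' threshold are flagged. For each flagged pair the member with the lower
#' loading is proposed for exclusion (configurable via `retain`).
#'
#' @param r a [polychoric_matrix()] or correlation matrix.
#' @param loadings one-factor loadings (default recomputed from `r`).
#' @param threshold flag residuals strictly greater than this (default 0.2).
#' @param retain optional character vector of item ids that must be kept
#'   when they appear in a flagged pair.
#' @return data frame `item_i`, `item_j`, `residual`, `drop` (the proposed
#'   exclusion), zero rows when nothing is flagged.
#' @export
flag_local_dependence <- function(r, loadings = one_factor_loadings(r),
                                  threshold = 0.2, retain = NULL) {
  R <- as_cor_matrix(r)
  p <- ncol(R)
  out <- NULL
  for (i in seq_len(p - 1)) for (j in (i + 1):p) {
    if (is.na(R[i, j])) next
    resid <- R[i, j] - loadings[i] * loadings[j]
    if (resid > threshold) {
      ids <- colnames(R)[c(i, j)]
      drop <- ids[which.min(loadings[c(i, j)])]
      if (!is.null(retain) && drop %in% retain)
        drop <- setdiff(ids, drop)[1]
      out <- rbind(out, data.frame(item_i = ids[1], item_j = ids[2],
                                   residual = as.numeric(resid), drop = drop,
                                   stringsAsFactors = FALSE))
    }
  }
  if (is.null(out))
    out <- data.frame(item_i = character(0), item_j = character(0),
                      residual = numeric(0), drop = character(0))
  out
}

#' First-to-second eigenvalue ratio of the item correlation matrix
#'
#' A simplified unidimensionality screen: a large ratio (> 3 by
#' convention) supports a strong general factor.
#'
#' @param r a [polychoric_matrix()] or correlation matrix.
#' @return the ratio `lambda_1 / lambda_2`; `Inf` when the second
#'   eigenvalue is not positive.
#' @export
eigenvalue_ratio <- function(r) {
  R <- smooth_psd(as_cor_matrix(r))
  ev <- eigen(R, symmetric = TRUE, only.values = TRUE)$values
  if (length(ev) < 2L || ev[2] <= 1e-12) return(Inf)
  ev[1] / ev[2]
}

#' Monotonicity check via rest-score bin means
#'
#' Rest-score = a respondent's total collapsed score over the scale's other
#' items (observed responses). Respondents are grouped into quantile bins
#' (average-rank ties) and the item's mean response per bin is inspected;
#' the item is non-monotone when an adjacent bin-mean decrease exceeds
#' `tolerance` times the category range (2).
#'
#' @param data collapsed `survey_dataset` or response matrix.
#' @param item item id (column name).
#' @param form scale for `survey_dataset` input.
#' @param n_bins target number of quantile bins (default 10); reduced (and
#'   logged) when the item has fewer than `20 * n_bins` complete cases.
#' @param tolerance allowed adjacent decrease as a fraction of the category
#'   range (default 0.03).
#' @return list with `verdict` (`"monotone"`, `"non-monotone"`,
#'   `"cannot-evaluate"`), `bin_means`, `max_decrease`, `n_bins`.
#' @export
monotonicity_check <- function(data, item, form = c("biological", "lived"),
                               n_bins = 10L, tolerance = 0.03) {
  if (inherits(data, "survey_dataset")) {
    form <- match.arg(form)
    items <- intersect(bank_items(data$bank, form, include_sensory = FALSE),
                       colnames(data$responses))
    x <- data$responses[, items, drop = FALSE]
  } else {
    x <- as.matrix(data)
  }
  if (!item %in% colnames(x)) stop_invalid("item", "not a data column")
  xi <- x[, item]
  rest <- rowSums(x[, setdiff(colnames(x), item), drop = FALSE], na.rm = TRUE)
  ok <- !is.na(xi)
  xi <- xi[ok]; rest <- rest[ok]
  if (length(unique(rest)) < 2L)
    return(list(verdict = "cannot-evaluate", bin_means = numeric(0),
                max_decrease = NA_real_, n_bins = 0L))
  if (length(xi) < 20L * n_bins) {
    n_bins <- max(2L, length(xi) %/% 20L)
    message(sprintf("monotonicity %s: reduced to %d bins (n=%d)",
                    item, n_bins, length(xi)))
  }
  rk <- rank(rest, ties.method = "average")
  bin <- ceiling(rk / length(rk) * n_bins)
  bin <- pmin(pmax(bin, 1L), n_bins)
  means <- tapply(xi, bin, mean)
  d <- diff(means)
  max_dec <- if (length(d)) max(-d, 0) else 0
  verdict <- if (max_dec > tolerance * 2) "non-monotone" else "monotone"
  list(verdict = verdict, bin_means = as.numeric(means),
       max_decrease = as.numeric(max_dec), n_bins = n_bins)
}

#' Run the full IRT assumption screen for one scale
#'
#' Combines the unidimensionality screen (eigenvalue ratio + one-factor
#' loadings), the local-independence scan (residual correlations) and the
#' per-item monotonicity check, and proposes the item set for calibration.
#'
#' @param data collapsed `survey_dataset`.
#' @param form `"biological"` or `"lived"`.
#' @param ld_threshold residual-correlation flag threshold (default 0.2).
#' @param ratio_threshold eigenvalue-ratio support threshold (default 3).
#' @param retain optional items to keep when flagged (see
#'   [flag_local_dependence()]).
#' @param n_bins,tolerance monotonicity settings.
#' @return object of class `assumption_report`: eigenvalue ratio and
#'   verdict, loadings, flagged pairs, per-item monotonicity verdicts, the
#'   excluded items and the retained item set.
#' @export
check_assumptions <- function(data, form = c("biological", "lived"),
                              ld_threshold = 0.2, ratio_threshold = 3,
                              retain = NULL, n_bins = 10L, tolerance = 0.03) {
  form <- match.arg(form)
  pc <- polychoric_matrix(data, form)
  lam <- one_factor_loadings(pc)
  ratio <- eigenvalue_ratio(pc)
  flags <- flag_local_dependence(pc, lam, ld_threshold, retain = retain)
  mono <- lapply(pc$items, function(it)
    monotonicity_check(data, it, form, n_bins = n_bins,
                       tolerance = tolerance))
  names(mono) <- pc$items
  verdicts <- vapply(mono, `[[`, character(1), "verdict")
  excluded <- union(unique(flags$drop),
                    names(verdicts)[verdicts == "non-monotone"])
  structure(list(
    form = form, eigenvalue_ratio = ratio,
    unidimensional = ratio > ratio_threshold,
    loadings = lam, flagged_pairs = flags,
    monotonicity = mono, excluded = excluded,
    retained = setdiff(pc$items, excluded)), class = "assumption_report")
}

#' @export
print.assumption_report <- function(x, ...) {
  cat(sprintf("<assumption_report> %s scale\n", x$form))
  cat(sprintf("  eigenvalue ratio %.2f (%ssupporting unidimensionality)\n",
              x$eigenvalue_ratio, if (x$unidimensional) "" else "not "))
  cat(sprintf("  %d locally dependent pair(s); %d item(s) excluded\n",
              nrow(x$flagged_pairs), length(x$excluded)))
  invisible(x)
}

#' Serialize an assumption report as JSON
#' @param report an `assumption_report`.
#' @param path output path.
#' @export
write_assumption_report <- function(report, path) {
  obj <- list(
    form = report$form,
    eigenvalue_ratio = report$eigenvalue_ratio,
    unidimensional = report$unidimensional,
    loadings = as.list(report$loadings),
    flagged_pairs = report$flagged_pairs,
    monotonicity = lapply(report$monotonicity, function(m)
      list(verdict = m$verdict, max_decrease = m$max_decrease)),
    excluded = report$excluded, retained = report$retained)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}
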