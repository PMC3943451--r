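# proportional-odds grid-search oracle: iterative zoom over (c1, gap, beta),
# independent of the package's optimizer
po_grid_oracle <- function(y, x, steps = 6L, span = 3) {
  ll <- function(c1, gap, beta) {
    cuts <- c(c1, c1 + gap)
    eta <- beta * x
    cum <- cbind(plogis(cuts[1] - eta), plogis(cuts[2] - eta))
    star <- cbind(0, cum, 1)
    n <- length(y)
    sum(log(pmax(star[cbind(1:n, y + 1L)] - star[cbind(1:n, y)], 1e-300)))
  }
  center <- c(0, 1, 0)
  width <- c(span, span, span)
  for (s in seq_len(steps)) {
    g1 <- seq(center[1] - width[1], center[1] + width[1], length.out = 13)
    g2 <- seq(max(center[2] - width[2], 1e-3), center[2] + width[2],
              length.out = 13)
    g3 <- seq(center[3] - width[3], center[3] + width[3], length.out = 13)
    best <- -Inf
    for (a in g1) for (b in g2) for (c3 in g3) {
      v <- ll(a, b, c3)
      if (v > best) {
        best <- v
        center <- c(a, b, c3)
      }
    }
    width <- width / 4
  }
  list(cuts = c(center[1], center[1] + center[2]), beta = center[3],
       loglik = ll(center[1], center[2], center[3]))
}


# brute-force importance oracles: re-predict permuted OOB data with a plain
# R tree walk, consuming the documented RNG protocol (per tree, per
# predictor in column order, one permutation of the OOB cases; trees with
# < 2 OOB cases draw nothing)
oracle_importance <- function(model, X, y, seed, conditional,
                              cond_threshold = 0.2) {
  p <- ncol(X)
  per_tree <- matrix(NA_real_, model$ntree, p)
  cm <- cor(X)
  set.seed(seed)
  for (b in seq_len(model$ntree)) {
    tree <- model$trees[[b]]
    oob <- which(model$inbag[, b] == 0L)
    if (length(oob) < 2L) next
    Xo <- X[oob, , drop = FALSE]
    mse0 <- mean((y[oob] - oracle_tree_predict(tree, Xo))^2)
    for (v in seq_len(p)) {
      perm <- sample.int(length(oob))
      Xp <- Xo
      if (!conditional) {
        Xp[, v] <- Xo[perm, v]
      } else {
        cs <- which(abs(cm[v, ]) > cond_threshold & seq_len(p) != v)
        if (length(cs) == 0L) {
          Xp[, v] <- Xo[perm, v]
        } else {
          cell <- rep("", length(oob))
          for (w in cs) {
            spw <- sort(unique(tree$split_val[tree$split_var == w]))
            cell <- paste(cell, findInterval(Xo[, w], spw), sep = "|")
          }
          for (cl in unique(cell)) {
            members <- which(cell == cl)
            if (length(members) < 2L) next
            sub <- members[order(match(members, perm))]
            Xp[members, v] <- Xo[sub, v]
          }
        }
      }
      per_tree[b, v] <- mean((y[oob] - oracle_tree_predict(tree, Xp))^2) - mse0
    }
  }
  colMeans(per_tree, na.rm = TRUE)
}
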