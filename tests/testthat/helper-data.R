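# shared fixtures and independent oracles, all built in code

table1_scores <- function() celf_scores()

toy_split <- function(toy) {
  lab <- !is.na(toy$label)
  list(X_lab = as.matrix(toy[lab, c("x1", "x2")]),
       y_lab = toy$label[lab],
       X_unlab = as.matrix(toy[!lab, c("x1", "x2")]))
}

# planted feature-level dataset: features 1-2 carry all the group signal
# (one per discriminative region, with opposite sign), the rest is noise
make_planted_features <- function(n_eff = 9L, n_ineff = 7L, n_unlab = 7L,
                                  n_noise = 50L, seed = 1L) {
  set.seed(seed)
  lat <- c(rep(1L, n_eff), rep(-1L, n_ineff),
           rep(1L, 4L), rep(-1L, n_unlab - 4L))
  n <- length(lat)
  X <- cbind(lat + rnorm(n, 0, 0.3), -lat + rnorm(n, 0, 0.3),
             matrix(rnorm(n * n_noise), n, n_noise))
  colnames(X) <- paste0("f", seq_len(ncol(X)))
  M <- n_eff + n_ineff
  list(X_lab = X[seq_len(M), , drop = FALSE], y_lab = lat[seq_len(M)],
       X_unlab = X[M + seq_len(n_unlab), , drop = FALSE],
       latent_unlab = lat[M + seq_len(n_unlab)])
}

# exact QP oracle: enumerate KKT active sets of the dual (lower/upper/free
# per sample), solve each candidate linear system, keep the feasible optimum
qp_oracle_objective <- function(X, y, C) {
  n <- nrow(X)
  Q <- (y %o% y) * tcrossprod(X)
  states <- as.matrix(expand.grid(rep(list(0:2), n)))
  best <- Inf
  tol <- 1e-9
  for (s in seq_len(nrow(states))) {
    st <- states[s, ]
    a <- ifelse(st == 1, C, 0)
    Fi <- which(st == 2)
    lam <- NA_real_
    if (length(Fi) > 0) {
      A <- rbind(cbind(Q[Fi, Fi, drop = FALSE], y[Fi]), c(y[Fi], 0))
      up <- st == 1
      rhs <- c(rep(1, length(Fi)) -
                 if (any(up)) drop(Q[Fi, up, drop = FALSE] %*% rep(C, sum(up)))
                 else 0,
               -C * sum(y[up]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      aF <- sol[seq_along(Fi)]
      lam <- sol[length(sol)]
      if (any(aF < -tol | aF > C + tol)) next
      a[Fi] <- pmin(pmax(aF, 0), C)
    }
    g <- drop(Q %*% a) - 1
    if (length(Fi) == 0) {
      if (abs(sum(y * a)) > tol) next
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        if (st[i] == 0) {
          if (y[i] > 0) lo <- max(lo, -g[i]) else hi <- min(hi, g[i])
        } else {
          if (y[i] > 0) hi <- min(hi, -g[i]) else lo <- max(lo, g[i])
        }
      }
      if (lo > hi + tol) next
    } else {
      ok <- TRUE
      for (i in seq_len(n)) {
        if (st[i] == 2) next
        v <- g[i] + lam * y[i]
        if (st[i] == 0 && v < -tol) ok <- FALSE
        if (st[i] == 1 && v > tol) ok <- FALSE
      }
      if (!ok) next
    }
    if (abs(sum(y * a)) > 1e-6) next
    best <- min(best, 0.5 * drop(t(a) %*% Q %*% a) - sum(a))
  }
  -best  # dual optimum equals the primal optimum
}

# brute-force BFS flood fill over 26-neighborhoods, independent of the
# union-find implementation under test
bfs_components <- function(selected) {
  dims <- dim(selected)
  offsets <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  offsets <- offsets[rowSums(abs(offsets)) > 0, ]
  remaining <- which(selected)
  sel_set <- array(FALSE, dims)
  sel_set[remaining] <- TRUE
  comps <- list()
  visited <- array(FALSE, dims)
  for (start in remaining) {
    if (visited[start]) next
    queue <- as.integer(start)
    visited[start] <- TRUE
    comp <- integer(0)
    while (length(queue) > 0) {
      cur <- queue[1]
      queue <- queue[-1]
      comp <- c(comp, cur)
      cc <- index_to_coords(cur, dims)
      nb <- sweep(offsets, 2, as.integer(cc), `+`)
      ok <- nb[, 1] >= 1 & nb[, 1] <= dims[1] &
        nb[, 2] >= 1 & nb[, 2] <= dims[2] &
        nb[, 3] >= 1 & nb[, 3] <= dims[3]
      nb <- nb[ok, , drop = FALSE]
      lin <- as.integer(nb[, 1] + dims[1] * (nb[, 2] - 1) +
                          dims[1] * dims[2] * (nb[, 3] - 1))
      new <- lin[sel_set[lin] & !visited[lin]]
      visited[new] <- TRUE
      queue <- c(queue, new)
    }
    comps[[length(comps) + 1L]] <- sort(comp)
  }
  comps[order(vapply(comps, min, integer(1)))]
}

# brute-force optimal 1-D 2-partition of sorted values by within-cluster SS
best_1d_split <- function(v) {
  v <- sort(v)
  n <- length(v)
  ss <- function(x) if (length(x) < 2) 0 else sum((x - mean(x))^2)
  costs <- vapply(seq_len(n - 1), function(k) ss(v[1:k]) + ss(v[(k + 1):n]),
                  numeric(1))
  k <- which.min(costs)
  list(cut = mean(v[k:(k + 1)]), lower = v[1:k], upper = v[(k + 1):n])
}

tiny_map_config <- function(seed = 1L, ...) {
  map_sim_config(grid_shape = c(12L, 12L, 12L),
                 n_controls = 5L, n_effective = 4L, n_ineffective = 3L,
                 n_unlabeled = 2L,
                 region_centers = list(c(4, 6, 6), c(9, 6, 6)),
                 region_radius = 2, seed = seed, ...)
}
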