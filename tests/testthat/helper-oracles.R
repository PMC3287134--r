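# Independent brute-force oracles: direct O(n^2) double loops and plain
# enumerations, deliberately sharing no code with the package internals.

cheb_dist_matrix <- function(A) {
  A <- as.matrix(A)
  n <- nrow(A)
  D <- matrix(0, n, n)
  for (i in seq_len(n))
    D[i, ] <- apply(abs(sweep(A, 2, A[i, ], "-")), 1, max)
  D
}

# neighbour counts with strict radius and Theiler exclusion
brute_counts <- function(points, radii, theiler, tidx) {
  D <- cheb_dist_matrix(points)
  n <- nrow(D)
  sapply(seq_len(n), function(i) {
    ok <- abs(tidx[i] - tidx) > theiler
    sum(D[i, ok] < radii[i])
  })
}

# full KSG transfer entropy by brute force
brute_te <- function(x, y, d, tau, u, k, theiler) {
  n <- length(x)
  tt <- seq.int((d - 1) * tau + 1, n - u)
  embed_at <- function(s) sapply(0:(d - 1), function(j) s[tt - j * tau])
  Y <- embed_at(y); X <- embed_at(x)
  if (!is.matrix(Y)) { Y <- matrix(Y, ncol = d); X <- matrix(X, ncol = d) }
  yf <- y[tt + u]
  J <- cbind(yf, Y, X)
  DJ <- cheb_dist_matrix(J)
  DY <- cheb_dist_matrix(Y)
  DYF <- cheb_dist_matrix(cbind(yf, Y))
  DYX <- cheb_dist_matrix(cbind(Y, X))
  np <- length(tt)
  kd <- ny <- nyf <- nyx <- numeric(np)
  for (i in seq_len(np)) {
    ok <- abs(tt[i] - tt) > theiler
    kd[i] <- sort(DJ[i, ok])[k]
    ny[i] <- sum(DY[i, ok] < kd[i])
    nyf[i] <- sum(DYF[i, ok] < kd[i])
    nyx[i] <- sum(DYX[i, ok] < kd[i])
  }
  v <- kd > 0
  digamma(k) + mean(digamma(ny[v] + 1) - digamma(nyf[v] + 1) -
                      digamma(nyx[v] + 1))
}

brute_mi <- function(a, b, k, theiler) {
  n <- length(a)
  J <- cbind(a, b)
  DJ <- cheb_dist_matrix(J)
  Da <- abs(outer(a, a, "-"))
  Db <- abs(outer(b, b, "-"))
  kd <- na <- nb <- nadm <- numeric(n)
  for (i in seq_len(n)) {
    ok <- abs(i - seq_len(n)) > theiler
    kd[i] <- sort(DJ[i, ok])[k]
    na[i] <- sum(Da[i, ok] < kd[i])
    nb[i] <- sum(Db[i, ok] < kd[i])
    nadm[i] <- sum(ok)
  }
  v <- kd > 0
  digamma(k) + mean(digamma(nadm[v] + 1)) -
    mean(digamma(na[v] + 1) + digamma(nb[v] + 1))
}

# Cao criterion by direct enumeration
brute_cao <- function(x, d_range, tau, k) {
  n <- length(x)
  Ed <- function(d) {
    tt <- seq.int(d * tau + 1, n)
    P <- sapply(0:d, function(j) x[tt - j * tau])
    a <- numeric(length(tt))
    for (i in seq_along(tt)) {
      dd <- apply(abs(sweep(P[, 1:d, drop = FALSE], 2,
                            P[i, 1:d], "-")), 1, max)
      dd[i] <- Inf
      nnk <- order(dd)[k]
      num <- max(abs(P[i, ] - P[nnk, ]))
      a[i] <- num / dd[nnk]
    }
    mean(a[is.finite(a)])
  }
  E <- sapply(c(d_range, max(d_range) + 1), Ed)
  names(E) <- c(d_range, max(d_range) + 1)
  E1 <- sapply(d_range, function(d)
    E[as.character(d + 1)] / E[as.character(d)])
  names(E1) <- d_range
  interior <- d_range[-c(1, length(d_range))]
  crit <- sapply(interior, function(d)
    E1[as.character(d - 1)] + E1[as.character(d + 1)] -
      2 * E1[as.character(d)])
  list(E = E[as.character(d_range)], E1 = E1,
       chosen_d = interior[which.min(crit)])
}

# local constant predictor by brute force
brute_lcp <- function(points, futures, tidx, mode, size, theiler) {
  points <- as.matrix(points)
  n <- nrow(points)
  pred <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    dd <- apply(abs(sweep(points, 2, points[i, ], "-")), 1, max)
    ok <- abs(tidx[i] - tidx) > theiler
    if (mode == "Range") sel <- ok & dd <= size
    else {
      cand <- which(ok)
      sel <- rep(FALSE, n)
      sel[cand[order(dd[cand])[seq_len(min(size, length(cand)))]]] <- TRUE
    }
    if (any(sel)) pred[i] <- mean(futures[sel])
  }
  pred
}

# exact permutation distribution for two independent groups
enumerate_perm_p <- function(a, b, stat, tail = 2) {
  pool <- c(a, b)
  n <- length(pool); na <- length(a)
  t_obt <- stat(a, b)
  splits <- combn(n, na)
  t_star <- apply(splits, 2, function(ii) stat(pool[ii], pool[-ii]))
  if (tail == 2) mean(abs(t_star) >= abs(t_obt)) else mean(t_star >= t_obt)
}

# small coupled pair for workflow tests: Y depends on lagged X
quick_coupled_pair <- function(n_trials, n_samples, coupling = 0.8,
                               lag = 1L, seed = 1L) {
  set.seed(seed)
  trials <- lapply(seq_len(n_trials), function(i) {
    x <- rnorm(n_samples + lag)
    y <- coupling * head(x, n_samples) + rnorm(n_samples)
    x <- tail(x, n_samples)
    rbind(X = x, Y = y)
  })
  times <- lapply(trials, function(m) seq_len(ncol(m)) / 1000)
  raw_dataset(trials, times, c("X", "Y"), 1000)
}
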