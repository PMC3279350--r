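# Independent brute-force oracles.  These deliberately share no code with the
# package: explicit double loops, closed forms, or routines from unrelated
# packages (survival) only.

# uniform random typed pattern
rpat <- function(n_k, n_a, window, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- n_k + n_a
  tpp(runif(n, window$xrange[1], window$xrange[2]),
      runif(n, window$yrange[1], window$yrange[2]),
      rep(c("K", "A"), c(n_k, n_a)), window)
}

naive_pairdist <- function(pattern, type_i, type_j) {
  xi <- pattern$x[pattern$type == type_i]
  yi <- pattern$y[pattern$type == type_i]
  xj <- pattern$x[pattern$type == type_j]
  yj <- pattern$y[pattern$type == type_j]
  out <- matrix(0, length(xi), length(xj))
  for (u in seq_along(xi))
    for (v in seq_along(xj))
      out[u, v] <- sqrt((xi[u] - xj[v])^2 + (yi[u] - yj[v])^2)
  out
}

naive_nndist <- function(pattern, from_type, to_type) {
  d <- naive_pairdist(pattern, from_type, to_type)
  same <- from_type == to_type
  out <- numeric(nrow(d))
  for (u in seq_len(nrow(d))) {
    row <- d[u, ]
    if (same) row <- row[-u]
    out[u] <- min(row)
  }
  out
}

# translation-corrected K by explicit double loop
naive_k <- function(pattern, type_i, type_j, r) {
  w <- pattern$window
  a <- diff(w$xrange); b <- diff(w$yrange)
  A <- a * b
  xi <- pattern$x[pattern$type == type_i]
  yi <- pattern$y[pattern$type == type_i]
  xj <- pattern$x[pattern$type == type_j]
  yj <- pattern$y[pattern$type == type_j]
  lami <- length(xi) / A
  lamj <- length(xj) / A
  same <- type_i == type_j
  K <- numeric(length(r))
  for (u in seq_along(xi)) {
    for (v in seq_along(xj)) {
      if (same && u == v) next
      dx <- abs(xi[u] - xj[v]); dy <- abs(yi[u] - yj[v])
      d <- sqrt(dx^2 + dy^2)
      wgt <- (a - dx) * (b - dy)
      K <- K + as.numeric(d <= r) / (lami * lamj * wgt)
    }
  }
  K
}

# Kaplan-Meier G via the survival package applied to (min(d, c), event) pairs
km_g_oracle <- function(pattern, from_type, to_type, r) {
  d <- naive_nndist(pattern, from_type, to_type)
  keep <- pattern$type == from_type
  cens <- pmin(pattern$x[keep] - pattern$window$xrange[1],
               pattern$window$xrange[2] - pattern$x[keep],
               pattern$y[keep] - pattern$window$yrange[1],
               pattern$window$yrange[2] - pattern$y[keep])
  tt <- pmin(d, cens)
  ev <- as.numeric(d <= cens)
  sf <- survival::survfit(survival::Surv(tt, ev) ~ 1)
  s_of_r <- stats::stepfun(sf$time, c(1, sf$surv))
  1 - s_of_r(r)
}

# annulus neighbour count by explicit loop
naive_pair_count <- function(x, y, type, pattern, pair, h, r) {
  other <- if (pair[1] == pair[2]) pair[1] else setdiff(pair, type)
  if (!type %in% pair) return(0L)
  cnt <- 0L
  for (j in seq_along(pattern$x)) {
    if (as.character(pattern$type[j]) != other) next
    d <- sqrt((pattern$x[j] - x)^2 + (pattern$y[j] - y)^2)
    if (d > h && d <= r) cnt <- cnt + 1L
  }
  cnt
}

# models reused across fitting/simulation tests: a two-type repulsive context
# (near-regular mounds and colonies) and its extension with cross attraction
test_reduced_model <- function(gamma = c(0.2, 0.5)) {
  mshc_model(beta = c(K = 1, A = 1),
             interactions = data.frame(
               type1 = c("K", "A"), type2 = c("K", "A"),
               h = c(5, 2), r = c(12, 8), gamma = gamma))
}

test_full_model <- function(gamma = c(0.2, 0.5, 3.7), h_cross = 1) {
  mshc_model(beta = c(K = 1, A = 1),
             interactions = data.frame(
               type1 = c("K", "A", "A"), type2 = c("K", "A", "K"),
               h = c(5, 2, h_cross), r = c(12, 8, 5.1), gamma = gamma))
}

# same specs with gamma free, for fitting
test_reduced_spec <- function() {
  mshc_model(interactions = data.frame(
    type1 = c("K", "A"), type2 = c("K", "A"),
    h = c(5, 2), r = c(12, 8), gamma = NA))
}

test_full_spec <- function(h_cross = 0) {
  mshc_model(interactions = data.frame(
    type1 = c("K", "A", "A"), type2 = c("K", "A", "K"),
    h = c(5, 2, h_cross), r = c(12, 8, 5.1), gamma = NA))
}
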