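# Independent oracles used across the suite. Each is a deliberately
# naive computation kept separate from the package's own code paths.

# Direct O(L^2) DFT magnitude via an explicit twiddle-factor matrix.
dft_direct <- local({
  cache <- new.env(parent = emptyenv())
  function(x) {
    L <- length(x)
    key <- as.character(L)
    if (is.null(cache[[key]])) {
      n <- 0:(L - 1)
      cache[[key]] <- exp(-2i * pi * outer(n, n) / L)
    }
    as.numeric(Mod(cache[[key]] %*% x))
  }
})

# Brute-force soft-margin dual solver by exhaustive active-set
# enumeration: every variable is tried at 0, at C, or free; the KKT
# stationarity system is solved for the free set and the multiplier, and
# the feasible solution with the best dual objective wins. Exact for
# small n (3^n assignments), independent of the SMO path.
svm_dual_oracle <- function(K, y, C = 1) {
  n <- length(y)
  Q <- outer(y, y) * K
  best <- NULL; best_obj <- -Inf
  obj <- function(a) sum(a) - 0.5 * sum(a * (Q %*% a))
  states <- expand.grid(rep(list(0:2), n))
  for (si in seq_len(nrow(states))) {
    st <- as.integer(states[si, ])
    a <- ifelse(st == 1L, C, 0)
    Fr <- which(st == 2L); Bd <- which(st != 2L)
    if (length(Fr) > 0) {
      # [ Q_FF  y_F ] [a_F    ]   [ 1 - Q_FB a_B  ]
      # [ y_F'  0   ] [lambda ] = [ -sum(a_B y_B) ]
      A <- rbind(cbind(Q[Fr, Fr, drop = FALSE], y[Fr]), c(y[Fr], 0))
      rhs <- c(1 - if (length(Bd)) Q[Fr, Bd, drop = FALSE] %*% a[Bd] else 0,
               -sum(a[Bd] * y[Bd]))
      sol <- tryCatch(solve(A, rhs), error = function(e) NULL)
      if (is.null(sol)) next
      a[Fr] <- sol[seq_along(Fr)]
      lambda <- sol[length(sol)]
      if (any(a[Fr] < -1e-9) || any(a[Fr] > C + 1e-9)) next
    } else {
      if (abs(sum(a * y)) > 1e-9) next
      # lambda is only interval-determined; take the interval midpoint
      g <- 1 - as.numeric(Q %*% a)
      lo <- -Inf; hi <- Inf
      for (i in seq_len(n)) {
        if (st[i] == 0L) {
          if (y[i] > 0) lo <- max(lo, g[i]) else hi <- min(hi, -g[i])
        } else {
          if (y[i] > 0) hi <- min(hi, g[i]) else lo <- max(lo, -g[i])
        }
      }
      if (lo > hi + 1e-9) next
      lambda <- mean(c(max(lo, hi - 2), min(hi, lo + 2)))
    }
    # bound-multiplier sign conditions: at 0 need g_i - lambda y_i <= 0,
    # at C need >= 0, where g = 1 - Q a
    g <- 1 - as.numeric(Q %*% a) - lambda * y
    if (any(g[st == 0L] > 1e-6) || any(g[st == 1L] < -1e-6)) next
    o <- obj(a)
    if (o > best_obj + 1e-12) {
      best_obj <- o
      best <- list(alpha = a, b = lambda)
    }
  }
  best$decision <- function(Kx) as.numeric(Kx %*% (best$alpha * y)) + best$b
  best
}

# Full graph-Laplacian nodal analysis of the row/column resistor network:
# every sensor R[i, j] is an edge between row node i and column node
# nr + j; the selected row is driven at 1 V, the selected column held at
# 0 V, all other nodes float. Returns the effective resistance seen by
# the source and the source/sink current imbalance.
nodal_oracle <- function(R, r, c) {
  nr <- nrow(R); nc <- ncol(R)
  n <- nr + nc
  G <- matrix(0, n, n)
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    g <- 1 / R[i, j]
    G[i, nr + j] <- G[i, nr + j] + g
    G[nr + j, i] <- G[nr + j, i] + g
  }
  Lap <- diag(rowSums(G)) - G
  known <- c(r, nr + c)
  v_known <- c(1, 0)
  unknown <- setdiff(seq_len(n), known)
  v <- numeric(n)
  v[known] <- v_known
  if (length(unknown) > 0)
    v[unknown] <- solve(Lap[unknown, unknown, drop = FALSE],
                        -Lap[unknown, known, drop = FALSE] %*% v_known)
  i_source <- sum(G[r, ] * (v[r] - v))
  i_sink <- sum(G[nr + c, ] * (v - v[nr + c]))
  list(r_eff = 1 / i_source, imbalance = abs(i_source - i_sink))
}

# quick labelled feature fixtures built through the generator
tiny_features <- function(n_per_class = 12, section = "dynamic", seed = 42,
                          subject_sd = 0.05, posture_sd = 0.1,
                          noise_sd = 2, subjects = default_cohort()) {
  ds <- make_dataset(n_per_class, subjects = subjects,
                     cfg = sim_config(section = section, noise_sd = noise_sd),
                     seed = seed, subject_sd = subject_sd,
                     posture_sd = posture_sd)
  extract_features(ds)
}
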