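# Independent brute-force LP oracle: enumerate every basic feasible
# solution of the standard-form program and keep the best objective.
# Only viable for tiny instances; used to cross-check the simplex.
bf_lp <- function(obj, A, rhs, dir, maximize = FALSE, tol = 1e-8) {
  m <- nrow(A)
  ineq <- which(dir != "=")
  S <- matrix(0, m, length(ineq))
  for (k in seq_along(ineq)) {
    S[ineq[k], k] <- if (dir[ineq[k]] == "<=") 1 else -1
  }
  As <- cbind(A, S)
  cs <- c(obj, rep(0, length(ineq)))
  nv <- ncol(As)
  best <- if (maximize) -Inf else Inf
  found <- FALSE
  for (B in utils::combn(nv, m, simplify = FALSE)) {
    AB <- As[, B, drop = FALSE]
    qrAB <- qr(AB)
    if (qrAB$rank < m) next
    zB <- tryCatch(solve(qrAB, rhs), error = function(e) NULL)
    if (is.null(zB) || any(!is.finite(zB)) || any(zB < -tol)) next
    found <- TRUE
    v <- sum(cs[B] * zB)
    if ((maximize && v > best) || (!maximize && v < best)) best <- v
  }
  if (!found) return(list(status = "infeasible", value = NA_real_))
  list(status = "optimal", value = best)
}

# Brute-force CCR: radial efficiency and the phase-2 maximal slack sum
# (slacks measured on the per-variable max-normalised scale, the same
# scale-free objective the package's two-phase solver optimises).
bf_ccr <- function(X, Y, j, vrs = FALSE) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  cx <- apply(X, 2, max); cy <- apply(Y, 2, max)
  Xs <- sweep(X, 2, cx, "/"); Ys <- sweep(Y, 2, cy, "/")
  x0 <- Xs[j, ]; y0 <- Ys[j, ]
  A <- rbind(cbind(-x0, t(Xs)), cbind(0, t(Ys)))
  rhs <- c(rep(0, m), y0)
  dir <- c(rep("<=", m), rep(">=", s))
  if (vrs) {
    A <- rbind(A, c(0, rep(1, n))); rhs <- c(rhs, 1); dir <- c(dir, "=")
  }
  p1 <- bf_lp(c(1, rep(0, n)), A, rhs, dir, maximize = FALSE)
  theta <- p1$value
  A2 <- rbind(cbind(t(Xs), diag(m), matrix(0, m, s)),
              cbind(t(Ys), matrix(0, s, m), -diag(s)))
  rhs2 <- c(theta * x0, y0)
  dir2 <- rep("=", m + s)
  if (vrs) {
    A2 <- rbind(A2, c(rep(1, n), rep(0, m + s)))
    rhs2 <- c(rhs2, 1); dir2 <- c(dir2, "=")
  }
  p2 <- bf_lp(c(rep(0, n), rep(1, m + s)), A2, rhs2, dir2,
              maximize = TRUE)
  list(theta = theta, slacksum = p2$value)
}

# random positive DEA instance, rows = DMUs
rand_dea_instance <- function(n, m, s) {
  list(X = matrix(round(stats::runif(n * m, 1, 10), 2), n, m),
       Y = matrix(round(stats::runif(n * s, 1, 10), 2), n, s))
}

# normalised slack sum of a dea_solve() result, comparable with bf_ccr
norm_slacksum <- function(res, X, Y) {
  cx <- apply(as.matrix(X), 2, max); cy <- apply(as.matrix(Y), 2, max)
  sum(res$slack_input / cx) + sum(res$slack_output / cy)
}

# small deterministic panel for screening / pipeline tests
toy_panel <- function(seed = 42, n_units = 8, n_periods = 4) {
  generate_panel(synthetic_config(n_units = n_units,
                                  n_periods = n_periods, seed = seed))
}
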