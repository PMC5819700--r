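#' Solve a small dense linear program
#'
#' A two-phase primal simplex over the dense tableau, using Bland's
#' anti-cycling rule throughout.  All structural variables are
#' nonnegative.  This is the workhorse behind the DEA envelopment and
#' multiplier programs, which are small (tens of variables) but
#' routinely degenerate: phase-2 slack maximisation fixes the radial
#' efficiency at its optimum, so many bases are ties and a pivoting rule
#' with a termination guarantee is required.
#'
#' @param obj numeric objective coefficients, one per column of `A`.
#' @param A dense constraint matrix.
#' @param rhs right-hand side vector.
#' @param dir character vector of constraint directions, each one of
#'   `"<="`, `">="`, `"="`.
#' @param maximize maximise instead of minimise the objective.
#' @param tol pivot tolerance.
#' @param maxit iteration cap (a safety net only; Bland's rule cannot
#'   cycle).
#' @return list with `status` (`"optimal"`, `"infeasible"` or
#'   `"unbounded"`), `value` and the primal solution `x`.
#' @keywords internal
lp_solve <- function(obj, A, rhs, dir, maximize = FALSE,
                     tol = 1e-9, maxit = 10000L) {
  A <- as.matrix(A)
  m <- nrow(A)
  n <- ncol(A)
  stopifnot(length(obj) == n, length(rhs) == m, length(dir) == m,
            all(dir %in% c("<=", ">=", "=")))

  # normalise rows so the rhs is nonnegative
  neg <- rhs < 0
  if (any(neg)) {
    A[neg, ] <- -A[neg, , drop = FALSE]
    rhs[neg] <- -rhs[neg]
    dir[neg] <- c("<=" = ">=", ">=" = "<=", "=" = "=")[dir[neg]]
  }

  # slack / surplus columns
  ineq <- which(dir != "=")
  ns <- length(ineq)
  S <- matrix(0, m, ns)
  for (k in seq_along(ineq)) {
    S[ineq[k], k] <- if (dir[ineq[k]] == "<=") 1 else -1
  }
  Afull <- cbind(A, S)
  ntot <- n + ns

  # initial basis: slacks where available, artificials elsewhere
  basis <- integer(m)
  slack_col <- integer(m)
  slack_col[ineq] <- n + seq_len(ns)
  need_art <- dir != "<="
  basis[!need_art] <- slack_col[!need_art]
  art_rows <- which(need_art)
  nart <- length(art_rows)
  if (nart > 0L) {
    Aart <- matrix(0, m, nart)
    Aart[cbind(art_rows, seq_len(nart))] <- 1
    basis[art_rows] <- ntot + seq_len(nart)
    Afull <- cbind(Afull, Aart)
  }
  Tm <- cbind(Afull, rhs)
  struct <- seq_len(ntot)          # non-artificial columns

  pivot <- function(Tm, pr, pc) {
    Tm[pr, ] <- Tm[pr, ] / Tm[pr, pc]
    other <- setdiff(seq_len(nrow(Tm)), pr)
    Tm[other, ] <- Tm[other, , drop = FALSE] -
      outer(Tm[other, pc], Tm[pr, ])
    Tm
  }

  run <- function(Tm, basis, cost, allowed) {
    rhs_col <- ncol(Tm)
    for (it in seq_len(maxit)) {
      cB <- cost[basis]
      red <- drop(crossprod(cB, Tm[, -rhs_col, drop = FALSE])) -
        cost                       # z_j - c_j; > 0 improves a minimum
      cand <- which(allowed & red > tol)
      if (length(cand) == 0L) {
        return(list(Tm = Tm, basis = basis, status = "optimal"))
      }
      pc <- cand[1L]               # Bland: lowest index enters
      col <- Tm[, pc]
      rows <- which(col > tol)
      if (length(rows) == 0L) {
        return(list(Tm = Tm, basis = basis, status = "unbounded"))
      }
      ratio <- Tm[rows, rhs_col] / col[rows]
      best <- rows[ratio <= min(ratio) + tol]
      pr <- best[which.min(basis[best])]  # Bland: lowest basis index leaves
      Tm <- pivot(Tm, pr, pc)
      basis[pr] <- pc
    }
    list(Tm = Tm, basis = basis, status = "maxit")
  }

  # phase 1: drive artificials to zero
  if (nart > 0L) {
    cost1 <- c(rep(0, ntot), rep(1, nart))
    allowed1 <- rep(TRUE, ntot + nart)
    r1 <- run(Tm, basis, cost1, allowed1)
    Tm <- r1$Tm
    basis <- r1$basis
    if (r1$status != "optimal" ||
        sum(Tm[, ncol(Tm)][basis > ntot]) > 1e-7) {
      return(list(status = "infeasible", value = NA_real_,
                  x = rep(NA_real_, n)))
    }
    # remove artificials still basic at zero level
    keep <- rep(TRUE, nrow(Tm))
    for (i in which(basis > ntot)) {
      piv <- which(abs(Tm[i, struct]) > tol)
      if (length(piv) > 0L) {
        Tm <- pivot(Tm, i, piv[1L])
        basis[i] <- piv[1L]
      } else {
        keep[i] <- FALSE           # redundant constraint
      }
    }
    if (!all(keep)) {
      Tm <- Tm[keep, , drop = FALSE]
      basis <- basis[keep]
    }
  }

  cost2 <- c(if (maximize) -obj else obj, rep(0, ncol(Tm) - 1L - n))
  allowed2 <- c(rep(TRUE, ntot), rep(FALSE, ncol(Tm) - 1L - ntot))
  r2 <- run(Tm, basis, cost2, allowed2)
  if (r2$status != "optimal") {
    return(list(status = r2$status, value = NA_real_,
                x = rep(NA_real_, n)))
  }
  x <- numeric(ntot)
  x[r2$basis] <- r2$Tm[, ncol(r2$Tm)]
  x <- x[seq_len(n)]
  value <- sum(obj * x)
  list(status = "optimal", value = value, x = x)
}
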