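#' Peer-appraisal cross-efficiency matrix
#'
#' Every unit rates every other unit with its own optimal factor
#' weights.  For each rating unit the CCR multiplier program is solved
#' first; among its (generally non-unique) optimal weights the benevolent
#' secondary goal is applied, i.e. the weights that maximise the combined
#' weighted output of the other units while preserving the rater's own
#' CCR score.  Entry `E[r, j]` is the efficiency of unit `j` under rater
#' `r`'s weights; the diagonal reproduces the CCR efficiencies and the
#' per-unit column mean is the cross-efficiency score.
#'
#' @param data cross-section data frame (one row per unit).
#' @param inputs,outputs character vectors of column names.
#' @param unit name of the unit-identifier column.
#' @param tol numeric tolerance.
#' @return An object of class `cross_efficiency_matrix`: list with the
#'   square matrix `E` (raters in rows), and `scores`, a tibble with
#'   `unit`, `ccr` (own CCR efficiency) and `cross` (mean appraisal by
#'   all raters).
#' @export
#' @examples
#' d <- data.frame(unit = c("a", "b"), x = c(2, 4), y = c(4, 4))
#' cross_efficiency(d, inputs = "x", outputs = "y")$scores
cross_efficiency <- function(data, inputs, outputs, unit = "unit",
                             tol = 1e-6) {
  stopifnot(all(c(inputs, outputs, unit) %in% names(data)),
            nrow(data) >= 2)
  sl <- panel_slice(data, inputs, outputs, unit)
  X <- sl$X; Y <- sl$Y
  n <- nrow(X); m <- ncol(X); s <- ncol(Y)
  if (any(X <= 0) || any(Y <= 0)) {
    stop("DEA requires strictly positive inputs and outputs", call. = FALSE)
  }
  cx <- apply(X, 2, max); cy <- apply(Y, 2, max)
  Xs <- sweep(X, 2, cx, "/"); Ys <- sweep(Y, 2, cy, "/")

  # feasibility rows shared by both programs: u'y_j - v'x_j <= 0
  Afeas <- cbind(-Xs, Ys)
  E <- matrix(NA_real_, n, n,
              dimnames = list(rownames(X), rownames(X)))
  for (r in seq_len(n)) {
    # CCR multiplier program of rater r
    p1 <- lp_solve(c(rep(0, m), Ys[r, ]),
                   rbind(Afeas, c(Xs[r, ], rep(0, s))),
                   c(rep(0, n), 1),
                   c(rep("<=", n), "="),
                   maximize = TRUE)
    if (p1$status != "optimal") {
      stop("cross-efficiency multiplier program ", p1$status,
           " for rater ", rownames(X)[r], call. = FALSE)
    }
    theta_r <- p1$value
    others <- setdiff(seq_len(n), r)
    xo <- colSums(Xs[others, , drop = FALSE])
    yo <- colSums(Ys[others, , drop = FALSE])
    # benevolent secondary goal at preserved own score
    p2 <- lp_solve(c(rep(0, m), yo),
                   rbind(Afeas,
                         c(xo, rep(0, s)),
                         c(-theta_r * Xs[r, ], Ys[r, ])),
                   c(rep(0, n), 1, 0),
                   c(rep("<=", n), "=", "="),
                   maximize = TRUE)
    w <- if (p2$status == "optimal" && sum(p2$x) > tol) p2$x else p1$x
    v <- w[seq_len(m)]; u <- w[m + seq_len(s)]
    if (sum(u) <= tol && sum(v) <= tol) {
      stop("degenerate all-zero multipliers for rater ",
           rownames(X)[r], call. = FALSE)
    }
    E[r, ] <- as.numeric(Ys %*% u) / as.numeric(Xs %*% v)
  }
  scores <- tibble::tibble(
    unit = rownames(X),
    ccr = diag(E),
    cross = colMeans(E)
  )
  names(scores)[1] <- unit
  structure(list(E = E, scores = scores),
            class = "cross_efficiency_matrix")
}

#' @export
print.cross_efficiency_matrix <- function(x, ...) {
  cat("<cross_efficiency_matrix> (", nrow(x$E), " units)\n", sep = "")
  print(x$scores)
  invisible(x)
}

#' @export
tidy.cross_efficiency_matrix <- function(x, ...) {
  x$scores
}
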