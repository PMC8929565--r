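#' Input-oriented data envelopment analysis with variable returns to scale
#'
#' Solves the envelopment-form DEA problem for every decision-making unit
#' (DMU): minimize the radial input contraction `theta` subject to a convex
#' combination of peers producing at least the unit's outputs from at most
#' `theta` times its inputs, with the convexity constraint `sum(lambda) = 1`
#' (variable returns to scale, the BCC model). Slacks are maximized in a
#' second phase at the optimal `theta`, replacing the non-Archimedean
#' epsilon of the classical single-LP formulation, whose finite surrogates
#' distort `theta` numerically; `epsilon` is retained as an option for
#' fidelity to the single-LP form.
#'
#' @param X input matrix, DMUs in rows, strictly positive.
#' @param Y output matrix, DMUs in rows, nonnegative.
#' @param rts returns to scale: `"vrs"` (convexity constraint, default) or
#'   `"crs"` (constant returns, constraint dropped).
#' @param slacks if `TRUE` (default) run the second phase and report
#'   maximal slacks and the reference weights; `FALSE` computes `theta`
#'   only (used inside the Monte Carlo loop where only scores are needed).
#' @param epsilon if non-`NULL`, solve the single LP
#'   `min theta - epsilon * sum(slacks)` instead of the two-phase method.
#' @param tol numeric tolerance for efficiency classification.
#' @return an object of class `"dea"`: list with `theta` (per-DMU score in
#'   (0, 1]), `lambda` (DMUs x DMUs reference weights), `slack_input`,
#'   `slack_output`, `efficient` (strongly efficient: `theta` = 1 and zero
#'   slacks), `weakly_efficient` (`theta` = 1 with nonzero slack), `rts`,
#'   and `labels`.
#' @examples
#' X <- matrix(c(2, 4, 4), ncol = 1)
#' Y <- matrix(c(2, 4, 2), ncol = 1)
#' dea(X, Y)$theta  # c(1, 1, 0.5)
#' @export
dea <- function(X, Y, rts = c("vrs", "crs"), slacks = TRUE,
                epsilon = NULL, tol = 1e-6) {
  rts <- match.arg(rts)
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- nrow(X); ni <- ncol(X); nj <- ncol(Y)
  if (nrow(Y) != d) stop("X and Y must have the same number of rows (DMUs)")
  if (d < 1 || ni < 1 || nj < 1) stop("need at least one DMU, input and output")
  if (anyNA(X) || anyNA(Y)) stop("X and Y must not contain NA")
  if (any(X <= 0)) stop("inputs must be strictly positive")
  if (any(Y < 0)) stop("outputs must be nonnegative")

  labels <- rownames(X) %||% paste0("dmu", seq_len(d))
  theta <- numeric(d)
  lambda <- matrix(0, d, d, dimnames = list(labels, labels))
  s_in <- matrix(0, d, ni, dimnames = list(labels, colnames(X)))
  s_out <- matrix(0, d, nj, dimnames = list(labels, colnames(Y)))

  for (o in seq_len(d)) {
    sol <- dea_solve_one(X, Y, o, rts = rts, slacks = slacks,
                         epsilon = epsilon)
    theta[o] <- sol$theta
    if (slacks) {
      lambda[o, ] <- sol$lambda
      s_in[o, ] <- sol$slack_input
      s_out[o, ] <- sol$slack_output
    }
  }
  # clip scores sitting on the bounds within solver precision
  theta[abs(theta - 1) < 1e-7] <- 1
  theta[theta < 0] <- 0

  slack_any <- if (slacks) {
    rowSums(s_in > tol) + rowSums(s_out > tol) > 0
  } else rep(NA, d)
  structure(list(theta = stats::setNames(theta, labels),
                 lambda = if (slacks) lambda else NULL,
                 slack_input = if (slacks) s_in else NULL,
                 slack_output = if (slacks) s_out else NULL,
                 efficient = theta >= 1 - tol & !slack_any,
                 weakly_efficient = theta >= 1 - tol & slack_any,
                 rts = rts, orientation = "in", labels = labels),
            class = "dea")
}

# Envelopment LP for one DMU.
# Variables: theta, lambda_1..d, s_minus_1..i, s_plus_1..j (all >= 0).
#   inputs : sum_m x_hm lam_m + s_minus_h - theta x_ho = 0
#   outputs: sum_m y_rm lam_m - s_plus_r            = y_ro
#   vrs    : sum_m lam_m                            = 1
dea_solve_one <- function(X, Y, o, rts = "vrs", slacks = TRUE,
                          epsilon = NULL) {
  d <- nrow(X); ni <- ncol(X); nj <- ncol(Y)
  n <- 1 + d + ni + nj
  idx_lam <- 1 + seq_len(d)
  idx_sin <- 1 + d + seq_len(ni)
  idx_sout <- 1 + d + ni + seq_len(nj)

  nrow_A <- ni + nj + (rts == "vrs")
  A <- matrix(0, nrow_A, n)
  b <- numeric(nrow_A)
  A[seq_len(ni), 1] <- -X[o, ]
  A[seq_len(ni), idx_lam] <- t(X)
  A[cbind(seq_len(ni), idx_sin)] <- 1
  A[ni + seq_len(nj), idx_lam] <- t(Y)
  A[cbind(ni + seq_len(nj), idx_sout)] <- -1
  b[ni + seq_len(nj)] <- Y[o, ]
  if (rts == "vrs") A[ni + nj + 1, idx_lam] <- 1
  if (rts == "vrs") b[ni + nj + 1] <- 1

  # column scaling keeps the tableau well conditioned when raw magnitudes
  # differ by orders of magnitude (e.g. budgets vs rates)
  row_scale <- apply(abs(A), 1, max)
  row_scale[row_scale == 0] <- 1
  As <- A / row_scale
  bs <- b / row_scale

  obj <- numeric(n)
  obj[1] <- 1
  if (!is.null(epsilon)) {
    # single-LP non-Archimedean form: min theta - epsilon * sum(slacks)
    obj[c(idx_sin, idx_sout)] <- -epsilon
    sol <- .cpp_simplex(obj, As, bs)
    if (sol$status != 0) stop_lp(sol$status, o)
    x <- sol$x
    return(list(theta = x[1], lambda = x[idx_lam],
                slack_input = x[idx_sin], slack_output = x[idx_sout]))
  }

  sol <- .cpp_simplex(obj, As, bs)
  if (sol$status != 0) stop_lp(sol$status, o)
  theta <- sol$x[1]
  if (!slacks)
    return(list(theta = theta))

  # phase 2: fix theta, maximize total slack
  A2 <- rbind(As, c(1, numeric(n - 1)))
  b2 <- c(bs, theta)
  obj2 <- numeric(n)
  obj2[c(idx_sin, idx_sout)] <- -1
  sol2 <- .cpp_simplex(obj2, A2, b2)
  if (sol2$status != 0) stop_lp(sol2$status, o)
  x <- sol2$x
  list(theta = theta, lambda = x[idx_lam],
       slack_input = x[idx_sin], slack_output = x[idx_sout])
}

stop_lp <- function(status, o) {
  msg <- c("1" = "infeasible", "2" = "unbounded", "3" = "iteration limit reached")
  stop(sprintf("DEA LP for DMU %d failed: %s", o, msg[as.character(status)]))
}

#' @export
print.dea <- function(x, digits = 4, ...) {
  cat(sprintf("Input-oriented DEA (%s), %d DMU(s)\n",
              toupper(x$rts), length(x$theta)))
  print(round(x$theta, digits))
  cat(sprintf("Efficient: %d strongly, %d weakly\n",
              sum(x$efficient, na.rm = TRUE),
              sum(x$weakly_efficient, na.rm = TRUE)))
  invisible(x)
}

#' @export
summary.dea <- function(object, ...) {
  res <- data.frame(
    dmu = object$labels,
    theta = unname(object$theta),
    efficient = object$efficient,
    stringsAsFactors = FALSE
  )
  if (!is.null(object$slack_input)) {
    res$total_slack <- rowSums(object$slack_input) + rowSums(object$slack_output)
    res$peers <- vapply(seq_len(nrow(res)), function(o) {
      p <- which(object$lambda[o, ] > 1e-7)
      paste(object$labels[p], collapse = ",")
    }, character(1))
  }
  res
}

#' Brute-force grid oracle for the input-oriented VRS score
#'
#' Independent check of the LP solution by direct enumeration: convex
#' weights over the DMUs are enumerated on a simplex grid of resolution
#' `1/steps`; for every grid point whose combined outputs cover the
#' evaluated unit's outputs, the smallest feasible radial contraction is
#' `max_h (sum_m x_hm lam_m) / x_ho`, and the oracle returns the minimum
#' over the grid. The result upper-bounds the LP optimum and converges to
#' it as the grid refines; intended for small instances only.
#'
#' @param X,Y input/output matrices, DMUs in rows.
#' @param o index of the evaluated DMU.
#' @param steps grid resolution (weights are multiples of `1/steps`).
#' @return the grid-minimal `theta` (a scalar >= the LP optimum).
#' @export
dea_reference_oracle <- function(X, Y, o, steps = 20) {
  X <- as.matrix(X); Y <- as.matrix(Y)
  d <- nrow(X)
  if (d > 8) stop("grid oracle is intended for small instances (d <= 8)")
  L <- simplex_grid(d, steps)            # d x N weight matrix
  YL <- t(Y) %*% L                       # j x N combined outputs
  feas <- colSums(YL >= Y[o, ] - 1e-9) == ncol(Y)
  if (!any(feas)) return(1)              # self-reference grid point is always there
  XL <- t(X) %*% L                       # i x N combined inputs
  ratios <- XL[, feas, drop = FALSE] / X[o, ]
  th <- ratios[1, ]
  for (h in seq_len(nrow(ratios))[-1]) th <- pmax(th, ratios[h, ])
  min(th)
}

# all compositions of `steps` into d nonnegative parts, as weights summing to 1
simplex_grid <- function(d, steps) {
  if (d == 1) return(matrix(1, 1, 1))
  rec <- function(d, s) {
    if (d == 1) return(matrix(s, 1, 1))
    do.call(cbind, lapply(0:s, function(k) rbind(k, rec(d - 1, s - k))))
  }
  rec(d, steps) / steps
}
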