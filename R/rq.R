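# Quantile regression by exact simplex on the check-loss LP
#
# Minimizes sum_i rho_tau(y_i - x_i'beta), rho_tau(u) = u*(tau - 1{u<0}).
# A basic (vertex) solution interpolates p observations; the algorithm
# moves between such vertices: given a basis h, dual multipliers for the
# basic rows are solved from the stationarity condition and checked
# against [tau-1, tau]; a violated row leaves the basis along its descent
# direction, and the entering row is found by a one-dimensional weighted
# search over the piecewise-linear objective.
#
# Degeneracy is handled by a lexicographic perturbation computed on its
# own scale: alongside the data residuals r_y, the algorithm tracks the
# residuals r_e of a fixed low-discrepancy perturbation vector
# e_i = frac(i * golden ratio).  A residual's sign is that of r_y unless
# r_y is zero (a tied observation), in which case the sign of r_e
# decides.  Because r_e is computed separately it is never swamped by
# the data's floating-point noise, tied observations resolve
# deterministically, and the simplex cannot cycle.  Reported
# coefficients come from the unperturbed data, so exact properties
# (interpolation, location-shift recovery) are preserved.
#
# tau itself is shifted down by an amount far below the 1/n granularity
# of the dual values but far above the feasibility tolerance, so that
# when the minimizer is a face (e.g. an intercept-only fit with n*tau an
# integer) the lowest vertex is selected.

RQ_TIE_EPS <- 1e-7    # downward tau perturbation selecting the lower vertex
RQ_DUAL_TOL <- 1e-9   # per-observation dual feasibility tolerance
RQ_ZERO_REL <- 1e-11  # relative primal tolerance: |r_y| below this is a tie

#' Quantile regression fit
#'
#' Exact minimization of the asymmetric check loss
#' \eqn{\sum_i \rho_\tau(y_i - x_i'\beta)} by a simplex method on the
#' equivalent linear program.  In degenerate cases where the minimizer is
#' an interval (for an intercept-only design, when \eqn{n\tau} is an
#' integer) the fit deterministically returns the lowest vertex, so an
#' intercept-only fit equals the lower empirical quantile
#' (inverse-ECDF convention).
#'
#' @param x design matrix (full column rank).
#' @param y response vector.
#' @param tau quantile level strictly inside (0, 1).
#' @param max_pivots safety cap on simplex pivots.
#' @return list with `coefficients`, `residuals`, `fitted`, `basis` (the
#'   interpolated observation indices), `loss` (minimized check loss),
#'   `tau` and `pivots`.
#' @examples
#' fit <- rq_fit(cbind(1, rnorm(50)), rnorm(50), tau = 0.5)
#' fit$coefficients
#' @export
rq_fit <- function(x, y, tau, max_pivots = NULL) {
  x <- as.matrix(x)
  storage.mode(x) <- "double"
  n <- nrow(x); p <- ncol(x)
  if (length(y) != n) stop("length(y) must equal nrow(x)")
  if (!is.numeric(tau) || length(tau) != 1L || is.na(tau) ||
      tau <= 0 || tau >= 1)
    stop("tau must be a single value strictly inside (0, 1)")
  if (n < p) stop("need at least as many observations as parameters")
  qx <- qr(x)
  if (qx$rank < p) {
    bad <- colnames(x)[qx$pivot[(qx$rank + 1L):p]]
    stop("design matrix is rank deficient; collinear column(s): ",
         toString(bad))
  }
  if (is.null(max_pivots)) max_pivots <- 100L * (n + p)

  tau_eff <- tau - min(tau, 1 - tau) * RQ_TIE_EPS
  dtol <- RQ_DUAL_TOL * n
  ztol_y <- RQ_ZERO_REL * (max(abs(y)) + 1)
  ztol_e <- 1e-9
  # tie-break perturbation: a deterministic hash sequence; unlike linear
  # sequences it is not closed under the integer combinations that relate
  # a row to a basis, so tied rows always separate
  e <- (sin(seq_len(n) * 12.9898) * 43758.5453123) %% 1

  # initial basis: observations nearest the least-squares fit, chosen
  # greedily subject to keeping the basis rows independent
  r0 <- y - x %*% qr.coef(qx, y)
  h <- integer(0)
  for (i in order(abs(r0))) {
    cand <- c(h, i)
    if (qr(x[cand, , drop = FALSE])$rank == length(cand)) h <- cand
    if (length(h) == p) break
  }
  if (length(h) < p) stop("could not find a non-singular starting basis")

  nb_mask <- rep(TRUE, n)
  nb_mask[h] <- FALSE
  pivots <- 0L
  repeat {
    xh <- x[h, , drop = FALSE]
    beta <- solve(xh, y[h])
    ry <- y - drop(x %*% beta)
    re <- e - drop(x %*% solve(xh, e[h]))
    ry[h] <- 0; re[h] <- 0
    tied <- abs(ry) <= ztol_y
    neg <- (!tied & ry < 0) | (tied & re < -ztol_e)
    psi <- ifelse(neg, tau_eff - 1, tau_eff)
    xi <- drop(crossprod(x[nb_mask, , drop = FALSE], psi[nb_mask]))
    psi_h <- drop(solve(t(xh), -xi))

    viol_up <- psi_h - tau_eff
    viol_dn <- (tau_eff - 1) - psi_h
    worst <- pmax(viol_up, viol_dn)
    if (max(worst) <= dtol) break

    if (pivots >= max_pivots)
      stop("simplex did not converge within ", max_pivots, " pivots")
    jj <- which.max(worst)
    # leaving row h[jj]: push its residual negative (sigma = +1) when its
    # multiplier fell below tau-1, positive (sigma = -1) when above tau
    sigma <- if (viol_up[jj] > viol_dn[jj]) -1 else 1
    v <- sigma * solve(xh, diag(p)[, jj])
    w <- drop(x %*% v)
    g <- if (sigma > 0) psi_h[jj] - (tau_eff - 1) else tau_eff - psi_h[jj]

    # breakpoints at lexicographic step (ty, te) > 0: data-scale crossing
    # first, perturbation-scale crossing breaking the tie
    cand <- which(nb_mask & abs(w) > 1e-12)
    ty <- ry[cand] / w[cand]
    te <- re[cand] / w[cand]
    ty[tied[cand]] <- 0
    ok <- ty > 0 | (ty == 0 & (te > ztol_e | (abs(te) <= ztol_e & w[cand] > 0)))
    cand <- cand[ok]; ty <- ty[ok]; te <- te[ok]
    if (length(cand) == 0L) stop("quantile regression problem is unbounded")
    ord <- order(ty, te, cand)
    grad <- g + cumsum(abs(w[cand[ord]]))
    kstar <- which(grad >= 0)[1L]
    if (is.na(kstar)) stop("quantile regression problem is unbounded")
    enter <- cand[ord[kstar]]

    nb_mask[h[jj]] <- TRUE
    nb_mask[enter] <- FALSE
    h[jj] <- enter
    pivots <- pivots + 1L
  }

  names(beta) <- colnames(x)
  r <- y - drop(x %*% beta)
  r[h] <- 0
  loss <- sum(r * (tau - (r < 0)))
  list(coefficients = beta, residuals = r, fitted = y - r,
       basis = sort(h), loss = loss, tau = tau, pivots = pivots)
}

#' Check loss
#'
#' @param u residual vector.
#' @param tau quantile level.
#' @return \eqn{\sum_i u_i (\tau - 1\{u_i < 0\})}.
#' @export
check_loss <- function(u, tau) sum(u * (tau - (u < 0)))
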