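# Independent oracles used across the suite.  These deliberately avoid
# the package's own code paths: the coverage oracle walks day by day,
# the Wilcoxon oracle enumerates assignments of the pooled sample, and
# the quantile-regression oracle enumerates candidate vertex bases.

# Day-by-day consumption simulation under the truncation-at-next-fill
# rule: the supply counter resets at every (same-day-merged) fill and is
# never carried over; a day is covered iff supply remains.
oracle_covered_days <- function(fill_day, n_packages, follow_up_end) {
  keep <- fill_day < follow_up_end
  fill_day <- fill_day[keep]; n_packages <- n_packages[keep]
  if (length(fill_day) == 0L) return(0)
  pk <- tapply(n_packages, fill_day, sum)
  days <- as.integer(names(pk))
  dur <- ifelse(pk == 1, 100, 75 * pk)
  lookup <- rep(0, follow_up_end)
  lookup[days + 1L] <- dur
  supply <- 0; covered <- 0L
  for (d in seq_len(follow_up_end)) {
    if (lookup[d] > 0) supply <- lookup[d]
    if (supply > 0) { covered <- covered + 1L; supply <- supply - 1 }
  }
  covered
}

random_fill_stream <- function() {
  n <- sample(0:6, 1L)
  list(day = sort(sample(0:400, n)),
       pk = if (n > 0) sample(1:3, n, replace = TRUE) else integer(),
       fu = sample(30:550, 1L))
}

# Exact two-sided rank-sum p-value by enumeration over all assignments
# of the pooled sample, using the Mann-Whitney U count of (x > y) pairs
# with ties counted half (an algebraically different route from the
# package's rank-sum enumeration).
oracle_wilcoxon_p <- function(x, y) {
  n1 <- length(x); N <- n1 + length(y)
  pooled <- c(x, y)
  ustat <- function(a, b)
    sum(outer(a, b, ">")) + 0.5 * sum(outer(a, b, "=="))
  u_obs <- ustat(x, y)
  idx <- utils::combn(N, n1)
  us <- apply(idx, 2L, function(i) ustat(pooled[i], pooled[-i]))
  tol <- 1e-9
  min(1, 2 * min(mean(us <= u_obs + tol), mean(us >= u_obs - tol)))
}

# Minimal check loss over all vertex (interpolating) bases.
oracle_rq_min_loss <- function(x, y, tau) {
  n <- nrow(x); p <- ncol(x)
  best <- Inf
  for (cols in asplit(utils::combn(n, p), 2L)) {
    xh <- x[cols, , drop = FALSE]
    if (abs(det(xh)) < 1e-10) next
    beta <- solve(xh, y[cols])
    r <- y - drop(x %*% beta)
    best <- min(best, sum(r * (tau - (r < 0))))
  }
  best
}

# Lower empirical quantile: the smallest minimizer of the intercept-only
# check loss (inverse-ECDF convention).
q_lower <- function(y, tau) sort(y)[max(1L, ceiling(length(y) * tau - 1e-9))]
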