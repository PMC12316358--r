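# Temporal-trend estimation: logistic models for yearly any-use,
# Wilcoxon rank-sum cohort comparisons, and quantile regression of
# 5-year cumulative exposure across a percentile grid with a
# person-level bootstrap.

#' Default percentile grid for quantile-regression trend analyses
#' @return numeric vector 0.10, 0.15, ..., 0.90.
#' @export
tau_grid <- function() seq(0.10, 0.90, by = 0.05)

# Build a full-rank design matrix from categorical covariates; reference
# level of each factor is its first level.
build_design <- function(data, covariates) {
  data <- as.data.frame(data)
  for (v in covariates) {
    if (!is.factor(data[[v]])) data[[v]] <- factor(data[[v]])
    data[[v]] <- droplevels(data[[v]])
  }
  mm <- model.matrix(reformulate(covariates), data)
  qx <- qr(mm)
  if (qx$rank < ncol(mm)) {
    bad <- colnames(mm)[qx$pivot[(qx$rank + 1L):ncol(mm)]]
    stop("design matrix is rank deficient; collinear term(s): ",
         toString(bad))
  }
  mm
}

#' Wilcoxon rank-sum test
#'
#' Two-sample rank-sum test with midranks for ties.  When both samples
#' have at most `exact_max` observations the two-sided p-value is
#' computed by exact enumeration of all assignments of the pooled sample
#' (valid under ties); otherwise a normal approximation with
#' tie-corrected variance and continuity correction is used.
#'
#' @param x,y numeric samples (non-empty).
#' @param exact_max both-sample size threshold for exact enumeration.
#' @return list with `statistic` (rank sum of `x`), `p.value` and
#'   `method`.
#' @examples
#' wilcoxon_rank_sum(c(1, 2, 3), c(4, 5, 6))$p.value  # 0.1
#' @export
wilcoxon_rank_sum <- function(x, y, exact_max = 10L) {
  if (length(x) == 0L || length(y) == 0L)
    stop("both samples must be non-empty")
  n1 <- length(x); n2 <- length(y); N <- n1 + n2
  pooled <- c(x, y)
  rk <- rank(pooled)           # midranks
  W <- sum(rk[seq_len(n1)])
  if (length(unique(pooled)) == 1L)
    return(list(statistic = W, p.value = 1, method = "degenerate"))

  if (n1 <= exact_max && n2 <= exact_max) {
    idx <- combn(N, n1)
    sums <- colSums(matrix(rk[idx], nrow = n1))
    tol <- 1e-9
    p_lo <- mean(sums <= W + tol)
    p_hi <- mean(sums >= W - tol)
    p <- min(1, 2 * min(p_lo, p_hi))
    return(list(statistic = W, p.value = p, method = "exact enumeration"))
  }

  EW <- n1 * (N + 1) / 2
  ties <- table(pooled)
  V <- n1 * n2 / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (V <= 0) return(list(statistic = W, p.value = 1, method = "degenerate"))
  d <- W - EW
  d <- sign(d) * max(0, abs(d) - 0.5)   # continuity correction
  p <- min(1, 2 * pnorm(-abs(d) / sqrt(V)))
  list(statistic = W, p.value = p,
       method = "normal approximation, tie-corrected")
}

#' Logistic regression of yearly any-use on calendar cohort
#'
#' Maximum-likelihood logistic fit of a binary any-use outcome on the
#' calendar cohort plus adjustment covariates (all categorical, first
#' level as reference).  Reports the odds ratio per non-reference level
#' with Wald confidence interval and p-value.
#'
#' @param data data frame/table holding outcome and covariates.
#' @param outcome name of the binary (logical or 0/1) outcome column.
#' @param covariates character vector of covariate column names; the
#'   first is the term of interest (calendar cohort).
#' @param ci_level confidence level for the Wald intervals.
#' @return `data.table` with one row per non-reference level of each
#'   covariate: `term`, `level`, `estimate` (log odds ratio), `se`,
#'   `or`, `ci_low`, `ci_high` (odds-ratio scale), `p`, plus `n` and
#'   `n_events` as attributes-free columns.
#' @export
fit_logistic_anyuse <- function(data, outcome,
                                covariates = c("calendar_cohort",
                                               "age_category", "sex",
                                               "education", "birth_region",
                                               "diagnosis_hospital",
                                               "prior_hospital_cat",
                                               "prior_outpatient_cat"),
                                ci_level = 0.95) {
  data <- as.data.frame(data)
  yv <- data[[outcome]]
  if (is.logical(yv)) yv <- as.integer(yv)
  if (!all(yv %in% c(0L, 1L))) stop("outcome must be binary")
  if (sum(yv) == 0L) stop("outcome has no events; model cannot be fit")
  if (sum(yv) == length(yv)) stop("outcome has no non-events; model cannot be fit")
  mm <- build_design(data, covariates)   # errors on collinearity

  fml <- reformulate(covariates, response = outcome)
  data[[outcome]] <- yv
  fit <- glm(fml, data = data, family = binomial())
  if (!fit$converged) warning("logistic fit did not converge")

  est <- coef(fit)
  se <- sqrt(diag(vcov(fit)))
  z <- qnorm(1 - (1 - ci_level) / 2)
  keep <- names(est) != "(Intercept)"

  # map coefficient names back to term/level
  asg <- attr(mm, "assign")[match(names(est), colnames(mm))]
  term <- c("(Intercept)", covariates)[asg + 1L]
  level <- mapply(function(nm, tm) sub(tm, "", nm, fixed = TRUE),
                  names(est), term)

  data.table(term = term[keep], level = level[keep],
             estimate = unname(est[keep]), se = unname(se[keep]),
             or = exp(unname(est[keep])),
             ci_low = exp(unname(est[keep] - z * se[keep])),
             ci_high = exp(unname(est[keep] + z * se[keep])),
             p = 2 * pnorm(-abs(unname(est[keep] / se[keep]))),
             ci_level = ci_level,
             n = length(yv), n_events = sum(yv))
}

#' Quantile-regression trend with person-level bootstrap
#'
#' Fits [rq_fit()] at every percentile of `tau` and attaches
#' percentile-method bootstrap confidence intervals obtained by
#' resampling persons (rows) with replacement and refitting at every
#' percentile.  Bootstrap replicates whose resampled design loses a
#' factor level (rank deficiency) are dropped and counted; more than 10%
#' dropped is an error.
#'
#' @param data data frame/table holding outcome and covariates.
#' @param outcome name of the numeric outcome column (cumulative dose in
#'   mg, or PDC as a proportion).
#' @param covariates character vector of categorical covariate names;
#'   the first is the calendar cohort.
#' @param tau percentile grid.
#' @param n_boot number of bootstrap replicates (at least 100), or 0 to
#'   skip the bootstrap.
#' @param ci_level confidence level of the percentile intervals
#'   (default 0.90).
#' @param seed integer seed for the bootstrap resampling.
#' @return `data.table` with one row per tau and coefficient: `model`,
#'   `tau`, `term`, `level`, `estimate`, and with bootstrap: `se`
#'   (bootstrap standard error), `ci_low`, `ci_high`, `ci_level`,
#'   `n_boot`, `n_dropped`; plus `n`.
#' @examples
#' d <- data.frame(dose = rlnorm(200, log(7000), 1),
#'                 calendar_cohort = sample(c("a", "b"), 200, TRUE))
#' fit_quantile_trend(d, "dose", "calendar_cohort", tau = 0.5, n_boot = 0)
#' @export
fit_quantile_trend <- function(data, outcome, covariates,
                               tau = tau_grid(), n_boot = 500L,
                               ci_level = 0.90, seed = 1L) {
  if (n_boot != 0 && n_boot < 100)
    stop("n_boot must be at least 100 (or 0 to skip the bootstrap)")
  data <- as.data.frame(data)
  yv <- data[[outcome]]
  if (!is.numeric(yv)) stop("outcome must be numeric")
  mm <- build_design(data, covariates)
  n <- nrow(mm)

  asg <- attr(mm, "assign")
  term <- c("(Intercept)", covariates)[asg + 1L]
  level <- mapply(function(nm, tm) sub(tm, "", nm, fixed = TRUE),
                  colnames(mm), term)

  point <- rbindlist(lapply(tau, function(tt) {
    fit <- rq_fit(mm, yv, tt)
    data.table(model = "quantile", tau = tt, term = term,
               level = unname(level),
               estimate = unname(fit$coefficients), n = n)
  }))
  if (n_boot == 0) return(point[])

  set.seed(seed)
  p <- ncol(mm)
  boots <- vector("list", n_boot)
  dropped <- 0L
  for (b in seq_len(n_boot)) {
    idx <- sample.int(n, n, replace = TRUE)
    mb <- mm[idx, , drop = FALSE]
    if (qr(mb)$rank < p) { dropped <- dropped + 1L; next }
    yb <- yv[idx]
    boots[[b]] <- vapply(tau, function(tt) rq_fit(mb, yb, tt)$coefficients,
                         numeric(p))
  }
  if (dropped > 0.10 * n_boot)
    stop("more than 10% of bootstrap replicates had a degenerate design (",
         dropped, "/", n_boot, ")")
  boots <- boots[!vapply(boots, is.null, logical(1))]
  arr <- simplify2array(boots)            # p x n_tau x n_kept
  if (length(tau) == 1L) arr <- array(arr, c(p, 1L, length(boots)))
  alpha <- (1 - ci_level) / 2

  bsum <- rbindlist(lapply(seq_along(tau), function(ti) {
    mat <- arr[, ti, , drop = TRUE]
    if (is.null(dim(mat))) mat <- matrix(mat, nrow = p)
    data.table(tau = tau[ti], term = term, level = unname(level),
               se = apply(mat, 1L, sd),
               ci_low = apply(mat, 1L, quantile, probs = alpha),
               ci_high = apply(mat, 1L, quantile, probs = 1 - alpha))
  }))
  out <- merge(point, bsum, by = c("tau", "term", "level"), sort = FALSE)
  out[, `:=`(ci_level = ci_level, n_boot = n_boot, n_dropped = dropped)]
  setcolorder(out, c("model", "tau", "term", "level", "estimate", "se",
                     "ci_low", "ci_high", "ci_level", "n", "n_boot",
                     "n_dropped"))
  out[]
}
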