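## Two-isoform Bayesian PSI model.
##
## Reads informative for an event either support inclusion or exclusion.
## The read-origin fraction theta gets a Uniform(0,1) prior, so theta |
## (k of n inclusion reads) ~ Beta(k+1, n-k+1).  PSI is the monotone
## length correction psi(theta) = (theta/l_inc) / (theta/l_inc +
## (1-theta)/l_exc); with equal effective lengths psi == theta and the
## posterior mean is (k+1)/(n+2).  Differential splicing is scored by the
## Bayes factor of independent-theta vs shared-theta models, which is
## available in closed form through Beta functions.

.psi_transform <- function(theta, l_inc, l_exc)
  (theta / l_inc) / (theta / l_inc + (1 - theta) / l_exc)

#' Posterior distribution of PSI for one event in one condition
#'
#' @param k Inclusion-supporting read count.
#' @param n Total informative reads (inclusion + exclusion), `k <= n`.
#' @param l_inc,l_exc Effective lengths of the inclusion and exclusion
#'   isoform read classes; equal lengths (the default) make PSI equal the
#'   raw read-origin fraction.
#' @param level Credible level of the equal-tailed interval.
#' @return A `psi_posterior`: list with `posterior_mean`, `ci_low`,
#'   `ci_high` (all in `[0, 1]`), plus the inputs.
#' @examples
#' psi_posterior(9, 10)$posterior_mean   # (9+1)/(10+2) = 0.8333
#' @export
psi_posterior <- function(k, n, l_inc = 1, l_exc = 1, level = 0.95) {
  pk_assert(length(k) == 1 && length(n) == 1 && is.finite(k) && is.finite(n) &&
              k == round(k) && n == round(n) && k >= 0 && n >= 0 && k <= n,
            "need integer counts 0 <= k <= n")
  pk_assert(l_inc > 0 && l_exc > 0, "effective lengths must be positive")
  a <- k + 1; b <- n - k + 1
  alpha <- (1 - level) / 2
  qs <- qbeta(c(alpha, 1 - alpha), a, b)
  if (l_inc == l_exc) {
    m <- a / (a + b)
    ci <- qs
  } else {
    m <- stats::integrate(function(t) .psi_transform(t, l_inc, l_exc) *
                            dbeta(t, a, b),
                          0, 1, rel.tol = 1e-10)$value
    ci <- .psi_transform(qs, l_inc, l_exc)  # transform is increasing
  }
  structure(list(posterior_mean = m, ci_low = ci[1], ci_high = ci[2],
                 k = k, n = n, l_inc = l_inc, l_exc = l_exc, level = level),
            class = "psi_posterior")
}

#' @export
print.psi_posterior <- function(x, ...) {
  cat(sprintf("PSI = %.4f  [%.4f, %.4f]  (k = %d, n = %d)\n",
              x$posterior_mean, x$ci_low, x$ci_high, x$k, x$n))
  invisible(x)
}

#' Bayes factor for differential splicing between two conditions
#'
#' Compares M1 (each condition has its own uniform-prior read-origin
#' fraction) against M0 (one shared fraction).  Both marginal likelihoods
#' are Beta integrals, giving
#' `BF = B(k_c+1, n_c-k_c+1) B(k_d+1, n_d-k_d+1) / B(k_c+k_d+1,
#' n_c+n_d-k_c-k_d+1)`, evaluated in log space.  BF > 1 favors a splicing
#' change; the statistic is symmetric in the two conditions.  All
#' arguments are vectorized.
#'
#' @param k_c,n_c Inclusion and total counts in the control condition.
#' @param k_d,n_d Same for the depleted / treated condition.
#' @param log If `TRUE` return the natural log Bayes factor.
#' @return Positive numeric vector (or its log).
#' @examples
#' bayes_factor(0, 10, 10, 10)   # ~3.2e4, strong change
#' bayes_factor(5, 10, 5, 10)    # ~0.50, favors no change
#' @export
bayes_factor <- function(k_c, n_c, k_d, n_d, log = FALSE) {
  m <- max(length(k_c), length(n_c), length(k_d), length(n_d))
  k_c <- rep_len(k_c, m); n_c <- rep_len(n_c, m)
  k_d <- rep_len(k_d, m); n_d <- rep_len(n_d, m)
  pk_assert(all(k_c >= 0 & k_d >= 0 & k_c <= n_c & k_d <= n_d &
                  k_c == round(k_c) & k_d == round(k_d) &
                  n_c == round(n_c) & n_d == round(n_d)),
            "need integer counts with 0 <= k <= n in both conditions")
  lbf <- lbeta(k_c + 1, n_c - k_c + 1) + lbeta(k_d + 1, n_d - k_d + 1) -
    lbeta(k_c + k_d + 1, n_c + n_d - k_c - k_d + 1)
  if (log) lbf else exp(lbf)
}

#' Call PSI, delta-PSI and Bayes factors for a set of events
#'
#' Replicates are pooled by summation within each condition before
#' inference (one PSI per condition).  Events whose pooled total falls
#' below `min_reads` are still called but flagged `low_coverage`; events
#' with counts in only one condition are skipped with a warning.
#'
#' @param counts Counts data frame in the [read_counts_table()] schema.
#' @param events Optional named list of `splicing_event` objects (or a
#'   character vector of event types named by event id) used to attach
#'   `event_type`; by default the event id is parsed as a MISO-style
#'   string when possible.
#' @param conditions Length-2 character vector: control first, depleted
#'   second; `delta_psi` is depleted minus control.
#' @param l_inc,l_exc Effective length model passed to [psi_posterior()].
#' @param min_reads Minimum pooled informative reads before a call is
#'   trusted (flag only, never a filter).
#' @return A data frame of class `psi_calls`: one row per event with
#'   `event_id`, `event_type`, per-condition posterior means and 95%
#'   bounds, `delta_psi`, `bayes_factor`, `n_control`, `n_depleted`,
#'   `low_coverage`.
#' @export
call_events <- function(counts, events = NULL,
                        conditions = c("control", "depleted"),
                        l_inc = 1, l_exc = 1, min_reads = 20) {
  counts <- validate_counts_table(counts)
  pk_assert(length(conditions) == 2, "exactly two conditions required")
  counts <- counts[counts$condition %in% conditions, , drop = FALSE]
  pooled <- aggregate(cbind(inclusion_reads, exclusion_reads) ~
                        event_id + condition, data = counts, FUN = sum)
  ids <- unique(pooled$event_id)
  type_of <- function(id) {
    if (!is.null(events)) {
      ev <- if (is.list(events)) events[[id]] else NULL
      if (inherits(ev, "splicing_event")) return(ev$event_type)
      if (is.character(events) && id %in% names(events)) return(events[[id]])
    }
    nb <- length(strsplit(id, "@", fixed = TRUE)[[1L]])
    if (nb == 3L) "SE" else if (nb == 2L) "RI" else NA_character_
  }
  rows <- lapply(ids, function(id) {
    sub <- pooled[pooled$event_id == id, , drop = FALSE]
    if (!all(conditions %in% sub$condition)) {
      warning("event '", id, "' has counts in only one condition; skipped",
              call. = FALSE)
      return(NULL)
    }
    cc <- sub[sub$condition == conditions[1L], ]
    dd <- sub[sub$condition == conditions[2L], ]
    kc <- cc$inclusion_reads; nc <- kc + cc$exclusion_reads
    kd <- dd$inclusion_reads; nd <- kd + dd$exclusion_reads
    pc <- psi_posterior(kc, nc, l_inc, l_exc)
    pd <- psi_posterior(kd, nd, l_inc, l_exc)
    data.frame(event_id = id, event_type = type_of(id),
               psi_control = pc$posterior_mean,
               ci_low_control = pc$ci_low, ci_high_control = pc$ci_high,
               psi_depleted = pd$posterior_mean,
               ci_low_depleted = pd$ci_low, ci_high_depleted = pd$ci_high,
               delta_psi = pd$posterior_mean - pc$posterior_mean,
               bayes_factor = bayes_factor(kc, nc, kd, nd),
               n_control = nc, n_depleted = nd,
               low_coverage = (nc + nd) < min_reads,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) out <- data.frame()
  rownames(out) <- NULL
  class(out) <- c("psi_calls", class(out))
  out
}
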