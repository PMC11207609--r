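# Fault tolerance of a repairable I-node broker cluster.
#
# Node lifetimes are i.i.d. exponential with mean 1/lambda; repairs are
# exponential with mean 1/beta. With gamma = mean_repair / mean_lifetime the
# cluster-failure probability (all I nodes simultaneously down at the instant
# of the last failure) has the closed forms
#   PF(2) = g / (1 + g),   PF(3) = 2 g^2 / ((2 g + 1)(g + 2)),
# and in general PF(I) = prod_{k=1}^{I-1} (I-k) g / ((I-k) g + k), which
# follows from the independent exponential spacings of the lifetime order
# statistics: the gap t_(k+1) - t_(k) is exponential with rate (I-k) lambda,
# so the probability that the k-th failed node is still down at the last
# failure integrates to (I-k) g / ((I-k) g + k) per ordered node.
# Each node fails at most once per cycle (single-cycle model).

#' Two-node cluster failure probability
#'
#' `PF(2) = gamma / (1 + gamma)` where `gamma` is the ratio of mean repair
#' time to mean node lifetime. Strictly increasing in `gamma`, 0 at 0,
#' tending to 1 as `gamma` grows.
#'
#' @param gamma Non-negative repair/lifetime ratio.
#' @return Failure probability in \[0, 1).
#' @examples
#' pf2(0.1) # 0.0909...
#' @export
pf2 <- function(gamma) {
  check_gamma(gamma)
  gamma / (1 + gamma)
}

#' Three-node cluster failure probability
#'
#' `PF(3) = 2 gamma^2 / ((2 gamma + 1)(gamma + 2))`; dominated by [pf2()]
#' for every `gamma >= 0`.
#'
#' @inheritParams pf2
#' @return Failure probability in \[0, 1).
#' @examples
#' pf3(0.1) # 0.00794
#' @export
pf3 <- function(gamma) {
  check_gamma(gamma)
  2 * gamma^2 / ((2 * gamma + 1) * (gamma + 2))
}

check_gamma <- function(gamma) {
  if (anyNA(gamma) || any(gamma < 0)) {
    stop_icufusion("gamma must be non-negative", "icufusion_domain_error")
  }
  invisible(gamma)
}

#' General I-node cluster failure probability
#'
#' `PF(I) = prod_{k=1}^{I-1} (I-k) gamma / ((I-k) gamma + k)`. Reduces
#' exactly to [pf2()] at `I = 2` and [pf3()] at `I = 3`; increasing in
#' `gamma` and decreasing in `I`.
#'
#' @param I Node count, >= 2.
#' @inheritParams pf2
#' @return Failure probability.
#' @export
pf_general <- function(I, gamma) {
  if (length(I) != 1L || is.na(I) || I < 2 || I != round(I)) {
    stop_icufusion("I must be an integer >= 2", "icufusion_domain_error")
  }
  check_gamma(gamma)
  k <- seq_len(I - 1)
  vapply(gamma, function(g) {
    prod((I - k) * g / ((I - k) * g + k))
  }, 0)
}

#' Reliability parameters for a repairable cluster
#'
#' @param I Node count >= 2.
#' @param mean_lifetime Mean node lifetime, hours (`1 / lambda`).
#' @param mean_repair Mean repair duration, hours (`1 / beta`).
#' @return A `reliability_params` list with the derived ratio
#'   `gamma = mean_repair / mean_lifetime` (always recomputed, never stored
#'   independently).
#' @export
reliability_params <- function(I, mean_lifetime, mean_repair) {
  stopifnot(I >= 2, mean_lifetime > 0, mean_repair > 0)
  structure(
    list(
      I = as.integer(I), mean_lifetime = mean_lifetime,
      mean_repair = mean_repair
    ),
    class = "reliability_params"
  )
}

#' @export
print.reliability_params <- function(x, ...) {
  cat(sprintf(
    "<reliability_params> I = %d, mean lifetime = %g h, mean repair = %g h (gamma = %.4g)\n",
    x$I, x$mean_lifetime, x$mean_repair, x$mean_repair / x$mean_lifetime
  ))
  invisible(x)
}

sort_rows <- function(m) {
  # row-wise sort; closed forms for I <= 3 avoid an apply() over 1e6 rows
  I <- ncol(m)
  if (I == 2L) {
    return(cbind(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2])))
  }
  if (I == 3L) {
    lo <- pmin(m[, 1], m[, 2], m[, 3])
    hi <- pmax(m[, 1], m[, 2], m[, 3])
    cbind(lo, m[, 1] + m[, 2] + m[, 3] - lo - hi, hi)
  } else {
    t(apply(m, 1, sort))
  }
}

#' Monte-Carlo estimate of the cluster failure probability
#'
#' Each replication draws `I` exponential lifetimes and, for each of the
#' `I - 1` earliest failures, an exponential repair duration. Under the
#' default event (`"all_down"`) the cluster fails iff every earlier-failed
#' node is still unrepaired at the instant of the last failure — the event
#' whose probability the closed forms give. `event = "repair_deadline"`
#' instead negates the conservative sufficient condition for continued
#' operation ("every earlier-failed node is repaired before the last
#' failure"): it counts a replication as failed as soon as *any* earlier
#' node is still down at the last failure, an upper bound on the all-down
#' probability kept for comparison.
#'
#' @param I Node count >= 2.
#' @param mean_lifetime,mean_repair Exponential means, hours.
#' @param N Replications (>= 1).
#' @param seed RNG seed; identical seeds give identical estimates.
#' @param event `"all_down"` (default) or `"repair_deadline"`.
#' @return A `failure_estimate` list: `estimate`, `se`
#'   (`sqrt(p(1-p)/N)`), `N`, `seed`, `I`, `gamma`, `event`.
#' @export
simulate_failure <- function(I, mean_lifetime, mean_repair, N = 1e5,
                             seed = 1L, event = c("all_down", "repair_deadline")) {
  event <- match.arg(event)
  stopifnot(I >= 2, mean_lifetime > 0, mean_repair > 0)
  if (N < 1) stop_icufusion("N must be >= 1", "icufusion_domain_error")
  N <- as.integer(N)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  lifetimes <- matrix(stats::rexp(N * I, rate = 1 / mean_lifetime), nrow = N)
  ts <- sort_rows(lifetimes)
  d <- matrix(stats::rexp(N * (I - 1), rate = 1 / mean_repair), nrow = N)
  gaps_to_last <- ts[, I] - ts[, -I, drop = FALSE]
  fail <- switch(event,
    all_down = rowSums(d > gaps_to_last) == I - 1L,
    repair_deadline = rowSums(d > gaps_to_last) >= 1L
  )
  p <- mean(fail)
  structure(
    list(
      estimate = p, se = sqrt(p * (1 - p) / N), N = N, seed = seed,
      I = as.integer(I), gamma = mean_repair / mean_lifetime, event = event
    ),
    class = "failure_estimate"
  )
}

#' @export
print.failure_estimate <- function(x, ...) {
  cat(sprintf(
    "<failure_estimate> I = %d, gamma = %.4g: p = %.6g (SE %.2g, N = %d)\n",
    x$I, x$gamma, x$estimate, x$se, x$N
  ))
  invisible(x)
}

#' Tidy a Monte-Carlo failure estimate
#'
#' @param x A `failure_estimate` from [simulate_failure()].
#' @param ... Unused.
#' @return One-row tibble with the estimate, its binomial standard error and
#'   the matching closed-form probability.
#' @method tidy failure_estimate
#' @export
tidy.failure_estimate <- function(x, ...) {
  tibble::tibble(
    I = x$I, gamma = x$gamma, estimate = x$estimate, std.error = x$se,
    closed_form = pf_general(x$I, x$gamma), N = x$N, event = x$event
  )
}

#' Maximum mean repair time meeting a failure-probability target
#'
#' Solves `PF(I)(r / mean_lifetime) = target_pf` for the mean repair time
#' `r` by monotone bisection on `log(gamma)` over the bracket
#' `[1e-9, 1e3]`, to relative tolerance `1e-9`. The inverse identity
#' `pf_general(I, max_repair_time(...)$repair_h / mean_lifetime) ==
#' target_pf` holds to that tolerance.
#'
#' @param I Node count >= 2.
#' @param mean_lifetime Mean node lifetime, hours.
#' @param target_pf Target failure probability in (0, 1).
#' @return A list: `repair_h` (hours), `repair_h_rounded` (nearest hour),
#'   `gamma`.
#' @examples
#' max_repair_time(3, 8760, 1e-6) # about 8.77 h, rounds to 9
#' @export
max_repair_time <- function(I, mean_lifetime, target_pf) {
  if (!is.numeric(target_pf) || target_pf <= 0 || target_pf >= 1) {
    stop_icufusion("target_pf must lie in (0, 1)", "icufusion_domain_error")
  }
  stopifnot(mean_lifetime > 0)
  f <- function(lg) log(pf_general(I, exp(lg))) - log(target_pf)
  lo <- log(1e-9)
  hi <- log(1e3)
  if (f(lo) > 0 || f(hi) < 0) {
    stop_icufusion("target failure probability unattainable in bracket",
      "icufusion_domain_error")
  }
  root <- stats::uniroot(f, c(lo, hi), tol = 1e-12)$root
  gamma <- exp(root)
  r <- gamma * mean_lifetime
  list(repair_h = r, repair_h_rounded = round(r), gamma = gamma)
}

#' Reliability improvement of a third node
#'
#' `(PF(2) - PF(3)) / PF(2) = 1 - 2 gamma (1 + gamma) / ((2 gamma + 1)(gamma
#' + 2))`: the fraction of two-node failure risk removed by adding a third
#' node. Strictly decreasing in `gamma` and tending to 1 as `gamma -> 0`,
#' so fast repairs relative to lifetimes make the third node remove
#' essentially all residual risk.
#'
#' @param gamma Positive repair/lifetime ratio.
#' @return Improvement fraction in (0, 1).
#' @examples
#' improvement(1e-3) # 0.9990...
#' @export
improvement <- function(gamma) {
  if (anyNA(gamma) || any(gamma <= 0)) {
    stop_icufusion("gamma must be positive (the ratio is 0/0 at gamma = 0)",
      "icufusion_domain_error")
  }
  (pf2(gamma) - pf3(gamma)) / pf2(gamma)
}

#' Failure-probability curves over gamma
#'
#' @param gamma Vector of repair/lifetime ratios.
#' @param I_values Node counts to tabulate.
#' @return A long tibble with columns `gamma`, `I`, `pf`, suitable for
#'   [plot_reliability_curves()] or CSV export.
#' @export
reliability_curves <- function(gamma = 10^seq(-4, 1, length.out = 101),
                               I_values = c(2L, 3L)) {
  purrr::map(I_values, function(I) {
    tibble::tibble(gamma = gamma, I = I, pf = pf_general(I, gamma))
  }) |> dplyr::bind_rows()
}
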