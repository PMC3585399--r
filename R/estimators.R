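# Free energy estimators: exponential averaging (EXP) and the Bennett
# acceptance ratio (BAR), with block-based standard errors.

#' Lambda schedule for an alchemical leg
#'
#' @param kind `"dense_endpoints"` (default for restraint morphs: extra
#'   windows crowded against both endpoints where ligand sets appear and
#'   disappear) or `"uniform"`.
#' @param n Number of values for the uniform schedule.
#' @param values Explicit values overriding `kind` (must be strictly
#'   increasing and include 0 and 1).
#' @param direction `"forward"` traverses 0 to 1, `"reverse"` is the exact
#'   mirror.
#' @return Object of class `lambda_schedule` with `values` (ascending) and
#'   `direction`.
#' @export
lambda_schedule <- function(kind = c("dense_endpoints", "uniform"), n = 21,
                            values = NULL,
                            direction = c("forward", "reverse")) {
  direction <- match.arg(direction)
  if (is.null(values)) {
    kind <- match.arg(kind)
    values <- if (kind == "dense_endpoints") {
      c(0, 1e-5, 1e-4, 1e-3, 1e-2, seq(0.05, 0.95, by = 0.05),
        0.99, 0.999, 0.9999, 0.99999, 1)
    } else {
      seq(0, 1, length.out = n)
    }
  }
  values <- as.numeric(values)
  if (is.unsorted(values, strictly = TRUE))
    stop("lambda schedule must be strictly increasing")
  if (values[1] != 0 || values[length(values)] != 1)
    stop("lambda schedule must include both endpoints 0 and 1")
  structure(list(values = values, direction = direction),
            class = "lambda_schedule")
}

#' Traversal order of a schedule
#' @param schedule A `lambda_schedule`.
#' @return Values in simulation order (reversed for a reverse schedule).
#' @export
schedule_traversal <- function(schedule) {
  if (schedule$direction == "reverse") rev(schedule$values) else schedule$values
}

exp_estimate <- function(du, kT) {
  # dG = -kT log mean exp(-du/kT), computed stably
  m <- min(du)
  m - kT * log(mean(exp(-(du - m) / kT)))
}

exp_with_se <- function(du, kT, nblocks = 10) {
  n <- length(du)
  dg <- exp_estimate(du, kT)
  nb <- max(2, min(nblocks, floor(n / 2)))
  blocks <- split(seq_len(n), cut(seq_len(n), nb, labels = FALSE))
  bvals <- vapply(blocks, function(ix) exp_estimate(du[ix], kT), numeric(1))
  c(dG = dg, se = stats::sd(bvals) / sqrt(length(bvals)))
}

bar_solve <- function(wf, wr, kT) {
  # Bennett self-consistency: solve for C in
  #   sum_F fermi((wF - C)/kT) = sum_R fermi((wR + C)/kT),
  # then dG = C - kT log(nR/nF).  fermi(x) = 1/(1+exp(x)).
  nF <- length(wf); nR <- length(wr)
  fermi <- function(x) 1 / (1 + exp(pmin(x, 500)))
  g <- function(C) sum(fermi((wf - C) / kT)) - sum(fermi((wr + C) / kT))
  lo <- min(c(wf, -wr)) - 50 * kT
  hi <- max(c(wf, -wr)) + 50 * kT
  if (g(lo) > 0 || g(hi) < 0) return(exp_estimate(wf, kT))  # degenerate data
  C <- stats::uniroot(g, c(lo, hi), tol = 1e-10, maxiter = 10000)$root
  C - kT * log(nR / nF)
}

bar_with_se <- function(wf, wr, kT, nblocks = 10) {
  dg <- bar_solve(wf, wr, kT)
  nb <- max(2, min(nblocks, floor(min(length(wf), length(wr)) / 2)))
  bf <- split(seq_along(wf), cut(seq_along(wf), nb, labels = FALSE))
  br <- split(seq_along(wr), cut(seq_along(wr), nb, labels = FALSE))
  bvals <- vapply(seq_len(nb), function(b)
    bar_solve(wf[bf[[b]]], wr[br[[b]]], kT), numeric(1))
  c(dG = dg, se = stats::sd(bvals) / sqrt(nb))
}

# fep_samples: windows stored in ascending lambda order; each window holds
# u_self (potential at its own lambda), u_hi (re-evaluated at the next higher
# lambda) and u_lo (next lower lambda), over post-equilibration frames.
new_fep_samples <- function(windows, direction, temperature) {
  structure(list(windows = windows, direction = direction,
                 temperature = temperature),
            class = "fep_samples")
}

check_window_samples <- function(w, i) {
  if (length(w$u_self) < 10)
    stop("insufficient sampling: window ", i, " has fewer than 10 samples")
}

#' Exponential-averaging (EXP) free energy estimate
#'
#' Per-window increments
#' `dG_i = -kB T log < exp(-(U_next - U_self) / kB T) >` over the
#' post-equilibration samples of each window, summed along the leg's
#' traversal. A forward leg estimates `G(1) - G(0)`; a reverse leg estimates
#' `G(0) - G(1)` (the opposite sign convention, as conventional for
#' hysteresis checks).
#'
#' @param samples A `fep_samples` object (each window holds the potential
#'   energy at its own lambda and at its neighbours).
#' @param temperature Temperature (K).
#' @return List of class `fep_estimate`: `per_window` data frame
#'   (`lambda_from`, `lambda_to`, `dG`, `se`), `total_dG`, `total_se`,
#'   `estimator`, `direction`.
#' @export
estimate_exp <- function(samples, temperature = 310) {
  kT <- rlf_constants()$kB * temperature
  wins <- samples$windows
  K <- length(wins)
  idx <- if (samples$direction == "reverse") seq(K, 2) else seq_len(K - 1)
  rows <- lapply(idx, function(i) {
    w <- wins[[i]]
    check_window_samples(w, i)
    if (samples$direction == "reverse") {
      du <- w$u_lo - w$u_self
      to <- wins[[i - 1]]$lambda
    } else {
      du <- w$u_hi - w$u_self
      to <- wins[[i + 1]]$lambda
    }
    est <- exp_with_se(du, kT)
    data.frame(lambda_from = w$lambda, lambda_to = to,
               dG = est[["dG"]], se = est[["se"]])
  })
  per <- do.call(rbind, rows)
  structure(list(per_window = per, total_dG = sum(per$dG),
                 total_se = sqrt(sum(per$se^2)), estimator = "exp",
                 direction = samples$direction),
            class = "fep_estimate")
}

#' Bennett acceptance ratio (BAR) free energy estimate
#'
#' Solves the Bennett self-consistency for every adjacent window pair, using
#' the forward work from the lower window's samples and the reverse work from
#' the upper window's samples. When a separately simulated reverse leg is
#' supplied, the reverse work comes from its samples; otherwise both sides
#' come from `samples` (every state is simulated once per leg). The total is
#' reported in the traversal direction of `samples`.
#'
#' @param samples `fep_samples` for the leg.
#' @param reverse_samples Optional `fep_samples` from a run of the same
#'   schedule in the opposite direction.
#' @param temperature Temperature (K).
#' @return A `fep_estimate` (see [estimate_exp()]).
#' @export
estimate_bar <- function(samples, reverse_samples = NULL, temperature = 310) {
  kT <- rlf_constants()$kB * temperature
  wins <- samples$windows
  upper <- if (is.null(reverse_samples)) wins else reverse_samples$windows
  K <- length(wins)
  if (length(upper) != K) stop("mismatched window counts between directions")
  rows <- lapply(seq_len(K - 1), function(i) {
    w <- wins[[i]]
    wu <- upper[[i + 1]]
    check_window_samples(w, i)
    check_window_samples(wu, i + 1)
    wf <- w$u_hi - w$u_self   # U(l_{i+1}) - U(l_i) on l_i samples
    wr <- wu$u_lo - wu$u_self # U(l_i) - U(l_{i+1}) on l_{i+1} samples
    est <- bar_with_se(wf, wr, kT)
    data.frame(lambda_from = w$lambda, lambda_to = wins[[i + 1]]$lambda,
               dG = est[["dG"]], se = est[["se"]])
  })
  per <- do.call(rbind, rows)
  total <- sum(per$dG)
  if (samples$direction == "reverse") {
    total <- -total
    per$dG <- -per$dG
  }
  structure(list(per_window = per, total_dG = total,
                 total_se = sqrt(sum(per$se^2)), estimator = "bar",
                 direction = samples$direction),
            class = "fep_estimate")
}

#' Hysteresis between forward and reverse legs
#'
#' Sign-aligned disagreement `|dG_forward + dG_reverse|` (a reverse leg
#' estimates the negated free energy difference, so a perfectly converged
#' pair sums to zero). A standard convergence diagnostic for alchemical
#' campaigns.
#'
#' @param forward,reverse `fep_leg` (or `fep_estimate`) objects for the same
#'   leg run in opposite directions.
#' @return Absolute discrepancy in kcal/mol.
#' @export
hysteresis <- function(forward, reverse) {
  abs(forward$total_dG + reverse$total_dG)
}

#' Aggregate hysteresis over a campaign
#' @param values Numeric vector of per-leg hysteresis values.
#' @return Named numeric `c(max = , mean = )`.
#' @export
hysteresis_summary <- function(values) {
  c(max = max(values), mean = mean(values))
}
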