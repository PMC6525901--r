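#' Daily-arrival distribution specification
#'
#' Arrival volumes are modelled as a distribution of *daily arrival counts*
#' (one real draw per day, clamped at zero and rounded to a count). Two
#' families are supported: the bounded four-parameter Johnson SB
#' distribution, and the uniform distribution.
#'
#' @param family `"johnson_sb"` or `"uniform"`.
#' @param params numeric parameter vector: Johnson SB `(gamma, delta, xi,
#'   lambda)` — two shape parameters, location and scale, support
#'   `(xi, xi + lambda)`, requiring `delta > 0`, `lambda > 0`; uniform
#'   `(lo, hi)` with `hi > lo`.
#' @return Object of class `arrival_spec`.
#' @examples
#' arrival_spec("johnson_sb", c(0.025, 0.803, -8.16, 85.98))
#' arrival_spec("uniform", c(-0.72, 43.75))
#' @export
arrival_spec <- function(family = c("johnson_sb", "uniform"), params) {
  family <- match.arg(family)
  params <- as.numeric(params)
  if (family == "johnson_sb") {
    if (length(params) != 4)
      stop_bad("johnson_sb needs 4 parameters (gamma, delta, xi, lambda)")
    if (params[2] <= 0 || params[4] <= 0)
      stop_bad("johnson_sb requires delta > 0 and lambda > 0")
    names(params) <- c("gamma", "delta", "xi", "lambda")
  } else {
    if (length(params) != 2) stop_bad("uniform needs 2 parameters (lo, hi)")
    if (params[2] <= params[1]) stop_bad("uniform requires hi > lo")
    names(params) <- c("lo", "hi")
  }
  structure(list(family = family, params = params), class = "arrival_spec")
}

#' @export
print.arrival_spec <- function(x, ...) {
  cat(sprintf("<arrival %s (%s)>\n", x$family,
              paste(format(x$params, trim = TRUE), collapse = ", ")))
  invisible(x)
}

#' Sample from a Johnson SB distribution
#'
#' Draws `z` from a standard normal and returns
#' `xi + lambda / (1 + exp((gamma - z) / delta))`, which always lies in the
#' open interval `(xi, xi + lambda)`.
#'
#' @param n number of draws.
#' @param spec an [arrival_spec()] with family `"johnson_sb"`, or a numeric
#'   vector `(gamma, delta, xi, lambda)`.
#' @return Numeric vector of `n` draws.
#' @export
sample_johnson_sb <- function(n, spec) {
  if (!inherits(spec, "arrival_spec")) spec <- arrival_spec("johnson_sb", spec)
  if (spec$family != "johnson_sb") stop_bad("spec is not johnson_sb")
  p <- spec$params
  z <- stats::rnorm(n)
  p[["xi"]] + p[["lambda"]] / (1 + exp((p[["gamma"]] - z) / p[["delta"]]))
}

# Johnson SB density-weighted moment, for moment checks
johnson_sb_moment <- function(spec, order = 1) {
  p <- spec$params
  f <- function(z) {
    x <- p[["xi"]] + p[["lambda"]] / (1 + exp((p[["gamma"]] - z) / p[["delta"]]))
    x^order * stats::dnorm(z)
  }
  stats::integrate(f, -12, 12, rel.tol = 1e-10)$value
}

#' Sample daily arrival counts
#'
#' Draws one real per day from the arrival distribution, clamps negative
#' draws to zero, and rounds half-up to an integer count.
#'
#' @param n number of days.
#' @param spec an [arrival_spec()].
#' @return Integer vector of daily arrival counts.
#' @export
sample_daily_arrivals <- function(n, spec) {
  stopifnot(inherits(spec, "arrival_spec"))
  x <- switch(spec$family,
    johnson_sb = sample_johnson_sb(n, spec),
    uniform = stats::runif(n, spec$params[["lo"]], spec$params[["hi"]]))
  as.integer(round_half_up(pmax(x, 0)))
}

#' Department simulation configuration
#'
#' @param arrival an [arrival_spec()], or `NULL` when a fixed arrival vector
#'   will be supplied to [simulate_department()].
#' @param los_days constant service time in whole days (the department's
#'   median length of stay), `>= 1`.
#' @param admit_prob probability that an arriving patient is admitted (the
#'   hospitalization proportion); the remainder leave immediately.
#' @param beds number of identical bed-servers, `>= 1`.
#' @param horizon_days simulated horizon in days (default one year, 365).
#' @param seed RNG seed making the run reproducible.
#' @param name optional department label.
#' @return Object of class `dept_sim_config`.
#' @examples
#' dept_sim_config(arrival_spec("johnson_sb", c(0.025, 0.803, -8.16, 85.98)),
#'                 los_days = 10, admit_prob = 0.43, beds = 236, seed = 1)
#' @export
dept_sim_config <- function(arrival, los_days, admit_prob, beds,
                            horizon_days = 365L, seed = 1L, name = NULL) {
  if (!is.null(arrival)) stopifnot(inherits(arrival, "arrival_spec"))
  los_days <- as.integer(los_days); beds <- as.integer(beds)
  horizon_days <- as.integer(horizon_days)
  if (los_days < 1) stop_bad("los_days must be >= 1")
  if (admit_prob < 0 || admit_prob > 1) stop_bad("admit_prob must be in [0,1]")
  if (beds < 1) stop_bad("beds must be >= 1")
  if (horizon_days <= 0) stop_bad("horizon_days must be positive")
  structure(list(arrival = arrival, los_days = los_days,
                 admit_prob = admit_prob, beds = beds,
                 horizon_days = horizon_days, seed = as.integer(seed),
                 name = name),
            class = "dept_sim_config")
}

# Core day-stepped occupancy engine. `admitted` is the integer vector of
# daily admitted counts; all of a day's admissions join the queue at day
# start, service lasts exactly `los` days, discharges happen at day end.
# Returns occupied bed-days within the horizon, discharges completing within
# the horizon, and the end-of-horizon queue length.
run_occupancy <- function(admitted, beds, los) {
  horizon <- length(admitted)
  comp <- integer(horizon + los)   # completions at end of day t
  busy <- 0L; queue <- 0L
  occupied <- 0; discharges <- 0L
  for (t in seq_len(horizon)) {
    if (t > 1L) busy <- busy - comp[t - 1L]
    queue <- queue + admitted[t]
    start_n <- min(queue, beds - busy)
    if (start_n > 0L) {
      queue <- queue - start_n
      busy <- busy + start_n
      comp[t + los - 1L] <- comp[t + los - 1L] + start_n
    }
    occupied <- occupied + busy
  }
  discharges <- sum(comp[seq_len(horizon)])
  list(occupied_bed_days = occupied, discharges = discharges,
       queue_end = queue)
}

#' Simulate one department's bed occupancy for a year
#'
#' Day-stepped discrete-event simulation: each day a number of patients
#' arrives (drawn from the configured daily-arrival distribution), each is
#' independently admitted with probability `admit_prob` (otherwise leaving
#' immediately), admitted patients wait in an unbounded FIFO queue for one of
#' `beds` identical beds, and occupy a bed for exactly `los_days` days. The
#' system starts empty and runs for `horizon_days` days with no warm-up.
#' A discharge is counted when service completes within the horizon; the bed
#' occupancy rate is in-horizon occupied bed-days over
#' `beds * horizon_days`, so it always lies in `[0, 1]`.
#'
#' @param config a [dept_sim_config()].
#' @param arrivals optional fixed integer vector of daily *arrival* counts
#'   (length `horizon_days`), bypassing the arrival distribution — used for
#'   deterministic checks and common-random-number sweeps.
#' @param admitted optional fixed integer vector of daily *admitted* counts,
#'   bypassing both arrival sampling and admission thinning.
#' @return Object of class `bed_sim`: list with `beds`, `discharges`, `bor`,
#'   `occupied_bed_days`, `admitted_total`, `arrivals_total`, `queue_end`,
#'   `config`.
#' @examples
#' cfg <- dept_sim_config(NULL, los_days = 1, admit_prob = 1, beds = 10,
#'                        horizon_days = 365, seed = 1)
#' simulate_department(cfg, arrivals = rep(5L, 365))  # BOR 0.5, 1825 discharges
#' @export
simulate_department <- function(config, arrivals = NULL, admitted = NULL) {
  stopifnot(inherits(config, "dept_sim_config"))
  h <- config$horizon_days
  if (is.null(admitted)) {
    local_seed(config$seed, {
      if (is.null(arrivals)) {
        if (is.null(config$arrival))
          stop_bad("config has no arrival spec and no fixed arrivals given")
        arrivals <- sample_daily_arrivals(h, config$arrival)
      }
      stopifnot(length(arrivals) == h)
      admitted <- if (config$admit_prob >= 1) as.integer(arrivals)
        else stats::rbinom(h, arrivals, config$admit_prob)
    })
  } else {
    if (is.null(arrivals)) arrivals <- admitted
    stopifnot(length(admitted) == h)
  }
  res <- run_occupancy(as.integer(admitted), config$beds, config$los_days)
  structure(list(
    beds = config$beds,
    discharges = res$discharges,
    bor = res$occupied_bed_days / (config$beds * h),
    occupied_bed_days = res$occupied_bed_days,
    admitted_total = sum(admitted),
    arrivals_total = sum(arrivals),
    queue_end = res$queue_end,
    config = config), class = "bed_sim")
}

#' @export
print.bed_sim <- function(x, ...) {
  cat(sprintf("<bed_sim%s beds=%d discharges=%d BOR=%.1f%% queue_end=%d>\n",
              if (!is.null(x$config$name)) paste0(" ", x$config$name) else "",
              x$beds, x$discharges, 100 * x$bor, x$queue_end))
  invisible(x)
}

#' Sweep candidate bed counts and record the beds-to-BOR curve
#'
#' Runs the occupancy simulation at each candidate bed count, averaging over
#' replications. Within a replication the same sampled admission stream is
#' reused for every bed count (common random numbers), so along the sweep
#' BOR is non-increasing and discharges are non-decreasing in the bed count,
#' pathwise.
#'
#' @param config a [dept_sim_config()]; its `beds` field is ignored.
#' @param bed_values integer vector of candidate bed counts.
#' @param replications number of independent replications (`>= 1`).
#' @return Data frame of class `bed_sweep` with columns `beds`,
#'   `discharges`, `bor` (replication means).
#' @seealso [fit_bor_curves()] for fitting the resulting curve.
#' @export
sweep_beds <- function(config, bed_values, replications = 1L) {
  stopifnot(inherits(config, "dept_sim_config"))
  if (!length(bed_values)) stop_bad("bed_values must be nonempty")
  if (replications < 1) stop_bad("replications must be >= 1")
  bed_values <- as.integer(bed_values)
  h <- config$horizon_days
  streams <- local_seed(config$seed, {
    lapply(seq_len(replications), function(r) {
      arr <- sample_daily_arrivals(h, config$arrival)
      adm <- if (config$admit_prob >= 1) arr
        else stats::rbinom(h, arr, config$admit_prob)
      as.integer(adm)
    })
  })
  disch <- bor <- matrix(0, length(bed_values), replications)
  for (r in seq_len(replications)) {
    for (i in seq_along(bed_values)) {
      res <- run_occupancy(streams[[r]], bed_values[i], config$los_days)
      disch[i, r] <- res$discharges
      bor[i, r] <- res$occupied_bed_days / (bed_values[i] * h)
    }
  }
  structure(
    data.frame(beds = bed_values,
               discharges = rowMeans(disch),
               bor = rowMeans(bor)),
    class = c("bed_sweep", "data.frame"),
    replications = replications, config = config)
}

#' Relative validation error of a simulated point against observed data
#'
#' @param sim a `bed_sim`, one-row `bed_sweep`, or list with `discharges`
#'   and `bor`.
#' @param observed_discharges,observed_bor observed annual discharges and
#'   bed occupancy rate (both `> 0`).
#' @return Named numeric vector `c(discharges = , bor = )` of relative
#'   differences in percent.
#' @examples
#' validate_simulation(list(discharges = 5984, bor = 0.695), 5478, 0.752)
#' @export
validate_simulation <- function(sim, observed_discharges, observed_bor) {
  if (observed_discharges <= 0 || observed_bor <= 0)
    stop_bad("observed values must be positive")
  c(discharges = 100 * abs(sim$discharges - observed_discharges) /
      observed_discharges,
    bor = 100 * abs(sim$bor - observed_bor) / observed_bor)
}

#' Read/write a bed-sweep table
#'
#' CSV with columns `beds,discharges,bor` (`bor` as a decimal fraction;
#' `discharges` optional on read).
#'
#' @param x a `bed_sweep` or data frame.
#' @param file path.
#' @return `read_sweep` returns a `bed_sweep` data frame.
#' @export
write_sweep <- function(x, file) {
  y <- as.data.frame(x)
  y$bor <- round(y$bor, 6)
  utils::write.csv(y, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_sweep
#' @export
read_sweep <- function(file) {
  x <- utils::read.csv(file)
  if (!all(c("beds", "bor") %in% names(x)))
    stop_bad("sweep file needs columns beds, bor")
  structure(x, class = c("bed_sweep", "data.frame"))
}
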