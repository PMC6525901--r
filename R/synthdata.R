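# Synthetic fixtures with known ground truth: registries for the census
# stage, noisy BOR curves for the curve-fitting stage, and small allocation
# problems with an attached exact optimum for solver cross-validation.

#' Specification of a synthetic admission/discharge registry
#'
#' Emulates the structure of a hospital information system registry: many
#' departments, stays that cross the analysis-window boundary (carry-over
#' admissions before the window, discharges after it), and a configurable
#' fraction of discharges whose admission record is missing.
#'
#' @param departments data frame with columns `name`, `beds`,
#'   `arrival_mean` (mean admitted patients per day), `median_los` (days);
#'   optional `los_sdlog` (log-scale spread of the discretized lognormal
#'   length-of-stay, default 0.5).
#' @param window an [analysis_window()].
#' @param missing_admission_rate fraction of in-window discharges whose
#'   admission date is deleted (producing missing-admission records).
#' @param carryover_rate fraction of stays forced to cross the window end
#'   (their discharge is pushed past it).
#' @param seed mandatory RNG seed.
#' @return Object of class `registry_spec`.
#' @export
registry_spec <- function(departments, window,
                          missing_admission_rate = 0,
                          carryover_rate = 0, seed) {
  stopifnot(inherits(window, "analysis_window"),
            is.data.frame(departments),
            all(c("name", "beds", "arrival_mean", "median_los") %in%
                  names(departments)))
  if (missing(seed)) stop_bad("registry_spec requires a seed")
  if (missing_admission_rate < 0 || missing_admission_rate > 1 ||
      carryover_rate < 0 || carryover_rate > 1)
    stop_bad("rates must be in [0, 1]")
  if (is.null(departments$los_sdlog)) departments$los_sdlog <- 0.5
  structure(list(departments = departments, window = window,
                 missing_admission_rate = missing_admission_rate,
                 carryover_rate = carryover_rate,
                 seed = as.integer(seed)),
            class = "registry_spec")
}

# discretized lognormal LOS, median-matched, >= 1 day
sample_los <- function(n, median_los, sdlog) {
  pmax(1, round_half_up(stats::rlnorm(n, meanlog = log(median_los),
                                      sdlog = sdlog)))
}

#' Generate a synthetic registry with ground-truth census
#'
#' Simulates admitted stays per department (Poisson daily admissions over a
#' lead-in period plus the analysis window, discretized-lognormal length of
#' stay), optionally forces a fraction of stays to cross the window end, and
#' deletes admission dates from a fraction of in-window discharges. The
#' exact per-department stay-type counts, in-window bed-day totals and BOR
#' that a census of the emitted records should recover are computed
#' alongside by direct arithmetic.
#'
#' @param spec a [registry_spec()].
#' @return List with `records` (registry data frame, shuffled), `truth`
#'   (per-department data frame: `department`, `beds`, `n_type1`,
#'   `n_type2`, `n_type3`, `los_total`, `median_los`, `bor`, `group`), and
#'   `spec`.
#' @examples
#' w <- analysis_window("2013-01-01", "2013-12-31")
#' deps <- data.frame(name = "D1", beds = 30, arrival_mean = 2,
#'                    median_los = 8)
#' reg <- generate_registry(registry_spec(deps, w, seed = 1))
#' all.equal(department_census(reg$records, c(D1 = 30), w)$bor,
#'           reg$truth$bor)
#' @export
generate_registry <- function(spec) {
  stopifnot(inherits(spec, "registry_spec"))
  w <- spec$window
  local_seed(spec$seed, {
    recs <- list(); truths <- list()
    for (r in seq_len(nrow(spec$departments))) {
      d <- spec$departments[r, ]
      lead <- ceiling(stats::qlnorm(0.999, log(d$median_los), d$los_sdlog))
      days <- seq(w$start - lead, w$end, by = "day")
      n_adm <- stats::rpois(length(days), d$arrival_mean)
      adm <- rep(days, n_adm)
      los <- sample_los(length(adm), d$median_los, d$los_sdlog)
      dis <- adm + los
      # force a fraction of in-window admissions to carry over the window end
      if (spec$carryover_rate > 0) {
        inw <- which(adm >= w$start & dis <= w$end)
        push <- inw[stats::runif(length(inw)) < spec$carryover_rate]
        dis[push] <- w$end + sample(1:30, length(push), replace = TRUE)
      }
      # all admissions are <= window end by construction
      type <- ifelse(dis < w$start, "out",
                     ifelse(dis <= w$end, "type1", "type2"))
      # delete admission dates on a fraction of in-window discharges
      drop_adm <- type == "type1" &
        stats::runif(length(adm)) < spec$missing_admission_rate
      type[drop_adm] <- "type3"

      los1 <- as.numeric(dis[type == "type1"] -
                           pmax(adm[type == "type1"], w$start))
      los2 <- as.numeric(w$end - pmax(adm[type == "type2"], w$start))
      med <- if (length(los1)) stats::median(los1) else NA_real_
      n3 <- sum(type == "type3")
      los_total <- sum(los1) + sum(los2) + n3 * med
      truths[[r]] <- data.frame(
        department = d$name, beds = d$beds,
        n_type1 = sum(type == "type1"), n_type2 = sum(type == "type2"),
        n_type3 = n3, n_out = sum(type == "out"),
        los_total = los_total, median_los = med,
        bor = los_total / (d$beds * w$capacity_days),
        stringsAsFactors = FALSE)
      recs[[r]] <- data.frame(
        patient_id = sprintf("%s-%05d", d$name, seq_along(adm)),
        department = d$name,
        admission_date = replace(adm, drop_adm, NA),
        discharge_date = dis,
        stringsAsFactors = FALSE)
    }
    records <- do.call(rbind, recs)
    records <- records[sample.int(nrow(records)), ]
    rownames(records) <- NULL
    truth <- do.call(rbind, truths)
    truth$group <- group_departments(truth$bor)
    list(records = records, truth = truth, spec = spec)
  })
}

#' Generate a noisy beds-to-BOR curve from a known response function
#'
#' @param fn a [bor_function()] (the ground truth).
#' @param bed_values bed counts at which to evaluate.
#' @param noise_sd standard deviation of additive Gaussian noise
#'   (`>= 0`).
#' @param seed RNG seed.
#' @return Data frame with columns `beds`, `bor`.
#' @export
generate_bor_curve <- function(fn, bed_values, noise_sd = 0, seed = 1L) {
  stopifnot(inherits(fn, "bor_function"), noise_sd >= 0)
  local_seed(seed, {
    data.frame(beds = bed_values,
               bor = evaluate_bor(fn, bed_values) +
                 stats::rnorm(length(bed_values), 0, noise_sd))
  })
}

#' Generate a small random allocation problem with known optimum
#'
#' Draws `n` departments with random concave quadratic BOR responses and
#' narrow bed bounds (so exhaustive enumeration stays below one million
#' candidates), sets the budget inside the feasible band, and attaches the
#' exact optimum found by [solve_exact()] — a harness for validating
#' [solve_ga()] against the oracle.
#'
#' @param n number of departments (2 to 4).
#' @param seed RNG seed.
#' @return List with `problem` (an [allocation_problem()]) and `optimum`
#'   (the `allocation_solution` from [solve_exact()]).
#' @export
generate_problem <- function(n, seed) {
  stopifnot(n >= 2, n <= 4)
  local_seed(seed, {
    centers <- sample(40:120, n, replace = TRUE)
    width <- sample(5:10, n, replace = TRUE)
    L <- pmax(12L, as.integer(centers - width))
    U <- as.integer(centers + width)
    deps <- lapply(seq_len(n), function(i) {
      beta <- stats::runif(1, 0.6, 0.95)
      a <- stats::runif(1, 0.002, 0.012)
      b <- -stats::runif(1, 2e-5, 2e-4)
      department_spec(paste0("S", i), bor_function(beta, a, b), L[i], U[i])
    })
    slack <- sum(U) - sum(L)
    total <- sum(L) + sample.int(slack + 1L, 1L) - 1L
    problem <- allocation_problem(deps, total)
    list(problem = problem, optimum = solve_exact(problem))
  })
}
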