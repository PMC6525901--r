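# Accessors for the packaged five-department case study (a large tertiary
# hospital's 2013 registry): per-department arrival distributions and median
# stays, bed-sweep simulation tables, fitted quadratic BOR responses, bed
# bounds and the 644-bed budget.

case_study_file <- function(name) {
  f <- system.file("extdata", name, package = "bedalloc", mustWork = TRUE)
  f
}

#' Packaged case-study inputs
#'
#' `case_study_config()` returns the raw parameter list of the packaged
#' five-department case study (departments W9, W10, W6, W27, W19): current
#' beds, observed BOR, fitted daily-arrival distributions, median lengths of
#' stay, quadratic BOR response coefficients, bed bounds and the total-bed
#' budget. `case_study_problem()` builds the corresponding
#' [allocation_problem()]; `case_study_sweeps()` returns the five packaged
#' beds-to-BOR sweep tables; `case_study_initial_bors()` returns the
#' simulated pre-optimization BOR of each department at its current bed
#' count (the last column of each sweep at the current beds).
#'
#' @return See above; `case_study_sweeps()` gives a named list of
#'   `bed_sweep` data frames.
#' @examples
#' p <- case_study_problem()
#' objective_z(case_study_initial_bors())  # 0.7344
#' @export
case_study_config <- function() {
  jsonlite::read_json(case_study_file("case_study.json"),
                      simplifyVector = TRUE, simplifyDataFrame = FALSE)
}

#' @rdname case_study_config
#' @export
case_study_problem <- function() {
  cfg <- case_study_config()
  deps <- lapply(cfg$departments, function(d)
    department_spec(d$name,
                    bor_function(d$bor_fn$beta, d$bor_fn$a, d$bor_fn$b),
                    d$lower, d$upper))
  allocation_problem(deps, cfg$total_beds)
}

#' @rdname case_study_config
#' @export
case_study_sweeps <- function() {
  cfg <- case_study_config()
  nm <- vapply(cfg$departments, `[[`, character(1), "name")
  stats::setNames(
    lapply(nm, function(d) read_sweep(case_study_file(paste0("sweep_", d, ".csv")))),
    nm)
}

#' @rdname case_study_config
#' @export
case_study_initial_bors <- function() {
  cfg <- case_study_config()
  stats::setNames(
    vapply(cfg$departments, `[[`, numeric(1), "initial_sim_bor"),
    vapply(cfg$departments, `[[`, character(1), "name"))
}
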