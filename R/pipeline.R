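# End-to-end orchestration: census -> per-department simulation sweep ->
# curve fitting -> allocation -> ward-mix enumeration. Stage boundaries are
# plain R structures (and CSV/JSON on disk), so any stage's output can be
# substituted from another tool.

pipeline_yaml <- function(config) {
  if (is.character(config) && length(config) == 1 && file.exists(config))
    yaml::read_yaml(config) else config
}

#' Run the three-stage bed-allocation pipeline
#'
#' Executes, in order: (I) registry census and occupancy grouping, (II) a
#' bed-count sweep of the occupancy simulation per selected department
#' followed by curve estimation of the beds-to-BOR response, and (III) the
#' allocation model, solved exactly and/or by the genetic algorithm, with
#' ward mixes enumerated for the chosen bed counts. Stages may be skipped by
#' supplying their outputs directly (e.g. precomputed sweep tables), so the
#' pipeline can mix simulated and externally produced artifacts.
#'
#' Department selection after the census is threshold-driven (occupancy
#' groups A and B are the candidates) but deliberately requires an explicit
#' confirmation list (`select`): reallocating beds is a managerial decision,
#' not an automatic one.
#'
#' @param config a named list (or path to an equivalent YAML file) with
#'   entries:
#'   \describe{
#'     \item{`window`}{list with `start`, `end` (dates); required when the
#'       census stage runs.}
#'     \item{`census`}{optional list: `records` (data frame or CSV path),
#'       `beds` (named vector/data frame/CSV path), optional `low`, `high`
#'       thresholds.}
#'     \item{`select`}{character vector of confirmed departments to
#'       reallocate (required when a census is run).}
#'     \item{`departments`}{optional named list of per-department simulation
#'       settings: `arrival` (list `family`, `params`), `los_days`,
#'       `admit_prob`, `sweep_beds` (integer vector), `replications`.}
#'     \item{`sweeps`}{optional named list of sweep tables (data frames or
#'       CSV paths), used instead of simulating.}
#'     \item{`current_beds`}{named vector of present bed counts.}
#'     \item{`initial_bors`}{optional named vector of pre-optimization BORs;
#'       when absent they are taken from each department's sweep row at its
#'       current bed count.}
#'     \item{`allocation`}{list: `bounds` (named list of `c(lower, upper)`),
#'       optional `total_beds` (default: sum of current beds), `solver`
#'       (`"exact"`, `"ga"` or `"both"`; default `"exact"`), `seed`, and
#'       optional `ga` parameter list passed to [solve_ga()].}
#'     \item{`seed`}{base seed for the simulation stage.}
#'     \item{`out_dir`}{optional directory to write per-stage artifacts
#'       (census CSV, sweep CSVs, fit tables, solution JSON, report JSON).}
#'   }
#' @return Object of class `bed_pipeline`: list with `census`, `sweeps`,
#'   `fits`, `bor_functions`, `initial` (`beds`, `bors`, `z`), `solutions`,
#'   `best` (lowest-Z solution), `report` (plain-list summary mirroring the
#'   initial-vs-optimal comparison), and the effective `config`.
#' @examples
#' cfg <- case_study_config()
#' sol <- run_pipeline(list(
#'   sweeps = case_study_sweeps(),
#'   current_beds = sapply(cfg$departments, `[[`, "current_beds"),
#'   allocation = list(bounds = lapply(cfg$departments,
#'                                     function(d) c(d$lower, d$upper)),
#'                     solver = "exact")))
#' @export
run_pipeline <- function(config) {
  config <- pipeline_yaml(config)
  out <- list(config = config)
  window <- if (!is.null(config$window))
    analysis_window(config$window$start %||% config$window[[1]],
                    config$window$end %||% config$window[[2]])

  ## Stage I: census
  census <- NULL
  if (!is.null(config$census)) {
    if (is.null(window)) stop_bad("census stage requires a window")
    rec <- config$census$records
    if (is.character(rec)) rec <- read_registry(rec)
    beds <- config$census$beds
    if (is.character(beds)) beds <- utils::read.csv(beds)
    census <- department_census(rec, beds, window,
                                low = config$census$low %||% 0.85,
                                high = config$census$high %||% 0.90)
    out$census <- census
    candidates <- census$department[census$group != "C"]
    if (is.null(config$select))
      stop_bad("census ran; confirm departments to reallocate via ",
               "config$select (candidates: ",
               paste(candidates, collapse = ", "), ")")
    unknown <- setdiff(config$select, census$department)
    if (length(unknown))
      stop_bad("selected department(s) not in census: ",
               paste(unknown, collapse = ", "))
  }

  ## establish department set and current beds
  current_beds <- config$current_beds
  if (is.list(current_beds)) current_beds <- unlist(current_beds)
  if (is.null(current_beds) && !is.null(census))
    current_beds <- stats::setNames(census$beds, census$department)
  select <- config$select %||%
    names(config$sweeps) %||% names(config$departments)
  if (is.null(select)) stop_bad("no departments to process")
  select <- as.character(select)

  ## Stage II(a): sweeps (simulate, or take as supplied)
  sweeps <- list()
  for (d in select) {
    sw <- config$sweeps[[d]]
    if (!is.null(sw)) {
      if (is.character(sw)) sw <- read_sweep(sw)
    } else {
      dc <- config$departments[[d]]
      if (is.null(dc))
        stop_bad("department ", d, ": no sweep supplied and no simulation ",
                 "settings under config$departments — cannot run stage II")
      spec <- arrival_spec(dc$arrival$family, unlist(dc$arrival$params))
      cfg <- dept_sim_config(spec, dc$los_days, dc$admit_prob,
                             beds = current_beds[[d]],
                             horizon_days = dc$horizon_days %||% 365L,
                             seed = dc$seed %||% config$seed %||% 1L,
                             name = d)
      sw <- sweep_beds(cfg, unlist(dc$sweep_beds),
                       replications = dc$replications %||% 10L)
    }
    sweeps[[d]] <- sw
  }
  out$sweeps <- sweeps

  ## Stage II(b): curve estimation per department
  fits <- lapply(sweeps, fit_bor_curves)
  out$fits <- fits
  # the allocation model needs a quadratic response; if another family wins
  # the R^2 ranking, fall back to the quadratic fit with a warning
  fns <- lapply(names(fits), function(d) {
    f <- fits[[d]]
    if (f$best$form != "quadratic") {
      if (is.null(f$fits$quadratic))
        stop_bad("department ", d, ": no quadratic fit available for the ",
                 "allocation stage")
      warning("department ", d, ": best fit is '", f$best$form,
              "'; using the quadratic fit for allocation", call. = FALSE)
      as_bor_function(f$fits$quadratic)
    } else as_bor_function(f)
  })
  names(fns) <- names(fits)
  out$bor_functions <- fns

  ## initial state
  initial_bors <- config$initial_bors
  if (is.list(initial_bors)) initial_bors <- unlist(initial_bors)
  if (is.null(initial_bors)) {
    initial_bors <- vapply(select, function(d) {
      sw <- sweeps[[d]]
      i <- match(current_beds[[d]], sw$beds)
      if (is.na(i)) stop_bad("department ", d, ": current bed count not in ",
                             "its sweep; supply config$initial_bors")
      sw$bor[i]
    }, numeric(1))
  } else initial_bors <- initial_bors[select]
  initial <- list(beds = current_beds[select],
                  bors = initial_bors,
                  z = objective_z(initial_bors))
  out$initial <- initial

  ## Stage III: allocation
  al <- config$allocation
  if (is.null(al$bounds)) stop_bad("config$allocation$bounds is required")
  deps <- lapply(select, function(d) {
    b <- unlist(al$bounds[[d]])
    department_spec(d, fns[[d]], b[1], b[2])
  })
  total <- al$total_beds %||% sum(unlist(current_beds[select]))
  problem <- allocation_problem(deps, total)
  solver <- al$solver %||% "exact"
  solutions <- list()
  if (solver %in% c("exact", "both"))
    solutions$exact <- solve_exact(problem, cap = al$cap %||% 1e8)
  if (solver %in% c("ga", "both"))
    solutions$ga <- do.call(solve_ga, c(list(problem = problem,
                                             seed = al$seed %||% 1L),
                                        al$ga %||% list()))
  out$problem <- problem
  out$solutions <- solutions
  zs <- vapply(solutions, `[[`, numeric(1), "objective_z")
  out$best <- solutions[[which.min(zs)]]

  ## report
  out$report <- list(
    departments = select,
    initial_beds = as.list(initial$beds),
    initial_bors = as.list(initial$bors),
    initial_z = initial$z,
    optimal_beds = as.list(out$best$beds),
    optimal_bors = as.list(out$best$bors),
    optimal_z = out$best$objective_z,
    solver = out$best$solver,
    seeds = list(simulation = config$seed, ga = al$seed),
    bor_spread_initial = max(initial$bors) - min(initial$bors),
    bor_spread_optimal = max(out$best$bors) - min(out$best$bors))

  if (!is.null(config$out_dir)) write_pipeline(out, config$out_dir)
  class(out) <- "bed_pipeline"
  out
}

write_pipeline <- function(out, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(out$census))
    write_census(out$census, file.path(dir, "census.csv"))
  for (d in names(out$sweeps))
    write_sweep(out$sweeps[[d]], file.path(dir, paste0("sweep_", d, ".csv")))
  for (d in names(out$fits))
    utils::write.csv(out$fits[[d]]$table,
                     file.path(dir, paste0("fits_", d, ".csv")),
                     row.names = FALSE)
  best <- out$best
  jsonlite::write_json(
    list(beds = as.list(best$beds), bors = as.list(best$bors),
         objective_z = best$objective_z, solver = best$solver,
         seed = best$seed),
    file.path(dir, "solution.json"), auto_unbox = TRUE, digits = NA)
  mixes <- do.call(rbind, lapply(names(best$ward_mixes), function(d) {
    m <- best$ward_mixes[[d]]
    if (is.null(m) || !nrow(m)) return(NULL)
    cbind(department = d, as.data.frame(m))
  }))
  if (!is.null(mixes))
    utils::write.csv(mixes, file.path(dir, "ward_mixes.csv"),
                     row.names = FALSE)
  jsonlite::write_json(out$report, file.path(dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' @export
print.bed_pipeline <- function(x, ...) {
  cat("Bed-allocation pipeline run\n")
  cat(sprintf("  departments: %s\n",
              paste(x$report$departments, collapse = ", ")))
  cat(sprintf("  initial Z  = %.4f  (BOR spread %.1f%%)\n",
              x$report$initial_z, 100 * x$report$bor_spread_initial))
  cat(sprintf("  optimal Z  = %.4f  (BOR spread %.1f%%, %s solver)\n",
              x$report$optimal_z, 100 * x$report$bor_spread_optimal,
              x$report$solver))
  tab <- data.frame(department = x$report$departments,
                    beds = unlist(x$report$initial_beds),
                    bor = sprintf("%.1f%%", 100 * unlist(x$report$initial_bors)),
                    beds_opt = unlist(x$report$optimal_beds),
                    bor_opt = sprintf("%.2f%%", 100 * unlist(x$report$optimal_bors)))
  print(tab, row.names = FALSE)
  invisible(x)
}
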