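# shared fixtures, built in code

window_2013 <- function() analysis_window("2013-01-01", "2013-12-31")

# two departments whose BOR responses cross linearly: deviations cancel at
# any feasible split of the 400-bed budget
toy_problem <- function() {
  allocation_problem(list(
    department_spec("A", bor_function(0.5, 0.001, 0), 100, 300),
    department_spec("B", bor_function(0.9, -0.001, 0), 100, 300)), 400)
}

# independent brute-force minimizer over the full bounded grid
brute_force_z <- function(problem) {
  L <- problem$lower; U <- problem$upper
  grid <- do.call(expand.grid, lapply(seq_len(problem$n), function(i)
    seq.int(L[i], U[i])))
  grid <- grid[rowSums(grid) == problem$total_beds, , drop = FALSE]
  z <- apply(grid, 1, function(cc) {
    bors <- mapply(function(d, c) with(d$bor_fn, beta + a * c + b * c^2),
                   problem$departments, cc)
    sum(abs(bors - mean(bors)))
  })
  list(z = min(z), beds = as.integer(grid[which.min(z), ]))
}

quiet <- function(expr) suppressMessages(suppressWarnings(expr))

small_registry_spec <- function(seed = 1, missing = 0, carryover = 0) {
  deps <- data.frame(name = c("D1", "D2"), beds = c(30, 15),
                     arrival_mean = c(2.5, 1.2), median_los = c(8, 5))
  registry_spec(deps, window_2013(), missing_admission_rate = missing,
                carryover_rate = carryover, seed = seed)
}
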