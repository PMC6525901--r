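#' Department specification for the allocation model
#'
#' @param name department code.
#' @param bor_fn a [bor_function()] (quadratic BOR response).
#' @param lower,upper integer bed bounds, `lower <= upper`. Bed counts below
#'   12 admit no feasible single/double/triple ward mix (the smallest mix
#'   with at least two wards of each type is `2 + 2*2 + 3*2 = 12`) and are
#'   flagged with a warning.
#' @return Object of class `department_spec`.
#' @export
department_spec <- function(name, bor_fn, lower, upper) {
  stopifnot(inherits(bor_fn, "bor_function"))
  lower <- as.integer(lower); upper <- as.integer(upper)
  if (lower < 1 || lower > upper) stop_bad(name, ": need 1 <= lower <= upper")
  if (lower < 12)
    warning(name, ": bed counts below 12 admit no feasible ward mix",
            call. = FALSE)
  structure(list(name = as.character(name), bor_fn = bor_fn,
                 lower = lower, upper = upper),
            class = "department_spec")
}

#' Bed-allocation problem
#'
#' `n` departments, each with a quadratic BOR response function and integer
#' bed bounds, sharing a fixed total-bed budget. The model chooses integer
#' bed counts `C_i` with `sum(C_i) = total_beds` and
#' `lower_i <= C_i <= upper_i`, minimizing the total absolute deviation of
#' the department BORs from their mean ([objective_z()]). Ward-mix
#' integrality (single/double/triple-bed rooms, at least two of each type
#' for gender separation) is handled by post-hoc enumeration
#' ([enumerate_ward_mixes()]), since any bed count of at least 12 admits a
#' mix.
#'
#' @param departments list of [department_spec()]s (length `>= 2`).
#' @param total_beds total bed budget; must satisfy
#'   `sum(lower) <= total_beds <= sum(upper)`.
#' @return Object of class `allocation_problem`.
#' @seealso [solve_exact()], [solve_ga()], [case_study_problem()]
#' @export
allocation_problem <- function(departments, total_beds) {
  stopifnot(length(departments) >= 2,
            all(vapply(departments, inherits, logical(1), "department_spec")))
  total_beds <- as.integer(total_beds)
  L <- vapply(departments, `[[`, integer(1), "lower")
  U <- vapply(departments, `[[`, integer(1), "upper")
  if (total_beds < sum(L) || total_beds > sum(U))
    stop_bad("infeasible: total_beds must lie in [",
             sum(L), ", ", sum(U), "]")
  structure(list(departments = departments, total_beds = total_beds,
                 n = length(departments),
                 names = vapply(departments, `[[`, character(1), "name"),
                 lower = L, upper = U),
            class = "allocation_problem")
}

#' @export
print.allocation_problem <- function(x, ...) {
  cat(sprintf("Bed-allocation problem: %d departments, %d beds total\n",
              x$n, x$total_beds))
  for (d in x$departments)
    cat(sprintf("  %-6s [%d, %d]  BOR(C) = %.4g %+.4g C %+.4g C^2\n",
                d$name, d$lower, d$upper,
                d$bor_fn$beta, d$bor_fn$a, d$bor_fn$b))
  invisible(x)
}

#' Imbalance objective: total absolute deviation of BORs from their mean
#'
#' `Z = sum_i |BOR_i - mean(BOR)|`; zero iff all departments share the same
#' occupancy. Adding a common constant to every BOR leaves `Z` unchanged.
#'
#' @param bors numeric vector of department BORs (nonempty).
#' @return Nonnegative scalar `Z`.
#' @examples
#' objective_z(c(0.695, 0.647, 0.981, 0.985, 0.689))  # 0.7344
#' @export
objective_z <- function(bors) {
  if (!length(bors)) stop_bad("empty BOR vector")
  sum(abs(bors - mean(bors)))
}

# per-department BOR lookup tables over [L, U]
bor_tables <- function(problem) {
  lapply(problem$departments, function(d)
    evaluate_bor(d$bor_fn, seq.int(d$lower, d$upper)))
}

# assemble an allocation_solution object
make_solution <- function(problem, beds, solver, seed = NA_integer_,
                          extra = list()) {
  bors <- mapply(function(d, c) evaluate_bor(d$bor_fn, c),
                 problem$departments, beds)
  mixes <- lapply(beds, function(b)
    if (b >= 12) enumerate_ward_mixes(b, max_results = 3L) else NULL)
  names(mixes) <- problem$names
  out_of_range <- bors < 0 | bors > 1
  if (any(out_of_range))
    message("BOR outside [0,1] for: ",
            paste(problem$names[out_of_range], collapse = ", "))
  structure(c(list(
    beds = stats::setNames(as.integer(beds), problem$names),
    bors = stats::setNames(as.numeric(bors), problem$names),
    objective_z = objective_z(bors),
    ward_mixes = mixes,
    solver = solver, seed = seed,
    problem = problem), extra), class = "allocation_solution")
}

#' @export
print.allocation_solution <- function(x, ...) {
  cat(sprintf("Bed allocation (%s solver): Z = %.6g\n",
              x$solver, x$objective_z))
  print(data.frame(department = names(x$beds), beds = unname(x$beds),
                   bor = sprintf("%.2f%%", 100 * unname(x$bors))),
        row.names = FALSE)
  invisible(x)
}

#' @export
summary.allocation_solution <- function(object, ...) {
  print(object)
  cat(sprintf("Total beds: %d; BOR spread (max - min): %.2f%%\n",
              sum(object$beds),
              100 * (max(object$bors) - min(object$bors))))
  cat("Example ward mixes (k1 singles, k2 doubles, k3 triples):\n")
  for (nm in names(object$ward_mixes)) {
    m <- object$ward_mixes[[nm]]
    if (is.null(m) || !nrow(m)) { cat(" ", nm, ": none\n"); next }
    cat(sprintf("  %s (%d mixes): %s\n", nm, attr(m, "count"),
                paste(apply(m, 1, function(r)
                  sprintf("(%d,%d,%d)", r[1], r[2], r[3])), collapse = " ")))
  }
  invisible(object)
}

#' Exact bed allocation by exhaustive enumeration
#'
#' Brute-force oracle: enumerates every integer bed vector within bounds
#' with the last department eliminated through the budget equality, and
#' returns the global minimizer of [objective_z()]. Candidates are visited
#' in lexicographic order and a new incumbent must improve the objective by
#' more than `tol`, so among numerically tied optima the lexicographically
#' smallest bed vector is returned. The search is vectorized over the last
#' two free departments and processed in chunks.
#'
#' @param problem an [allocation_problem()].
#' @param cap refuse searches with more than this many candidate vectors
#'   (default 1e8); larger problems should use [solve_ga()].
#' @param tol numeric tie tolerance on the objective (default 1e-12).
#' @return Object of class `allocation_solution` with fields `beds`, `bors`,
#'   `objective_z`, `ward_mixes` (up to three per department), `solver =
#'   "exact"`, `n_candidates`, `n_feasible`.
#' @examples
#' p <- allocation_problem(list(
#'   department_spec("A", bor_function(0.5, 0.001, 0), 100, 300),
#'   department_spec("B", bor_function(0.9, -0.001, 0), 100, 300)), 400)
#' solve_exact(p)$beds  # c(A = 100, B = 300), Z = 0
#' @export
solve_exact <- function(problem, cap = 1e8, tol = 1e-12) {
  stopifnot(inherits(problem, "allocation_problem"))
  n <- problem$n
  L <- problem$lower; U <- problem$upper; Ct <- problem$total_beds
  space <- prod(as.numeric(U[-n] - L[-n] + 1))
  if (space > cap)
    stop_bad("search space ", format(space, big.mark = ","),
             " exceeds cap; use solve_ga()")
  tbl <- bor_tables(problem)

  # vectorized dims: the last two free departments (or fewer when n < 4)
  if (n == 2) {
    c1 <- seq.int(L[1], U[1])
    cn <- Ct - c1
    feas <- cn >= L[n] & cn <= U[n]
    b1 <- tbl[[1]]
    bn <- rep(NA_real_, length(cn))
    bn[feas] <- tbl[[n]][cn[feas] - L[n] + 1]
    m <- (b1 + bn) / 2
    z <- abs(b1 - m) + abs(bn - m)
    z[!feas] <- Inf
    zmin <- min(z)
    if (!is.finite(zmin)) stop_bad("infeasible problem")
    i <- which(z <= zmin + tol)[1]
    sol <- make_solution(problem, c(c1[i], cn[i]), "exact",
                         extra = list(n_candidates = length(c1),
                                      n_feasible = sum(feas)))
    return(sol)
  }

  # grid over departments n-2 and n-1
  gA <- seq.int(L[n - 2], U[n - 2])
  gB <- seq.int(L[n - 1], U[n - 1])
  grid_a <- rep(gA, each = length(gB))
  grid_b <- rep(gB, times = length(gA))
  BA <- rep(tbl[[n - 2]], each = length(gB))
  BB <- rep(tbl[[n - 1]], times = length(gA))
  sAB <- grid_a + grid_b

  prefix_dims <- seq_len(n - 3)            # odometer dims (may be empty)
  widths <- U - L + 1L
  best_z <- Inf; best <- NULL
  n_feas <- 0; n_cand <- 0
  idx <- rep(0L, max(0L, n - 3L))          # odometer counters (0-based)
  repeat {
    pre <- if (length(prefix_dims)) L[prefix_dims] + idx else integer(0)
    pre_b <- if (length(prefix_dims))
      vapply(prefix_dims, function(j) tbl[[j]][pre[j] - L[j] + 1],
             numeric(1)) else numeric(0)
    rem <- Ct - sum(pre)
    cn <- rem - sAB
    feas <- cn >= L[n] & cn <= U[n]
    n_cand <- n_cand + length(cn)
    if (any(feas)) {
      n_feas <- n_feas + sum(feas)
      bn <- rep(NA_real_, length(cn))
      bn[feas] <- tbl[[n]][cn[feas] - L[n] + 1]
      tot <- sum(pre_b) + BA + BB + bn
      m <- tot / n
      z <- abs(BA - m) + abs(BB - m) + abs(bn - m)
      for (pb in pre_b) z <- z + abs(pb - m)
      z[!feas] <- Inf
      zmin <- min(z)
      if (zmin < best_z - tol) {
        i <- which(z <= zmin + tol)[1]
        best_z <- zmin
        best <- c(pre, grid_a[i], grid_b[i], cn[i])
      }
    }
    # advance odometer (last prefix dim fastest => lexicographic order)
    if (!length(prefix_dims)) break
    j <- length(idx)
    repeat {
      idx[j] <- idx[j] + 1L
      if (idx[j] < widths[j]) break
      idx[j] <- 0L; j <- j - 1L
      if (j == 0L) break
    }
    if (j == 0L) break
  }
  if (is.null(best)) stop_bad("infeasible problem")
  make_solution(problem, best, "exact",
                extra = list(n_candidates = n_cand, n_feasible = n_feas))
}

#' Enumerate feasible ward mixes for a bed count
#'
#' A department's beds are arranged in single-, double- and triple-bed
#' wards `(k1, k2, k3)` with `k1 + 2 k2 + 3 k3 = beds`; gender separation
#' requires at least two wards of each type, so the smallest feasible bed
#' count is 12. Mixes are returned in lexicographic order of
#' `(k1, k2, k3)`.
#'
#' @param beds positive integer bed count.
#' @param max_results truncate the returned list at this many mixes (the
#'   exact total count is still reported in the `count` attribute).
#' @return Data frame with columns `k1`, `k2`, `k3` and attribute `count`
#'   (exact number of feasible mixes). Bed counts below 12 yield an empty
#'   data frame with a warning.
#' @examples
#' enumerate_ward_mixes(12)          # the single mix (2, 2, 2)
#' attr(enumerate_ward_mixes(166, max_results = 5), "count")
#' @export
enumerate_ward_mixes <- function(beds, max_results = Inf) {
  beds <- as.integer(beds)
  if (beds < 1) stop_bad("beds must be positive")
  empty <- data.frame(k1 = integer(0), k2 = integer(0), k3 = integer(0))
  if (beds < 12) {
    warning("no feasible ward mix for ", beds,
            " beds (minimum is 12)", call. = FALSE)
    return(structure(empty, count = 0L))
  }
  k3 <- 2:((beds - 6) %/% 3)
  rows <- lapply(k3, function(z) {
    k2max <- (beds - 3L * z - 2L) %/% 2L
    if (k2max < 2L) return(NULL)
    k2 <- 2:k2max
    data.frame(k1 = beds - 2L * k2 - 3L * z, k2 = k2, k3 = z)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$k1, out$k2, out$k3), , drop = FALSE]
  rownames(out) <- NULL
  count <- nrow(out)
  if (is.finite(max_results) && count > max_results)
    out <- out[seq_len(max_results), , drop = FALSE]
  structure(out, count = count)
}
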