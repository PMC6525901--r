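# Genetic algorithm for the bed-allocation model.
#
# Integer-vector chromosomes (one gene per department). Every individual is
# kept feasible: after initialization, crossover and mutation, a repair
# operator redistributes the budget residual one bed at a time, always
# moving the bed whose reassignment most decreases the imbalance objective
# without leaving the bounds. Selection is tournament, crossover uniform,
# mutation per-gene random reset, with elitism.

# BOR matrix (n x pop) for a population matrix of bed counts
ga_bors <- function(pop, tbl, L) {
  n <- nrow(pop)
  B <- pop
  for (i in seq_len(n)) B[i, ] <- tbl[[i]][pop[i, ] - L[i] + 1L]
  B
}

ga_z <- function(B) {
  m <- colMeans(B)
  colSums(abs(B - rep(m, each = nrow(B))))
}

# Repair the whole population in lock step: at each pass every infeasible
# column moves one bed into (or out of) the department whose single-bed
# change most decreases Z among bound-respecting moves.
ga_repair <- function(pop, tbl, L, U, Ct) {
  n <- nrow(pop)
  repeat {
    d <- Ct - colSums(pop)
    if (all(d == 0L)) break
    B <- ga_bors(pop, tbl, L)
    for (dir in c(1L, -1L)) {
      cols <- if (dir > 0L) which(d > 0L) else which(d < 0L)
      if (!length(cols)) next
      zcand <- matrix(Inf, n, length(cols))
      for (j in seq_len(n)) {
        cj <- pop[j, cols]
        ok <- if (dir > 0L) cj < U[j] else cj > L[j]
        if (!any(ok)) next
        Bj <- B[, cols, drop = FALSE]
        Bj[j, ok] <- tbl[[j]][cj[ok] + dir - L[j] + 1L]
        zj <- ga_z(Bj)
        zj[!ok] <- Inf
        zcand[j, ] <- zj
      }
      jstar <- max.col(-t(zcand), ties.method = "first")
      if (any(!is.finite(zcand[cbind(jstar, seq_along(cols))])))
        stop_bad("no feasible repair move; problem bounds inconsistent")
      pop[cbind(jstar, cols)] <- pop[cbind(jstar, cols)] + dir
    }
  }
  pop
}

#' Genetic-algorithm bed allocation
#'
#' Solves the allocation model of [allocation_problem()] with an integer
#' genetic algorithm: uniform-random initialization within bounds followed
#' by budget repair, tournament selection, uniform crossover, per-gene
#' random-reset mutation, elitism, and a greedy repair operator that keeps
#' the budget equality satisfied for every evaluated individual. The run is
#' reproducible bit-for-bit from `seed`.
#'
#' @param problem an [allocation_problem()].
#' @param seed RNG seed (required; the GA is stochastic).
#' @param pop_size population size (default 200).
#' @param generations number of generations (default 500).
#' @param tournament tournament size for selection (default 2).
#' @param p_crossover per-pair uniform-crossover probability (default 0.9).
#' @param p_mutation per-gene random-reset mutation probability
#'   (default 0.1).
#' @param elitism number of best individuals copied unchanged (default 2).
#' @return Object of class `allocation_solution` (see [solve_exact()]) with
#'   `solver = "ga"`, the `seed`, and `generations` run.
#' @seealso [solve_exact()] for the exhaustive oracle on small problems.
#' @export
solve_ga <- function(problem, seed, pop_size = 200L, generations = 500L,
                     tournament = 2L, p_crossover = 0.9, p_mutation = 0.1,
                     elitism = 2L) {
  stopifnot(inherits(problem, "allocation_problem"))
  if (missing(seed) || is.null(seed)) stop_bad("solve_ga requires a seed")
  n <- problem$n
  L <- problem$lower; U <- problem$upper; Ct <- problem$total_beds
  tbl <- bor_tables(problem)
  local_seed(seed, {
    pop <- matrix(0L, n, pop_size)
    for (i in seq_len(n))
      pop[i, ] <- sample(seq.int(L[i], U[i]), pop_size, replace = TRUE)
    pop <- ga_repair(pop, tbl, L, U, Ct)
    z <- ga_z(ga_bors(pop, tbl, L))
    best_i <- which.min(z)
    best <- pop[, best_i]; best_z <- z[best_i]
    n_off <- pop_size - elitism
    for (gen in seq_len(generations)) {
      # tournament selection of two parent sets
      pick <- function() {
        cand <- matrix(sample.int(pop_size, n_off * tournament,
                                  replace = TRUE), nrow = tournament)
        zmat <- matrix(z[cand], nrow = tournament)
        win <- max.col(-t(zmat), ties.method = "first")
        cand[cbind(win, seq_len(n_off))]
      }
      p1 <- pop[, pick(), drop = FALSE]
      p2 <- pop[, pick(), drop = FALSE]
      # uniform crossover
      cross <- stats::runif(n_off) < p_crossover
      mask <- matrix(stats::runif(n * n_off) < 0.5, n)
      mask[, !cross] <- FALSE
      off <- p1
      off[mask] <- p2[mask]
      # random-reset mutation
      mut <- matrix(stats::runif(n * n_off) < p_mutation, n)
      if (any(mut)) {
        wi <- which(mut, arr.ind = TRUE)
        off[mut] <- L[wi[, 1]] +
          as.integer(floor(stats::runif(nrow(wi)) * (U[wi[, 1]] - L[wi[, 1]] + 1L)))
      }
      off <- ga_repair(off, tbl, L, U, Ct)
      # elitism: carry the current best individuals unchanged
      elite <- pop[, order(z)[seq_len(elitism)], drop = FALSE]
      pop <- cbind(elite, off)
      z <- ga_z(ga_bors(pop, tbl, L))
      gi <- which.min(z)
      if (z[gi] < best_z) { best_z <- z[gi]; best <- pop[, gi] }
    }
  })
  make_solution(problem, best, "ga", seed = as.integer(seed),
                extra = list(generations = as.integer(generations),
                             pop_size = as.integer(pop_size)))
}
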