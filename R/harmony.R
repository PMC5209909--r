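# Harmony search: a population metaheuristic for bounded continuous
# maximization. Each new candidate ("harmony") is composed per variable by
# one of three improvisation rules: recall a value from the harmony memory
# (probability HMCR), optionally pitch-adjust it by a bounded uniform
# perturbation (probability PAR, half-width = bandwidth), or draw a fresh
# uniform value from the variable's bounds.

#' Harmony search control parameters
#'
#' Defaults are the canonical settings for this pipeline: memory size 100,
#' memory considering rate 0.8, pitch adjusting rate 0.3, bandwidth 0.5,
#' and 10000 iterations.
#'
#' @param memory_size Number of harmonies kept in memory (HMS).
#' @param memory_considering_rate Probability of recalling a variable's
#'   value from memory (HMCR), in `[0, 1]`.
#' @param pitch_adjusting_rate Probability of perturbing a recalled value
#'   (PAR), in `[0, 1]`.
#' @param bandwidth Half-width of the uniform pitch perturbation.
#' @param iterations Number of improvisations.
#' @param seed Optional integer seed; fixing it makes the run bit-identical.
#' @return List of validated parameters.
#' @export
harmony_control <- function(memory_size = 100L,
                            memory_considering_rate = 0.8,
                            pitch_adjusting_rate = 0.3,
                            bandwidth = 0.5,
                            iterations = 10000L,
                            seed = NULL) {
  stopifnot(memory_size >= 1,
            memory_considering_rate >= 0, memory_considering_rate <= 1,
            pitch_adjusting_rate >= 0, pitch_adjusting_rate <= 1,
            bandwidth > 0, iterations >= 1)
  list(memory_size = as.integer(memory_size),
       memory_considering_rate = memory_considering_rate,
       pitch_adjusting_rate = pitch_adjusting_rate,
       bandwidth = bandwidth,
       iterations = as.integer(iterations),
       seed = seed)
}

#' Maximize an objective with Harmony search
#'
#' The memory is initialized with `memory_size` uniform samples over the
#' bounds, all evaluated. Each iteration improvises one candidate (see
#' [harmony_control()]), evaluates it, and replaces the worst memory row iff
#' the candidate scores strictly better (ties keep the incumbent). All
#' candidates are clipped to the bounds; a non-finite objective value is an
#' error.
#'
#' @param objective Function mapping a numeric vector to a finite scalar;
#'   maximized.
#' @param lower,upper Numeric vectors of finite per-variable bounds.
#' @param control Parameters from [harmony_control()].
#' @return Object of class `harmony_fit`: `best_par`, `best_value`, `trace`
#'   (data frame: `iteration`, candidate `w_*`, `candidate_value`,
#'   `best_value`, best-so-far `best_w_*`), `memory` / `memory_values`
#'   (final state) and `init` (the evaluated initial memory).
#' @export
harmony_search <- function(objective, lower, upper,
                           control = harmony_control()) {
  n <- length(lower)
  stopifnot(n >= 1, length(upper) == n,
            all(is.finite(lower)), all(is.finite(upper)), all(upper >= lower))
  if (!is.null(control$seed)) {
    old_seed <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    }
    on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()),
            add = TRUE)
    set.seed(control$seed)
  }
  hms <- control$memory_size
  hmcr <- control$memory_considering_rate
  par_rate <- control$pitch_adjusting_rate
  bw <- control$bandwidth
  iters <- control$iterations

  eval_obj <- function(x) {
    v <- objective(x)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      stop("objective returned a non-finite value at candidate (",
           paste(fmt_double(x), collapse = ", "), ")")
    }
    v
  }

  memory <- matrix(stats::runif(hms * n, rep(lower, each = hms),
                                rep(upper, each = hms)),
                   nrow = hms, ncol = n)
  mem_values <- apply(memory, 1L, eval_obj)
  init <- list(memory = memory, values = mem_values)

  best_i <- which.max(mem_values)
  best_par <- memory[best_i, ]
  best_value <- mem_values[best_i]

  cand_mat <- matrix(NA_real_, nrow = iters, ncol = n)
  best_mat <- matrix(NA_real_, nrow = iters, ncol = n)
  cand_val <- numeric(iters)
  best_val <- numeric(iters)

  for (it in seq_len(iters)) {
    use_mem <- stats::runif(n) < hmcr
    rows <- sample.int(hms, n, replace = TRUE)
    adjust <- stats::runif(n) < par_rate
    x <- numeric(n)
    if (any(use_mem)) {
      idx <- which(use_mem)
      x[idx] <- memory[cbind(rows[idx], idx)]
      pj <- idx[adjust[idx]]
      if (length(pj)) {
        x[pj] <- x[pj] + stats::runif(length(pj), -bw, bw)
      }
    }
    if (any(!use_mem)) {
      idx <- which(!use_mem)
      x[idx] <- stats::runif(length(idx), lower[idx], upper[idx])
    }
    x <- pmin(pmax(x, lower), upper)
    fx <- eval_obj(x)
    worst <- which.min(mem_values)
    if (fx > mem_values[worst]) {
      memory[worst, ] <- x
      mem_values[worst] <- fx
    }
    if (fx > best_value) {
      best_value <- fx
      best_par <- x
    }
    cand_mat[it, ] <- x
    best_mat[it, ] <- best_par
    cand_val[it] <- fx
    best_val[it] <- best_value
  }

  trace <- data.frame(iteration = seq_len(iters))
  for (j in seq_len(n)) trace[[paste0("w_", j)]] <- cand_mat[, j]
  trace$candidate_value <- cand_val
  trace$best_value <- best_val
  for (j in seq_len(n)) trace[[paste0("best_w_", j)]] <- best_mat[, j]

  structure(
    list(best_par = best_par, best_value = best_value, trace = trace,
         memory = memory, memory_values = mem_values, init = init,
         control = control),
    class = "harmony_fit"
  )
}

#' @export
print.harmony_fit <- function(x, ...) {
  cat(sprintf("<harmony_fit> %d iterations, best value %s at (%s)\n",
              nrow(x$trace), fmt_double(x$best_value),
              paste(sprintf("%.4f", x$best_par), collapse = ", ")))
  invisible(x)
}
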