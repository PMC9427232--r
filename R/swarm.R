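#' Salp leader weight schedule
#'
#' The exploration weight `c1 = 2 exp(-(4 l / L)^2)` decays from 2 at the
#' first iteration towards ~2.25e-7 at the last, shifting the chain from
#' exploration to exploitation.
#'
#' @param l Current iteration (0-based, `0 <= l <= L`).
#' @param L Total number of iterations (`>= 1`).
#' @export
c1_schedule <- function(l, L) {
  if (L < 1) stop("L must be >= 1")
  if (any(l < 0) || any(l > L)) stop("l must satisfy 0 <= l <= L")
  2 * exp(-(4 * l / L)^2)
}

#' Repair a continuous swarm position into a valid threshold vector
#'
#' Clamps to `[0, 254]`, rounds half-up, sorts ascending and resolves
#' duplicates by incrementing later duplicates upward (cascading); overflow
#' past 254 pushes earlier entries downward.
#'
#' @param position Numeric vector of finite reals (length `<= 255`).
#' @return Strictly increasing integer vector in `[0, 254]`.
#' @export
repair_thresholds <- function(position) {
  if (length(position) > 255L) stop("at most 255 thresholds supported")
  if (any(!is.finite(position))) stop("position must be finite")
  t <- sort(round_half_up(pmin(pmax(position, 0), 254)))
  n <- length(t)
  if (n > 1) {
    for (i in 2:n) if (t[i] <= t[i - 1]) t[i] <- t[i - 1] + 1
    if (t[n] > 254) {
      t[n] <- 254
      for (i in (n - 1):1) if (t[i] >= t[i + 1]) t[i] <- t[i + 1] - 1
    }
  }
  as.integer(t)
}

#' Threshold-search objective: negated between-class variance
#'
#' Returns a closure mapping an integer threshold vector to
#' `-sigma_B^2(h, tv)`; all optimizers minimize it, so reported fitness
#' values are negative (a lower fitness is a better segmentation).
#'
#' @param h A `gray_histogram`.
#' @export
make_bcv_objective <- function(h) {
  stopifnot(inherits(h, "gray_histogram"))
  g <- h$g
  s0 <- c(0, cumsum(g))
  s1 <- c(0, cumsum((0:255) * g))
  mu_T <- s1[257]
  function(tv) {
    hi <- c(as.integer(tv), 255L) + 2L   # 1-based prefix index of class end
    w  <- diff(c(0, s0[hi]))
    m1 <- diff(c(0, s1[hi]))
    nz <- w > 0
    -sum(w[nz] * (m1[nz] / w[nz] - mu_T)^2)
  }
}

new_search_result <- function(best_position, best_fitness, history, seed,
                              n_evals, config) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 history = history, seed = seed, n_evals = n_evals,
                 config = config),
            class = "search_result")
}

#' @export
print.search_result <- function(x, ...) {
  cat("<search_result>", x$config$optimizer, "\n")
  cat("  best position:", paste(signif(x$best_position, 6), collapse = ", "), "\n")
  cat("  best fitness :", format(x$best_fitness, digits = 10), "\n")
  cat("  iterations   :", length(x$history), " evals:", x$n_evals, "\n")
  invisible(x)
}

# evaluate a position matrix (n x d) through optional repair; returns
# list(fitness vector, repaired list)
eval_positions <- function(pos, objective, repair) {
  n <- nrow(pos)
  fit <- numeric(n)
  rep_list <- vector("list", n)
  for (i in seq_len(n)) {
    p <- if (is.null(repair)) pos[i, ] else repair(pos[i, ])
    rep_list[[i]] <- p
    fit[i] <- objective(p)
    if (!is.finite(fit[i])) stop("objective returned a non-finite value")
  }
  list(fitness = fit, repaired = rep_list)
}

#' Particle swarm minimization over a box
#'
#' Standard inertia-weight PSO. Velocities follow
#' `V <- w V + c1p r1 (Pp - Z) + c2p r2 (Pg - Z)` with per-particle,
#' per-coordinate uniform `r1, r2`; positions update additively and are
#' clamped to the box, velocities to half the box width. When `repair` is
#' supplied (e.g. [repair_thresholds()]) fitness is evaluated on the
#' repaired position while the continuous position drives the dynamics.
#'
#' @param objective Function of a position vector returning a finite scalar
#'   to minimize.
#' @param lower,upper Box bounds (scalars or length-`dim` vectors).
#' @param dim Search-space dimension.
#' @param n_particles,iters Swarm size and iteration count.
#' @param w,c1p,c2p Inertia and acceleration constants.
#' @param repair Optional position-repair function applied before evaluation.
#' @param seed Optional integer seed (`NULL` uses the current RNG stream).
#' @return A `search_result` (best position is repaired when `repair` given).
#' @export
pso_minimize <- function(objective, lower, upper, dim,
                         n_particles = 30L, iters = 100L,
                         w = 0.729, c1p = 1.49445, c2p = 1.49445,
                         repair = NULL, seed = NULL) {
  if (n_particles < 1 || iters < 1) stop("config must be positive")
  if (!is.null(seed)) set.seed(seed)
  lb <- rep_len(lower, dim); ub <- rep_len(upper, dim)
  if (any(lb >= ub)) stop("lower must be < upper")
  vmax <- (ub - lb) / 2
  Z <- matrix(runif(n_particles * dim, rep(lb, each = n_particles),
                    rep(ub, each = n_particles)), n_particles, dim)
  V <- matrix(0, n_particles, dim)
  ev <- eval_positions(Z, objective, repair)
  P <- Z; pfit <- ev$fitness
  gi <- which.min(pfit)
  gbest <- P[gi, ]; gfit <- pfit[gi]; gbest_rep <- ev$repaired[[gi]]
  n_evals <- n_particles
  history <- numeric(iters)
  for (k in seq_len(iters)) {
    r1 <- matrix(runif(n_particles * dim), n_particles, dim)
    r2 <- matrix(runif(n_particles * dim), n_particles, dim)
    V <- w * V + c1p * r1 * (P - Z) +
      c2p * r2 * (matrix(gbest, n_particles, dim, byrow = TRUE) - Z)
    V <- pmin(pmax(V, matrix(-vmax, n_particles, dim, byrow = TRUE)),
              matrix(vmax, n_particles, dim, byrow = TRUE))
    Z <- Z + V
    Z <- pmin(pmax(Z, matrix(lb, n_particles, dim, byrow = TRUE)),
              matrix(ub, n_particles, dim, byrow = TRUE))
    ev <- eval_positions(Z, objective, repair)
    n_evals <- n_evals + n_particles
    imp <- ev$fitness < pfit
    P[imp, ] <- Z[imp, ]; pfit[imp] <- ev$fitness[imp]
    gi <- which.min(pfit)
    if (pfit[gi] < gfit) {
      # a new global best always comes from this iteration's evaluation
      gfit <- pfit[gi]; gbest <- P[gi, ]
      gbest_rep <- ev$repaired[[gi]]
    }
    history[k] <- gfit
  }
  best_pos <- if (is.null(repair)) gbest else gbest_rep
  new_search_result(best_pos, gfit, history, seed, n_evals,
                    list(optimizer = "pso", n_particles = n_particles,
                         iters = iters, w = w, c1p = c1p, c2p = c2p,
                         lower = lb, upper = ub))
}

#' One salp-chain update step
#'
#' Leaders move around the food position `F`:
#' `x = F +/- c1 ((ub - lb) c2 + lb)` with the sign taken positive when the
#' per-draw uniform `c3 >= 0.5`; followers move to the midpoint of
#' themselves and their predecessor. Positions are clamped to the box, all
#' salps are (re-)evaluated through `repair`, and the food is updated if any
#' candidate improves on it.
#'
#' @param chain List with `positions` (`n_salps x dim`), `food`,
#'   `food_fitness`, `food_position` (repaired), `n_leader`.
#' @param c1 Leader weight for this iteration ([c1_schedule()]).
#' @param lower,upper Box bounds (length-`dim`).
#' @param objective,repair As in [pso_minimize()].
#' @param c2_values Optional per-leader step-length coefficients in `[0,1]`
#'   (the PMSSA `Pc2`); default draws `c2 ~ U(0,1)` per leader per
#'   coordinate (plain MSSA).
#' @return The updated chain (with `$fitness` of the current population).
#' @export
mssa_step <- function(chain, c1, lower, upper, objective, repair = NULL,
                      c2_values = NULL) {
  X <- chain$positions
  n <- nrow(X); d <- ncol(X)
  nl <- chain$n_leader
  lb <- rep_len(lower, d); ub <- rep_len(upper, d)
  for (i in seq_len(nl)) {
    c2 <- if (is.null(c2_values)) runif(d) else rep_len(c2_values[i], d)
    c3 <- runif(d)
    step <- c1 * ((ub - lb) * c2 + lb)
    X[i, ] <- ifelse(c3 >= 0.5, chain$food + step, chain$food - step)
  }
  if (n > nl) for (i in (nl + 1):n) X[i, ] <- (X[i, ] + X[i - 1, ]) / 2
  X <- pmin(pmax(X, matrix(lb, n, d, byrow = TRUE)),
            matrix(ub, n, d, byrow = TRUE))
  ev <- eval_positions(X, objective, repair)
  bi <- which.min(ev$fitness)
  if (ev$fitness[bi] < chain$food_fitness) {
    chain$food <- X[bi, ]
    chain$food_fitness <- ev$fitness[bi]
    chain$food_position <- ev$repaired[[bi]]
  }
  chain$positions <- X
  chain$fitness <- ev$fitness
  chain
}

init_chain <- function(objective, lb, ub, dim, n_salps, n_leader, repair) {
  X <- matrix(runif(n_salps * dim, rep(lb, each = n_salps),
                    rep(ub, each = n_salps)), n_salps, dim)
  ev <- eval_positions(X, objective, repair)
  bi <- which.min(ev$fitness)
  list(positions = X, food = X[bi, ], food_fitness = ev$fitness[bi],
       food_position = ev$repaired[[bi]], n_leader = n_leader,
       fitness = ev$fitness)
}

#' Multi-salp-swarm minimization
#'
#' The salp chain follows the best-ever ("food") position; leader weight
#' `c1` decays via [c1_schedule()] and leader step lengths are fresh
#' uniforms each draw.
#'
#' @inheritParams pso_minimize
#' @param n_salps Chain length.
#' @param n_leader Number of leaders (default half the chain, rounded up).
#' @export
mssa_minimize <- function(objective, lower, upper, dim,
                          n_salps = 30L, n_leader = ceiling(n_salps / 2),
                          iters = 100L, repair = NULL, seed = NULL) {
  if (n_salps < 1 || iters < 1) stop("config must be positive")
  if (n_leader < 1 || n_leader > n_salps) stop("need 1 <= n_leader <= n_salps")
  if (!is.null(seed)) set.seed(seed)
  lb <- rep_len(lower, dim); ub <- rep_len(upper, dim)
  chain <- init_chain(objective, lb, ub, dim, n_salps, n_leader, repair)
  history <- numeric(iters)
  for (l in seq_len(iters)) {
    c1 <- c1_schedule(l, iters)
    chain <- mssa_step(chain, c1, lb, ub, objective, repair)
    history[l] <- chain$food_fitness
  }
  new_search_result(chain$food_position %||% chain$food, chain$food_fitness,
                    history, seed, n_salps * (iters + 1L),
                    list(optimizer = "mssa", n_salps = n_salps,
                         n_leader = n_leader, iters = iters,
                         lower = lb, upper = ub))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Generate the PMSSA leader step-length coefficients Pc2
#'
#' An inner particle swarm searches `[0,1]^n_leader` for the vector
#' maximizing the mean absolute deviation
#' `f_pso = sum_i |Pc2_i - mean(Pc2)| / n_leader`, i.e. the most dispersed
#' set of step lengths; the analytic optimum is 0.5 (half the entries at 0,
#' half at 1, for even `n_leader`). The result is clamped to `[0,1]` and
#' sorted ascending so successive leaders sweep step lengths uniformly.
#'
#' @param n_leader Number of leaders (`>= 1`).
#' @param n_particles,iters Inner-PSO budget.
#' @param seed Optional seed; `NULL` draws from the current RNG stream.
#' @return List with `pc2` (sorted vector in `[0,1]`) and `f_pso` (attained
#'   dispersion).
#' @export
generate_pc2 <- function(n_leader, n_particles = 20L, iters = 30L,
                         seed = NULL) {
  if (n_leader < 1) stop("n_leader must be >= 1")
  obj <- function(x) -mean(abs(x - mean(x)))
  res <- pso_minimize(obj, 0, 1, dim = n_leader, n_particles = n_particles,
                      iters = iters, seed = seed)
  pc2 <- sort(pmin(pmax(res$best_position, 0), 1))
  list(pc2 = pc2, f_pso = -res$best_fitness)
}

#' PSO-improved multi-salp-swarm minimization (PMSSA)
#'
#' Salp-chain search in which the leader step-length coefficients are not
#' fresh uniforms but the maximally dispersed `Pc2` vector synthesized by an
#' inner particle swarm ([generate_pc2()]), so the leaders probe step
#' lengths spread uniformly over `[0,1]` around the food position at every
#' iteration.
#'
#' @inheritParams mssa_minimize
#' @param inner_particles,inner_iters Budget of the inner PSO that
#'   synthesizes `Pc2`.
#' @param pc2_refresh `"each"` regenerates `Pc2` every outer iteration
#'   (default), `"once"` generates it a single time at the start.
#' @export
pmssa_minimize <- function(objective, lower, upper, dim,
                           n_salps = 30L, n_leader = ceiling(n_salps / 2),
                           iters = 100L, inner_particles = 20L,
                           inner_iters = 30L,
                           pc2_refresh = c("each", "once"),
                           repair = NULL, seed = NULL) {
  if (n_salps < 1 || iters < 1) stop("config must be positive")
  if (n_leader < 1 || n_leader > n_salps) stop("need 1 <= n_leader <= n_salps")
  pc2_refresh <- match.arg(pc2_refresh)
  if (!is.null(seed)) set.seed(seed)
  lb <- rep_len(lower, dim); ub <- rep_len(upper, dim)
  chain <- init_chain(objective, lb, ub, dim, n_salps, n_leader, repair)
  pc2 <- generate_pc2(n_leader, inner_particles, inner_iters)$pc2
  history <- numeric(iters)
  for (l in seq_len(iters)) {
    c1 <- c1_schedule(l, iters)
    if (pc2_refresh == "each" && l > 1)
      pc2 <- generate_pc2(n_leader, inner_particles, inner_iters)$pc2
    chain <- mssa_step(chain, c1, lb, ub, objective, repair, c2_values = pc2)
    history[l] <- chain$food_fitness
  }
  new_search_result(chain$food_position %||% chain$food, chain$food_fitness,
                    history, seed, n_salps * (iters + 1L),
                    list(optimizer = "pmssa", n_salps = n_salps,
                         n_leader = n_leader, iters = iters,
                         inner_particles = inner_particles,
                         inner_iters = inner_iters,
                         pc2_refresh = pc2_refresh, lower = lb, upper = ub))
}

#' Optimize multilevel Otsu thresholds on a histogram
#'
#' Convenience front-end running one of the swarm optimizers on the
#' negated between-class variance with threshold repair. By default the
#' search box is restricted to the occupied gray-level range of the
#' histogram: the objective is constant with respect to threshold
#' positions outside it (they only create empty classes), so excluding
#' that dead space concentrates the budget where the partition can change.
#'
#' @param h A `gray_histogram`.
#' @param dim Number of thresholds (1--7).
#' @param optimizer `"pmssa"`, `"mssa"` or `"pso"`.
#' @param seed Optional integer seed.
#' @param bounds `"occupied"` (default) restricts the box to
#'   `[min gray, max gray - 1]` of the occupied bins; `"full"` uses
#'   `[0, 254]`.
#' @param ... Further arguments to the selected optimizer.
#' @return A `search_result`; `best_position` is a valid integer threshold
#'   vector and `best_fitness` equals `-between_class_variance()` at it.
#' @export
optimize_thresholds <- function(h, dim, optimizer = c("pmssa", "mssa", "pso"),
                                seed = NULL, bounds = c("occupied", "full"),
                                ...) {
  optimizer <- match.arg(optimizer)
  bounds <- match.arg(bounds)
  if (bounds == "occupied") {
    occ <- which(h$g > 0) - 1L
    lb <- min(occ)
    ub <- max(max(occ) - 1L, lb + 1L)
  } else {
    lb <- 0; ub <- 254
  }
  obj <- make_bcv_objective(h)
  fn <- switch(optimizer, pmssa = pmssa_minimize, mssa = mssa_minimize,
               pso = pso_minimize)
  fn(obj, lower = lb, upper = ub, dim = dim, repair = repair_thresholds,
     seed = seed, ...)
}
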