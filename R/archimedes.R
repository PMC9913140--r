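#' Configuration of the Archimedes-style population optimizer
#'
#' A bounded black-box minimizer in which each candidate ("object immersed in
#' fluid") carries a position, a density, a volume and an acceleration.  A
#' transfer operator moves the population from a collision-driven exploration
#' phase to a best-object exploitation phase as iterations advance.
#'
#' @param n_pop Population size N (>= 2).
#' @param max_iter Iteration budget tmax (>= 1).
#' @param lower,upper Bound vectors (recycled to a common length);
#'   `lower < upper` elementwise (equal bounds give a degenerate fixed
#'   dimension).
#' @param c1,c2 Step constants of the exploration (2) and exploitation (6)
#'   position updates.
#' @param c3,c4 Exploitation schedule constant and direction-flag offset;
#'   defaults 2 and 0.5 (the source algorithm's values; never pinned down in
#'   the method description, so both are exposed).
#' @param norm_l,norm_u Lower/upper normalization limits for the acceleration
#'   (defaults 0.1 and 0.9).
#' @param seed Integer seed; the full run is reproducible given it.
#' @return An `aoa_config` list with `dim` set to the bound length.
#' @export
aoa_config <- function(n_pop = 20, max_iter = 100, lower = -1, upper = 1,
                       c1 = 2, c2 = 6, c3 = 2, c4 = 0.5,
                       norm_l = 0.1, norm_u = 0.9, seed = 1) {
  if (n_pop < 2) abort("Population size must be >= 2.", class = "histodbn_parameter_error")
  if (max_iter < 1) abort("max_iter must be >= 1.", class = "histodbn_parameter_error")
  d <- max(length(lower), length(upper))
  lower <- rep_len(as.numeric(lower), d)
  upper <- rep_len(as.numeric(upper), d)
  if (any(lower > upper)) {
    abort("Require lower <= upper elementwise.", class = "histodbn_parameter_error")
  }
  if (!(0 < norm_l && norm_l < norm_u)) {
    abort("Require 0 < norm_l < norm_u.", class = "histodbn_parameter_error")
  }
  structure(list(n_pop = as.integer(n_pop), max_iter = as.integer(max_iter),
                 lower = lower, upper = upper, dim = d,
                 c1 = c1, c2 = c2, c3 = c3, c4 = c4,
                 norm_l = norm_l, norm_u = norm_u, seed = as.integer(seed)),
            class = "aoa_config")
}

#' Initialize the object population
#'
#' Positions and accelerations are uniform within the bounds; densities and
#' volumes are uniform in (0, 1).  Uses the current RNG state; seed it (e.g.
#' via [withr::with_seed()]) for reproducibility — [aoa_optimize()] does this
#' from `config$seed`.
#'
#' @param config An [aoa_config()].
#' @return List of matrices `X`, `Dn`, `V`, `A` (each `n_pop x dim`) and
#'   fitness vector `fit` (NA until evaluated).
#' @export
initialize_population <- function(config) {
  N <- config$n_pop; d <- config$dim
  ru <- function() matrix(runif(N * d), N, d)
  span <- function(m) sweep(sweep(m, 2, config$upper - config$lower, "*"),
                            2, config$lower, "+")
  list(X = span(ru()), V = ru(), Dn = ru(), A = span(ru()),
       fit = rep(NA_real_, N))
}

#' Transfer operator
#'
#' `TF(t) = exp((t - tmax) / tmax)`: strictly increasing in `t`, reaching
#' exactly 1 at the final iteration.  `TF <= 0.5` selects the exploration
#' branch of the updates, `TF > 0.5` the exploitation branch.
#'
#' @param t Iteration, `0 <= t <= tmax`.
#' @param tmax Iteration budget (>= 1).
#' @return Value in `(0, 1]`.
#' @examples
#' transfer_operator(100, 100)  # 1
#' @export
transfer_operator <- function(t, tmax) {
  if (tmax < 1) abort("tmax must be >= 1.", class = "histodbn_parameter_error")
  if (any(t < 0) || any(t > tmax)) {
    abort("Require 0 <= t <= tmax.", class = "histodbn_parameter_error")
  }
  exp((t - tmax) / tmax)
}

#' Density-decrease factor
#'
#' `d(t) = exp((tmax - t) / tmax) - t / tmax`: strictly decreasing, handing
#' the search from global to local moves, and equal to 0 at `t = tmax`.
#'
#' @inheritParams transfer_operator
#' @return Non-negative real.
#' @export
density_decrease <- function(t, tmax) {
  if (tmax < 1) abort("tmax must be >= 1.", class = "histodbn_parameter_error")
  if (any(t < 0) || any(t > tmax)) {
    abort("Require 0 <= t <= tmax.", class = "histodbn_parameter_error")
  }
  exp((tmax - t) / tmax) - t / tmax
}

#' Move density and volume toward the best object
#'
#' Each component moves toward the best object's value by an independent
#' uniform(0,1) fraction, so outputs lie between the old value and the best
#' value componentwise (and, with (0,1) initialization, stay in (0,1)).
#'
#' @param object List with vectors `V` and `Dn` (volume, density).
#' @param best List with vectors `V` and `Dn` of the best object.
#' @param rand Optional fixed fraction(s) in `[0, 1]` replacing the random
#'   draw (used in tests); `NULL` draws per component.
#' @return Updated `object` list.
#' @export
update_density_volume <- function(object, best, rand = NULL) {
  r_v <- rand %||% runif(length(object$V))
  r_d <- rand %||% runif(length(object$Dn))
  object$V <- object$V + r_v * (best$V - object$V)
  object$Dn <- object$Dn + r_d * (best$Dn - object$Dn)
  object
}

#' Acceleration update
#'
#' `A_i <- (D_s + V_s * A_s) / (D_i * V_i)` where the source `s` is a random
#' population member during exploration (`TF <= 0.5`, collisions) or the best
#' object during exploitation.  `D_i`, `V_i` are the object's already-advanced
#' density and volume; the denominator is guarded below by `eps`.
#'
#' @param object List with vectors `Dn`, `V` (values at t+1).
#' @param source List with vectors `Dn`, `V`, `A` of the random material or
#'   the best object.
#' @param eps Denominator guard (default 1e-12).
#' @return Acceleration vector.
#' @export
update_acceleration <- function(object, source, eps = 1e-12) {
  denom <- pmax(object$Dn * object$V, eps)
  out <- (source$Dn + source$V * source$A) / denom
  if (any(!is.finite(out))) {
    abort("Non-finite acceleration after guard.", class = "histodbn_numerical_error")
  }
  out
}

#' Normalize accelerations over the population
#'
#' Affine map `u * (A - min A) / (max A - min A) + l` with the min/max taken
#' over all components of the population: the minimum maps to `l`, the maximum
#' to `u + l`.  An all-equal population (degenerate range) maps to the
#' midpoint `(l + (u + l)) / 2` of the attainable range.
#'
#' @param accelerations Numeric vector or `n_pop x dim` matrix of
#'   accelerations.
#' @param l,u Normalization limits (defaults 0.1, 0.9).
#' @return Object of the same shape with normalized values.
#' @examples
#' normalize_acceleration(c(2, 4, 6))  # 0.10 0.55 1.00
#' @export
normalize_acceleration <- function(accelerations, l = 0.1, u = 0.9) {
  lo <- min(accelerations); hi <- max(accelerations)
  if (hi - lo < .Machine$double.eps * max(1, abs(hi))) {
    out <- accelerations
    out[] <- (l + (u + l)) / 2
    return(out)
  }
  u * (accelerations - lo) / (hi - lo) + l
}

#' Position update
#'
#' Exploration (`TF <= 0.5`):
#' `x <- x + c1 * rand * A_norm * d * (x_rand - x)`;
#' exploitation (`TF > 0.5`):
#' `x <- x_best + F * c2 * rand * A_norm * d * T * (x_best - x)` with
#' `T = clip(c3 * TF, c3 * 0.3, 1)` and direction flag `F = +1` if
#' `P = 2 * rand - c4 <= 0.5`, else `-1` (`P` is a scalar draw per object;
#' the step fraction `rand` is drawn per component).  During exploration
#' `x_ref` is a random location of the search box — the object drifts toward
#' unexplored fluid; during exploitation it is the best position.  The result
#' is clamped to the bounds.
#'
#' @param x Current position vector.
#' @param x_ref Reference position: a random member's position (exploration)
#'   or the best position (exploitation).
#' @param a_norm Normalized acceleration vector for this object.
#' @param tf Transfer-operator value at this iteration.
#' @param d Density-decrease factor at this iteration.
#' @param config An [aoa_config()].
#' @param rand,rand_p Optional fixed draws for the step fraction and the flag
#'   variable (tests); `NULL` draws them per component.
#' @return Updated, clamped position vector.
#' @export
update_position <- function(x, x_ref, a_norm, tf, d, config,
                            rand = NULL, rand_p = NULL) {
  r <- rand %||% runif(length(x))
  if (tf <= 0.5) {
    x_new <- x + config$c1 * r * a_norm * d * (x_ref - x)
  } else {
    Tt <- clamp(config$c3 * tf, config$c3 * 0.3, 1)
    p <- 2 * (rand_p %||% runif(1)) - config$c4
    Fd <- if (p[1] <= 0.5) 1 else -1
    x_new <- x_ref + Fd * config$c2 * r * a_norm * d * Tt * (x_ref - x)
  }
  clamp(x_new, config$lower, config$upper)
}

#' Classifier error-rate fitness
#'
#' `100 * (# misclassified) / (total)` — the percentage objective minimized by
#' the hyperparameter search.
#'
#' @param predictions,truth Equal-length non-empty label vectors.
#' @return Percentage in `[0, 100]`.
#' @export
fitness_error_rate <- function(predictions, truth) {
  if (length(predictions) == 0 || length(truth) == 0) {
    abort("Labels must be non-empty.", class = "histodbn_parameter_error")
  }
  if (length(predictions) != length(truth)) {
    abort("Prediction/truth lengths differ.", class = "histodbn_parameter_error")
  }
  100 * sum(as.character(predictions) != as.character(truth)) / length(truth)
}

#' Run the optimizer
#'
#' Each iteration evaluates the population, updates the best record, advances
#' densities and volumes toward the best object, computes the transfer
#' operator and density-decrease factor, updates and normalizes accelerations,
#' and moves positions on the branch selected by the transfer operator.  Fully
#' reproducible from `config$seed`.
#'
#' @param objective Function mapping a position vector to a finite scalar to
#'   be minimized.
#' @param config An [aoa_config()].
#' @return An `aoa_result` with `best` (position, fitness, iteration found,
#'   density/volume/acceleration snapshot) and `trace` (tibble: iteration,
#'   best_fitness, mean_fitness).  `best_fitness` is non-increasing.
#' @examples
#' res <- aoa_optimize(function(x) sum(x^2),
#'                     aoa_config(n_pop = 10, max_iter = 20,
#'                                lower = c(-5, -5), upper = c(5, 5), seed = 1))
#' glance(res)
#' @export
aoa_optimize <- function(objective, config) {
  withr::with_seed(config$seed, aoa_optimize_impl(objective, config))
}

aoa_optimize_impl <- function(objective, config) {
  N <- config$n_pop
  pop <- initialize_population(config)
  best <- list(x = NULL, Dn = NULL, V = NULL, A = NULL,
               fitness = Inf, iteration = NA_integer_)
  trace <- vector("list", config$max_iter)
  eval_pop <- function(X) {
    vapply(seq_len(N), function(i) {
      f <- objective(X[i, ])
      if (!is.finite(f)) {
        abort(paste0("Objective returned a non-finite value at position [",
                     paste(signif(X[i, ], 6), collapse = ", "), "]."),
              class = "histodbn_objective_error")
      }
      f
    }, numeric(1))
  }
  for (t in seq_len(config$max_iter)) {
    pop$fit <- eval_pop(pop$X)
    i_min <- which.min(pop$fit)
    if (pop$fit[i_min] < best$fitness) {
      best <- list(x = pop$X[i_min, ], Dn = pop$Dn[i_min, ],
                   V = pop$V[i_min, ], A = pop$A[i_min, ],
                   fitness = pop$fit[i_min], iteration = t)
    }
    trace[[t]] <- c(iteration = t, best_fitness = best$fitness,
                    mean_fitness = mean(pop$fit))
    tf <- transfer_operator(t, config$max_iter)
    dfac <- density_decrease(t, config$max_iter)
    # densities/volumes move toward the best (per-component uniform fraction)
    d <- config$dim
    pop$V <- pop$V + matrix(runif(N * d), N, d) *
      (matrix(best$V, N, d, byrow = TRUE) - pop$V)
    pop$Dn <- pop$Dn + matrix(runif(N * d), N, d) *
      (matrix(best$Dn, N, d, byrow = TRUE) - pop$Dn)
    A_new <- matrix(0, N, d)
    for (i in seq_len(N)) {
      src <- if (tf <= 0.5) {
        mr <- sample.int(N, 1)
        list(Dn = pop$Dn[mr, ], V = pop$V[mr, ], A = pop$A[mr, ])
      } else {
        list(Dn = best$Dn, V = best$V, A = best$A)
      }
      A_new[i, ] <- update_acceleration(
        list(Dn = pop$Dn[i, ], V = pop$V[i, ]), src)
    }
    A_norm <- normalize_acceleration(A_new, config$norm_l, config$norm_u)
    for (i in seq_len(N)) {
      x_ref <- if (tf <= 0.5) {
        config$lower + runif(d) * (config$upper - config$lower)
      } else {
        best$x
      }
      pop$X[i, ] <- update_position(pop$X[i, ], x_ref, A_norm[i, ],
                                    tf, dfac, config)
    }
    # the normalized acceleration is the state carried to the next iteration:
    # A_mr and A_best in the acceleration update refer to these values
    pop$A <- A_norm
  }
  trace <- tibble::as_tibble(do.call(rbind, trace))
  structure(list(best = best, trace = trace, population = pop,
                 config = config),
            class = "aoa_result")
}

#' @export
print.aoa_result <- function(x, ...) {
  cat("<aoa_result> best fitness ", signif(x$best$fitness, 6),
      " at iteration ", x$best$iteration, " (",
      x$config$n_pop, " objects x ", x$config$max_iter, " iterations)\n",
      sep = "")
  cat("position: ", paste(signif(x$best$x, 4), collapse = ", "), "\n")
  invisible(x)
}

# ---- hyperparameter search space ----

#' Define a hyperparameter search space
#'
#' A search space is a list of named dimensions, each with real bounds and a
#' decoding rule: `"real"` (identity), `"log"` (bounds given in log10, decoded
#' as `10^x`), `"int"` (rounded half-up to the nearest integer in range), or
#' `"cat"` (binned uniformly over `values`).
#'
#' @param name Dimension name.
#' @param type One of `"real"`, `"log"`, `"int"`, `"cat"`.
#' @param lower,upper Bounds on the internal (position) scale; for `"cat"`
#'   they default to the value-index range.
#' @param values Candidate values for `"cat"` dimensions.
#' @return `space_dim()`: one dimension; `search_space()`: a list of them.
#' @examples
#' sp <- search_space(
#'   space_dim("learning_rate", "log", -3, -1),
#'   space_dim("epochs", "int", 1, 10)
#' )
#' decode_position(c(-2, 4.7), sp)
#' @export
space_dim <- function(name, type = c("real", "log", "int", "cat"),
                      lower = NULL, upper = NULL, values = NULL) {
  type <- match.arg(type)
  if (type == "cat") {
    if (is.null(values) || length(values) < 1) {
      abort("`cat` dimensions need `values`.", class = "histodbn_parameter_error")
    }
    lower <- lower %||% 1
    upper <- upper %||% length(values)
  }
  if (is.null(lower) || is.null(upper) || lower >= upper) {
    abort("Dimension needs lower < upper.", class = "histodbn_parameter_error")
  }
  structure(list(name = name, type = type, lower = lower, upper = upper,
                 values = values), class = "space_dim")
}

#' @rdname space_dim
#' @export
search_space <- function(...) {
  dims <- list(...)
  if (length(dims) == 0) {
    abort("Search space must have at least one dimension.",
          class = "histodbn_parameter_error")
  }
  if (!all(purrr::map_lgl(dims, inherits, "space_dim"))) {
    abort("All arguments must be space_dim objects.",
          class = "histodbn_parameter_error")
  }
  structure(dims, names = purrr::map_chr(dims, "name"), class = "search_space")
}

#' @rdname space_dim
#' @param position Numeric vector, one value per dimension.
#' @param space A `search_space`.
#' @export
decode_position <- function(position, space) {
  stopifnot(length(position) == length(space))
  out <- purrr::map2(space, position, function(dim, x) {
    x <- clamp(x, dim$lower, dim$upper)
    switch(dim$type,
      real = x,
      log = 10^x,
      int = as.integer(clamp(round_half_up(x), ceiling(dim$lower), floor(dim$upper))),
      cat = dim$values[[as.integer(clamp(round_half_up(x), 1, length(dim$values)))]]
    )
  })
  setNames(out, names(space))
}

#' Tune hyperparameters with the population optimizer
#'
#' Wraps [aoa_optimize()] around a decoded objective: each candidate position
#' is decoded through the search space and scored by `objective`, by
#' convention a classifier error-rate percentage on held-out data (see
#' [fitness_error_rate()]; [run_experiment()] supplies an objective that
#' trains the feature extractor's softmax head and scores the validation
#' split).
#'
#' @param space A [search_space()].
#' @param objective Function taking the decoded named list of hyperparameters
#'   and returning a finite scalar to minimize.
#' @param config An [aoa_config()]; its bounds are overwritten by the space's.
#' @return List with `best` (decoded named list), `best_fitness`, `result`
#'   (the `aoa_result`), and `log` — a tibble of every evaluation (iteration
#'   implicit in order, decoded values, fitness).
#' @export
tune_hyperparameters <- function(space, objective, config = aoa_config()) {
  if (!inherits(space, "search_space")) {
    abort("`space` must be a search_space.", class = "histodbn_parameter_error")
  }
  config$lower <- purrr::map_dbl(space, "lower")
  config$upper <- purrr::map_dbl(space, "upper")
  config$dim <- length(space)
  log_env <- new.env()
  log_env$rows <- list()
  wrapped <- function(x) {
    decoded <- decode_position(x, space)
    f <- objective(decoded)
    row <- tibble::as_tibble(purrr::map(decoded, function(v) {
      if (is.numeric(v) || is.character(v) || is.logical(v)) v else list(v)
    }))
    row$fitness <- f
    log_env$rows[[length(log_env$rows) + 1L]] <- row
    f
  }
  res <- aoa_optimize(wrapped, config)
  list(best = decode_position(res$best$x, space),
       best_fitness = res$best$fitness,
       result = res,
       log = dplyr::bind_rows(log_env$rows))
}
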