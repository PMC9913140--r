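#' Adamax optimizer state
#'
#' Adamax is the infinity-norm variant of Adam: the per-parameter scale is an
#' exponentially decayed maximum of past gradient magnitudes rather than a
#' second moment.  The first moment is bias-corrected; the infinity-norm
#' moment is not (its max recursion makes the correction unnecessary).
#'
#' @param learning_rate Step size eta (default 0.01).
#' @param beta1,beta2 Decay rates in `[0, 1)` for the first moment and the
#'   infinity-norm moment (defaults 0.9, 0.999).
#' @param epsilon Denominator guard (default 1e-8).
#' @return An `adamax_state` with `m`, `u` initialized lazily to zero and step
#'   counter `t = 0`.
#' @export
adamax_state <- function(learning_rate = 0.01, beta1 = 0.9, beta2 = 0.999,
                         epsilon = 1e-8) {
  if (beta1 < 0 || beta1 >= 1 || beta2 < 0 || beta2 >= 1) {
    abort("beta1, beta2 must lie in [0, 1).", class = "histodbn_parameter_error")
  }
  if (learning_rate <= 0 || epsilon <= 0) {
    abort("learning_rate and epsilon must be positive.",
          class = "histodbn_parameter_error")
  }
  structure(list(m = NULL, u = NULL, t = 0L,
                 learning_rate = learning_rate, beta1 = beta1, beta2 = beta2,
                 epsilon = epsilon),
            class = "adamax_state")
}

#' One Adamax update
#'
#' With step `t' = t + 1`:
#' `m' = beta1 * m + (1 - beta1) * g`;
#' `u' = max(beta2 * u, |g|)` componentwise;
#' `w' = w - eta * (m' / (1 - beta1^t')) / (u' + epsilon)`.
#'
#' @param state An [adamax_state()].
#' @param w Numeric vector/matrix/array of parameters.
#' @param g Gradient of the cost with respect to `w`, same shape.
#' @return List with `state` (advanced) and `w` (updated parameters).
#' @examples
#' st <- adamax_state()
#' adamax_step(st, 0, 2)$w  # first step: about -0.01
#' @export
adamax_step <- function(state, w, g) {
  if (!identical(dim(w), dim(g)) || length(w) != length(g)) {
    abort("`w` and `g` must have identical shapes.",
          class = "histodbn_structural_error")
  }
  if (any(!is.finite(g))) {
    abort("Non-finite gradient passed to adamax_step.",
          class = "histodbn_numerical_error")
  }
  if (is.null(state$m)) { state$m <- w * 0; state$u <- w * 0 }
  state$t <- state$t + 1L
  state$m <- state$beta1 * state$m + (1 - state$beta1) * g
  state$u <- pmax(state$beta2 * state$u, abs(g))
  m_hat <- state$m / (1 - state$beta1^state$t)
  w <- w - state$learning_rate * m_hat / (state$u + state$epsilon)
  list(state = state, w = w)
}

# Adamax over a named list of parameter blocks (weights/biases); gradients is
# a parallel list.  Used by the DBN head and the tuning objective.
adamax_step_list <- function(state, params, grads) {
  if (is.null(state$m)) {
    state$m <- purrr::map(params, function(p) p * 0)
    state$u <- purrr::map(params, function(p) p * 0)
  }
  state$t <- state$t + 1L
  for (nm in names(params)) {
    g <- grads[[nm]]
    if (any(!is.finite(g))) {
      abort(paste0("Non-finite gradient in parameter block `", nm, "`."),
            class = "histodbn_numerical_error")
    }
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$u[[nm]] <- pmax(state$beta2 * state$u[[nm]], abs(g))
    m_hat <- state$m[[nm]] / (1 - state$beta1^state$t)
    params[[nm]] <- params[[nm]] -
      state$learning_rate * m_hat / (state$u[[nm]] + state$epsilon)
  }
  list(state = state, params = params)
}
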