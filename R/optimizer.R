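# Gradient-ascent optimizers. Plain ascent (the printed update rule) is
# the default everywhere; Adam is available as a configurable alternative
# for desk-scale budgets where plain REINFORCE anneals too slowly.

#' Create an optimizer for policy training
#'
#' @param kind `"sgd"` (plain ascent, the default printed rule) or
#'   `"adam"` (first/second-moment adaptive ascent, beta1 = 0.9,
#'   beta2 = 0.999, eps = 1e-8).
#' @param lr learning rate.
#' @param max_norm global gradient-norm cap applied before the update
#'   (direction-preserving; `Inf` disables).
#' @return a function `(params, grad, state) -> list(params, state)`;
#'   pass `state = NULL` on the first call.
#' @export
make_optimizer <- function(kind = c("sgd", "adam"), lr = 1e-3,
                           max_norm = 10) {
  kind <- match.arg(kind)
  force(lr); force(max_norm)
  if (kind == "sgd") {
    return(function(params, grad, state = NULL)
      list(params = policy_update(params, grad, lr, max_norm = max_norm),
           state = state))
  }
  b1 <- 0.9; b2 <- 0.999; eps <- 1e-8
  function(params, grad, state = NULL) {
    if (is.finite(max_norm)) {
      gn <- sqrt(sum(vapply(grad, function(m) sum(m^2), numeric(1))))
      if (is.finite(gn) && gn > max_norm)
        grad <- lapply(grad, function(m) m * (max_norm / gn))
    }
    if (is.null(state))
      state <- list(t = 0L, m = lapply(params, function(x) x * 0),
                    v = lapply(params, function(x) x * 0))
    state$t <- state$t + 1L
    for (nm in names(params)) {
      g <- grad[[nm]]
      if (!all(is.finite(g)))
        stop(sprintf("non-finite gradient in '%s'; training diverged", nm),
             call. = FALSE)
      state$m[[nm]] <- b1 * state$m[[nm]] + (1 - b1) * g
      state$v[[nm]] <- b2 * state$v[[nm]] + (1 - b2) * g^2
      mhat <- state$m[[nm]] / (1 - b1^state$t)
      vhat <- state$v[[nm]] / (1 - b2^state$t)
      params[[nm]] <- params[[nm]] + lr * mhat / (sqrt(vhat) + eps)
    }
    list(params = params, state = state)
  }
}

# scale the sigma-head blocks of a gradient (separate effective learning
# rate for the exploration-noise parameters)
scale_sigma_head <- function(grad, scale) {
  if (scale == 1) return(grad)
  grad$W3_sig <- grad$W3_sig * scale
  grad$b3_sig <- grad$b3_sig * scale
  grad
}
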