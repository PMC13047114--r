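# Adam optimizer over flat named lists of numeric matrices.

#' @keywords internal
adam_init <- function(params, lr = 0.001, beta1 = 0.9, beta2 = 0.999,
                      eps = 1e-8) {
  list(
    lr = lr, beta1 = beta1, beta2 = beta2, eps = eps, t = 0L,
    m = lapply(params, function(p) array(0, dim = dim(as_matrix(p)))),
    v = lapply(params, function(p) array(0, dim = dim(as_matrix(p))))
  )
}

#' @keywords internal
adam_step <- function(params, grads, state) {
  state$t <- state$t + 1L
  corr1 <- 1 - state$beta1^state$t
  corr2 <- 1 - state$beta2^state$t
  for (nm in names(params)) {
    g <- grads[[nm]]
    state$m[[nm]] <- state$beta1 * state$m[[nm]] + (1 - state$beta1) * g
    state$v[[nm]] <- state$beta2 * state$v[[nm]] + (1 - state$beta2) * g^2
    mhat <- state$m[[nm]] / corr1
    vhat <- state$v[[nm]] / corr2
    params[[nm]] <- params[[nm]] - state$lr * mhat / (sqrt(vhat) + state$eps)
  }
  list(params = params, state = state)
}

# Plain SGD step used by inner-loop adaptation and by deterministic test modes.
#' @keywords internal
sgd_step <- function(params, grads, lr) {
  for (nm in names(params)) {
    params[[nm]] <- params[[nm]] - lr * grads[[nm]]
  }
  params
}
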