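# Adam optimizer over a named list of numeric arrays, with global-norm
# gradient clipping and an exponential learning-rate schedule
# lr_g = lr * dr^(g / ds) at global step g.

adam_new <- function(params) {
  list(m = lapply(params, function(p) p * 0),
       v = lapply(params, function(p) p * 0),
       t = 0L)
}

clip_global_norm <- function(grads, max_norm) {
  sq <- sum(vapply(grads, function(g) sum(g^2), numeric(1)))
  nrm <- sqrt(sq)
  if (is.finite(nrm) && nrm > max_norm) {
    grads <- lapply(grads, function(g) g * (max_norm / nrm))
  }
  grads
}

adam_step <- function(params, grads, state, lr,
                      beta1 = 0.9, beta2 = 0.999, eps = 1e-8) {
  state$t <- state$t + 1L
  t <- state$t
  for (nm in names(grads)) {
    g <- grads[[nm]]
    state$m[[nm]] <- beta1 * state$m[[nm]] + (1 - beta1) * g
    state$v[[nm]] <- beta2 * state$v[[nm]] + (1 - beta2) * g^2
    mhat <- state$m[[nm]] / (1 - beta1^t)
    vhat <- state$v[[nm]] / (1 - beta2^t)
    params[[nm]] <- params[[nm]] - lr * mhat / (sqrt(vhat) + eps)
  }
  list(params = params, state = state)
}

#' Learning rate under the exponential decay schedule
#'
#' @param base_lr base learning rate
#' @param decay_rate multiplicative decay per \code{decay_steps} steps
#' @param decay_steps step granularity of the schedule
#' @param step global step (0-based)
#' @return \code{base_lr * decay_rate^(step / decay_steps)}
#' @export
lr_schedule <- function(base_lr, decay_rate, decay_steps, step) {
  base_lr * decay_rate^(step / decay_steps)
}
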