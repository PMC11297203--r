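# Independent oracles used across the suite.

# Exhaustive forward enumeration of every sample path of the within-patch
# chain (2^R outcome sequences), accumulating probability-weighted propagule
# counts and waiting times. Independent of the backward-recursion dynamic
# program it checks; only feasible for small R.
enum_life_history <- function(model, theta, R) {
  e_prop <- 0
  e_time <- 0
  stack <- list(list(n = 1, r = R, prob = 1, props = 0, time = 0))
  while (length(stack)) {
    s <- stack[[length(stack)]]
    stack[[length(stack)]] <- NULL
    if (s$n == 0 || s$r == 0) {
      e_prop <- e_prop + s$prob * s$props
      e_time <- e_time + s$prob * s$time
      next
    }
    p <- duplication_probability(model, theta, s$n)
    wait <- 1 / s$n
    if (p > 0) {
      stack[[length(stack) + 1]] <- list(n = s$n + 1, r = s$r - 1,
                                         prob = s$prob * p,
                                         props = s$props, time = s$time + wait)
    }
    if (p < 1) {
      stack[[length(stack) + 1]] <- list(n = s$n - 1, r = s$r - 1,
                                         prob = s$prob * (1 - p),
                                         props = s$props + 1,
                                         time = s$time + wait)
    }
  }
  list(rho = e_prop, tau = e_time)
}

# Monte-Carlo means of single-patch propagule count and lifespan.
mc_life_history <- function(model, theta, R, nrep) {
  props <- numeric(nrep)
  spans <- numeric(nrep)
  for (i in seq_len(nrep)) {
    s <- simulate_single_patch(model, theta, R)
    props[i] <- s$propagules
    spans[i] <- s$lifespan
  }
  list(rho_hat = mean(props), rho_se = stats::sd(props) / sqrt(nrep),
       tau_hat = mean(spans), tau_se = stats::sd(spans) / sqrt(nrep))
}
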