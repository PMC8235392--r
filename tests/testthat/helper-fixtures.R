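# shared fixtures and independent oracles

# noiseless or noisy spectrum from known Cole parameters
make_spectrum <- function(params, grid = default_frequency_grid(),
                          noise_sd = 0, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  synthesize_spectrum(params, grid, noise_sd = noise_sd, ...)
}

# independent brute-force Mann-Whitney oracle: U by direct pair counting
# (not ranks), p by full enumeration of group assignments
mwu_brute_force <- function(a, b) {
  pooled <- c(a, b)
  n_a <- length(a); n <- length(pooled)
  u_of <- function(xs, ys) {
    sum(outer(xs, ys, ">")) + 0.5 * sum(outer(xs, ys, "=="))
  }
  u_obs <- u_of(a, b)
  idx <- utils::combn(n, n_a)
  u_all <- apply(idx, 2L, function(ii) u_of(pooled[ii], pooled[-ii]))
  eps <- 1e-9
  p <- min(1, 2 * min(mean(u_all <= u_obs + eps),
                      mean(u_all >= u_obs - eps)))
  list(U = min(u_obs, n_a * (n - n_a) - u_obs), p_value = p)
}

# central-difference gradient of the LSTM loss, step scaled per parameter
lstm_numeric_gradient <- function(model, x, y) {
  v <- lstm_param_vector(model)
  num <- numeric(length(v))
  for (k in seq_along(v)) {
    h <- 1e-5 * max(abs(v[k]), 1)
    vp <- v; vp[k] <- v[k] + h
    vm <- v; vm[k] <- v[k] - h
    lp <- lstm_loss(lstm_set_param_vector(model, vp), x, y,
                    training = TRUE)$loss
    lm <- lstm_loss(lstm_set_param_vector(model, vm), x, y,
                    training = TRUE)$loss
    num[k] <- (lp - lm) / (2 * h)
  }
  num
}

# tiny deterministic cohort for I/O tests
small_cohort <- function(seed = 7L, n_fast = 2L, n_slow = 2L, ...) {
  generate_cohort(simulator_config(seed = seed, n_fast = n_fast,
                                   n_slow = n_slow, ...))
}
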