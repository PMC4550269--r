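# Shared fixtures, all generated in code.

# small bold4d with known content
toy_bold <- function(dims = c(6, 6, 6), T = 40, tr = 2, seed = 1) {
  set.seed(seed)
  bold4d(array(rnorm(prod(dims) * T), dim = c(dims, T)), tr = tr)
}

# a planted-structure ReHo stack without any imaging: cluster columns carry
# a latent mediator signal, the rest are noise
planted_stack <- function(n, V, cluster_cols, a = -0.4, b = 0.4,
                          c_prime = 0.4, seed = 1) {
  set.seed(seed)
  X <- rnorm(n)
  gender <- rbinom(n, 1, 0.32)
  M <- a * X + rnorm(n, 0, sqrt(1 - a^2))
  Y <- c_prime * X + b * M + rnorm(n, 0, 0.8)
  stack <- matrix(rnorm(n * V), n, V)
  stack[, cluster_cols] <- M + 0.5 * matrix(rnorm(n * length(cluster_cols)),
                                            n, length(cluster_cols))
  list(X = X, Y = Y, gender = gender, M = M, stack = stack)
}

# linear congruential sub-seeds so loops over replicates stay < 2^31
sub_seed <- function(seed, i) (seed * 1000L + i) %% .Machine$integer.max
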