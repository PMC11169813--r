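# fixtures are generated in code; no binary data

rand_spd <- function(n, jitter = 0.5) {
  A <- matrix(rnorm(n * n), n)
  crossprod(A) / n + diag(jitter, n)
}

rand_sym <- function(n) {
  A <- matrix(rnorm(n * n), n)
  (A + t(A)) / 2
}

# family of simultaneously diagonalizable (here: diagonal) SPD matrices
commuting_family <- function(n, k, lo = 0.2, hi = 3) {
  lapply(seq_len(k), function(i) diag(runif(n, lo, hi), n))
}

rand_orthogonal <- function(n) qr.Q(qr(matrix(rnorm(n * n), n)))

max_abs <- function(A, B = 0) max(abs(A - B))

# two-class benchmark where one log-coordinate carries only large noise;
# metric learning should suppress it, a plain LEM nearest-mean cannot
make_anisotropic_benchmark <- function(n_per_class, seed,
                                       sigma_info = 0.3, sigma_noise = 3) {
  set.seed(seed)
  n <- 3
  mu <- list(c(0.5, 0.3, -0.4, 0.2, 0, 0),
             c(-0.5, -0.3, 0.4, -0.2, 0, 0))
  sig <- c(rep(sigma_info, 5), sigma_noise)
  mats <- list()
  labels <- integer(0)
  for (k in 1:2) for (i in seq_len(n_per_class)) {
    v <- mu[[k]] + sig * rnorm(6)
    mats <- c(mats, list(sym_expm(coords_to_sym(v, n))))
    labels <- c(labels, k)
  }
  spd_dataset(mats, labels, "aniso", validate = FALSE)
}

# small labeled two-domain pair with a known log-translation
translated_pair <- function(n = 4, C = 2, n_per_class = 20, sigma = 0.3,
                            seed = 1, bnorm = 1.5) {
  set.seed(seed)
  log_means <- lapply(make_class_means(n, C, 2), sym_logm)
  src <- riemalign:::sample_mixture(log_means, sigma, n_per_class, "src")
  tgt0 <- riemalign:::sample_mixture(log_means, sigma, n_per_class, "tgt")
  B <- rand_sym(n)
  B <- B * bnorm / sqrt(sum(B^2))
  list(source = src,
       target = apply_shift(tgt0, shift_spec("log_translation",
                                             translation = B)),
       oracle = tgt0, logB = B)
}
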