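# fixture builders shared across test files

const_epoch <- function(x, y, z, n = 3000) {
  matrix(rep(c(x, y, z), each = n), ncol = 3)
}

random_epoch <- function(n = 3000, sd = 0.3) {
  matrix(rnorm(n * 3, mean = c(0, 0, 1), sd = sd), ncol = 3, byrow = TRUE)
}

# magnitude sinusoid 1 + a*sin(2*pi*f*t + phi) pointing along +z
sine_epoch <- function(a = 0.1, f = 2, phi = 0.3, rate = 100, dur = 30) {
  tt <- (seq_len(rate * dur) - 1) / rate
  r <- 1 + a * sin(2 * pi * f * tt + phi)
  cbind(x = 0 * r, y = 0 * r, z = r)
}

# small censored survival data with known structure
random_surv <- function(n, seed) {
  set.seed(seed)
  data.frame(time = round(rexp(n, 0.2), 2),
             event = rbinom(n, 1, 0.6),
             risk = rnorm(n))
}

tiny_sim_config <- function(...) {
  sim_config(n_participants = 50, recording_days = 30 * 10 / 86400, ...)
}
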