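# shared numerical helpers

# run expr with a local RNG stream seeded at `seed`, restoring global state
.withSeed <- function(seed, expr) {
  if (!is.null(seed)) {
    had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (had) assign(".Random.seed", old, envir = globalenv())
      else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(expr)
}

.sem <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  stats::sd(x) / sqrt(length(x))
}

# von Mises sampler, Best & Fisher (1979) rejection scheme; mu in radians
.rvonmises <- function(n, mu, kappa) {
  if (kappa < 0) stop("kappa must be >= 0")
  if (kappa == 0) return(stats::runif(n, -pi, pi))
  if (kappa < 1e-6) return((mu + stats::runif(n, -pi, pi)) %% (2 * pi) - pi)
  a <- 1 + sqrt(1 + 4 * kappa^2)
  b <- (a - sqrt(2 * a)) / (2 * kappa)
  r <- (1 + b^2) / (2 * b)
  out <- numeric(n)
  for (i in seq_len(n)) {
    repeat {
      u <- stats::runif(3)
      z <- cos(pi * u[1])
      f <- (1 + r * z) / (r + z)
      c0 <- kappa * (r - f)
      if (c0 * (2 - c0) - u[2] > 0 || log(c0 / u[2]) + 1 - c0 >= 0) {
        out[i] <- sign(u[3] - 0.5) * acos(f)
        break
      }
    }
  }
  (mu + out + pi) %% (2 * pi) - pi
}

# concentration parameter for which the mean resultant length equals rho;
# standard A1-inverse approximation
.kappaFromPersistence <- function(rho) {
  if (rho <= 0) return(0)
  rho <- min(rho, 0.999)
  if (rho < 0.53) 2 * rho + rho^3 + 5 * rho^5 / 6
  else if (rho < 0.85) -0.4 + 1.39 * rho + 0.43 / (1 - rho)
  else 1 / (rho^3 - 4 * rho^2 + 3 * rho)
}

# structured exclusion log: message() one line per excluded entity
.logExclusion <- function(stage, id, reason) {
  message(sprintf("[%s] excluded %s: %s", stage, id, reason))
}
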