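# Internal helpers shared across modules.

# Run code with a private RNG stream; the caller's .Random.seed is restored.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  code
}

# Truncated normal sampling by inverse-CDF; exact for moderate truncation.
rtrunc_norm <- function(n, mean, sd, lower = -Inf, upper = Inf) {
  plo <- pnorm((lower - mean) / sd)
  phi <- pnorm((upper - mean) / sd)
  qnorm(runif(n, plo, phi)) * sd + mean
}

# Exponentially tilted uniform on [a, b]: density proportional to exp(g*x).
# The log density ratio against the flat uniform is linear in x, which keeps
# a logistic propensity model exactly correct.
rtilt_unif <- function(n, a, b, g) {
  if (abs(g) < 1e-12) return(runif(n, a, b))
  u <- runif(n)
  log(exp(g * a) + u * (exp(g * b) - exp(g * a))) / g
}

ptrunc_norm_ge <- function(x, mean, sd, lower) {
  # P(X >= x | X >= lower) for X ~ N(mean, sd)
  (1 - pnorm((x - mean) / sd)) / (1 - pnorm((lower - mean) / sd))
}

# Linear-interpolation (type 7) quantile; the package-wide convention.
quantile_linear <- function(x, probs) {
  unname(quantile(x, probs = probs, type = 7, names = FALSE))
}

weighted_mean <- function(x, w) sum(w * x) / sum(w)

# Calendar-month shift with day-of-month clamping (e.g. Aug 31 - 6 months
# lands on Feb 29/28).
add_months <- function(date, k) {
  lt <- as.POSIXlt(date)
  m <- lt$year * 12L + lt$mon + as.integer(k)
  yr <- m %/% 12L
  mo <- m %% 12L
  last <- c(31L, 28L, 31L, 30L, 31L, 30L, 31L, 31L, 30L, 31L, 30L, 31L)[mo + 1L]
  leap <- (yr + 1900L) %% 4L == 0L & ((yr + 1900L) %% 100L != 0L |
                                        (yr + 1900L) %% 400L == 0L)
  last <- ifelse(mo == 1L & leap, 29L, last)
  lt$year <- yr
  lt$mon <- mo
  lt$mday <- pmin(lt$mday, last)
  as.Date(lt)
}

is_treated_arm <- function(arm) arm %in% c("treated_high", "treated_low")

`%||%` <- function(a, b) if (is.null(a)) b else a
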