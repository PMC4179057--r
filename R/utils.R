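#' @keywords internal
"_PACKAGE"

# Night event alphabet shared by every service.
#' Sensor event alphabet
#'
#' The eight event symbols used throughout the package: passive-infrared
#' room events (bathroom \code{Ba}, kitchen \code{K}, hallway \code{H},
#' living room \code{L}), wearable inactivity \code{I}, door opening
#' \code{D}, and bed entrance/exit \code{Bin}/\code{Bout}.
#'
#' @return Character vector of the eight symbols.
#' @export
event_alphabet <- function() {
  c("Ba", "K", "H", "L", "I", "D", "Bin", "Bout")
}

# Run expr with a temporary RNG seed, restoring the caller's RNG state.
with_local_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(expr)
}

# Deterministic child seed from (seed, night, stream-name); stays < 2^31.
child_seed <- function(seed, night_id, what) {
  h <- sum(utf8ToInt(what)) %% 1009L
  as.integer((as.numeric(seed) * 48271 + as.numeric(night_id) * 16807 + h) %%
               2147483629)
}

# Moments of a normal(mu, sigma) truncated below at `lower`.
tnorm_moments <- function(mu, sigma, lower = 0) {
  a <- (lower - mu) / sigma
  lambda <- stats::dnorm(a) / (1 - stats::pnorm(a))
  m <- mu + sigma * lambda
  v <- sigma^2 * (1 + a * lambda - lambda^2)
  list(mean = m, sd = sqrt(v))
}

# Sample from a normal truncated below at `lower` by inverse-CDF; mu and
# sigma are the pre-truncation parameters.
rtnorm <- function(n, mu, sigma, lower = 0) {
  if (sigma <= 0) return(rep(max(mu, lower), n))
  p_lo <- stats::pnorm(lower, mu, sigma)
  u <- stats::runif(n, p_lo, 1)
  stats::qnorm(u, mu, sigma)
}

# Population standard deviation (denominator n).
pop_sd <- function(x) {
  m <- mean(x)
  sqrt(mean((x - m)^2))
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) is.numeric(x) && length(x) == 1 && !is.na(x) &&
  x >= 1 && x == floor(x)
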