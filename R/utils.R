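# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(sprintf(...), call. = FALSE)

assert_that <- function(cond, ...) {
  if (!isTRUE(cond)) stop_input(...)
  invisible(TRUE)
}

#' Run an expression under a local, explicit random seed
#'
#' All stochastic operations in the package take an explicit integer seed and
#' evaluate under it without disturbing the caller's global random state.
#'
#' @param seed integer seed
#' @param expr expression to evaluate
#' @keywords internal
with_seed <- function(seed, expr) {
  assert_that(is.numeric(seed) && length(seed) == 1 && is.finite(seed),
              "seed must be a single finite number")
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit(if (had) assign(".Random.seed", old, envir = genv)
          else if (exists(".Random.seed", envir = genv, inherits = FALSE))
            rm(".Random.seed", envir = genv))
  set.seed(as.integer(seed))
  expr
}

# Derive a stream of child seeds from one master seed (kept below 2^31).
child_seeds <- function(seed, n) {
  with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

# Circular statistics on angles in radians.
circ_mean <- function(theta) atan2(mean(sin(theta)), mean(cos(theta)))

circ_sd <- function(theta) {
  r <- sqrt(mean(sin(theta))^2 + mean(cos(theta))^2)
  r <- min(max(r, .Machine$double.eps), 1)
  sqrt(-2 * log(r))
}

rad2deg <- function(x) x * 180 / pi
deg2rad <- function(x) x * pi / 180

# Wrap an angle difference into (-pi, pi].
wrap_angle <- function(x) {
  y <- (x + pi) %% (2 * pi) - pi
  y[y <= -pi] <- pi
  y
}

# Sample index (1-based) of a time point at rate fs; time 0 -> sample 1.
time_to_sample <- function(t, fs) as.integer(round(t * fs)) + 1L

sample_to_time <- function(i, fs) (i - 1L) / fs

is_scalar_num <- function(x) is.numeric(x) && length(x) == 1 && is.finite(x)
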