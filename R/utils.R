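# Internal helpers shared across modules.

# Run `code` under a fixed RNG seed without clobbering the caller's RNG
# state. `seed = NULL` leaves the RNG alone (non-reproducible path).
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    # touch the RNG so there is a state to restore
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  force(code)
}

# Derive a child seed from a master seed; keeps child streams decoupled
# while staying inside the 32-bit integer range.
child_seed <- function(seed, k) {
  if (is.null(seed)) return(NULL)
  as.integer((as.numeric(seed) * 48271 + 7919 * k) %% 2147483647)
}

stop_validation <- function(...) {
  stop(structure(class = c("tpsd_validation_error", "error", "condition"),
                 list(message = paste0(...), call = sys.call(-1))))
}

assert_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop_validation(name, " must be a finite numeric scalar")
  if (positive && x <= 0)
    stop_validation(name, " must be positive")
  invisible(x)
}

assert_fraction <- function(x, name) {
  assert_scalar_number(x, name)
  if (x < 0 || x > 1) stop_validation(name, " must lie in [0, 1]")
  invisible(x)
}

# round-half-up (base round() is round-half-even)
round_half_up <- function(x) floor(x + 0.5)
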