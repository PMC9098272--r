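# Classed condition helpers: every user-facing validation failure carries a
# condition class so callers (and tests) can distinguish configuration
# problems from I/O or geometry problems.

mid_stop <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "midecoder_error")))
}

stop_config <- function(msg) mid_stop(msg, "midecoder_config_error")
stop_validation <- function(msg) mid_stop(msg, "midecoder_validation_error")
stop_io <- function(msg) mid_stop(msg, "midecoder_io_error")
stop_geometry <- function(msg) mid_stop(msg, "midecoder_geometry_error")
stop_mapping <- function(msg) mid_stop(msg, "midecoder_mapping_error")

# Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Round half away from zero (base round() rounds half to even).
round_haz <- function(x) sign(x) * floor(abs(x) + 0.5)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
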