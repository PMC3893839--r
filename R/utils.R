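# Classed error conditions so callers (and the CLI) can distinguish
# bad input from bad parameters without parsing messages.

.flowseg_error <- function(class, msg, call = sys.call(-1)) {
  stop(structure(
    class = c(class, "flowseg_error", "error", "condition"),
    list(message = msg, call = call)
  ))
}

.input_error     <- function(msg) .flowseg_error("flowseg_input_error", msg)
.shape_error     <- function(msg) .flowseg_error("flowseg_shape_error", msg)
.parameter_error <- function(msg) .flowseg_error("flowseg_parameter_error", msg)
.numeric_error   <- function(msg) .flowseg_error("flowseg_numeric_error", msg)
.io_error        <- function(msg) .flowseg_error("flowseg_io_error", msg)

.is_odd <- function(x) x %% 2L == 1L

# Evaluate `expr` with the RNG seeded to `seed`, restoring the caller's
# RNG state afterwards so generators never perturb user simulations.
.with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(seed)
  expr
}
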