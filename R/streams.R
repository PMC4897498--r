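# Reproducible random streams.
#
# A "stream" is a saved R RNG state advanced only by the draws made inside
# stream_eval(). Block-decomposed execution gives every (kernel, block)
# pair its own stream, seeded by a deterministic integer mix of the chain
# seed, the block coordinates and a kernel id — the per-block random states
# of the decomposition scheme. The same mechanism drives the serial chain
# (one block per kernel), so a 1x1 blocked run reproduces it bit for bit.

stream_seed <- function(seed, block_row, block_col, kernel_id) {
  s <- as.numeric(seed) %% 2147483647
  h <- (s * 31 + block_row * 2654435 + block_col * 40503 + kernel_id * 97) %% 2147483647
  as.integer(h)
}

make_stream <- function(seed) {
  old <- get_rng_state()
  set.seed(seed)
  st <- new.env(parent = emptyenv())
  st$state <- .GlobalEnv$.Random.seed
  set_rng_state(old)
  st
}

get_rng_state <- function() {
  if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
    get(".Random.seed", envir = .GlobalEnv, inherits = FALSE)
  } else {
    NULL
  }
}

set_rng_state <- function(state) {
  if (is.null(state)) {
    if (exists(".Random.seed", envir = .GlobalEnv, inherits = FALSE)) {
      rm(".Random.seed", envir = .GlobalEnv)
    }
  } else {
    assign(".Random.seed", state, envir = .GlobalEnv)
  }
  invisible(state)
}

# Evaluate fn() with the stream's RNG state active; persist the advanced
# state back into the stream and restore the caller's state.
stream_eval <- function(stream, fn) {
  old <- get_rng_state()
  set_rng_state(stream$state)
  on.exit(set_rng_state(old), add = TRUE)
  out <- fn()
  stream$state <- .GlobalEnv$.Random.seed
  out
}
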