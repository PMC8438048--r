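# Internal helpers shared across modules.

# The 16 permitted score levels: 0, 0.1, ..., 1.5.
SCORE_LEVELS <- seq(0, 1.5, by = 0.1)

# Scores live on a 0.1-spaced grid; comparing them as doubles invites
# bin-edge artifacts, so every comparison goes through integer tenths.
score_tenths <- function(x) as.integer(round(x * 10))

# Round a position up to the nearest score step (multiple of 0.1).
# A value already on the grid (to within numerical fuzz) stays put.
ceiling_score_step <- function(x, tol = 1e-9) {
  ceiling(x * 10 - tol) / 10
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if_not_matrix <- function(x, name) {
  if (!is.matrix(x) || !is.numeric(x)) {
    stop(sprintf("'%s' must be a numeric matrix", name), call. = FALSE)
  }
}
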