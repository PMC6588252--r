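# Named RNG sub-streams.
#
# Every stochastic component draws from a sub-stream whose seed is a hash of
# the master seed and a path of labels (e.g. subject id, eye, layer). This
# makes cohorts fully reproducible and ensures that adding subjects or layers
# never perturbs the fields already generated for existing ones.

#' Derive a deterministic sub-stream seed
#'
#' Hashes a master seed together with an arbitrary path of labels (numbers
#' or strings) into an integer seed in `[0, 2^31 - 1)`.
#'
#' @param seed Integer master seed.
#' @param ... Path labels identifying the sub-stream.
#' @return A single integer seed.
#' @export
substream_seed <- function(seed, ...) {
  labels <- paste(c(seed, ...), collapse = "/")
  bytes <- utf8ToInt(labels)
  h <- 5381
  m <- 2147483647  # 2^31 - 1, keeps everything in exact double range
  for (b in bytes) h <- (h * 33 + b) %% m
  as.integer(h)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_substream <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(seed)
  force(code)
}
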