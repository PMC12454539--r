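# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library calls never perturb user
# simulations.
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  })
  set.seed(seed)
  force(code)
}

# Deterministic sub-stream seeds: facilities / patients / outcomes each get
# their own seed derived from the master seed, so e.g. changing n_patients
# leaves the facility table untouched.  Kept below 2^31 - 1.
sub_seed <- function(seed, stream) {
  as.integer((as.numeric(seed) %% 44488L * 48271 + stream) %% 2147483647)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_config <- function(...) stop(sprintf(...), call. = FALSE)

assert_columns <- function(df, cols, what = "input") {
  missing <- setdiff(cols, names(df))
  if (length(missing)) {
    stop_config("%s is missing required column(s): %s", what,
                paste(missing, collapse = ", "))
  }
  invisible(df)
}
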