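# internal helpers: classed conditions, scoped RNG, tiny hashing

ns_abort <- function(msg, class) {
  stop(errorCondition(msg, class = c(class, "nmfselect_error", "error", "condition")))
}

# Evaluate `expr` under a temporary RNG state seeded with `seed`, restoring
# the caller's .Random.seed afterwards so library code never disturbs the
# user's random stream.
ns_with_seed <- function(seed, expr) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE))
      rm(".Random.seed", envir = env)
  })
  set.seed(seed)
  force(expr)
}

# Derive a stream of independent sub-seeds from one master seed.
ns_derive_seeds <- function(seed, n) {
  ns_with_seed(seed, sample.int(.Machine$integer.max - 1L, n))
}

ns_is_wholenumber <- function(x, tol = 1e-8) {
  is.finite(x) & abs(x - round(x)) < tol
}

# Polynomial rolling hash over a character string; used to stamp artifact
# files with a config fingerprint (no cryptographic intent).
ns_hash <- function(x) {
  bytes <- utf8ToInt(paste(x, collapse = "\n"))
  h <- 5381
  for (b in bytes) h <- (h * 33 + b) %% 2147483647
  sprintf("%08x", h)
}

ns_stopifnot_scalar_prob <- function(x, name, open = TRUE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (open) x > 0 && x < 1 else x >= 0 && x <= 1)
  if (!ok) ns_abort(sprintf("`%s` must be a fraction in %s", name,
                            if (open) "(0, 1)" else "[0, 1]"),
                    "ns_config_error")
  invisible(x)
}
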