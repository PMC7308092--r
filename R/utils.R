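# Internal helpers shared across modules.

# Deterministic sub-seed derivation: one master seed, fixed offsets per
# component. Kept below 2^31 - 1 so it is always a valid integer seed.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) %% 100000L) * 16807 + offset) %% 2147483647L
}

# Evaluate `code` under `seed`, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_scalar_number <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  invisible(x)
}

# Symmetric-matrix helpers used by the Riemannian machinery.
sym_part <- function(m) (m + t(m)) / 2

spd_eigen <- function(m, name = "matrix") {
  e <- eigen(sym_part(m), symmetric = TRUE)
  if (any(e$values <= 0)) {
    abort(sprintf("%s is not positive definite (min eigenvalue %.3g).",
                  name, min(e$values)))
  }
  e
}

mat_fun_spd <- function(m, fun, name = "matrix") {
  e <- spd_eigen(m, name)
  sym_part(e$vectors %*% (fun(e$values) * t(e$vectors)))
}

logm_spd <- function(m, name = "matrix") mat_fun_spd(m, log, name)
expm_sym <- function(m) {
  e <- eigen(sym_part(m), symmetric = TRUE)
  sym_part(e$vectors %*% (exp(e$values) * t(e$vectors)))
}
powm_spd <- function(m, p, name = "matrix") {
  mat_fun_spd(m, function(v) v^p, name)
}
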