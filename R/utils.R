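# Internal helpers shared across modules.

clip <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Derive a reproducible child seed
#'
#' Expands one user-facing seed into per-stage (and per-subject) streams so a
#' stage can be regenerated in isolation without replaying earlier stages.
#' Values stay below 2^31 - 1.
#'
#' @param seed Integer base seed.
#' @param ... Integer stage / unit indices.
#' @return A single integer seed.
#' @keywords internal
child_seed <- function(seed, ...) {
  s <- as.double(abs(as.integer(seed)) %% 2147483647L)
  for (k in c(...)) s <- (s * 48271 + as.double(k) + 1) %% 2147483647
  as.integer(s)
}

# Evaluate `code` under `seed` without disturbing the caller's RNG state.
with_seed <- function(seed, code) {
  genv <- globalenv()
  old <- if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
    get(".Random.seed", envir = genv, inherits = FALSE)
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
        rm(".Random.seed", envir = genv)
      }
    } else {
      assign(".Random.seed", old, envir = genv)
    }
  })
  set.seed(seed)
  code
}

is_symmetric_matrix <- function(M, tol = 1e-10) {
  is.matrix(M) && nrow(M) == ncol(M) && max(abs(M - t(M))) <= tol
}

# Cheap deterministic checksum of a config list (polynomial hash of its YAML
# serialization); recorded in output manifests for provenance.
config_checksum <- function(x) {
  s <- yaml::as.yaml(unclass_recursive(x))
  b <- utf8ToInt(s)
  h <- 0
  for (i in seq_along(b)) h <- (h * 31 + b[i]) %% 2147483647
  sprintf("%08x", as.integer(h))
}

unclass_recursive <- function(x) {
  if (is.list(x)) {
    x <- unclass(x)
    lapply(x, unclass_recursive)
  } else {
    x
  }
}

# Nearest positive semi-definite correlation matrix: eigenvalue clipping at
# `eps`, then renormalization to unit diagonal.
psd_repair <- function(M, eps = 1e-8) {
  e <- eigen(M, symmetric = TRUE)
  if (min(e$values) >= eps) return(M)
  vals <- pmax(e$values, eps)
  R <- e$vectors %*% (vals * t(e$vectors))
  R <- (R + t(R)) / 2
  d <- sqrt(diag(R))
  R <- R / outer(d, d)
  diag(R) <- 1
  R
}
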