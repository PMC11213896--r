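# Internal helpers shared across modules.

# Derive a reproducible sub-seed from a master seed and a stream name, so each
# simulated layer consumes an independent RNG stream: adding a layer never
# perturbs the others. Kept strictly below 2^31 (R integers are 32-bit).
substream_seed <- function(master, name) {
  stopifnot(is.numeric(master), length(master) == 1L, is.character(name))
  codes <- utf8ToInt(name)
  h <- sum(codes * seq_along(codes)) %% 1000003
  as.integer((abs(as.numeric(master)) * 48271 + h * 7919 + 1) %% 2147483629)
}

# Evaluate `expr` under a fixed seed without clobbering the caller's RNG state.
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(seed)
  expr
}

# Validate a feature x sample omics matrix: numeric, uniquely named axes.
check_omics_matrix <- function(m, what = "matrix") {
  if (!is.matrix(m) || !is.numeric(m)) {
    stop(what, " must be a numeric matrix (features x samples)", call. = FALSE)
  }
  if (is.null(rownames(m)) || is.null(colnames(m))) {
    stop(what, " must have feature rownames and sample colnames", call. = FALSE)
  }
  if (anyDuplicated(rownames(m))) {
    stop(what, " has duplicated feature ids", call. = FALSE)
  }
  if (anyDuplicated(colnames(m))) {
    stop(what, " has duplicated sample ids", call. = FALSE)
  }
  invisible(m)
}

# Extract the z matrix from either a zscore_matrix object or a plain matrix.
as_z_matrix <- function(z) {
  if (inherits(z, "zscore_matrix")) z$z else {
    check_omics_matrix(z, "z")
    z
  }
}

`%||%` <- function(a, b) if (is.null(a)) b else a
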