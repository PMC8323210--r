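# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

# Evaluate expr with a locally seeded RNG, restoring the caller's RNG state.
# All stochastic operations in the package route through this so that a config
# seed fully determines the output regardless of surrounding code.
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
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
  set.seed(as.integer(seed), kind = "Mersenne-Twister",
           normal.kind = "Inversion", sample.kind = "Rejection")
  expr
}

is_binary01 <- function(x) {
  x <- x[!is.na(x)]
  length(x) == 0L || all(x %in% c(0, 1))
}

# all unordered index pairs (i < j), ordered by i then j
index_pairs <- function(n) {
  stopifnot(n >= 2)
  ia <- rep.int(seq_len(n - 1L), times = (n - 1L):1L)
  ib <- unlist(lapply(seq_len(n - 1L), function(i) (i + 1L):n), use.names = FALSE)
  cbind(a = ia, b = ib)
}

# patients x items 0/1 presence matrix (robust to 0/1-length item vectors)
presence_matrix <- function(value_sets, items) {
  m <- matrix(0, nrow = length(value_sets), ncol = length(items),
              dimnames = list(names(value_sets), items))
  for (i in seq_along(value_sets)) {
    m[i, ] <- as.numeric(items %in% value_sets[[i]])
  }
  m
}

assert_probability <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0) || any(x > 1)) {
    stop(sprintf("`%s` must lie in [0, 1]", name), call. = FALSE)
  }
  invisible(x)
}
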