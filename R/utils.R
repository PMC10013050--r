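# Run expr under a temporary RNG seed, restoring the caller's RNG state.
# seed = NULL leaves the current stream untouched.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Deterministic sub-seed for work unit i of stream `stream` under a master
# seed; independent of execution order so realizations can be resumed or
# reordered without changing their draws. Kept below 2^31.
subSeed <- function(master, stream, i) {
  as.integer((as.double(master) * 48271 + stream * 30269 + i * 7907) %% 2147483629)
}

stopifnotScalar <- function(x, name, positive = TRUE) {
  if (length(x) != 1 || !is.finite(x) || (positive && x <= 0))
    stop(sprintf("'%s' must be a %s scalar", name,
                 if (positive) "positive finite" else "finite"), call. = FALSE)
  invisible(x)
}
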