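# Internal helpers shared across modules.

# Deterministic child seeds from one master seed. Keeps every stream
# below 2^31 - 1 so seeds remain valid R integers.
child_seed <- function(seed, stream) {
  stopifnot(is.numeric(seed), length(seed) == 1)
  offsets <- c(
    catalog = 101L, truth = 211L, abundances = 307L, arrays = 401L,
    trace = 503L, pipeline = 601L, misc = 701L
  )
  off <- offsets[[stream]]
  as.integer((abs(seed) * 48271 + off) %% 2147483587)
}

with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  set.seed(seed)
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  expr
}

stop_if_not_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x <= 0) {
    stop(sprintf("'%s' must be a single positive finite number", name),
         call. = FALSE)
  }
  invisible(x)
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  read.delim(path, sep = "\t", stringsAsFactors = FALSE, ...)
}

# Trapezoidal integral on an arbitrary grid.
trapezoid <- function(x, y) {
  n <- length(x)
  if (n < 2) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n]) / 2)
}
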