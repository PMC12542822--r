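# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.stop_config <- function(field, why) {
  stop(sprintf("invalid configuration field '%s': %s", field, why), call. = FALSE)
}

.check_prop <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    .stop_config(field, "must be a single proportion in [0, 1]")
  x
}

.check_count <- function(x, field, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x))
    .stop_config(field, sprintf("must be a single integer >= %d", min))
  as.integer(x)
}

.check_pos <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0)
    .stop_config(field, "must be a single positive number")
  x
}

# Evaluate code with a temporary RNG state seeded from `seed`, restoring the
# caller's .Random.seed afterwards so simulators do not perturb user sessions.
.with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

# Deterministic TSV writer used for all persisted outputs.
.write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "", eol = "\n")
  invisible(path)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  read.delim(path, sep = "\t", check.names = FALSE, stringsAsFactors = FALSE)
}

# Draw n values from a positive-integer distribution spec: either a single
# integer (constant) or list(dist = "poisson"|"uniform"|"constant", ...).
# Poisson is shifted by 1 so counts are always >= 1.
.draw_counts <- function(spec, n, field) {
  if (is.numeric(spec) && length(spec) == 1L) {
    k <- .check_count(spec, field)
    return(rep.int(k, n))
  }
  if (!is.list(spec) || is.null(spec$dist))
    .stop_config(field, "must be an integer or list(dist = ..., ...)")
  switch(spec$dist,
    constant = rep.int(.check_count(spec$value %||% 1L, field), n),
    poisson = {
      lambda <- .check_pos(spec$lambda %||% 1, field)
      1L + rpois(n, lambda)
    },
    uniform = {
      lo <- .check_count(spec$min %||% 1L, field)
      hi <- .check_count(spec$max %||% lo, field, min = lo)
      if (lo == hi) rep.int(lo, n) else sample(lo:hi, n, replace = TRUE)
    },
    .stop_config(field, sprintf("unknown distribution '%s'", spec$dist))
  )
}

.AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
           "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")
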