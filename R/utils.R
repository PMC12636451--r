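# internal helpers shared across modules

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_if <- function(cond, ...) if (isTRUE(cond)) stop(..., call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         allow_equal_lower = FALSE) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x),
          sprintf("'%s' must be a single finite number", name))
  if (allow_equal_lower) {
    stop_if(x < lower, sprintf("'%s' must be >= %g", name, lower))
  } else {
    stop_if(x <= lower, sprintf("'%s' must be > %g", name, lower))
  }
  stop_if(x > upper, sprintf("'%s' must be <= %g", name, upper))
  invisible(x)
}

check_count <- function(x, name, min = 1L) {
  stop_if(!is.numeric(x) || length(x) != 1L || !is.finite(x) ||
            x != round(x) || x < min,
          sprintf("'%s' must be an integer >= %d", name, min))
  as.integer(x)
}

# local RNG scope: every generator seeds its own stream and restores the
# caller's RNG state afterwards (no global side effects)
with_seed <- function(seed, code) {
  stop_if(!is.numeric(seed) || length(seed) != 1L || !is.finite(seed),
          "'seed' must be a single integer")
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

trapezoid <- function(x, y) pracma::trapz(x, y)

file_md5 <- function(path) unname(tools::md5sum(path))
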