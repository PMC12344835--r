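#' @import stats
#' @importFrom utils head tail
NULL

# Run-length encoding of a logical/char vector as (start, end, value) index runs.
run_table <- function(x) {
  r <- rle(as.vector(x))
  end <- cumsum(r$lengths)
  data.frame(start = c(1L, head(end, -1L) + 1L), end = end,
             value = r$values, stringsAsFactors = FALSE)
}

# Deterministic hierarchical sub-seeds: one call consumes the parent seed and
# yields n child seeds, so per-participant / per-trial streams are independent
# of how many draws any sibling consumes.
spawn_seeds <- function(seed, n) {
  force(seed)                      # before touching the caller's RNG state
  if (n == 0L) return(integer(0))
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

# Evaluate expr under a local RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
with_seed <- function(seed, expr) {
  force(seed)                      # before touching the caller's RNG state
  old <- get0(".Random.seed", envir = globalenv(), inherits = FALSE)
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

# Nominal inter-sample interval (ms) of a trace, robust to missing rows.
nominal_dt <- function(time_ms) {
  d <- diff(time_ms)
  if (length(d) == 0L) return(NA_real_)
  stats::median(d)
}

stop_config <- function(...) stop("configuration error: ", ..., call. = FALSE)

`%||%` <- function(a, b) if (is.null(a)) b else a

CONDITIONS <- c("gap", "overlap_silent", "overlap_cued")
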