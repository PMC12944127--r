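#' Evaluate an expression with a temporary RNG seed
#'
#' Sets the seed, runs the code, and restores the caller's RNG state, so
#' seeded generators do not perturb the global random stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @export
with_seed <- function(seed, code) {
  env <- globalenv()
  had <- exists(".Random.seed", envir = env, inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = env, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = env)
    else if (exists(".Random.seed", envir = env, inherits = FALSE)) {
      rm(".Random.seed", envir = env)
    }
  })
  set.seed(seed)
  code
}

# Min-max rescaling to [0, 1]. An all-zero vector stays all zero; a nonzero
# constant vector maps to all ones (its own maximum).
minmax01 <- function(r) {
  mn <- min(r); mx <- max(r)
  if (mx - mn < 1e-15) {
    if (abs(mx) < 1e-15) return(rep(0, length(r)))
    return(rep(1, length(r)))
  }
  (r - mn) / (mx - mn)
}

round_half_up <- function(x) floor(x + 0.5)

# segments/intervals: data.frame(start, end), 0-based half-open
validate_segments <- function(segs) {
  stopifnot(is.data.frame(segs), all(c("start", "end") %in% names(segs)))
  if (nrow(segs) > 0L) {
    if (any(segs$end <= segs$start)) stop("segments must satisfy start < end")
    if (nrow(segs) > 1L) {
      if (any(diff(segs$start) < 0)) stop("segments must be sorted by start")
      if (any(segs$start[-1L] < segs$end[-nrow(segs)])) {
        stop("segments must be non-overlapping")
      }
    }
  }
  invisible(segs)
}
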