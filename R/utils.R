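#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG
# stream. `seed = NULL` leaves the current stream untouched.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  expr
}

# Derive a reproducible child seed from a parent seed and an index,
# staying inside the 32-bit integer range.
child_seed <- function(seed, index) {
  as.integer((as.double(seed) + 97003L * as.double(index)) %% 2147483629)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

abort_mr <- function(msg, class) {
  stop(structure(class = c(class, "mrscreen_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}
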