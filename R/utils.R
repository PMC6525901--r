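# internal helpers

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @noRd
round_half_up <- function(x) floor(x + 0.5)

# Evaluate `code` under `seed` without disturbing the caller's RNG stream.
local_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

stop_bad <- function(...) stop(..., call. = FALSE)

# ISO-8601 character (empty string = absent) or Date -> Date
as_date <- function(x) {
  if (inherits(x, "Date")) return(x)
  x <- as.character(x)
  x[is.na(x) | !nzchar(x)] <- NA_character_
  as.Date(x)
}
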