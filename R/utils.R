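# Internal helpers: seed substreams and argument validation.

#' Derive a reproducible substream seed from a master seed and a stream name
#'
#' Each generator draws from its own named substream so that adding a new
#' generator (or re-ordering calls) does not perturb the output of existing
#' ones. The derived seed is a deterministic 31-bit hash of the master seed
#' and the stream name.
#'
#' @param seed master integer seed
#' @param name character stream name
#' @return an integer seed in [0, 2^31 - 1]
#' @keywords internal
substream_seed <- function(seed, name) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(name))
  h <- as.double(seed %% 2147483647)
  for (k in utf8ToInt(name)) {
    h <- (h * 31 + k) %% 2147483647
  }
  as.integer(h)
}

# run expr with a local RNG state seeded from (seed, name); restores the
# caller's RNG state afterwards
with_substream <- function(seed, name, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(substream_seed(seed, name))
  expr
}

stop_field <- function(field, msg) {
  stop(sprintf("invalid `%s`: %s", field, msg), call. = FALSE)
}

check_count <- function(x, field, positive = TRUE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != round(x)) {
    stop_field(field, "must be a single whole number")
  }
  if (positive && x <= 0) stop_field(field, "must be > 0")
  if (!positive && x < 0) stop_field(field, "must be >= 0")
  invisible(as.integer(x))
}

check_sd <- function(x, field) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0) {
    stop_field(field, "must be a single number >= 0")
  }
  invisible(as.numeric(x))
}
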