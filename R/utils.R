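# Internal helpers shared across modules.

# Run code with a temporary RNG state so generators are reproducible without
# clobbering the caller's random stream.
with_seed <- function(seed, code) {
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

#' Derive a reproducible child seed
#'
#' Deterministically maps a master seed plus stage/replicate labels to a
#' 31-bit child seed, so every stochastic stage of a pipeline run gets its
#' own stream while remaining fully reproducible from one master seed.
#'
#' @param seed Integer master seed.
#' @param ... Stage labels (coerced to character), e.g. `"background"`, 3.
#' @return A positive integer below 2^31.
#' @export
derive_seed <- function(seed, ...) {
  parts <- paste(c(format(seed), vapply(list(...), as.character, "")),
                 collapse = "/")
  h <- 7
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483629
  as.integer(h + 1)
}

# Mean Earth radius (km), IUGG mean radius; used for all great-circle and
# area computations in the package.
EARTH_RADIUS_KM <- 6371.0088

`%||%` <- function(a, b) if (is.null(a)) b else a
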