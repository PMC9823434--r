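# Run expr under a temporary RNG state seeded with `seed`; the caller's
# .Random.seed is untouched. seed = NULL runs expr as-is.
withSeed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

#' Deterministic sub-stream seed
#'
#' Derives a reproducible child seed from a base seed plus arbitrary
#' labels (date index, protocol name, emission band, stage name), so
#' that adding a protocol or stage to a run never perturbs the random
#' draws of existing ones. Polynomial string hash modulo 2^31 - 1.
#'
#' @param seed base integer seed.
#' @param ... labels coerced to character.
#' @return an integer in [0, 2^31 - 2].
#' @export
substreamSeed <- function(seed, ...) {
  parts <- paste(c(as.character(seed), vapply(list(...), as.character,
                                              character(1))),
                 collapse = "|")
  h <- 0
  for (ch in utf8ToInt(parts)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Format p-values for text output; below 1e-15 the digits are spurious.
formatPValue <- function(p) {
  ifelse(p < 1e-15, "< 1e-15", formatC(p, format = "g", digits = 3))
}
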