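# Internal helpers shared across modules.

#' Normalize a species binomial
#'
#' Trims and collapses whitespace, lower-cases the name and capitalizes the
#' genus, so survey and trait tables match case-insensitively on the trimmed
#' binomial.
#'
#' @param x character vector of species names.
#' @return character vector of normalized binomials.
#' @examples
#' normalizeSpecies("  xanthoria   PARIETINA ")
#' @export
normalizeSpecies <- function(x) {
  x <- trimws(gsub("\\s+", " ", as.character(x)))
  out <- tolower(x)
  first <- substr(out, 1L, 1L)
  substr(out, 1L, 1L) <- toupper(first)
  out
}

# Run `fun` under a fixed seed without disturbing the caller's RNG stream.
# Every generator routes its randomness through this single point.
.withSeed <- function(seed, fun) {
  if (is.null(seed)) return(fun())
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  fun()
}

# Report rounding convention: 3 decimals, matching the precision of the
# published figures of merit.
.roundReport <- function(x, digits = 3L) round(x, digits)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.warnf <- function(...) warning(sprintf(...), call. = FALSE)

.msgStage <- function(stage, t0) {
  message(sprintf("[epilichen] %-12s %7.2fs", stage,
                  as.numeric(proc.time()[["elapsed"]]) - t0))
}
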