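#' @include AllClasses.R
NULL

## Run `expr` under a fixed RNG seed, restoring the caller's RNG state.
withSeed <- function(seed, expr) {
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

## Derive a stream seed from a base seed and an index, staying inside the
## 32-bit integer range.
deriveSeed <- function(seed, k) {
  as.integer((as.numeric(seed) * 1103515245 + 12345 * as.numeric(k)) %% 2147483647)
}

## Parse/format the ';'-separated flag field of call tables.
splitFlags <- function(flags) {
  if (!nzchar(flags)) character() else strsplit(flags, ";", fixed = TRUE)[[1L]]
}

addFlag <- function(flags, flag) {
  f <- unique(c(splitFlags(flags), flag))
  paste(f, collapse = ";")
}

hasFlag <- function(flags, flag) {
  vapply(flags, function(f) flag %in% splitFlags(f), logical(1), USE.NAMES = FALSE)
}

isUnflagged <- function(flags) !nzchar(flags)

## Empty peak table with the canonical columns.
emptyPeaks <- function() {
  data.frame(channel = integer(), apexScan = numeric(), height = numeric(),
             area = numeric(), fwhmScans = numeric(), saturated = logical())
}

emptyCalls <- function() {
  data.frame(locus = character(), designation = character(),
             size = numeric(), height = numeric(), flags = character(),
             stringsAsFactors = FALSE)
}
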