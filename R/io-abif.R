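#' @include AllClasses.R AllGenerics.R utils.R
NULL

## --- raw-byte helpers (ABIF is big-endian throughout) ---------------------

rawInt <- function(x, size) {
  unlist(lapply(as.integer(x), function(v)
    writeBin(v, raw(), size = size, endian = "big")), use.names = FALSE)
}

rawDouble <- function(x) {
  writeBin(as.double(x), raw(), size = 8, endian = "big")
}

rawPString <- function(s) {
  b <- charToRaw(s)
  if (length(b) > 255L) b <- b[1:255]
  c(as.raw(length(b)), b)
}

readIntBE <- function(raw, offset, size, signed = TRUE) {
  readBin(raw[(offset + 1L):(offset + size)], "integer", size = size,
          endian = "big", signed = signed)
}

## ABIF element type codes used by this dialect
ABIF_SHORT <- 4L; ABIF_DOUBLE <- 8L; ABIF_PSTRING <- 18L; ABIF_DIR <- 1023L

## one 28-byte directory entry
abifEntry <- function(name, number, type, elementSize, nElem, data) {
  list(name = name, number = number, type = type, elementSize = elementSize,
       nElem = nElem, data = data)
}

#' Write an electropherogram as an ABIF (.fsa) file
#'
#' Emits an ABIF version-101 container (big-endian) with a minimal tag set:
#' per-channel \code{DATA} entries (16-bit signed integers, values rounded
#' and clipped to the int16 range), \code{Dye#} and \code{DyeN} dye names,
#' \code{SMPL} sample name, a \code{RunK} run-kind tag, and (for simulated
#' traces) an \code{XTlk} crosstalk-matrix tag so analysis can recover the
#' mixing. Conventional fragment-analysis viewers accept this dialect.
#' \code{\link{readFsa}} inverts it; the round trip is exact for
#' integer-valued traces.
#'
#' @param trace An \linkS4class{Electropherogram} with at least one scan.
#' @param path Output path (conventionally \code{.fsa}).
#' @return \code{path}, invisibly.
#' @export
writeFsa <- function(trace, path) {
  v <- trace@values
  if (nrow(v) == 0L || ncol(v) == 0L) stop("cannot write a zero-length trace")
  md <- trace@metadata
  dyeNames <- colnames(v)
  if (is.null(dyeNames)) dyeNames <- paste0("DYE", seq_len(ncol(v)))
  entries <- list()
  for (j in seq_len(ncol(v))) {
    x <- pmax(pmin(round(v[, j]), 32767), -32768)
    entries[[length(entries) + 1L]] <-
      abifEntry("DATA", j, ABIF_SHORT, 2L, nrow(v), rawInt(x, 2L))
  }
  entries[[length(entries) + 1L]] <-
    abifEntry("Dye#", 1L, ABIF_SHORT, 2L, 1L, rawInt(ncol(v), 2L))
  for (j in seq_len(ncol(v))) {
    ps <- rawPString(dyeNames[j])
    entries[[length(entries) + 1L]] <-
      abifEntry("DyeN", j, ABIF_PSTRING, 1L, length(ps), ps)
  }
  ps <- rawPString(md$sampleId %||% "sample")
  entries[[length(entries) + 1L]] <-
    abifEntry("SMPL", 1L, ABIF_PSTRING, 1L, length(ps), ps)
  ps <- rawPString(md$runKind %||% "sample")
  entries[[length(entries) + 1L]] <-
    abifEntry("RunK", 1L, ABIF_PSTRING, 1L, length(ps), ps)
  if (!is.null(md$crosstalk))
    entries[[length(entries) + 1L]] <-
      abifEntry("XTlk", 1L, ABIF_DOUBLE, 8L, length(md$crosstalk),
                rawDouble(as.vector(md$crosstalk)))

  # lay out data blocks after the 128-byte header; entries with <= 4 bytes
  # of data are stored inside the offset field per the ABIF convention
  offset <- 128L
  blocks <- raw()
  for (i in seq_along(entries)) {
    e <- entries[[i]]
    size <- length(e$data)
    if (size > 4L) {
      entries[[i]]$offset <- offset
      blocks <- c(blocks, e$data)
      offset <- offset + size
    } else {
      entries[[i]]$offset <- NA_integer_  # inline
    }
  }
  dirOffset <- offset
  dirBytes <- raw()
  for (e in entries) {
    size <- length(e$data)
    offField <- if (size > 4L) rawInt(e$offset, 4L)
                else c(e$data, raw(4L - size))
    dirBytes <- c(dirBytes, charToRaw(e$name), rawInt(e$number, 4L),
                  rawInt(e$type, 2L), rawInt(e$elementSize, 2L),
                  rawInt(e$nElem, 4L), rawInt(size, 4L), offField,
                  rawInt(0L, 4L))
  }
  header <- c(charToRaw("ABIF"), rawInt(101L, 2L),
              charToRaw("tdir"), rawInt(1L, 4L), rawInt(ABIF_DIR, 2L),
              rawInt(28L, 2L), rawInt(length(entries), 4L),
              rawInt(28L * length(entries), 4L), rawInt(dirOffset, 4L),
              rawInt(0L, 4L), raw(94L))
  stopifnot(length(header) == 128L)
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(header, blocks, dirBytes), con)
  invisible(path)
}

#' Read an ABIF (.fsa) file into an electropherogram
#'
#' Parses the big-endian ABIF container written by \code{\link{writeFsa}}
#' (and the common subset produced by CE instruments): \code{DATA} channel
#' entries, dye names, sample name, and the optional run-kind and crosstalk
#' tags.
#'
#' @param path Path to the \code{.fsa} file.
#' @return An \linkS4class{Electropherogram}.
#' @export
readFsa <- function(path) {
  raw <- readBin(path, "raw", n = file.info(path)$size)
  if (length(raw) < 128L || rawToChar(raw[1:4]) != "ABIF")
    stop("not an ABIF file (bad magic): ", path)
  nEntries <- readIntBE(raw, 18L, 4L)
  dirOffset <- readIntBE(raw, 26L, 4L)
  if (dirOffset + 28L * nEntries > length(raw))
    stop("truncated ABIF directory: ", path)
  entries <- lapply(seq_len(nEntries) - 1L, function(k) {
    o <- dirOffset + 28L * k
    name <- rawToChar(raw[(o + 1L):(o + 4L)])
    number <- readIntBE(raw, o + 4L, 4L)
    type <- readIntBE(raw, o + 8L, 2L)
    nElem <- readIntBE(raw, o + 12L, 4L)
    size <- readIntBE(raw, o + 16L, 4L)
    data <- if (size > 4L) {
      do <- readIntBE(raw, o + 20L, 4L)
      raw[(do + 1L):(do + size)]
    } else raw[(o + 21L):(o + 20L + size)]
    list(name = name, number = number, type = type, nElem = nElem,
         data = data)
  })
  getEntry <- function(name, number) {
    for (e in entries) if (e$name == name && e$number == number) return(e)
    NULL
  }
  asShorts <- function(e) readBin(e$data, "integer", n = e$nElem, size = 2L,
                                  endian = "big", signed = TRUE)
  asPString <- function(e) {
    n <- as.integer(e$data[1L])
    if (n == 0L) "" else rawToChar(e$data[2L:(1L + n)])
  }
  channels <- list()
  j <- 1L
  repeat {
    e <- getEntry("DATA", j)
    if (is.null(e)) break
    channels[[j]] <- asShorts(e)
    j <- j + 1L
  }
  if (!length(channels)) stop("no DATA entries in ABIF file: ", path)
  v <- do.call(cbind, channels)
  storage.mode(v) <- "double"
  nm <- vapply(seq_len(ncol(v)), function(k) {
    e <- getEntry("DyeN", k)
    if (is.null(e)) paste0("DYE", k) else asPString(e)
  }, character(1))
  colnames(v) <- nm
  smpl <- getEntry("SMPL", 1L)
  runk <- getEntry("RunK", 1L)
  xtlk <- getEntry("XTlk", 1L)
  meta <- list(sampleId = if (is.null(smpl)) "sample" else asPString(smpl),
               panelId = "panel",
               runKind = if (is.null(runk)) "sample" else asPString(runk))
  if (!is.null(xtlk)) {
    m <- readBin(xtlk$data, "double", n = xtlk$nElem, size = 8L,
                 endian = "big")
    n <- as.integer(sqrt(xtlk$nElem))
    meta$crosstalk <- matrix(m, n, n)
  }
  new("Electropherogram", values = v, metadata = meta)
}
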