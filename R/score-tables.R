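## Point tables are shipped as reviewable YAML data (inst/extdata/
## score_tables/), not hard-coded, so each table can be diffed against its
## source publication. This file loads them and provides the band lookup
## shared by all engines.

.tableCache <- new.env(parent = emptyenv())

#' Load a published score point table
#'
#' @param system One of `"CASUS"`, `"SOFA"`, `"SAPS2"`, `"APACHE2"`.
#' @param path Optional path to an alternative YAML table with the same
#'   structure (e.g. a corrected transcription); default is the packaged
#'   file.
#' @return The parsed table as a nested list. Results from the packaged
#'   files are cached per session.
#' @export
loadScoreTable <- function(system, path = NULL) {
  system <- match.arg(toupper(system), .SCORE_SYSTEMS)
  if (is.null(path)) {
    if (!is.null(.tableCache[[system]])) return(.tableCache[[system]])
    path <- system.file("extdata", "score_tables",
                        paste0(tolower(system), ".yaml"),
                        package = "icubench")
    tab <- yaml::read_yaml(path)
    .tableCache[[system]] <- tab
    return(tab)
  }
  yaml::read_yaml(path)
}

## Vectorized band lookup: bands are {lo, hi, points} with lo inclusive and
## hi exclusive; the bands partition the real line.
.bandPoints <- function(x, bands) {
  lo <- vapply(bands, function(b) as.numeric(b$lo), numeric(1))
  pts <- vapply(bands, function(b) as.numeric(b$points), numeric(1))
  o <- order(lo)
  pts[o][findInterval(x, lo[o])]
}

## "Most abnormal per score": score both daily extremes, keep the larger.
.bandPointsBidir <- function(xmin, xmax, bands) {
  pmax(.bandPoints(xmin, bands), .bandPoints(xmax, bands))
}
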