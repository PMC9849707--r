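#' Construct a TemporalGrouping
#'
#' @param label character vector of period labels.
#' @param start,end integer vectors of inclusive year bounds; periods must be
#'   chronologically ordered and non-overlapping. Gaps between periods are
#'   allowed (years falling in a gap belong to no period).
#' @return a \linkS4class{TemporalGrouping}.
#' @export
TemporalGrouping <- function(label, start, end) {
  new("TemporalGrouping", label = as.character(label),
      start = as.integer(start), end = as.integer(end))
}

#' The five-period Saimaa temporal grouping
#'
#' Pre-bottleneck (1894-1939), bottleneck (1960-1979 and 1980-1989), recovery
#' (1990-1999) and increase (2000-2011). Note the deliberate gap 1940-1959:
#' years in it are assigned to no period.
#'
#' @return a \linkS4class{TemporalGrouping} with periods TG1..TG5.
#' @export
saimaaGrouping <- function() {
  TemporalGrouping(paste0("TG", 1:5),
                   start = c(1894L, 1960L, 1980L, 1990L, 2000L),
                   end   = c(1939L, 1979L, 1989L, 1999L, 2011L))
}

#' Assign a collection year to a temporal period
#'
#' @param year integer vector of calendar years.
#' @param grouping a \linkS4class{TemporalGrouping}.
#' @return character vector of period labels, \code{NA} for years covered by
#'   no period (a legal outcome: the grouping may have gaps).
#' @export
assignPeriod <- function(year, grouping) {
  stopifnot(is(grouping, "TemporalGrouping"))
  year <- as.integer(year)
  vapply(year, function(y) {
    if (is.na(y)) return(NA_character_)
    hit <- which(grouping@start <= y & y <= grouping@end)
    if (length(hit)) grouping@label[hit] else NA_character_
  }, character(1L))
}

#' Midpoint year of each period
#'
#' @param grouping a \linkS4class{TemporalGrouping}.
#' @return named numeric vector of period midpoints.
#' @export
periodMidpoints <- function(grouping) {
  stats::setNames((grouping@start + grouping@end) / 2, grouping@label)
}
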