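#' Socio-economic indicator registry
#'
#' The five indicators scored for every land use, with the direction in which
#' each is desirable. Net present value and food production are
#' "more is better"; discounted payback period, labour demand and investment
#' costs are "less is better".
#'
#' @return A data frame with columns \code{indicator}, \code{direction}
#'   (\code{"more"} or \code{"less"}) and \code{units}.
#' @export
#' @examples
#' lu_indicators()
lu_indicators <- function() {
  data.frame(
    indicator = c("npv", "payback", "food", "labour", "investment"),
    direction = c("more", "less", "more", "less", "less"),
    units     = c("$/ha", "years", "Mcal/ha/yr", "days/ha/yr", "$/ha"),
    stringsAsFactors = FALSE
  )
}

#' The seven land uses in canonical row order
#' @return Character vector of land-use names.
#' @export
lu_land_uses <- function() {
  c("rice", "maize", "pasture", "teak_plantation",
    "alley_cropping", "silvopasture", "forest")
}

# direction lookup for a (possibly extended) indicator set; extra indicators
# carry their direction as an attribute on the table
indicator_directions <- function(indicators) {
  reg <- lu_indicators()
  dirs <- reg$direction[match(indicators, reg$indicator)]
  names(dirs) <- indicators
  dirs
}

#' Construct an indicator coefficient table
#'
#' Container for the optimiser's sole input: per land use and indicator, the
#' predicted (mean) value and its standard deviation from the Monte-Carlo
#' simulations, plus the direction in which each indicator is desirable.
#'
#' @param mean,sd Numeric matrices, land uses in rows, indicators in columns.
#' @param directions Named character vector (\code{"more"}/\code{"less"}) per
#'   indicator; defaults to the registry in [lu_indicators()] for the five
#'   standard indicators.
#' @return An object of class \code{indicator_table}.
#' @export
indicator_table <- function(mean, sd, directions = NULL) {
  mean <- as.matrix(mean); sd <- as.matrix(sd)
  stopifnot(identical(dim(mean), dim(sd)))
  if (is.null(rownames(mean))) stop("land-use row names are required")
  if (is.null(colnames(mean))) stop("indicator column names are required")
  if (any(sd < 0)) stop("standard deviations must be non-negative")
  if (is.null(directions)) directions <- indicator_directions(colnames(mean))
  directions <- directions[colnames(mean)]
  if (anyNA(directions))
    stop("unknown indicator(s): ",
         paste(colnames(mean)[is.na(directions)], collapse = ", "))
  structure(
    list(mean = mean, sd = sd,
         land_uses = rownames(mean), indicators = colnames(mean),
         directions = directions),
    class = "indicator_table"
  )
}

#' @export
print.indicator_table <- function(x, digits = 1, ...) {
  cat("Indicator coefficient table:",
      length(x$land_uses), "land uses x",
      length(x$indicators), "indicators\n")
  txt <- matrix(paste0(format(round(x$mean, digits), trim = TRUE), " ± ",
                       format(round(x$sd, digits), trim = TRUE)),
                nrow = nrow(x$mean), dimnames = dimnames(x$mean))
  print(as.data.frame(txt), ...)
  invisible(x)
}

#' @export
as.data.frame.indicator_table <- function(x, ...) {
  out <- data.frame(land_use = x$land_uses, stringsAsFactors = FALSE)
  for (i in x$indicators) {
    out[[paste0(i, "_mean")]] <- x$mean[, i]
    out[[paste0(i, "_sd")]] <- x$sd[, i]
  }
  rownames(out) <- NULL
  out
}
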