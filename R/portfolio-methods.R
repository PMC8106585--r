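#' @export
print.lu_portfolio <- function(x, digits = 3, ...) {
  cat("Robust land-use portfolio (m =", x$config$m, ")\n")
  cat("Worst normalised distance beta:", round(x$beta, 2), "%\n")
  sh <- x$shares[x$shares > 5e-4]
  cat("Shares:\n")
  print(round(sh, digits))
  invisible(x)
}

#' @export
summary.lu_portfolio <- function(object, ...) {
  structure(list(portfolio = object), class = "summary.lu_portfolio")
}

#' @export
print.summary.lu_portfolio <- function(x, ...) {
  p <- x$portfolio
  print(p)
  cat("\nAchieved indicator levels (portfolio mean / guaranteed worst case):\n")
  print(round(p$achieved, 2))
  cfg <- p$config
  if (!is.null(cfg$labour_cap)) cat("Labour cap:", cfg$labour_cap, "days/ha/yr\n")
  if (!is.null(cfg$investment_cap)) cat("Investment cap:", cfg$investment_cap, "$/ha\n")
  if (any(cfg$weights != 1)) {
    cat("Indicator weights:\n"); print(cfg$weights)
  }
  invisible(x)
}

#' @export
coef.lu_portfolio <- function(object, ...) object$shares

#' @export
plot.lu_portfolio <- function(x, ...) {
  graphics::barplot(x$shares, las = 2, ylab = "area share",
                    main = paste0("Optimal portfolio (m = ", x$config$m, ")"),
                    ...)
  invisible(x)
}
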