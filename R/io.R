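#' Read a coefficient table from CSV
#'
#' Expects the interchange layout emitted by [write_coefficient_table()]:
#' one row per land use, a \code{land_use} column, and paired
#' \code{<indicator>_mean} / \code{<indicator>_sd} columns. Directions are
#' attached from the indicator registry; extra indicators (e.g. a preference
#' column) are treated as "more is better" unless registered.
#'
#' @param path CSV file path.
#' @return An [indicator_table].
#' @export
read_coefficient_table <- function(path) {
  df <- utils::read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (!"land_use" %in% names(df))
    stop("coefficient table must have a 'land_use' column")
  mcols <- grep("_mean$", names(df), value = TRUE)
  inds <- sub("_mean$", "", mcols)
  if (!length(inds)) stop("no '<indicator>_mean' columns found")
  for (i in inds)
    if (!paste0(i, "_sd") %in% names(df))
      stop("missing column '", i, "_sd'")
  mu <- as.matrix(df[, paste0(inds, "_mean")])
  sd <- as.matrix(df[, paste0(inds, "_sd")])
  if (anyNA(mu) || anyNA(sd))
    stop("missing cell(s) in coefficient table")
  bad <- which(sd < 0, arr.ind = TRUE)
  if (nrow(bad))
    stop("negative SD for land use '", df$land_use[bad[1, 1]],
         "', indicator '", inds[bad[1, 2]], "'")
  dimnames(mu) <- dimnames(sd) <- list(df$land_use, inds)
  reg <- lu_indicators()
  dirs <- stats::setNames(
    ifelse(inds %in% reg$indicator,
           reg$direction[match(inds, reg$indicator)], "more"), inds)
  indicator_table(mu, sd, directions = dirs)
}

#' Write a coefficient table to CSV
#'
#' @param table An [indicator_table].
#' @param path Output CSV path.
#' @export
write_coefficient_table <- function(table, path) {
  stopifnot(inherits(table, "indicator_table"))
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' Reference baseline coefficient table
#'
#' The packaged mean/SD coefficients (five indicators by seven land uses)
#' used for the baseline optimisation: NPV ($/ha), discounted payback
#' (years), food production (Mcal/ha/yr), labour demand (days/ha/yr) and
#' investment costs ($/ha), each as Monte-Carlo mean and standard deviation.
#'
#' @return An [indicator_table].
#' @export
#' @examples
#' baseline_coefficients()
baseline_coefficients <- function() {
  read_coefficient_table(system.file("extdata", "baseline_coefficients.csv",
                                     package = "agroportfolio",
                                     mustWork = TRUE))
}

#' Write a portfolio to TSV or JSON
#'
#' TSV: flat \code{land_use} / \code{share} rows (shares at 4 decimals).
#' JSON: shares, the optimised worst distance beta, achieved indicator
#' levels and the configuration.
#'
#' @param portfolio An \code{lu_portfolio}.
#' @param path Output path.
#' @param format \code{"tsv"} or \code{"json"}.
#' @export
write_portfolio <- function(portfolio, path, format = c("tsv", "json")) {
  stopifnot(inherits(portfolio, "lu_portfolio"))
  format <- match.arg(format)
  if (format == "tsv") {
    df <- data.frame(land_use = names(portfolio$shares),
                     share = sprintf("%.4f", portfolio$shares))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  } else {
    cfg <- portfolio$config
    cfg <- cfg[!vapply(cfg, is.null, logical(1))]
    jsonlite::write_json(
      list(shares = as.list(round(portfolio$shares, 4)),
           beta = portfolio$beta,
           achieved = as.data.frame(portfolio$achieved),
           config = cfg),
      path, auto_unbox = TRUE, digits = NA)
  }
  invisible(path)
}

md5_of <- function(paths) {
  unname(tools::md5sum(paths[file.exists(paths)]))
}

#' Run the full analysis pipeline from a config file
#'
#' Executes the configured stages — \code{simulate} (Monte-Carlo coefficient
#' table from the fixture), \code{optimize} (portfolios for each requested
#' uncertainty level) and optionally \code{sweep} — writing every output plus
#' a JSON run manifest into the output directory. All randomness flows from
#' the single configured seed, so identical configs give identical outputs.
#'
#' Config keys (YAML): \code{seed}, \code{n_reps}, \code{stages} (subset of
#' simulate/optimize/sweep), \code{m} (vector of uncertainty levels),
#' \code{coeffs} (optional CSV path, used when simulate is not staged;
#' default: the packaged baseline table), \code{fixture} (optional fixture
#' config path), \code{out_dir}, and for sweeps \code{sweep_parameter},
#' \code{sweep_grid}.
#'
#' @param config_path Path to the YAML config.
#' @return The run manifest (list), invisibly written as
#'   \code{manifest.json}.
#' @export
run_pipeline <- function(config_path) {
  cfg <- yaml::read_yaml(config_path)
  stages <- cfg$stages %||% c("simulate", "optimize")
  seed <- as.integer(cfg$seed %||% 1)
  n_reps <- cfg$n_reps %||% 10000
  mlevels <- as.numeric(cfg$m %||% c(0, 1.5, 3.0))
  out_dir <- cfg$out_dir %||% "."
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)

  t0 <- Sys.time()
  log_lines <- character()
  stage_log <- function(stage, msg) {
    log_lines <<- c(log_lines,
                    sprintf("[%s] %s: %s", format(Sys.time()), stage, msg))
  }
  outputs <- character()

  fixture <- if (!is.null(cfg$fixture)) read_fixture_config(cfg$fixture)
             else make_default_fixture(seed)

  tab <- NULL
  if ("simulate" %in% stages) {
    t <- system.time(
      tab <- simulate_indicators(fixture, n_reps = n_reps, seed = seed))
    coeff_path <- file.path(out_dir, "coefficients.csv")
    write_coefficient_table(tab, coeff_path)
    outputs <- c(outputs, coeff_path)
    stage_log("simulate", sprintf("%d reps in %.1fs", n_reps, t[["elapsed"]]))
  } else if (!is.null(cfg$coeffs)) {
    tab <- read_coefficient_table(cfg$coeffs)
    stage_log("load", paste("coefficients from", cfg$coeffs))
  } else {
    tab <- baseline_coefficients()
    stage_log("load", "packaged baseline coefficients")
  }

  if ("optimize" %in% stages) {
    for (m in mlevels) {
      t <- system.time(pf <- optimize_portfolio(tab, m = m))
      nconstr <- length(tab$indicators) * 2^length(tab$land_uses)
      stage_log("optimize",
                sprintf("m=%.1f: %d scenario constraints, beta=%.2f, %.2fs",
                        m, nconstr, pf$beta, t[["elapsed"]]))
      for (fmt in c("tsv", "json")) {
        p <- file.path(out_dir, sprintf("portfolio_m%s.%s", m, fmt))
        write_portfolio(pf, p, fmt)
        outputs <- c(outputs, p)
      }
    }
  }

  if ("sweep" %in% stages) {
    sp <- sweep_spec(parameter = cfg$sweep_parameter %||%
                       "agroforestry_investment",
                     grid = as.numeric(cfg$sweep_grid %||% seq(-1, 0, 0.1)),
                     m = utils::tail(mlevels, 1), n_reps = n_reps,
                     seed = seed)
    t <- system.time(sw <- sweep_parameter(fixture, sp))
    p <- file.path(out_dir, "sweep.tsv")
    utils::write.table(as.data.frame(sw)[, c("step", "alley_cropping_share",
                                             "silvopasture_share",
                                             "agroforestry", "beta")],
                       p, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs <- c(outputs, p)
    stage_log("sweep", sprintf("%s, %d steps, %.1fs", sp$parameter,
                               length(sp$grid), t[["elapsed"]]))
  }

  manifest <- list(
    command = "run_pipeline",
    package_version = as.character(utils::packageVersion("agroportfolio")),
    timestamp = format(t0, usetz = TRUE),
    seed = seed, n_reps = n_reps, m = mlevels, stages = stages,
    config_digest = md5_of(config_path),
    input_digests = if (!is.null(cfg$coeffs)) md5_of(cfg$coeffs) else NULL,
    outputs = stats::setNames(as.list(md5_of(outputs)), basename(outputs)),
    log = log_lines)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
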