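# Curve I/O (CSV) and the session driver tying the modalities together.

.curve_headers <- list(trast = c("width_s", "value"),
                       fcs = c("lag_s", "g"),
                       flow = c("t_s", "f_norm"))

#' Read a measurement curve from CSV
#'
#' Expected headers: `width_s,value[,sd]` (trast), `lag_s,g[,sd]` (fcs),
#' `t_s,f_norm` (flow). Decimal parsing is locale-independent (a point is
#' the only accepted decimal separator); a malformed header or a
#' non-monotone x grid raises an error naming the offending line.
#'
#' @param path CSV path.
#' @param kind One of `"trast"`, `"fcs"`, `"flow"`.
#' @return A `"trast_curve"`, `"fcs_curve"` or `"flow_profile"`.
#' @export
read_curve <- function(path, kind = c("trast", "fcs", "flow")) {
  kind <- match.arg(kind)
  want <- .curve_headers[[kind]]
  df <- utils::read.csv(path, colClasses = "character", comment.char = "#",
                        check.names = FALSE, strip.white = TRUE)
  if (!all(want %in% names(df)))
    stop(sprintf("line 1 of '%s': expected header containing %s, found %s",
                 path, paste(want, collapse = ","),
                 paste(names(df), collapse = ",")))
  num <- lapply(df, function(col) suppressWarnings(as.numeric(col)))
  for (nm in names(num)) {
    bad <- which(is.na(num[[nm]]) & !(df[[nm]] %in% c("", "NA")))
    if (length(bad) > 0)
      stop(sprintf("line %d of '%s': cannot parse '%s' as a number (use '.' as decimal separator)",
                   bad[1] + 1L, path, df[[nm]][bad[1]]))
  }
  x <- num[[want[1]]]
  mono_bad <- which(diff(x) <= 0)
  if (length(mono_bad) > 0)
    stop(sprintf("line %d of '%s': %s grid is not strictly increasing",
                 mono_bad[1] + 2L, path, want[1]))
  switch(kind,
         trast = {
           w0 <- attr_from_comment(path, "w0", default = min(x))
           new_trast_curve(x, num$value, sd = num$sd, w0 = w0)
         },
         fcs = new_fcs_curve(x, num$g, sd = num$sd),
         flow = new_flow_profile(x, num$f_norm))
}

# optional "# key: value" comment on the first line(s) of a curve file
attr_from_comment <- function(path, key, default) {
  ln <- readLines(path, n = 5)
  hit <- grep(sprintf("^#\\s*%s\\s*:", key), ln, value = TRUE)
  if (length(hit) == 0) return(default)
  as.numeric(sub(sprintf("^#\\s*%s\\s*:\\s*", key), "", hit[1]))
}

#' Write a measurement curve to CSV
#'
#' Full double precision; the inverse of [read_curve()].
#'
#' @param curve A curve object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_curve <- function(curve, path) {
  df <- as.data.frame(curve)
  con <- file(path, "w")
  on.exit(close(con))
  if (inherits(curve, "trast_curve"))
    writeLines(sprintf("# w0: %.17g", attr(curve, "w0")), con)
  cols <- names(df)
  writeLines(paste(cols, collapse = ","), con)
  body <- do.call(paste, c(lapply(df, function(x) sprintf("%.17g", x)),
                           sep = ","))
  writeLines(body, con)
  invisible(path)
}

#' Run an analysis session from a config
#'
#' Drives one fitting workflow from a configuration (a YAML/JSON file or
#' an equivalent named list): reads the input curves, runs the fit for
#' the requested modality, and writes a JSON report with estimates,
#' standard errors, residual summaries, the package version, a config
#' echo and the seed.
#'
#' Config fields: `modality` (`"trast"`, `"trast_mixture"`, `"fcs"`,
#' `"flow"`); `inputs` (paths); `output` (report path); `seed`; plus
#' modality-specific blocks (`model` preset name or file,
#' `irradiance_kw_cm2` per curve, `scheme`, `sigma`, `A`, `tau`,
#' `R_nominal`, `Q_start`, field/flow geometry).
#'
#' @param config Path to a YAML/JSON config, or a named list.
#' @return The report, invisibly (a list); also written to
#'   `config$output` if set.
#' @export
run_session <- function(config) {
  if (is.character(config)) {
    config <- if (grepl("\\.json$", config))
      jsonlite::read_json(config, simplifyVector = TRUE)
    else yaml::read_yaml(config)
  }
  if (is.null(config$modality))
    stop("config error: 'modality' is required")
  if (is.null(config$inputs) || length(config$inputs) == 0)
    stop("config error: 'inputs' must list at least one curve file")
  missing <- config$inputs[!file.exists(unlist(config$inputs))]
  if (length(missing) > 0)
    stop(sprintf("config error: input file not found: %s", missing[1]))
  if (!is.null(config$seed)) set.seed(as.integer(config$seed))

  fit <- switch(
    config$modality,
    trast = {
      cv <- read_curve(config$inputs[[1]], "trast")
      fit_trast(cv)
    },
    trast_mixture = {
      curves <- lapply(config$inputs, read_curve, kind = "trast")
      fit_trast_mixture(curves,
                        monoexp_params(config$A, config$tau),
                        R_nominal = config$R_nominal,
                        R_tol = config$R_tol %||% 0.03,
                        Q_start = config$Q_start %||% 2)
    },
    fcs = {
      curves <- lapply(config$inputs, read_curve, kind = "fcs")
      excs <- lapply(config$irradiance_kw_cm2, function(p)
        excitation(p * 1e3, config$wavelength %||% 640))
      global_fit_fcs(curves, excs, scheme = config$scheme,
                     sigma = config$sigma,
                     k10 = config$k10 %||% 1e9)
    },
    flow = {
      profiles <- lapply(config$inputs, read_curve, kind = "flow")
      field <- curtain_field(peak_irradiance = config$peak_irradiance %||% 1.3e3)
      flows <- lapply(config$flow_ul_min, flow_config)
      model <- fluorophore(config$model)
      fit_flow(profiles, field, flows, model,
               Q_ratio = config$Q_ratio)
    },
    stop(sprintf("config error: unknown modality '%s'", config$modality)))

  report <- list(
    package = "trastkit",
    version = as.character(utils::packageVersion("trastkit")),
    modality = config$modality,
    seed = config$seed %||% NA,
    config = config,
    converged = fit$converged,
    estimates = as.list(fit$coefficients),
    std_errors = as.list(fit$se),
    residual_rss = sum(fit$residuals^2),
    n_points = length(fit$residuals))
  if (!is.null(config$output))
    jsonlite::write_json(report, config$output, auto_unbox = TRUE,
                         digits = NA, pretty = TRUE)
  invisible(report)
}
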