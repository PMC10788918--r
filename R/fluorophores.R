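# Shipped fluorophore presets and JSON (de)serialization.

#' Load a fluorophore model preset or file
#'
#' Presets shipped with the package (JSON records under
#' `extdata/fluorophores/`):
#' \describe{
#'   \item{`"Cy5_free"`}{free Cy5 in aqueous solution; isomerization scheme
#'     with `sigma_N = 6.2e-16` cm^2, `k_iso = 29` us^-1,
#'     `sigma_biso = 0.15e-16` cm^2, thermal back-isomerization
#'     `0.0016` us^-1 and the high-irradiance triplet branch
#'     (`k_isc = 1.1` us^-1, `k_T = 0.5` us^-1).}
#'   \item{`"Cy5_SUV"`}{Cy5 conjugated to a small unilamellar vesicle;
#'     slower isomerization (`k_iso = 6.2` us^-1,
#'     `sigma_biso = 0.042e-16` cm^2).}
#'   \item{`"CF640R"`}{rhodamine-based CF640R; triplet scheme with
#'     `sigma_S = 4e-16` cm^2, `k_isc = 0.7` us^-1, `k_T = 0.5` us^-1.}
#' }
#'
#' @param name Preset name or path to a JSON model file.
#' @return A [iso_model()] or [triplet_model()] object.
#' @examples
#' fluorophore("Cy5_free")
#' @export
fluorophore <- function(name) {
  path <- if (file.exists(name)) name else
    system.file("extdata", "fluorophores", paste0(name, ".json"),
                package = "trastkit")
  if (!nzchar(path) || !file.exists(path))
    stop(sprintf("unknown fluorophore preset or file: '%s'", name))
  read_fluorophore(path)
}

#' Read a fluorophore model from JSON
#'
#' @param path Path to a JSON record
#'   `{name, scheme: "isomerization"|"triplet", parameters: {...}}`.
#' @return A fluorophore model object.
#' @export
read_fluorophore <- function(path) {
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (is.null(rec$scheme)) stop("fluorophore record lacks a 'scheme' field")
  p <- as.list(rec$parameters)
  if (rec$scheme == "isomerization") {
    iso_model(sigma_N = p$sigma_N, k_iso = p$k_iso, sigma_biso = p$sigma_biso,
              k10 = p$k10 %||% 1e9, k_biso_th = p$k_biso_th %||% 0,
              k_isc = p$k_isc %||% 0, k_T = p$k_T %||% 0,
              name = rec$name %||% "isomerization")
  } else if (rec$scheme == "triplet") {
    triplet_model(sigma_S = p$sigma_S, k_isc = p$k_isc, k_T = p$k_T,
                  k10 = p$k10 %||% 1e9, name = rec$name %||% "triplet")
  } else stop(sprintf("unknown scheme '%s'", rec$scheme))
}

#' Write a fluorophore model to JSON
#'
#' @param model A fluorophore model object.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fluorophore <- function(model, path) {
  stopifnot(inherits(model, "fluorophore_model"))
  pars <- model[setdiff(names(model), c("name", "scheme"))]
  rec <- list(name = model$name, scheme = model$scheme, parameters = pars)
  jsonlite::write_json(rec, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
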