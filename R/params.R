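#' Host parameter set
#'
#' Physiological parameters of the coral host. Defaults are the published
#' reference parameterization of the holobiont model.
#'
#' @param n_NH N:C molar ratio of host biomass.
#' @param n_NX N:C molar ratio of prey biomass.
#' @param j_HT0 Host biomass maintenance (turnover) rate, d^-1.
#' @param sigma_NH Proportion of host turnover nitrogen recycled.
#' @param sigma_CH Proportion of host metabolic CO2 recycled to photosynthesis.
#' @param j_Xm Maximum prey assimilation rate, C-mol X C-mol H^-1 d^-1.
#' @param K_X Half-saturation constant for prey assimilation, C-mol L^-1.
#' @param j_Nm Maximum dissolved-inorganic-nitrogen uptake rate,
#'   mol N C-mol H^-1 d^-1.
#' @param K_N Half-saturation constant for DIN uptake, mol N L^-1.
#' @param k_CO2 Efficacy of CO2 delivery by the host carbon-concentrating
#'   mechanism, mol CO2 per mol fixed C spent.
#' @param j_HGm Maximum specific host growth rate, d^-1.
#' @param y_C Yield of biomass formation from carbon (shared by host and
#'   symbiont growth), C-mol per mol C.
#' @return An object of class `host_params` (named list).
#' @export
host_params <- function(n_NH = 0.18, n_NX = 0.2, j_HT0 = 0.03,
                        sigma_NH = 0.9, sigma_CH = 0.1,
                        j_Xm = 0.13, K_X = 1e-6,
                        j_Nm = 0.035, K_N = 1.5e-6,
                        k_CO2 = 10, j_HGm = 1, y_C = 0.8) {
  p <- list(n_NH = n_NH, n_NX = n_NX, j_HT0 = j_HT0, sigma_NH = sigma_NH,
            sigma_CH = sigma_CH, j_Xm = j_Xm, K_X = K_X, j_Nm = j_Nm,
            K_N = K_N, k_CO2 = k_CO2, j_HGm = j_HGm, y_C = y_C)
  p <- lapply(p, as.numeric)
  vals <- unlist(p)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all host parameters must be finite and strictly positive",
         call. = FALSE)
  if (sigma_NH > 1 || sigma_CH > 1)
    stop("`sigma_NH` and `sigma_CH` must lie in [0, 1]", call. = FALSE)
  if (y_C > 1) stop("`y_C` must lie in (0, 1]", call. = FALSE)
  structure(p, class = "host_params")
}

#' Symbiont parameter set
#'
#' Physiological parameters of one algal symbiont population. The two bundled
#' presets differ in stress physiology: the `"sensitive"` symbiont
#' photosynthesizes and grows fast but is damaged by little unquenched light
#' (`k_ROS = 80`); the `"tolerant"` symbiont trades photosynthetic capacity
#' (`j_CPm = 1.0` vs 2.8) and growth (`j_SGm = 0.15` vs 0.25) for resistance
#' to reactive oxygen species (`k_ROS = 250`).
#'
#' @param label Preset name (`"sensitive"` or `"tolerant"`) or any custom
#'   label; presets fill `k_ROS`, `j_CPm` and `j_SGm` unless overridden.
#' @param n_NS N:C molar ratio of symbiont biomass.
#' @param j_ST0 Baseline symbiont biomass turnover rate, d^-1.
#' @param sigma_NS Proportion of baseline turnover nitrogen recycled.
#' @param sigma_CS Proportion of symbiont metabolic CO2 recycled.
#' @param y_CL Quantum yield of photosynthesis, mol C per mol photons.
#' @param a_star Effective light-absorbing cross-section, m^2 C-mol^-1.
#' @param k_NPQ Capacity of nonphotochemical quenching,
#'   mol photons C-mol^-1 d^-1.
#' @param k_ROS Unquenched photon flux that doubles baseline ROS production,
#'   mol photons C-mol^-1 d^-1.
#' @param j_CPm Maximum specific photosynthesis rate, mol C C-mol^-1 d^-1.
#' @param j_SGm Maximum specific growth rate, d^-1.
#' @param b Scaling of the bleaching (turnover) response to ROS.
#' @return An object of class `symbiont_params` (named list).
#' @export
symbiont_params <- function(label = "sensitive",
                            n_NS = 0.13, j_ST0 = 0.03,
                            sigma_NS = 0.9, sigma_CS = 0.9,
                            y_CL = 0.1, a_star = 1.34, k_NPQ = 112,
                            k_ROS = NULL, j_CPm = NULL, j_SGm = NULL,
                            b = 5) {
  preset <- switch(label,
    sensitive = list(k_ROS = 80,  j_CPm = 2.8, j_SGm = 0.25),
    tolerant  = list(k_ROS = 250, j_CPm = 1.0, j_SGm = 0.15),
    list(k_ROS = NULL, j_CPm = NULL, j_SGm = NULL)
  )
  k_ROS <- k_ROS %||% preset$k_ROS
  j_CPm <- j_CPm %||% preset$j_CPm
  j_SGm <- j_SGm %||% preset$j_SGm
  if (is.null(k_ROS) || is.null(j_CPm) || is.null(j_SGm))
    stop("`k_ROS`, `j_CPm` and `j_SGm` must be given for non-preset labels",
         call. = FALSE)
  p <- list(label = label, n_NS = n_NS, j_ST0 = j_ST0, sigma_NS = sigma_NS,
            sigma_CS = sigma_CS, y_CL = y_CL, a_star = a_star, k_NPQ = k_NPQ,
            k_ROS = k_ROS, j_CPm = j_CPm, j_SGm = j_SGm, b = b)
  p[-1] <- lapply(p[-1], as.numeric)
  vals <- unlist(p[-1])
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all symbiont parameters must be finite and strictly positive",
         call. = FALSE)
  if (sigma_NS > 1 || sigma_CS > 1)
    stop("`sigma_NS` and `sigma_CS` must lie in [0, 1]", call. = FALSE)
  structure(p, class = "symbiont_params")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Holobiont parameter set
#'
#' Bundles one host and one or more symbiont parameter sets.
#'
#' @param host A [host_params()] object.
#' @param symbionts A list of [symbiont_params()] objects (or preset label
#'   strings). Labels must be unique.
#' @return An object of class `holo_params`.
#' @export
holo_params <- function(host = host_params(),
                        symbionts = list("sensitive", "tolerant")) {
  stopifnot(inherits(host, "host_params"))
  symbionts <- lapply(symbionts, function(s) {
    if (is.character(s)) symbiont_params(s) else s
  })
  ok <- vapply(symbionts, inherits, logical(1), "symbiont_params")
  if (!all(ok)) stop("`symbionts` must be symbiont_params objects",
                     call. = FALSE)
  labels <- vapply(symbionts, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("symbiont labels must be unique",
                                  call. = FALSE)
  names(symbionts) <- labels
  structure(list(host = host, symbionts = symbionts), class = "holo_params")
}

#' @rdname holo_params
#' @export
default_params <- function() holo_params()

n_symbionts <- function(params) length(params$symbionts)

symbiont_labels <- function(params) names(params$symbionts)

#' Environmental conditions
#'
#' The three external drivers of the holobiont model.
#'
#' @param light Downwelling irradiance, mol photons m^-2 d^-1. The
#'   parameterization is considered valid for light within `light_range`.
#' @param din Dissolved inorganic nitrogen concentration, mol L^-1.
#' @param prey Prey carbon concentration, C-mol L^-1.
#' @param light_range Validity range for `light` (default 0--100).
#' @return An object of class `env_conditions`.
#' @export
env_conditions <- function(light, din, prey, light_range = c(0, 100)) {
  vals <- c(light = light, din = din, prey = prey)
  if (any(!is.finite(vals)) || any(vals < 0))
    stop("environmental variables must be finite and nonnegative",
         call. = FALSE)
  if (light < light_range[1] || light > light_range[2])
    stop(sprintf("`light` = %g outside the validity range [%g, %g]",
                 light, light_range[1], light_range[2]), call. = FALSE)
  structure(list(light = light, din = din, prey = prey),
            class = "env_conditions")
}

as_env_conditions <- function(x) {
  if (inherits(x, "env_conditions")) return(x)
  env_conditions(light = x[["light"]], din = x[["din"]], prey = x[["prey"]])
}

#' Read and write parameter sets as JSON
#'
#' Parameter sets serialize to flat key-value JSON documents. The bundled
#' files `host_default.json`, `symbiont_sensitive.json` and
#' `symbiont_tolerant.json` under `extdata/` carry the reference defaults.
#'
#' @param params A `host_params` or `symbiont_params` object.
#' @param path File path.
#' @return `read_params()` returns the reconstructed parameter object, using
#'   the `"type"` field of the document to pick the class.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, c("host_params", "symbiont_params")))
  doc <- unclass(params)
  doc <- c(list(type = if (inherits(params, "host_params")) "host"
                       else "symbiont"), doc)
  jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  type <- doc$type %||% stop("parameter document lacks a `type` field",
                             call. = FALSE)
  doc$type <- NULL
  switch(type,
    host = do.call(host_params, doc),
    symbiont = do.call(symbiont_params, doc),
    stop(sprintf("unknown parameter document type '%s'", type), call. = FALSE)
  )
}
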