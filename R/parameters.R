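.PARAM_KEYS <- c("k1", "k_m1", "k2", "k_m2", "k3", "k_m3", "k4", "k_m4",
  "kC", "alpha")

#' Construct a kinetic parameter set
#'
#' Defaults are the packaged reference parameter set for the RyR2 model
#' (also shipped as \code{system.file("extdata", "default_params.yaml",
#' package = "RyRgate")}): tight, slowly reversible binding of both
#' FK-binding proteins, a strongly activating conformational step for the
#' FKBP12-bound channel (efficacy ratio k2/k_m2 = 1/6) and a nearly silent
#' one for the FKBP12.6-bound channel (k4/k_m4 = 0.004), fast millisecond
#' gating (kC = 480 s^-1), and spontaneous background activity alpha = 0.005.
#'
#' @param k1,k_m1 FKBP12 association (uM^-1 s^-1) / dissociation (s^-1).
#' @param k2,k_m2 FKBP12-bound conformational forward/backward rates (s^-1).
#' @param k3,k_m3 FKBP12.6 association (uM^-1 s^-1) / dissociation (s^-1).
#' @param k4,k_m4 FKBP12.6-bound conformational forward/backward rates (s^-1).
#' @param kC channel closing rate (s^-1).
#' @param alpha spontaneous background open probability, in (0, 1).
#' @return A \linkS4class{KineticParameters} object.
#' @examples
#' defaultParameters()
#' updateParameters(defaultParameters(), k4 = 0)  # pure-antagonist limit
#' @export
KineticParameters <- function(k1 = 0.29e2, k_m1 = 6.11e-6, k2 = 0.03,
    k_m2 = 0.18, k3 = 0.33e6, k_m3 = 4.2e-4, k4 = 0.001, k_m4 = 0.25,
    kC = 480, alpha = 0.005) {
  new("KineticParameters", k1 = k1, k_m1 = k_m1, k2 = k2, k_m2 = k_m2,
    k3 = k3, k_m3 = k_m3, k4 = k4, k_m4 = k_m4, kC = kC, alpha = alpha)
}

#' @rdname KineticParameters
#' @export
defaultParameters <- function() KineticParameters()

#' Modify selected rate constants
#'
#' @param params a \linkS4class{KineticParameters} object.
#' @param ... named replacements among
#'   \code{k1, k_m1, k2, k_m2, k3, k_m3, k4, k_m4, kC, alpha}.
#' @return The modified, re-validated parameter object.
#' @export
updateParameters <- function(params, ...) {
  repl <- list(...)
  bad <- setdiff(names(repl), .PARAM_KEYS)
  if (length(bad))
    stop("unknown parameter(s): ", paste(bad, collapse = ", "))
  for (nm in names(repl)) slot(params, nm) <- as.numeric(repl[[nm]])
  validObject(params)
  params
}

#' Coerce a parameter object to a named list / vector
#' @param params a \linkS4class{KineticParameters} object.
#' @return named numeric vector in canonical key order.
#' @export
parameterVector <- function(params) {
  setNames(vapply(.PARAM_KEYS, function(k) slot(params, k), numeric(1)),
    .PARAM_KEYS)
}

#' Read / write kinetic parameters as flat key-value config
#'
#' YAML (.yaml/.yml) or JSON (.json), keys \code{k1 ... k_m4, kC, alpha}.
#' Unknown keys are rejected; missing keys fall back to packaged defaults
#' only when \code{partial = TRUE}.
#'
#' @param path file path.
#' @param partial allow a subset of keys (defaults fill the rest).
#' @return A \linkS4class{KineticParameters} object.
#' @export
readKineticParameters <- function(path, partial = FALSE) {
  if (!file.exists(path)) stop("parameter file not found: ", path)
  vals <- .read_config(path)
  bad <- setdiff(names(vals), .PARAM_KEYS)
  if (length(bad))
    stop("unknown parameter key(s) in ", path, ": ",
      paste(bad, collapse = ", "))
  if (!partial && length(miss <- setdiff(.PARAM_KEYS, names(vals))))
    stop("missing parameter key(s) in ", path, ": ",
      paste(miss, collapse = ", "))
  do.call(KineticParameters, lapply(vals, as.numeric))
}

#' @rdname readKineticParameters
#' @param params a \linkS4class{KineticParameters} object to write.
#' @export
writeKineticParameters <- function(params, path) {
  vals <- as.list(parameterVector(params))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else {
    yaml::write_yaml(vals, path)
  }
  invisible(path)
}

.read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}

#' Ligand concentrations (micromolar)
#'
#' @param fkbp12,fkbp12_6 concentrations in uM; use \code{asMicromolar} to
#'   convert from pM/nM.
#' @return A \linkS4class{LigandConcentrations} object.
#' @examples
#' LigandConcentrations(asMicromolar(1, "pM"), 0)
#' @export
LigandConcentrations <- function(fkbp12 = 0, fkbp12_6 = 0) {
  new("LigandConcentrations", fkbp12 = as.numeric(fkbp12),
    fkbp12_6 = as.numeric(fkbp12_6))
}

#' Convert a concentration to micromolar
#'
#' @param x numeric concentration value(s).
#' @param unit one of "uM", "nM", "pM", "mM", "M".
#' @return concentration in uM.
#' @export
asMicromolar <- function(x, unit = c("uM", "nM", "pM", "mM", "M")) {
  unit <- match.arg(unit)
  x * switch(unit, uM = 1, nM = 1e-3, pM = 1e-6, mM = 1e3, M = 1e6)
}

setMethod("show", "KineticParameters", function(object) {
  v <- parameterVector(object)
  cat("KineticParameters (RyR2 / FKBP model)\n")
  cat(sprintf("  binding   : k1 = %g uM^-1 s^-1, k-1 = %g s^-1 (FKBP12)\n",
    v["k1"], v["k_m1"]))
  cat(sprintf("              k3 = %g uM^-1 s^-1, k-3 = %g s^-1 (FKBP12.6)\n",
    v["k3"], v["k_m3"]))
  cat(sprintf("  conform.  : k2 = %g, k-2 = %g | k4 = %g, k-4 = %g s^-1\n",
    v["k2"], v["k_m2"], v["k4"], v["k_m4"]))
  cat(sprintf("  gating    : kC = %g s^-1, alpha = %g\n",
    v["kC"], v["alpha"]))
})

setMethod("show", "LigandConcentrations", function(object) {
  cat(sprintf("LigandConcentrations: [FKBP12] = %g uM, [FKBP12.6] = %g uM\n",
    object@fkbp12, object@fkbp12_6))
})

setMethod("show", "OccupancyDistribution", function(object) {
  cat("OccupancyDistribution over", paste(.OCC_LEVELS, collapse = ", "), "\n")
  print(signif(object@probs, 6))
  cat(sprintf("  nu (open-driving fraction) = %g\n", object@nu))
})

setMethod("show", "GatingRates", function(object) {
  cat(sprintf("GatingRates: kO = %g s^-1, kC = %g s^-1, Po(eq) = %g\n",
    object@kO, object@kC, object@poEq))
})
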