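#' Circuit parameterization for the two-gene inhibition cascade
#'
#' Constructs the full parameter set of the cascade in which gene 1 (GFP)
#' transcriptionally inhibits gene 2 (RFP). Defaults reproduce the standard
#' parameter set used throughout the analyses; any subset may be overridden.
#'
#' Units follow the deterministic model: concentrations are in arbitrary
#' concentration units (a.c.u.), time in mRNA lifetimes (all degradation rates
#' default to 1/time). `Omega` converts concentrations to molecule counts
#' (`count = concentration * Omega`) and only enters the stochastic model.
#'
#' @param km01,km02 Basal transcription rates (conc/time).
#' @param km1,km2 Induced transcription rate constants (conc/time per unit
#'   regulatory activity).
#' @param kp1,kp2 Translation rate constants (1/time).
#' @param dm1,dm2 mRNA degradation rate constants (1/time).
#' @param dp1,dp2 Protein degradation rate constants (1/time).
#' @param I1,I2 Inducer doses (dimensionless regulatory activities).
#' @param Jm1,Jm2 Transcriptional resource capacities (activity units); the
#'   effective RNA-polymerase pool available to each gene.
#' @param Jp1,Jp2 Translational resource capacities (conc units); the
#'   effective ribosome pool. Small `Jp2` means RFP competes strongly for
#'   ribosomes (its "resource competitivity" is `1/Jp2`).
#' @param n Hill coefficient of the GFP-mediated inhibition (dimensionless,
#'   `>= 1`).
#' @param Kg Dissociation constant of the GFP-mediated inhibition (conc).
#' @param Omega System size for concentration/count conversion.
#'
#' @return An object of class `circuit_params`: a named list of the 19
#'   parameters, validated.
#' @examples
#' p <- circuit_params()
#' p$Kg
#' circuit_params(I1 = 0.5)$I1
#' @export
circuit_params <- function(km01 = 0.4, km1 = 8, kp1 = 15, dm1 = 1, dp1 = 1,
                           I1 = 1, Jm1 = 40, Jp1 = 20,
                           km02 = 1, km2 = 25, kp2 = 30, dm2 = 1, dp2 = 1,
                           I2 = 1, Jm2 = 40, Jp2 = 2,
                           n = 3, Kg = 17, Omega = 1.5) {
  p <- list(km01 = km01, km1 = km1, kp1 = kp1, dm1 = dm1, dp1 = dp1,
            I1 = I1, Jm1 = Jm1, Jp1 = Jp1,
            km02 = km02, km2 = km2, kp2 = kp2, dm2 = dm2, dp2 = dp2,
            I2 = I2, Jm2 = Jm2, Jp2 = Jp2,
            n = n, Kg = Kg, Omega = Omega)
  p <- lapply(p, function(v) if (is.integer(v)) as.numeric(v) else v)
  validate_params(p)
  structure(p, class = "circuit_params")
}

#' @rdname circuit_params
#' @param x Object to test or print.
#' @export
is.circuit_params <- function(x) inherits(x, "circuit_params")

PARAM_NAMES <- c("km01", "km1", "kp1", "dm1", "dp1", "I1", "Jm1", "Jp1",
                 "km02", "km2", "kp2", "dm2", "dp2", "I2", "Jm2", "Jp2",
                 "n", "Kg", "Omega")

# Fields that must be strictly positive; inducer doses may be zero.
STRICT_POSITIVE <- c("km1", "kp1", "dm1", "dp1", "Jm1", "Jp1",
                     "km2", "kp2", "dm2", "dp2", "Jm2", "Jp2",
                     "Kg", "Omega")

validate_params <- function(p) {
  miss <- setdiff(PARAM_NAMES, names(p))
  if (length(miss))
    stop("missing circuit parameters: ", paste(miss, collapse = ", "))
  extra <- setdiff(names(p), PARAM_NAMES)
  if (length(extra))
    stop("unknown circuit parameters: ", paste(extra, collapse = ", "))
  for (nm in PARAM_NAMES) {
    v <- p[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) && !(nm %in% c("Jm1", "Jm2", "Jp1", "Jp2")))
      stop("parameter '", nm, "' must be a finite numeric scalar")
    if (is.na(v)) stop("parameter '", nm, "' is NA")
  }
  for (nm in STRICT_POSITIVE)
    if (p[[nm]] <= 0) stop("parameter '", nm, "' must be strictly positive")
  for (nm in c("km01", "km02", "I1", "I2"))
    if (p[[nm]] < 0) stop("parameter '", nm, "' must be non-negative")
  if (p$n < 1) stop("Hill coefficient 'n' must be >= 1")
  invisible(p)
}

#' @export
print.circuit_params <- function(x, ...) {
  cat("<circuit_params> two-gene inhibition cascade\n")
  cat("  gene 1 (GFP): km01=", x$km01, " km1=", x$km1, " kp1=", x$kp1,
      " dm1=", x$dm1, " dp1=", x$dp1, " I1=", x$I1, "\n", sep = "")
  cat("  gene 2 (RFP): km02=", x$km02, " km2=", x$km2, " kp2=", x$kp2,
      " dm2=", x$dm2, " dp2=", x$dp2, " I2=", x$I2, "\n", sep = "")
  cat("  resources:    Jm1=", x$Jm1, " Jm2=", x$Jm2, " Jp1=", x$Jp1,
      " Jp2=", x$Jp2, "\n", sep = "")
  cat("  inhibition:   n=", x$n, " Kg=", x$Kg, "   system size Omega=",
      x$Omega, "\n", sep = "")
  invisible(x)
}

#' Update circuit parameters
#'
#' Returns a copy of `params` with the named fields replaced. The pseudo-name
#' `inv_Jp2` sets `Jp2 = 1/value` (RFP resource competitivity, as used in
#' two-parameter bifurcation diagrams); `inv_Jp2 = 0` maps to `Jp2 = Inf`.
#'
#' @param params A [circuit_params()] object.
#' @param ... Named scalar replacements, e.g. `I1 = 0.5`.
#' @return A validated `circuit_params` object.
#' @export
update_params <- function(params, ...) {
  stopifnot(is.circuit_params(params))
  repl <- list(...)
  if (length(repl) == 0L) return(params)
  if (is.null(names(repl)) || any(names(repl) == ""))
    stop("all replacements must be named")
  p <- unclass(params)
  for (nm in names(repl)) {
    if (nm == "inv_Jp2") {
      v <- repl[[nm]]
      if (v < 0) stop("inv_Jp2 must be >= 0")
      p[["Jp2"]] <- if (v == 0) Inf else 1 / v
    } else if (nm %in% PARAM_NAMES) {
      p[[nm]] <- repl[[nm]]
    } else {
      stop("unknown parameter '", nm, "'")
    }
  }
  validate_params(p)
  structure(p, class = "circuit_params")
}

#' Read and write parameter sets as flat JSON
#'
#' Parameter sets serialize to a flat key-value JSON object using the field
#' names `km01 ... Omega`; files round-trip losslessly.
#'
#' @param params A [circuit_params()] object.
#' @param path File path.
#' @return `write_params` returns `path` invisibly; `read_params` returns a
#'   `circuit_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(is.circuit_params(params))
  jsonlite::write_json(unclass(params), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(circuit_params, as.list(p))
}

#' Resource regimes
#'
#' The three resource scenarios: `"unlimited"` (no competition),
#' `"shared"` (both genes draw on common RNAP and ribosome pools, so
#' production rates carry partition-function denominators summing over both
#' genes) and `"orthogonal"` (each gene has a private pool: the partition sum
#' keeps only its own term).
#'
#' @param mode Character; partial matching is not allowed.
#' @return The validated mode string.
#' @export
resource_modes <- function() c("unlimited", "shared", "orthogonal")

match_mode <- function(mode) {
  if (!is.character(mode) || length(mode) != 1L || !(mode %in% resource_modes()))
    stop("'mode' must be one of: ", paste(resource_modes(), collapse = ", "))
  mode
}

#' Concentration and count state constructors
#'
#' A deterministic state is the concentration 4-vector `(m1, p1, m2, p2)`;
#' a stochastic state is the molecule-count 4-vector `(M1, P1, M2, P2)` with
#' `count = concentration * Omega`.
#'
#' @param m1,p1,m2,p2 Non-negative concentrations.
#' @param M1,P1,M2,P2 Non-negative integer counts.
#' @return A named numeric vector.
#' @export
conc_state <- function(m1, p1, m2, p2) {
  x <- c(m1 = m1, p1 = p1, m2 = m2, p2 = p2)
  if (any(!is.finite(x))) stop("non-finite concentration state")
  if (any(x < 0)) stop("concentrations must be non-negative")
  x
}

#' @rdname conc_state
#' @export
count_state <- function(M1, P1, M2, P2) {
  x <- c(M1 = M1, P1 = P1, M2 = M2, P2 = P2)
  if (any(!is.finite(x))) stop("non-finite count state")
  if (any(x < 0)) stop("counts must be non-negative")
  if (any(x != round(x))) stop("counts must be integers")
  x
}

#' @rdname conc_state
#' @param counts A count state vector.
#' @param conc A concentration state vector.
#' @param params A [circuit_params()] object supplying `Omega`.
#' @export
counts_to_conc <- function(counts, params) {
  stats::setNames(as.numeric(counts) / params$Omega, c("m1", "p1", "m2", "p2"))
}

#' @rdname conc_state
#' @export
conc_to_counts <- function(conc, params) {
  stats::setNames(as.numeric(conc) * params$Omega, c("M1", "P1", "M2", "P2"))
}
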