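#' Diffusion b-value schemes
#'
#' Returns the b-value scheme of one of the three acquisitions used
#' throughout the package, or validates a custom scheme. The named schemes
#' are the standard lung protocols: a 10-step IVIM acquisition (dense
#' sampling below 200 s/mm2 to capture the pseudo-diffusion decay), a
#' 4-point DKI acquisition reaching b = 2000 s/mm2, and the 2-point DWI
#' acquisition used for the standard ADC.
#'
#' @param name One of `"ivim"`, `"dki"`, `"dwi"`. Ignored when `bvalues`
#'   is supplied.
#' @param bvalues Optional custom scheme: a strictly increasing numeric
#'   vector of non-negative diffusion weightings (s/mm2) containing 0.
#' @return Numeric vector of b-values in s/mm2.
#' @examples
#' bvalue_scheme("ivim")
#' bvalue_scheme(bvalues = c(0, 50, 400, 800))
#' @export
bvalue_scheme <- function(name = c("ivim", "dki", "dwi"), bvalues = NULL) {
  if (!is.null(bvalues)) {
    return(validate_bvalues(bvalues))
  }
  schemes <- list(
    ivim = c(0, 25, 50, 100, 150, 200, 400, 600, 800, 1000),
    dki  = c(0, 500, 1000, 2000),
    dwi  = c(0, 800)
  )
  if (!is.character(name) || length(name) < 1 || !all(name[1] %in% names(schemes))) {
    stop("unknown scheme name; valid names are: ",
         paste(sQuote(names(schemes)), collapse = ", "), call. = FALSE)
  }
  name <- name[1]
  schemes[[name]]
}

validate_bvalues <- function(b) {
  if (!is.numeric(b) || length(b) < 2) {
    stop("a b-value scheme needs at least two numeric values", call. = FALSE)
  }
  if (any(!is.finite(b)) || any(b < 0)) {
    stop("b-values must be finite and non-negative", call. = FALSE)
  }
  if (any(diff(b) <= 0)) {
    stop("b-values must be strictly increasing", call. = FALSE)
  }
  if (b[1] != 0) {
    stop("a b-value scheme must contain b = 0", call. = FALSE)
  }
  as.numeric(b)
}
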