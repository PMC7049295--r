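# Parameter bundles. Defaults are read once from the packaged YAML
# (inst/extdata/model_params.yaml) and cached.

.param_cache <- new.env(parent = emptyenv())

default_params <- function() {
  if (is.null(.param_cache$tbl)) {
    path <- system.file("extdata", "model_params.yaml", package = "qsswarm")
    if (path == "") path <- file.path("inst", "extdata", "model_params.yaml")
    .param_cache$tbl <- yaml::read_yaml(path)
  }
  .param_cache$tbl
}

#' Chemotaxis model parameters
#'
#' Parameter bundle for the run-and-tumble chemotaxis model. Defaults come
#' from the packaged parameter file; any value can be overridden.
#'
#' @param ... named overrides, e.g. `speed = 20`.
#' @return object of class `chemotaxis_params` with fields `tau0`, `tauT`
#'   (s), `sigma_chemo_CT` (s; the fitted product of chemotactic sensitivity
#'   and receptor count), `Kd` (uM), `speed` (um/s), `theta_mu`,
#'   `theta_sigma` (deg).
#' @export
chemotaxis_params <- function(...) {
  p <- default_params()$chemotaxis
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown chemotaxis parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (any(unlist(p) <= 0)) stop("all chemotaxis parameters must be positive")
  structure(p, class = "chemotaxis_params")
}

#' Quorum-sensing circuit and signal-field parameters
#'
#' @param eta ribosome-binding-site (RBS) strength in `(0, 1]`: the
#'   translation-initiation rate of the synthase RBS relative to the
#'   reference design. Scales the whole AHL production rate (basal term
#'   included) unless `eta_scales_basal = FALSE`, in which case it scales
#'   only the upregulated term.
#' @param ... named overrides of the packaged defaults: `A1`, `A2`
#'   (molecules/s), `H`, `Q0` (nM), `ktr` (molecules/s), `kGm` (1/s),
#'   `kdeg` (molecules/s), `Km` (molecules/cell), `Dsignal` (um^2/s),
#'   `Rd_per_h` (1/h), `gfp_threshold` (molecules/bacterium), `depth` (um).
#' @param eta_scales_basal see `eta`.
#' @return object of class `qs_params`.
#' @export
qs_params <- function(eta = 1, ..., eta_scales_basal = TRUE) {
  p <- default_params()$quorum_sensing
  ov <- list(...)
  bad <- setdiff(names(ov), names(p))
  if (length(bad)) stop("unknown QS parameter(s): ",
                        paste(bad, collapse = ", "))
  p[names(ov)] <- ov
  if (eta <= 0 || eta > 1) stop("eta must lie in (0, 1]")
  if (any(unlist(p) < 0)) stop("QS parameters must be non-negative")
  p$eta <- eta
  p$eta_scales_basal <- isTRUE(eta_scales_basal)
  p$Rd <- p$Rd_per_h / 3600 # 1/s
  structure(p, class = "qs_params")
}

#' Default growth parameters (doubling times, seconds)
#' @return list with `tau_dbl_bacteria` and `tau_dbl_biohybrid`.
#' @export
growth_params <- function() default_params()$growth

#' @export
print.chemotaxis_params <- function(x, ...) {
  cat("<chemotaxis_params>\n")
  for (nm in names(unclass(x)))
    cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}

#' @export
print.qs_params <- function(x, ...) {
  cat(sprintf("<qs_params: eta = %g%s>\n", x$eta,
              if (x$eta_scales_basal) "" else " (upregulated term only)"))
  for (nm in setdiff(names(unclass(x)), c("eta", "eta_scales_basal")))
    cat(sprintf("  %-15s %g\n", nm, x[[nm]]))
  invisible(x)
}
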