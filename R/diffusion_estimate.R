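#' Diffusion coefficient with uncertainty and provenance
#'
#' @param value diffusion coefficient, A^2/ns (>= 0)
#' @param uncertainty standard error / standard deviation, A^2/ns
#' @param r_squared linearity diagnostic of the underlying straight-line
#'   fit, in `[0, 1]`
#' @param method short method tag
#' @param corrections named logical flags: `finite_size`, `isotope_rescaled`,
#'   `crowding_scaled`
#' @return object of class `"diffusion_estimate"`
#' @export
diffusion_estimate <- function(value, uncertainty = NA_real_,
                               r_squared = NA_real_, method = "unspecified",
                               corrections = list(finite_size = FALSE,
                                                  isotope_rescaled = FALSE,
                                                  crowding_scaled = FALSE)) {
  stopifnot(value >= 0)
  if (!is.na(r_squared)) stopifnot(r_squared >= 0, r_squared <= 1)
  structure(list(value = value, uncertainty = uncertainty,
                 r_squared = r_squared, method = method,
                 corrections = corrections),
            class = "diffusion_estimate")
}

#' @export
print.diffusion_estimate <- function(x, ...) {
  flags <- names(Filter(isTRUE, x$corrections))
  cat(sprintf("<diffusion_estimate> %.4g +- %.3g A^2/ns [%s]%s%s\n",
              x$value, x$uncertainty, x$method,
              if (is.na(x$r_squared)) "" else sprintf(" R^2=%.4f", x$r_squared),
              if (length(flags)) paste0(" (", paste(flags, collapse = ","), ")")
              else ""))
  invisible(x)
}
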