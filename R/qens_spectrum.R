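#' QENS spectrum container
#'
#' Intensities and per-point uncertainties on a rectangular (q, omega) grid
#' together with the instrument resolution description.
#'
#' @param q momentum-transfer values, 1/A (strictly increasing)
#' @param omega energy-transfer grid, micro-eV
#' @param intensity matrix `length(q) x length(omega)`
#' @param sigma uncertainty matrix, same shape, `> 0` where intensity finite
#' @param resolution_fwhm Gaussian resolution FWHM, micro-eV (scalar or per q)
#' @param truth optional generator ground-truth record (for synthetic data)
#' @return object of class `"qens_spectrum"`
#' @export
qens_spectrum <- function(q, omega, intensity, sigma, resolution_fwhm,
                          truth = NULL) {
  intensity <- as.matrix(intensity); sigma <- as.matrix(sigma)
  stopifnot(all(diff(q) > 0),
            nrow(intensity) == length(q), ncol(intensity) == length(omega),
            identical(dim(intensity), dim(sigma)),
            all(resolution_fwhm > 0))
  if (any(sigma[is.finite(intensity)] <= 0)) {
    stop("sigma must be > 0 wherever intensity is finite")
  }
  structure(list(q = q, omega = omega, intensity = intensity, sigma = sigma,
                 resolution_fwhm = resolution_fwhm, truth = truth),
            class = "qens_spectrum")
}

#' @export
print.qens_spectrum <- function(x, ...) {
  cat(sprintf(paste0("<qens_spectrum> %d q in [%.2f, %.2f] 1/A, %d omega in ",
                     "[%.1f, %.1f] ueV, resolution %.2g ueV FWHM%s\n"),
              length(x$q), min(x$q), max(x$q), length(x$omega),
              min(x$omega), max(x$omega), mean(x$resolution_fwhm),
              if (is.null(x$truth)) "" else " (synthetic)"))
  invisible(x)
}

#' Read and write the flat CSV spectrum dialect
#'
#' Long-format CSV with columns `q, omega, intensity, sigma`; the resolution
#' FWHM and any synthetic ground truth travel in a JSON sidecar
#' (`<path>.meta.json`) written next to the CSV.
#'
#' @param spectrum a [qens_spectrum()]
#' @param path CSV file path
#' @return `read_spectrum_csv()` returns a [qens_spectrum()];
#'   `write_spectrum_csv()` returns `path` invisibly
#' @export
write_spectrum_csv <- function(spectrum, path) {
  grid <- expand.grid(omega = spectrum$omega, q = spectrum$q)[, 2:1]
  grid$intensity <- as.vector(t(spectrum$intensity))
  grid$sigma <- as.vector(t(spectrum$sigma))
  utils::write.csv(grid, path, row.names = FALSE)
  meta <- list(resolution_fwhm = spectrum$resolution_fwhm)
  if (!is.null(spectrum$truth)) meta$truth <- unclass(spectrum$truth)
  jsonlite::write_json(meta, paste0(path, ".meta.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  df <- utils::read.csv(path)
  stopifnot(all(c("q", "omega", "intensity", "sigma") %in% names(df)))
  q <- sort(unique(df$q)); omega <- sort(unique(df$omega))
  idx <- cbind(match(df$q, q), match(df$omega, omega))
  intensity <- sigma <- matrix(NA_real_, length(q), length(omega))
  intensity[idx] <- df$intensity
  sigma[idx] <- df$sigma
  meta_path <- paste0(path, ".meta.json")
  res <- 0.9
  if (file.exists(meta_path)) {
    meta <- jsonlite::read_json(meta_path, simplifyVector = TRUE)
    if (!is.null(meta$resolution_fwhm)) res <- meta$resolution_fwhm
  }
  qens_spectrum(q, omega, intensity, sigma, res)
}
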