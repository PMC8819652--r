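#' Fit quality metrics
#'
#' Reduced goodness-of-fit `sum(((y_exp - y_fit)/sigma)^2) / (#y - #p)`,
#' mean absolute deviation (L1), and mean squared deviation (L2).
#' Comparing L1 and L2 flags fits where a few points are badly missed even
#' though the bulk is described well.
#'
#' @param y_exp observed values
#' @param y_fit fitted values
#' @param sigma per-point uncertainties (> 0)
#' @param n_params number of fitted parameters
#' @return list with elements `gof`, `l1`, `l2`
#' @export
fit_metrics <- function(y_exp, y_fit, sigma, n_params) {
  stopifnot(length(y_exp) == length(y_fit), length(sigma) == length(y_exp),
            all(sigma > 0))
  n <- length(y_exp)
  if (n <= n_params) stop("goodness-of-fit undefined: #y <= #p")
  r <- y_exp - y_fit
  list(gof = sum((r / sigma)^2) / (n - n_params),
       l1 = mean(abs(r)),
       l2 = mean(r^2))
}

#' Solvent-term handling policy for spectrum fits
#'
#' Default `"fixed_width"`: the solvent Lorentzian width at each q is fixed
#' (either given explicitly via `width`, recycled per q, or computed as
#' `hbar * D_solvent * q^2` from a known solvent diffusion constant) with a
#' free amplitude.  `"free"`: both amplitude and width are fitted per q.
#' `"none"`: no solvent term.
#'
#' @param mode `"fixed_width"`, `"free"`, or `"none"`
#' @param width solvent HWHM(s) in micro-eV; overrides `D_solvent`
#' @param D_solvent solvent diffusion constant, A^2/ns (default 187, heavy
#'   water near ambient temperature)
#' @return object of class `"solvent_policy"`
#' @export
solvent_policy <- function(mode = c("fixed_width", "free", "none"),
                           width = NULL, D_solvent = 187) {
  mode <- match.arg(mode)
  structure(list(mode = mode, width = width, D_solvent = D_solvent),
            class = "solvent_policy")
}

.solvent_width_at <- function(policy, q) {
  if (!is.null(policy$width)) rep_len(policy$width, length(q))
  else fick_width(policy$D_solvent, q)
}

# --- variable projection machinery ------------------------------------------
# For fixed line widths the model at one q is a non-negative linear
# combination of convolved unit Lorentzians: c1*K(gamma) + c2*K(gamma+Gamma)
# [+ cs*K(ws)], with beta = c1 + c2 and A0 = c1/(c1 + c2) in [0, 1] by
# construction.  The linear coefficients are profiled out exactly by a small
# non-negative least-squares solve, leaving only the width parameters to the
# nonlinear optimizer.

# exact weighted NNLS for <= 3 columns: unconstrained solve first (usually
# feasible), full active-set enumeration otherwise
.nnls_small <- function(B, y, w) {
  k <- ncol(B)
  Bw <- B * w; yw <- y * w
  G <- crossprod(Bw); b <- crossprod(Bw, yw)
  yy <- sum(yw * yw)
  nsolve <- function(idx) {
    sol <- tryCatch(solve(G[idx, idx, drop = FALSE], b[idx]),
                    error = function(e) NULL)
    if (is.null(sol) || any(!is.finite(sol)) || any(sol < 0)) return(NULL)
    cf <- numeric(k); cf[idx] <- sol
    # ||yw - Bw cf||^2 = yy - 2 b'cf + cf'G cf
    list(coef = cf, sse = yy - 2 * sum(b * cf) + sum(cf * (G %*% cf)))
  }
  full <- nsolve(seq_len(k))
  if (!is.null(full)) return(full)
  best <- list(coef = numeric(k), sse = yy)
  if (k > 1) {
    for (mask in 1:(2^k - 2)) {
      free <- which(bitwAnd(mask, 2^(seq_len(k) - 1)) == 0)
      cand <- nsolve(free)
      if (!is.null(cand) && cand$sse < best$sse) best <- cand
    }
  }
  best
}

# convolved Lorentzian basis for all q at once; widths: nq x k matrix,
# columns ordered q-major: (q1 w1, q1 w2, ..., q2 w1, ...)
.conv_basis <- function(plan, widths) {
  wv <- as.vector(t(widths))               # q-major width vector
  if (any(wv <= 0)) stop("Lorentzian half-width must be > 0")
  wp <- plan$omega_pad
  cols <- t(wv / (pi * (outer(wv^2, wp^2, "+"))))
  .conv_apply(plan, cols)                  # n_omega x (nq*k)
}

# crude moment-based width scale from one q-slice
.width_scale <- function(omega, y) {
  bg <- stats::median(y[abs(omega) > 0.8 * max(abs(omega))])
  peak <- max(y) - bg
  area <- sum(pmax(y - bg, 0)) * mean(diff(omega))
  max(area / (pi * max(peak, 1e-12)), 0.2)
}

#' Per-q fit of the scattering model
#'
#' Independently at each q, a weighted (1/sigma^2) least-squares fit of the
#' resolution-convolved two-Lorentzian-plus-solvent model.  The line widths
#' `gamma` (center of mass) and `Gamma` (internal, additive) are optimized
#' by bounded Levenberg-Marquardt with several deterministic multi-starts;
#' the amplitudes are profiled out exactly by non-negative least squares, so
#' the EISF `A0 = c1/(c1+c2)` is confined to `[0, 1]` by construction.
#' Non-convergence at one q flags that slice and leaves the others
#' untouched; slices where the internal line carries no weight (`A0` at 1)
#' are flagged as having an unidentifiable `Gamma`.
#'
#' @param spectrum a [qens_spectrum()]
#' @param policy a [solvent_policy()]
#' @param n_starts number of multi-starts per q (deterministic width grid;
#'   the lowest weighted SSE wins)
#' @param seed kept for interface stability; the start grid is deterministic
#' @return object of class `"perq_fit"`: a data frame `per_q` of parameters,
#'   uncertainties, flags and metrics, plus the inputs
#' @export
fit_per_q <- function(spectrum, policy = solvent_policy(), n_starts = 5L,
                      seed = 1L) {
  omega <- spectrum$omega
  if (length(omega) < 8) stop("need >= 8 omega points per q")
  free_solvent <- policy$mode == "free"
  has_solvent <- policy$mode != "none"
  rows <- lapply(seq_along(spectrum$q), function(i) {
    q <- spectrum$q[i]
    y <- spectrum$intensity[i, ]; sg <- spectrum$sigma[i, ]
    ok <- is.finite(y) & is.finite(sg) & sg > 0
    res_fwhm <- if (length(spectrum$resolution_fwhm) > 1)
      spectrum$resolution_fwhm[i] else spectrum$resolution_fwhm
    plan <- .conv_plan(omega, res_fwhm)
    w <- ifelse(ok, 1 / sg, 0); y0 <- ifelse(ok, y, 0)
    fixed_ws <- if (has_solvent && !free_solvent)
      .solvent_width_at(policy, q) else NA
    g0 <- .width_scale(omega, y0)
    wmax <- max(abs(omega))

    widths_of <- function(p) {
      ws <- if (free_solvent) p[["ws"]] else fixed_ws
      if (has_solvent) c(p[["gamma"]], p[["gamma"]] + p[["Gamma"]], ws)
      else c(p[["gamma"]], p[["gamma"]] + p[["Gamma"]])
    }
    resid_fn <- function(p) {
      B <- .conv_basis(plan, matrix(widths_of(p), nrow = 1))
      sol <- .nnls_small(B, y0, w)
      (B %*% sol$coef - y0) * w
    }
    starts <- list(c(gamma = g0, Gamma = 3 * g0),
                   c(gamma = g0 / 2, Gamma = 6 * g0),
                   c(gamma = 2 * g0, Gamma = 2 * g0),
                   c(gamma = g0 / 4, Gamma = 1.5 * g0),
                   c(gamma = g0, Gamma = 12 * g0))[seq_len(min(n_starts, 5L))]
    lower <- c(gamma = 1e-4, Gamma = 0)
    upper <- c(gamma = 10 * wmax, Gamma = 10 * wmax)
    if (free_solvent) {
      starts <- lapply(starts, function(s) c(s, ws = 2 * wmax))
      lower <- c(lower, ws = 1); upper <- c(upper, ws = 100 * wmax)
    }
    best <- NULL
    for (s in starts) {
      fit <- tryCatch(
        minpack.lm::nls.lm(par = s, lower = lower, upper = upper,
                           fn = resid_fn,
                           control = minpack.lm::nls.lm.control(
                             maxiter = 500, ftol = 1e-14, ptol = 1e-12)),
        error = function(e) NULL)
      if (!is.null(fit) && (is.null(best) || fit$deviance < best$deviance)) {
        best <- fit
      }
    }
    if (is.null(best)) {
      return(data.frame(q = q, beta = NA, A0 = NA, gamma = NA, Gamma = NA,
                        bs = NA, ws = NA, gamma_se = NA, Gamma_se = NA,
                        A0_se = NA, gof = NA, l1 = NA, l2 = NA,
                        converged = FALSE, Gamma_identifiable = NA))
    }
    p <- best$par
    B <- .conv_basis(plan, matrix(widths_of(p), nrow = 1))
    cf <- .nnls_small(B, y0, w)$coef
    beta <- cf[1] + cf[2]
    A0 <- if (beta > 0) cf[1] / beta else NA_real_
    bs <- if (has_solvent) cf[3] else NA_real_
    yfit <- drop(B %*% cf)
    n_par <- length(p) + if (has_solvent) 3L else 2L
    met <- fit_metrics(y0[ok], yfit[ok], sg[ok], n_par)
    # full-parameter covariance at the solution (natural parametrization)
    full <- c(beta = beta, A0 = A0, gamma = p[["gamma"]],
              Gamma = p[["Gamma"]],
              if (has_solvent) c(bs = bs),
              if (free_solvent) c(ws = p[["ws"]]))
    se <- .numeric_se(function(v) {
      m <- v[["beta"]] * (v[["A0"]] * lorentzian(plan$omega_pad, v[["gamma"]]) +
                            (1 - v[["A0"]]) *
                              lorentzian(plan$omega_pad,
                                         v[["gamma"]] + v[["Gamma"]]))
      if (has_solvent) {
        ws <- if (free_solvent) v[["ws"]] else fixed_ws
        m <- m + v[["bs"]] * lorentzian(plan$omega_pad, ws)
      }
      drop(.conv_apply(plan, m))
    }, full, y0, w, sum(ok))
    data.frame(q = q, beta = beta, A0 = A0, gamma = p[["gamma"]],
               Gamma = p[["Gamma"]], bs = bs,
               ws = if (free_solvent) p[["ws"]] else fixed_ws,
               gamma_se = se[["gamma"]], Gamma_se = se[["Gamma"]],
               A0_se = se[["A0"]],
               gof = met$gof, l1 = met$l1, l2 = met$l2,
               converged = TRUE,
               # the internal width is identifiable only when the internal
               # line carries weight and its curvature supports a finite
               # standard error smaller than the width itself
               Gamma_identifiable = is.finite(A0) && A0 < 1 - 1e-6 &&
                 beta > 0 && is.finite(se[["Gamma"]]) &&
                 se[["Gamma"]] < p[["Gamma"]])
  })
  structure(list(per_q = do.call(rbind, rows), policy = policy,
                 spectrum = spectrum),
            class = "perq_fit")
}

# standard errors from a numeric Jacobian of a model function at a solution:
# cov = (J' W J)^-1 * s2 with s2 = weighted SSE / dof
.numeric_se <- function(model_fn, par, y, w, n_ok) {
  f0 <- model_fn(par)
  J <- vapply(seq_along(par), function(j) {
    h <- max(abs(par[j]) * 1e-6, 1e-9)
    pj <- par; pj[j] <- pj[j] + h
    (model_fn(pj) - f0) / h
  }, numeric(length(f0)))
  Jw <- J * w
  dof <- max(n_ok - length(par), 1)
  s2 <- sum(((f0 - y) * w)^2) / dof
  se <- tryCatch(sqrt(pmax(diag(solve(crossprod(Jw))) * s2, 0)),
                 error = function(e) rep(NA_real_, length(par)))
  stats::setNames(se, names(par))
}

#' Center-of-mass diffusion from per-q widths
#'
#' Weighted straight-line fit of the center-of-mass widths `gamma(q)`
#' against `hbar*q^2` through the origin; the slope is the apparent
#' diffusion coefficient D with its propagated standard error.
#'
#' @param gamma_q widths, micro-eV
#' @param q momentum transfers, 1/A
#' @param sigma_gamma width uncertainties (optional; uniform if missing)
#' @return a [diffusion_estimate()] with method `"per_q_gamma"`
#' @export
extract_D_from_gamma <- function(gamma_q, q, sigma_gamma = NULL) {
  ok <- is.finite(gamma_q) & is.finite(q)
  if (!is.null(sigma_gamma)) ok <- ok & is.finite(sigma_gamma) & sigma_gamma > 0
  if (sum(ok) < 1) stop("no valid (gamma, q) points")
  x <- physical_constants$hbar_ueV_ns * q[ok]^2
  y <- gamma_q[ok]
  w <- if (is.null(sigma_gamma)) rep(1, sum(ok)) else 1 / sigma_gamma[ok]^2
  D <- sum(w * x * y) / sum(w * x^2)
  se <- if (is.null(sigma_gamma)) {
    if (sum(ok) > 1) sqrt(sum(w * (y - D * x)^2) / (sum(ok) - 1) / sum(w * x^2))
    else NA_real_
  } else {
    sqrt(1 / sum(w * x^2))
  }
  diffusion_estimate(D, uncertainty = se, method = "per_q_gamma")
}

# natural-parameter model matrix (nq x n_omega), used for metrics/covariance
.global_model_matrix <- function(par, q, plan, fixed_ws, has_solvent,
                                 free_solvent) {
  wp <- plan$omega_pad
  gam <- fick_width(par$D, q)
  Gam <- jump_width(par$D_int, par$tau, q)
  y_pad <- vapply(seq_along(q), function(i) {
    m <- par$beta[i] * (par$A0[i] * lorentzian(wp, gam[i]) +
                          (1 - par$A0[i]) * lorentzian(wp, gam[i] + Gam[i]))
    if (has_solvent) {
      ws <- if (free_solvent) par$ws[i] else fixed_ws[i]
      m <- m + par$bs[i] * lorentzian(wp, ws)
    }
    m
  }, numeric(length(wp)))
  t(.conv_apply(plan, y_pad))
}

#' Global jump-diffusion fit of a spectrum
#'
#' Simultaneous weighted least-squares fit over the full (q, omega) grid
#' imposing the Fickian center-of-mass law `gamma = hbar*D*q^2` and the
#' jump-diffusion internal law `Gamma = hbar*D_int*q^2/(1 + D_int*q^2*tau)`
#' across all q, with shared positive `D`, `D_int`, `tau` and per-q EISF,
#' amplitude, and solvent amplitude.  The per-q amplitudes are profiled out
#' by non-negative least squares (variable projection), so the nonlinear
#' search runs over `(D, D_int, tau)` only (plus per-q solvent widths under
#' a free solvent policy); `A0` stays in `[0, 1]` by construction.
#' Deterministic multi-starts around a per-q-derived initialization guard
#' against secondary minima; the lowest weighted SSE wins.
#'
#' @param spectrum a [qens_spectrum()] with at least 4 q slices
#' @param policy a [solvent_policy()]
#' @param n_starts number of multi-starts (deterministic grid around the
#'   initialization)
#' @param seed kept for interface stability
#' @param start optional named start values `c(D=, D_int=, tau=)`
#' @param perq optional precomputed [fit_per_q()] result to initialize from
#' @param eisf_constraint `"monotone"` (default) constrains the fitted EISF
#'   to be non-increasing in q, which holds for any confined internal motion
#'   over this q window (the sphere EISF is monotone up to its first zero at
#'   `qa ~ 4.49`) and removes the exact label-swap degeneracy between the
#'   center-of-mass and internal lines in the `tau -> 0` limit; `"free"`
#'   leaves each A0 independent in `[0, 1]`
#' @return object of class `"global_fit"` with elements `D`, `D_int`, `tau`,
#'   their standard errors, per-q `A0_q`, `beta_q`, solvent terms, metrics,
#'   and convergence diagnostics
#' @export
fit_global <- function(spectrum, policy = solvent_policy(), n_starts = 5L,
                       seed = 1L, start = NULL, perq = NULL,
                       eisf_constraint = c("monotone", "free")) {
  eisf_constraint <- match.arg(eisf_constraint)
  monotone <- eisf_constraint == "monotone"
  nq <- length(spectrum$q)
  if (nq < 4) stop("global jump-diffusion fit needs >= 4 q slices")
  free_solvent <- policy$mode == "free"
  has_solvent <- policy$mode != "none"
  plan <- .conv_plan(spectrum$omega, mean(spectrum$resolution_fwhm))
  fixed_ws <- if (has_solvent) .solvent_width_at(policy, spectrum$q) else NULL
  y <- spectrum$intensity; sg <- spectrum$sigma
  ok <- is.finite(y) & is.finite(sg) & sg > 0
  w <- ifelse(ok, 1 / sg, 0); y0 <- ifelse(ok, y, 0)
  hbar <- physical_constants$hbar_ueV_ns
  k <- if (has_solvent) 3L else 2L
  # solvent basis columns do not depend on theta under a fixed-width policy
  solv_cached <- if (has_solvent && !free_solvent)
    .conv_basis(plan, matrix(fixed_ws, ncol = 1)) else NULL

  # theta layout: (log D, log D_int, log tau, [z_1..z_nq], [log ws_q]);
  # under the monotone constraint A0_q = prod_{j<=q} plogis(z_j)
  n_z <- if (monotone) nq else 0L
  project <- function(theta) {
    D <- exp(theta[1]); D_int <- exp(theta[2]); tau <- exp(theta[3])
    gam <- fick_width(D, spectrum$q)
    Gam <- jump_width(D_int, tau, spectrum$q)
    ws <- if (free_solvent) exp(theta[3 + n_z + seq_len(nq)]) else fixed_ws
    resid <- matrix(0, nq, ncol(y0))
    if (monotone) {
      A0 <- cumprod(stats::plogis(theta[3 + seq_len(nq)]))
      prot <- .conv_basis(plan, cbind(gam, gam + Gam))
      coefs <- matrix(0, nq, 2L)
      for (i in seq_len(nq)) {
        pcol <- A0[i] * prot[, 2 * i - 1] + (1 - A0[i]) * prot[, 2 * i]
        B <- if (has_solvent) {
          scol <- if (free_solvent)
            .conv_basis(plan, matrix(ws[i], 1, 1)) else solv_cached[, i]
          cbind(pcol, scol)
        } else cbind(pcol)
        sol <- .nnls_small(B, y0[i, ], w[i, ])
        coefs[i, ] <- c(sol$coef, 0)[1:2]
        resid[i, ] <- (B %*% sol$coef - y0[i, ]) * w[i, ]
      }
      cf <- cbind(coefs[, 1] * A0, coefs[, 1] * (1 - A0),
                  if (has_solvent) coefs[, 2])
    } else {
      widths <- cbind(gam, gam + Gam, if (has_solvent) ws)
      basis <- .conv_basis(plan, widths)
      cf <- matrix(0, nq, k)
      for (i in seq_len(nq)) {
        B <- basis[, (i - 1) * k + seq_len(k), drop = FALSE]
        sol <- .nnls_small(B, y0[i, ], w[i, ])
        cf[i, ] <- sol$coef
        resid[i, ] <- (B %*% sol$coef - y0[i, ]) * w[i, ]
      }
    }
    list(resid = as.vector(resid), coefs = cf,
         D = D, D_int = D_int, tau = tau, ws = ws)
  }

  if (is.null(perq) && is.null(start)) {
    perq <- fit_per_q(spectrum, policy, n_starts = 2L, seed = seed)
  }
  if (!is.null(perq)) {
    pq <- perq$per_q
    good <- which(pq$converged %in% TRUE & is.finite(pq$gamma))
    D0 <- extract_D_from_gamma(pq$gamma[good], pq$q[good],
                               pq$gamma_se[good])$value
    # linearized jump law 1/Gamma = 1/(hbar*D_int*q^2) + tau/hbar on the
    # internal widths that carry weight
    idf <- which(pq$converged %in% TRUE & is.finite(pq$Gamma) &
                   pq$Gamma > 1e-3 & pq$A0 < 0.95 & pq$beta > 0)
    Dint0 <- 2 * D0; tau0 <- 0.02
    if (length(idf) >= 2) {
      lf <- stats::lm(I(1 / pq$Gamma[idf]) ~ I(1 / pq$q[idf]^2))
      sl <- stats::coef(lf)[[2]]; ic <- stats::coef(lf)[[1]]
      if (is.finite(sl) && sl > 0) Dint0 <- 1 / (hbar * sl)
      if (is.finite(ic) && ic > 0) tau0 <- hbar * ic
    }
  } else {
    D0 <- 15; Dint0 <- 30; tau0 <- 0.02
  }
  if (!is.null(start)) {
    if (!is.null(start[["D"]])) D0 <- start[["D"]]
    if (!is.null(start[["D_int"]])) Dint0 <- start[["D_int"]]
    if (!is.null(start[["tau"]])) tau0 <- start[["tau"]]
  }
  D0 <- min(max(D0, 0.5), 500); Dint0 <- min(max(Dint0, 0.5), 500)
  tau0 <- min(max(tau0, 1e-4), 0.5)

  # deterministic multi-start grid around the initialization; physical
  # bounds keep the jump-diffusion pair from running away along its
  # high-q-plateau degeneracy (D_int capped at ~2.5x bulk water diffusion,
  # residence times between 0.1 ps and 1 ns)
  mults <- list(c(1, 1, 1), c(1, 3, 1 / 3), c(1, 1 / 3, 3),
                c(1.25, 1, 1), c(0.8, 1, 1),
                c(1, 3, 3), c(1, 1 / 3, 1 / 3),
                c(0.8, 3, 1 / 3), c(1.25, 1 / 3, 3))[seq_len(min(n_starts, 9L))]
  z_of <- function(A0_start) {
    A0_start <- cummin(pmin(pmax(A0_start, 0.02), 0.98))
    s <- A0_start / c(1, A0_start[-nq])
    stats::qlogis(pmin(pmax(s, 0.02), 0.98))
  }
  z_list <- list(NULL)
  if (monotone) {
    # two EISF start envelopes: the raw monotone envelope of the per-q
    # estimates, and the best-matching sphere-confinement shape (the latter
    # guards against per-q estimates stuck in a swapped labeling)
    a_perq <- if (!is.null(perq)) {
      a <- perq$per_q$A0; a[!is.finite(a)] <- 0.7; a
    } else eisf_sphere(spectrum$q, 1.2)
    radii <- c(0.5, 0.8, 1.2, 1.8, 2.6)
    sse <- vapply(radii, function(a) {
      sum((eisf_sphere(spectrum$q, a) - a_perq)^2)
    }, numeric(1))
    a_best <- radii[which.min(sse)]
    z_list <- list(z_of(a_perq), z_of(eisf_sphere(spectrum$q, a_best)))
  }
  theta_ws <- if (free_solvent) log(rep(2 * max(abs(spectrum$omega)), nq))
  lo <- c(log(0.05), log(0.05), log(1e-4),
          if (monotone) rep(-12, nq),
          if (free_solvent) rep(log(1), nq))
  hi <- c(log(500), log(500), log(1),
          if (monotone) rep(12, nq),
          if (free_solvent) rep(log(1e4), nq))
  # start list: two centers (per-q-derived and canonical jump-diffusion
  # values) crossed with width multipliers
  centers <- list(c(D0, min(max(Dint0, 0.5 * D0), 20 * D0),
                    min(max(tau0, 1e-3), 0.2)),
                  c(D0, 2 * D0, 0.02))
  starts3 <- list()
  for (mu in mults) for (ce in centers) {
    starts3[[length(starts3) + 1L]] <-
      log(c(ce[1] * mu[1], ce[2] * mu[2], ce[3] * mu[3]))
  }
  starts3 <- unique(starts3)[seq_len(min(2L * length(mults),
                                         max(n_starts, 2L) * 2L))]
  run_lm <- function(th0, idx_lo, idx_hi, fn, iters, ftol) {
    tryCatch(
      minpack.lm::nls.lm(par = pmin(pmax(th0, idx_lo + 1e-6), idx_hi - 1e-6),
                         fn = fn, lower = idx_lo, upper = idx_hi,
                         control = minpack.lm::nls.lm.control(
                           maxiter = iters, ftol = ftol, ptol = 1e-10)),
      error = function(e) NULL)
  }
  # exploration: shared widths only, EISF frozen at each candidate envelope
  best3 <- NULL
  for (th3 in starts3) for (z0 in z_list) {
    fn3 <- if (monotone) {
      function(th) project(c(th, z0, theta_ws))$resid
    } else {
      function(th) project(c(th, theta_ws))$resid
    }
    fit <- run_lm(th3, lo[1:3], hi[1:3], fn3, 25L, ftol = 1e-7)
    if (!is.null(fit) && (is.null(best3) || fit$deviance < best3$deviance)) {
      best3 <- fit
      best3$z0 <- z0
    }
  }
  if (is.null(best3)) stop("global jump-diffusion fit failed to converge")
  # polish: all nonlinear parameters free from the best exploration point
  best <- run_lm(c(best3$par, best3$z0, theta_ws), lo, hi,
                 function(th) project(th)$resid, 150L, ftol = 1e-12)
  if (is.null(best) || best$deviance > best3$deviance) {
    best <- best3
    best$par <- c(best3$par, best3$z0, theta_ws)
  }
  sol <- project(best$par)
  beta_q <- sol$coefs[, 1] + sol$coefs[, 2]
  A0_q <- ifelse(beta_q > 0, sol$coefs[, 1] / beta_q, NA_real_)
  bs_q <- if (has_solvent) sol$coefs[, 3] else NULL
  par <- list(D = sol$D, D_int = sol$D_int, tau = sol$tau, A0 = A0_q,
              beta = beta_q, bs = bs_q, ws = sol$ws)
  m <- .global_model_matrix(par, spectrum$q, plan, fixed_ws, has_solvent,
                            free_solvent)
  np <- 3L + nq * (k - 1L) + if (free_solvent) nq else 0L
  met <- fit_metrics(y0[ok], m[ok], sg[ok], np)
  # covariance of the shared parameters from the full natural-parameter
  # Jacobian at the solution
  nat <- c(D = sol$D, D_int = sol$D_int, tau = sol$tau,
           stats::setNames(A0_q, paste0("A0_", seq_len(nq))),
           stats::setNames(beta_q, paste0("beta_", seq_len(nq))),
           if (has_solvent) stats::setNames(bs_q, paste0("bs_", seq_len(nq))))
  model_fn <- function(v) {
    p <- list(D = v[["D"]], D_int = v[["D_int"]], tau = v[["tau"]],
              A0 = v[3 + seq_len(nq)], beta = v[3 + nq + seq_len(nq)],
              bs = if (has_solvent) v[3 + 2 * nq + seq_len(nq)],
              ws = sol$ws)
    as.vector(.global_model_matrix(p, spectrum$q, plan, fixed_ws,
                                   has_solvent, free_solvent))
  }
  se <- .numeric_se(model_fn, nat, as.vector(y0), as.vector(w), sum(ok))
  structure(list(D = sol$D, D_int = sol$D_int, tau = sol$tau,
                 D_se = se[["D"]], D_int_se = se[["D_int"]],
                 tau_se = se[["tau"]],
                 A0_q = A0_q, beta_q = beta_q,
                 solvent_amplitude_q = bs_q,
                 solvent_width_q = if (has_solvent) sol$ws else NULL,
                 q = spectrum$q, metrics = met,
                 converged = best$info %in% 1:4, info = best$info,
                 policy = policy),
            class = "global_fit")
}

#' @export
print.global_fit <- function(x, ...) {
  cat(sprintf(paste0("<global_fit> D = %.3f +- %.3f A^2/ns, D_int = %.2f +- ",
                     "%.2f A^2/ns, tau = %.4f +- %.4f ns (gof %.3f)\n"),
              x$D, x$D_se, x$D_int, x$D_int_se, x$tau, x$tau_se,
              x$metrics$gof))
  invisible(x)
}

#' Serialize a fit result to JSON
#'
#' @param fit a `"global_fit"` or `"perq_fit"` object
#' @param path output path
#' @return `path`, invisibly
#' @export
write_fit_json <- function(fit, path) {
  obj <- if (inherits(fit, "global_fit")) {
    list(type = "global",
         parameters = list(D = fit$D, D_int = fit$D_int, tau = fit$tau),
         uncertainties = list(D = fit$D_se, D_int = fit$D_int_se,
                              tau = fit$tau_se),
         per_q = list(q = fit$q, A0 = fit$A0_q, beta = fit$beta_q,
                      solvent_amplitude = fit$solvent_amplitude_q,
                      solvent_width = fit$solvent_width_q),
         metrics = fit$metrics, converged = fit$converged)
  } else {
    list(type = "per_q", per_q = fit$per_q)
  }
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       null = "null", na = "null")
  invisible(path)
}
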