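#' Load a pipeline configuration
#'
#' YAML configuration with blocks: `seed`, `output_dir`, `hydro` (temperature,
#' isotope, salt_molarity, concentration_mg_ml, n_residues), `spectrum_truth`
#' (any [spectrum_truth()] field), `fit` (`mode`: `"per_q"`, `"global"` or
#' `"both"`; `solvent`: a [solvent_policy()] mode; `n_starts`), and
#' `trajectory` (either a `file` in the XYZ-with-box dialect or a synthetic
#' truth block, plus `window`, `cutoffs`, finite-size/isotope options).
#'
#' @param path YAML file path
#' @return configuration list
#' @export
read_pipeline_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg
}

.cfg_hydro <- function(cfg) {
  h <- cfg$hydro
  if (is.null(h)) h <- list()
  hydro_context(temperature = h$temperature %||% 298,
                isotope = h$isotope %||% "D2O",
                salt_molarity = h$salt_molarity %||% 0,
                viscosity = h$viscosity)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

.stage <- function(report, name, expr) {
  t0 <- proc.time()[["elapsed"]]
  res <- tryCatch(list(ok = TRUE, value = expr),
                  error = function(e) list(ok = FALSE, error = conditionMessage(e)))
  res$wall_s <- round(proc.time()[["elapsed"]] - t0, 3)
  message(sprintf("[qensdiff] stage %-18s %s (%.2fs)", name,
                  if (res$ok) "ok" else paste("FAILED:", res$error),
                  res$wall_s))
  report$stages[[name]] <- res
  report
}

#' Run the experiment-emulation workflow
#'
#' Generates (or loads) a QENS spectrum, runs the per-q and/or global
#' jump-diffusion fits, and derives the downstream scalar chain: effective
#' hydrodynamic radius (Stokes-Einstein), inverted radius of gyration
#' (empirical IDP relation), dry and hydrodynamic volume fractions, and the
#' crowding scaling-law prediction.  Numeric tables are written as CSV/JSON
#' under the configured output directory; independent stages keep running if
#' one fails.
#'
#' @param config a configuration list ([read_pipeline_config()]) or a YAML
#'   path
#' @return a `"run_report"` list with per-stage results and provenance
#' @export
run_qens_workflow <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% tempfile("qens_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(workflow = "qens", seed = seed, out_dir = out_dir,
                 package_version = as.character(utils::packageVersion("qensdiff")),
                 config_hash = .config_hash(config), stages = list())
  ctx <- .cfg_hydro(config)

  # spectrum: synthetic block or CSV file
  report <- .stage(report, "spectrum", {
    if (!is.null(config$spectrum_file)) {
      read_spectrum_csv(config$spectrum_file)
    } else {
      tr_args <- config$spectrum_truth %||% list()
      tr_args$seed <- tr_args$seed %||% seed
      truth <- do.call(spectrum_truth, tr_args)
      sp <- generate_spectrum(truth)
      write_spectrum_csv(sp, file.path(out_dir, "spectrum.csv"))
      sp
    }
  })
  if (!report$stages$spectrum$ok) return(.finish_report(report))
  sp <- report$stages$spectrum$value

  fit_cfg <- config$fit %||% list()
  mode <- fit_cfg$mode %||% "both"
  policy <- solvent_policy(fit_cfg$solvent %||% "fixed_width",
                           width = fit_cfg$solvent_width,
                           D_solvent = fit_cfg$D_solvent %||% 187)
  n_starts <- fit_cfg$n_starts %||% 1L

  perq <- NULL
  if (mode %in% c("per_q", "both")) {
    report <- .stage(report, "fit_per_q", {
      pf <- fit_per_q(sp, policy, n_starts = n_starts, seed = seed)
      utils::write.csv(pf$per_q, file.path(out_dir, "per_q_fit.csv"),
                       row.names = FALSE)
      pf
    })
    if (report$stages$fit_per_q$ok) perq <- report$stages$fit_per_q$value
  }
  if (mode %in% c("global", "both")) {
    report <- .stage(report, "fit_global", {
      gf <- fit_global(sp, policy, n_starts = n_starts, seed = seed,
                       perq = perq)
      write_fit_json(gf, file.path(out_dir, "global_fit.json"))
      gf
    })
  }

  # scalar chain from the fitted (or configured) apparent diffusion
  report <- .stage(report, "hydro_chain", {
    D <- if (!is.null(config$hydro$D_apparent)) config$hydro$D_apparent
         else if (isTRUE(report$stages$fit_global$ok))
           report$stages$fit_global$value$D
         else extract_D_from_gamma(perq$per_q$gamma, perq$per_q$q,
                                   perq$per_q$gamma_se)$value
    N <- config$hydro$n_residues %||% 24
    c_p <- config$hydro$concentration_mg_ml %||% 50
    nu_p <- config$hydro$nu_p %||% 0.7023
    R_eff <- stokes_einstein_radius(D, ctx)
    R_g_inv <- tryCatch(nygaard_rg_inverse(R_eff, N), error = function(e) NA)
    phi <- volume_fraction(c_p, nu_p)
    R_g_dilute <- config$hydro$R_g %||% 13.8
    R_h <- nygaard_rh(R_g_dilute, N)
    phi_h <- hydrodynamic_volume_fraction(phi, R_h, R_g_dilute)
    tab <- data.frame(
      quantity = c("D_apparent_A2ns", "eta_mPas", "R_eff_A", "R_g_inverted_A",
                   "phi_dry", "R_h_from_Rg_A", "phi_h",
                   "D_crowding_scaled_A2ns"),
      value = c(D, ctx$viscosity, R_eff, R_g_inv, phi, R_h, phi_h,
                crowding_scale(D, phi_h)))
    utils::write.csv(tab, file.path(out_dir, "hydro_chain.csv"),
                     row.names = FALSE)
    tab
  })
  .finish_report(report)
}

#' Run the simulation-emulation workflow
#'
#' Loads (or generates) a multi-chain trajectory, computes per-chain and
#' ensemble diffusion over the configured MSD window with R^2 diagnostics,
#' applies the finite-size and isotope corrections, and derives cluster
#' statistics at both cutoffs, per-frame radii of gyration, the reduced
#' diffusion distribution, and the EISF.
#'
#' @param config a configuration list or YAML path
#' @return a `"run_report"` list
#' @export
run_traj_workflow <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  seed <- config$seed %||% 1L
  out_dir <- config$output_dir %||% tempfile("traj_run_")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  report <- list(workflow = "trajectory", seed = seed, out_dir = out_dir,
                 package_version = as.character(utils::packageVersion("qensdiff")),
                 config_hash = .config_hash(config), stages = list())
  ctx <- .cfg_hydro(config)
  tcfg <- config$trajectory %||% list()

  report <- .stage(report, "trajectory", {
    if (!is.null(tcfg$file)) {
      read_xyz_trajectory(tcfg$file)
    } else {
      truth <- brownian_system_truth(
        n_chains = tcfg$n_chains %||% 10L, D_t = tcfg$D_t %||% 15,
        box_edge = tcfg$box_edge %||% 100, dt = tcfg$dt %||% 0.1,
        n_steps = tcfg$n_steps %||% 200L, seed = tcfg$seed %||% seed)
      tr <- generate_brownian_chains(truth)
      write_xyz_trajectory(tr, file.path(out_dir, "trajectory.xyz"))
      tr
    }
  })
  if (!report$stages$trajectory$ok) return(.finish_report(report))
  traj <- report$stages$trajectory$value
  window <- unlist(tcfg$window %||% c(0, 4.6))

  report <- .stage(report, "diffusion", {
    res <- diffusion_from_trajectories(traj, window = window)
    est <- res$estimate
    if (isTRUE(tcfg$finite_size %||% TRUE)) {
      eta_sim <- tcfg$eta_sim %||% viscosity_water(ctx$temperature, "H2O")
      est <- yeh_hummer_correct(est, L = traj$box_edge, eta = eta_sim,
                                temperature = ctx$temperature,
                                lattice = tcfg$lattice %||% "cubic")
    }
    if (isTRUE(tcfg$isotope_rescale %||% TRUE)) {
      est <- isotope_rescale(est, ctx$temperature)
    }
    tab <- data.frame(chain = seq_along(res$per_chain),
                      D_t_A2ns = res$per_chain)
    utils::write.csv(tab, file.path(out_dir, "per_chain_diffusion.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(D_raw = res$estimate$value, D_corrected = est$value,
           uncertainty = est$uncertainty, corrections = est$corrections,
           window_ns = window, seed = seed),
      file.path(out_dir, "diffusion.json"), auto_unbox = TRUE, digits = NA)
    list(raw = res, corrected = est)
  })

  if (length(unique(traj$chain_id)) >= 2) {
    report <- .stage(report, "clusters", {
      frames <- tcfg$cluster_frames %||%
        unique(round(seq(1, length(traj$times),
                         length.out = min(20, length(traj$times)))))
      st <- cluster_statistics(traj, cutoffs = unlist(tcfg$cutoffs %||% c(6, 7)),
                               frames = frames)
      utils::write.csv(st, file.path(out_dir, "cluster_stats.csv"),
                       row.names = FALSE)
      st
    })
  }

  report <- .stage(report, "rg_distribution", {
    rg <- rg_series(traj, chain = unique(traj$chain_id)[1])
    out <- list(rg = rg)
    if (all(rg > 0)) {
      dist <- dt_distribution_from_rg(rg, tcfg$n_residues %||% 24, ctx)
      out$reduced <- dist$reduced
      utils::write.csv(data.frame(frame = seq_along(rg), rg_A = rg,
                                  reduced_Dt = dist$reduced),
                       file.path(out_dir, "rg_series.csv"), row.names = FALSE)
    }
    out
  })

  report <- .stage(report, "eisf", {
    tr_un <- if (traj$wrapped) unwrap_trajectory(traj) else traj
    qv <- tcfg$eisf_q %||% seq(0.2, 1.8, by = 0.2)
    ei <- eisf_from_trajectory(tr_un, qv,
                               n_orientations = tcfg$n_orientations %||% 32L,
                               remove_com = tcfg$remove_com %||% TRUE,
                               seed = seed)
    utils::write.csv(ei, file.path(out_dir, "eisf.csv"), row.names = FALSE)
    ei
  })
  .finish_report(report)
}

.config_hash <- function(config) {
  s <- jsonlite::toJSON(config, auto_unbox = TRUE, digits = NA)
  # small rolling hash; provenance only, not cryptographic
  sum(utf8ToInt(s) * seq_along(utf8ToInt(s))) %% 2147483647
}

.finish_report <- function(report) {
  report$ok <- all(vapply(report$stages, `[[`, TRUE, "ok"))
  summary_path <- file.path(report$out_dir, "run_report.json")
  slim <- report
  slim$stages <- lapply(report$stages, function(s) {
    s$value <- NULL
    s
  })
  jsonlite::write_json(slim, summary_path, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  class(report) <- "run_report"
  report
}

#' @export
print.run_report <- function(x, ...) {
  cat(sprintf("<run_report> %s workflow, seed %d, %s\n", x$workflow, x$seed,
              if (x$ok) "all stages ok" else "WITH FAILURES"))
  for (nm in names(x$stages)) {
    s <- x$stages[[nm]]
    cat(sprintf("  %-18s %s (%.2fs)\n", nm,
                if (s$ok) "ok" else paste("failed:", s$error), s$wall_s))
  }
  invisible(x)
}
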