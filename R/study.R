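#' Run the package's reference virtual-patient study
#'
#' Executes the standard comparison suite on one synthetic patient: isotropic
#' and anisotropic growth (A = 0, 25, 50) with heterogeneous stiffness, the
#' region-averaged constant-stiffness control, and vessel-wall pore sweeps
#' (100/200/300 nm) with drug sizes 2/70/150 nm riding on the A = 25 run.
#' All runs share one mesh and one virtual patient, so differences between
#' them isolate the modelling contrast of interest. Derived metrics mirror
#' the analysis of such studies: Dice overlaps of deformed tumor shapes,
#' sphericity, intratumoral mean/SD of vascular density and internalized
#' drug, angular asymmetry, and the interstitial-pressure plateau across
#' pore sizes.
#'
#' @param seed integer; seeds the virtual patient.
#' @param config base configuration; the study varies `growth$A`,
#'   `wall$pore_nm`, `drug$size_nm` and the constant-modulus switch on top
#'   of it.
#' @param verbose print per-run progress.
#' @return list with `runs` (named list of `gm_sim`) and `metrics`
#'   (named numeric list).
#' @export
reference_study <- function(seed = 1, config = simulation_config(),
                            verbose = FALSE) {
  cfg <- function(...) {
    over <- utils::modifyList(unclass(config), list(...))
    over <- utils::modifyList(over, list(patient = list(seed = as.integer(seed))))
    do.call(simulation_config, over)
  }
  base <- cfg()
  geo <- base$geometry
  shells <- geo$shells
  if (is.null(shells)) shells <- ball_shells(geo$tumor_radius, geo$outer_radius)
  mesh <- ball_mesh(shells, geo$subdiv, geo$tumor_radius)
  patient <- virtual_patient(base)
  run <- function(label, ..., constant_modulus = FALSE) {
    if (verbose) message("run: ", label)
    run_simulation(cfg(...), patient = patient, mesh = mesh,
                   constant_modulus = constant_modulus)
  }
  runs <- list(
    het_a25 = run("het A=25, pore 200, sizes 2/70/150",
                  growth = list(A = 25),
                  drug = list(size_nm = c(2, 70, 150))),
    het_a0 = run("het A=0", growth = list(A = 0)),
    het_a50 = run("het A=50", growth = list(A = 50)),
    const_a0 = run("const A=0", growth = list(A = 0), constant_modulus = TRUE),
    het_a25_p100 = run("het A=25, pore 100", growth = list(A = 25),
                       wall = list(pore_nm = 100)),
    het_a25_p300 = run("het A=25, pore 300", growth = list(A = 25),
                       wall = list(pore_nm = 300))
  )

  # two-regime IFP at reference vasculature (uncompressed Sv0) on the
  # undeformed domain: isolates the pore-size effect
  n <- nrow(mesh$nodes)
  tum_el <- mesh$region == "tumor"
  nr <- sqrt(rowSums(mesh$nodes^2))
  fl <- base$fluid
  wl <- base$wall
  Sv0 <- base$vascular$S_v0_per_mm
  Lp_host <- wall_transport(effective_gamma(wl, fl$host_pore_nm),
                            fl$host_pore_nm / 2 * 1e-6, wl$eta_Pa_s,
                            wl$L_vw_mm, 1e-5, 0)$L_p
  ops <- fem_operators(mesh)
  ifp_core <- vapply(c(100, 200, 300), function(pore) {
    Lp_t <- wall_transport(effective_gamma(wl, pore), pore / 2 * 1e-6,
                           wl$eta_Pa_s, wl$L_vw_mm, 1e-5, 0)$L_p
    f <- solve_ifp(mesh, rep(Sv0, n),
                   list(L_p = ifelse(tum_el, Lp_t, Lp_host), p_v = fl$p_v_Pa),
                   list(L_pl = fl$L_pl_mm_Pa_s, S_vl = fl$S_vl_per_mm,
                        p_vl = fl$p_vl_Pa),
                   fl$k_th_mm2_Pa_s, ops = ops)
    mean(f$p_i[nr < mesh$tumor_radius / 2])
  }, numeric(1))

  dtab <- runs$het_a25$summary$drug_table
  metrics <- list(
    n_nodes = nrow(mesh$nodes),
    tumor_volume_cm3 = runs$het_a25$shape$volume / 1000,
    dice_a25_vs_a50 = shape_dice(runs$het_a25$shape, runs$het_a50$shape),
    dice_a0_vs_a25 = shape_dice(runs$het_a0$shape, runs$het_a25$shape),
    sphericity_a0 = runs$het_a0$shape$sphericity,
    sphericity_a25 = runs$het_a25$shape$sphericity,
    sv_mean_het = unname(runs$het_a0$summary$vascular["mean"]),
    sv_sd_het = unname(runs$het_a0$summary$vascular["sd"]),
    sv_mean_const = unname(runs$const_a0$summary$vascular["mean"]),
    sv_sd_const = unname(runs$const_a0$summary$vascular["sd"]),
    sv_sd_ratio = unname(runs$het_a0$summary$vascular["sd"] /
                         runs$const_a0$summary$vascular["sd"]),
    drug_asymmetry_het = runs$het_a0$summary$drug_asymmetry,
    drug_asymmetry_const = runs$const_a0$summary$drug_asymmetry,
    drug_asymmetry_ratio = runs$het_a0$summary$drug_asymmetry /
      max(runs$const_a0$summary$drug_asymmetry, 1e-12),
    drug_mean_2nm = dtab$mean[dtab$size_nm == 2],
    drug_mean_70nm = dtab$mean[dtab$size_nm == 70],
    drug_mean_150nm = dtab$mean[dtab$size_nm == 150],
    drug_sd_pore100 = unname(runs$het_a25_p100$summary$drug["sd"]),
    drug_sd_pore200 = dtab$sd[dtab$size_nm == 2],
    drug_sd_pore300 = unname(runs$het_a25_p300$summary$drug["sd"]),
    fraction_above_halfplasma = dtab$fraction_above[dtab$size_nm == 2],
    ifp_core_frac_pv_pore100 = ifp_core[1] / fl$p_v_Pa,
    ifp_core_frac_pv_pore200 = ifp_core[2] / fl$p_v_Pa,
    ifp_core_frac_pv_pore300 = ifp_core[3] / fl$p_v_Pa)
  list(runs = runs, metrics = metrics)
}
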