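#' Simulation configuration
#'
#' Builds the full nested parameter list for [run_simulation()], recursively
#' merging user overrides into the package defaults. Units are stated in the
#' field names where they are not obvious; "day" is simulation time (growth
#' time is calibrated to the time step, not to patient chronology). The
#' defaults define the package's reference study: a 5 mm seed in a 50 mm
#' host ball, 43 simulated days, drug injected at day 41 and read out at
#' day 43. All biophysical constants are package assumptions documented in
#' the methods vignette; none are fitted quantities.
#'
#' @param ... named blocks overriding defaults, e.g.
#'   `growth = list(A = 0)`.
#' @return nested list of class `gm_config`.
#' @export
simulation_config <- function(...) {
  defaults <- list(
    geometry = list(tumor_radius = 5, outer_radius = 50, subdiv = 2,
                    shells = NULL),
    time = list(dt_day = 0.5, duration_day = 43, t_inject_day = 41,
                t_readout_day = 43, drug_dt_s = 60),
    patient = list(seed = 1L,
                   host_mean_Pa = 1500, host_sd_Pa = 300, host_corr_mm = 8,
                   host_extent_mm = 55, host_spacing_mm = 2.75,
                   tumor_mean_Pa = 1100, tumor_sd_Pa = 400,
                   tumor_corr_mm = 2.5, tumor_bbox_mm = c(20, 16, 12),
                   tumor_grid_n = 17L,
                   loss_to_storage_ratio = 0.4, clip_floor_Pa = 100,
                   dti_base_mm2_day = 0.02, dti_anisotropy = 0.3,
                   dti_corr_mm = 6),
    material = list(omega_rad_s = 2 * pi * 50, k_bulk_Pa = 5000,
                    isochoric = TRUE),
    growth = list(A = 25, k1_per_day = 0.035, k2 = 0.25,
                  rho_cell_per_day = 0.02),
    fluid = list(k_th_mm2_Pa_s = 4e-7, p_v_Pa = 2000,
                 L_pl_mm_Pa_s = 2.3e-9, S_vl_per_mm = 7, p_vl_Pa = 0,
                 host_pore_nm = 20),
    vascular = list(S_v0_per_mm = 7, sigma_half_Pa = 1000),
    oxygen = list(D_ox_mm2_s = 1e-3, A_ox_per_s = 4e-4, k_ox = 0.15,
                  c_iox = 1, Per_ox_mm_s = 2e-4),
    wall = list(gamma = 1e-3, eta_Pa_s = 3e-3, L_vw_mm = 5e-3,
                pore_nm = 200, pore_reference_nm = 200,
                pore_model = "fixed_density"),
    drug = list(size_nm = 2, Phi = 0.3, c_e = 1, k_on_per_s = 1e-3,
                k_off_per_s = 1e-4, k_int_per_s = 1e-5, k_d_day = 0.25,
                interstitial_fraction = 0.25, threshold = 0.5)
  )
  over <- list(...)
  merge_rec <- function(a, b) {
    for (nm in names(b)) {
      a[[nm]] <- if (is.list(a[[nm]]) && is.list(b[[nm]]))
        merge_rec(a[[nm]], b[[nm]]) else b[[nm]]
    }
    a
  }
  cfg <- merge_rec(defaults, over)
  tm <- cfg$time
  if (!(tm$t_inject_day >= 0 && tm$t_readout_day >= tm$t_inject_day &&
        tm$duration_day >= tm$t_readout_day))
    stop("config times must satisfy duration >= readout >= injection >= 0")
  structure(cfg, class = "gm_config")
}

#' Read / write a simulation configuration as YAML
#' @param path file path.
#' @return a `gm_config` (for `read_config_yaml`).
#' @export
read_config_yaml <- function(path) {
  do.call(simulation_config, yaml::read_yaml(path))
}

#' @rdname read_config_yaml
#' @param config a `gm_config`.
#' @export
write_config_yaml <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' Write a virtual patient to NIfTI with a JSON provenance sidecar
#'
#' @param patient output of [virtual_patient()].
#' @param path base path; channel files get suffixes, the sidecar is
#'   `<path>_provenance.json`.
#' @return invisibly, vector of files written.
#' @export
write_virtual_patient <- function(patient, path) {
  files <- c(write_voxel_field(patient$host, paste0(path, "_host")),
             write_voxel_field(patient$tumor, paste0(path, "_tumor")),
             write_voxel_field(patient$dti, paste0(path, "_dti")))
  side <- paste0(path, "_provenance.json")
  jsonlite::write_json(list(
    generator = "gliomech synthetic virtual patient (not real MRE/DTI data)",
    tumor_bbox = patient$tumor_bbox,
    seed_radius_mm = patient$seed_spec$radius,
    files = as.list(files)), side, auto_unbox = TRUE, pretty = TRUE)
  invisible(c(files, provenance = side))
}

#' Effective pore area fraction of the vessel wall
#'
#' Under the default `"fixed_density"` pore model the number of wall pores
#' per unit area is held fixed while their size varies, so the area fraction
#' scales with the pore radius squared relative to the reference pore size;
#' `"fixed_fraction"` keeps the area fraction constant instead. The fixed-
#' density model makes transvascular delivery grow with pore size even for
#' small solutes, the behaviour leaky tumor vessels display.
#'
#' @param wall the `wall` block of a [simulation_config()].
#' @param pore_nm pore diameter, nm.
#' @return dimensionless area fraction.
#' @export
effective_gamma <- function(wall, pore_nm) {
  if (identical(wall$pore_model, "fixed_fraction")) return(wall$gamma)
  wall$gamma * (pore_nm / wall$pore_reference_nm)^2
}

# per-element material fields from nodal patient data
.element_materials <- function(mesh, mat, config, constant_modulus = FALSE) {
  n <- nrow(mesh$nodes)
  G_node <- mat$G
  if (constant_modulus) {
    # region-averaged modulus: tumor average in the seed, host average outside
    tn <- tumor_nodes(mesh)
    tmask <- seq_len(n) %in% tn
    wt <- .lumped_mass(n, mesh$tets, mesh$vol)
    G_node <- ifelse(tmask,
                     sum((wt * mat$G)[tmask]) / sum(wt[tmask]),
                     sum((wt * mat$G)[!tmask]) / sum(wt[!tmask]))
  }
  G_elem <- node_to_elem(mesh, G_node)
  dti_elem <- sapply(seq_len(ncol(mat$dti)), function(j)
    node_to_elem(mesh, mat$dti[, j]))
  if (constant_modulus) {
    # the control is fully radially symmetric: isotropic mean diffusivity too
    dbar <- mean((dti_elem[, 1] + dti_elem[, 3] + dti_elem[, 6]) / 3)
    dti_elem <- matrix(rep(c(dbar, 0, dbar, 0, 0, dbar), each = nrow(dti_elem)),
                       nrow(dti_elem))
  }
  list(G_node = G_node, G_elem = G_elem,
       k_elem = rep(config$material$k_bulk_Pa, nrow(mesh$tets)),
       dti_elem = dti_elem)
}

#' Run the coupled tumor growth / perfusion / drug delivery simulation
#'
#' Staggered fixed-point coupling per growth step: oxygen-limited growth rate
#' and stress-biased anisotropy multipliers update the growth stretches; the
#' quasi-static mechanics is re-solved; interstitial fluid pressure, oxygen
#' and cell density follow; finally the bulk stress compresses the
#' vasculature for the next step. Between the injection and readout times a
#' drug sub-loop advances the free/bound/internalized fields on the frozen
#' within-step flow and vasculature.
#'
#' @param config a [simulation_config()].
#' @param patient optional [virtual_patient()] bundle (generated from the
#'   config seed when `NULL`).
#' @param constant_modulus replace the heterogeneous shear modulus by its
#'   region averages (the uniform-elasticity control case).
#' @param mesh optional pre-built [ball_mesh()] (must match the geometry
#'   block).
#' @param verbose print per-step progress.
#' @return object of class `gm_sim`; see Details.
#' @details The returned list carries `mesh`, `config`, final per-node fields
#'   (`T_cel`, `c_ox`, `p_i`, `Sv`, drug pools), per-element `sigma`,
#'   `sigma_bulk`, `lambda_g`, `J`, displacement `u`, the deformed tumor
#'   shape ([tumor_shape()]), a per-step `history` data frame and `summary`
#'   statistics (intratumoral mean/SD of vascular density and internalized
#'   drug, fraction above the drug threshold, asymmetry).
#' @export
run_simulation <- function(config = simulation_config(), patient = NULL,
                           constant_modulus = FALSE, mesh = NULL,
                           verbose = FALSE) {
  geo <- config$geometry
  if (is.null(mesh)) {
    shells <- geo$shells
    if (is.null(shells)) shells <- ball_shells(geo$tumor_radius, geo$outer_radius)
    mesh <- ball_mesh(shells, geo$subdiv, geo$tumor_radius)
  }
  if (is.null(patient)) patient <- virtual_patient(config)
  mat <- patient_on_mesh(patient, mesh, config$material$omega_rad_s)
  em <- .element_materials(mesh, mat, config, constant_modulus)
  ops <- fem_operators(mesh)
  n <- nrow(mesh$nodes)
  m <- nrow(mesh$tets)
  tumor_elem <- mesh$region == "tumor"
  tumor_node <- seq_len(n) %in% tumor_nodes(mesh)

  # wall coefficients: tumor pores in the seed, tight host pores elsewhere.
  # Several drug sizes can ride on one simulation: they share the flow and
  # vasculature history and differ only in their wall/diffusion coefficients.
  wl <- config$wall
  pore_radius_mm <- wl$pore_nm / 2 * 1e-6
  host_pore_mm <- config$fluid$host_pore_nm / 2 * 1e-6
  sizes <- config$drug$size_nm
  gamma_tum <- effective_gamma(wl, wl$pore_nm)
  gamma_host <- effective_gamma(wl, config$fluid$host_pore_nm)
  drug_cases <- lapply(sizes, function(size_nm) {
    drug_radius_mm <- size_nm / 2 * 1e-6
    D0 <- stokes_einstein_D0(drug_radius_mm, eta = wl$eta_Pa_s)
    wt_tum <- wall_transport(gamma_tum, pore_radius_mm, wl$eta_Pa_s, wl$L_vw_mm,
                             D0, min(drug_radius_mm / pore_radius_mm, 1))
    wt_host <- wall_transport(gamma_host, host_pore_mm, wl$eta_Pa_s, wl$L_vw_mm,
                              D0, min(drug_radius_mm / host_pore_mm, 1))
    list(size_nm = size_nm, D0 = D0,
         L_p_node = ifelse(tumor_node, wt_tum$L_p, wt_host$L_p),
         Per_node = ifelse(tumor_node, wt_tum$Per, wt_host$Per),
         sigf_node = ifelse(tumor_node, wt_tum$sigma_f, wt_host$sigma_f))
  })
  # interstitial fluid exchange (IFP sources) uses the wall conductivity of
  # plasma, independent of the drug size; region-wise per element so the
  # interface is represented consistently
  wt_tum_pl <- wall_transport(gamma_tum, pore_radius_mm, wl$eta_Pa_s,
                              wl$L_vw_mm, 1e-5, 0)
  wt_host_pl <- wall_transport(gamma_host, host_pore_mm, wl$eta_Pa_s,
                               wl$L_vw_mm, 1e-5, 0)
  L_p_elem <- ifelse(tumor_elem, wt_tum_pl$L_p, wt_host_pl$L_p)
  L_p_node <- ifelse(tumor_node, wt_tum_pl$L_p, wt_host_pl$L_p)

  fl <- config$fluid
  ox <- config$oxygen
  gr <- config$growth
  va <- config$vascular
  dr <- config$drug
  Sv0 <- va$S_v0_per_mm

  # state
  lambda_g <- matrix(1, m, 3)
  T_cel <- as.numeric(tumor_node)
  c_ox <- rep(ox$c_iox, n)
  Sv <- rep(Sv0, n)
  u <- matrix(0, n, 3)
  sigma <- matrix(0, m, 6)
  sigma_bulk <- numeric(m)
  Jel <- rep(1, m)
  drug_state <- lapply(drug_cases, function(dc)
    list(c_f = numeric(n), c_b = numeric(n), c_int = numeric(n)))
  chol_drug <- vector("list", length(drug_cases))
  fluid <- solve_ifp(mesh, Sv, list(L_p = L_p_elem, p_v = fl$p_v_Pa),
                     list(L_pl = fl$L_pl_mm_Pa_s, S_vl = fl$S_vl_per_mm,
                          p_vl = fl$p_vl_Pa),
                     fl$k_th_mm2_Pa_s, ops = ops)

  dt <- config$time$dt_day
  nsteps <- max(0L, round(config$time$duration_day / dt))
  hist <- vector("list", nsteps)
  growth_params <- list(k1 = gr$k1_per_day, k2 = gr$k2,
                        rho_cell = gr$rho_cell_per_day)
  ox_params <- list(D_ox = ox$D_ox_mm2_s * 86400,  # mm^2/day for steady op
                    A_ox = ox$A_ox_per_s * 86400,
                    k_ox = ox$k_ox, c_iox = ox$c_iox,
                    Per_ox = ox$Per_ox_mm_s * 86400)
  drug_params <- lapply(drug_cases, function(dc)
    list(D_f = dr$interstitial_fraction * dc$D0,
         k_on = dr$k_on_per_s, k_off = dr$k_off_per_s,
         k_int = dr$k_int_per_s, c_e = dr$c_e, Phi = dr$Phi))

  for (s in seq_len(nsteps)) {
    t0 <- (s - 1) * dt
    t1 <- s * dt
    # growth kinetics at frozen stress/oxygen
    cox_e <- node_to_elem(mesh, c_ox)
    Tc_e <- node_to_elem(mesh, T_cel)
    r_g <- growth_rate(pmax(cox_e, 0), pmax(Tc_e, 0), gr$k1_per_day, gr$k2)
    Gam <- anisotropy_multipliers(normal_stresses(sigma), gr$A,
                                  config$material$k_bulk_Pa)
    upd <- tumor_elem
    lambda_g[upd, ] <- step_growth_stretches(lambda_g[upd, , drop = FALSE],
                                             r_g[upd],
                                             Gam[upd, , drop = FALSE], dt)
    # mechanics
    sol <- solve_displacement(mesh, em$G_elem, em$k_elem, lambda_g,
                              p_node = fluid$p_i, bc = "fixed_outer", u0 = u,
                              isochoric = config$material$isochoric)
    u <- sol$u; sigma <- sol$sigma; sigma_bulk <- sol$sigma_bulk; Jel <- sol$J
    # fluid
    fluid <- solve_ifp(mesh, Sv, list(L_p = L_p_elem, p_v = fl$p_v_Pa),
                       list(L_pl = fl$L_pl_mm_Pa_s, S_vl = fl$S_vl_per_mm,
                            p_vl = fl$p_vl_Pa),
                       fl$k_th_mm2_Pa_s, ops = ops)
    # oxygen (quasi-steady; velocities mm/s -> mm/day)
    c_ox <- solve_oxygen_steady(fluid$v_f * 86400, Sv, T_cel, mesh, ox_params,
                                c_init = c_ox, ops = ops)
    # cells
    T_cel <- step_cells(T_cel, em$dti_elem, c_ox, mesh, growth_params, dt,
                        ops = ops, tumor_node = tumor_node)
    # vasculature from fresh stress (nodal bulk stress)
    sb_node <- elem_to_node(mesh, sigma_bulk)
    Sv <- functional_density(vessel_compression(sb_node, va$sigma_half_Pa), Sv0)
    # drug sub-loop over the overlap of [t0, t1] with the delivery window
    wa <- max(t0, config$time$t_inject_day)
    wb <- min(t1, config$time$t_readout_day)
    if (wb > wa + 1e-12) {
      nsub <- max(1L, round((wb - wa) * 86400 / config$time$drug_dt_s))
      hsub <- (wb - wa) * 86400 / nsub
      conv_drug <- if (any(fluid$v_f != 0)) ops$convection(fluid$v_f) else NULL
      for (q in seq_len(nsub)) {
        tq <- wa + (q - 1) * hsub / 86400
        Civ <- vascular_concentration(tq, config$time$t_inject_day, dr$k_d_day)
        for (ci in seq_along(drug_cases)) {
          dc <- drug_cases[[ci]]
          Qs <- starling_flux(dc$Per_node, Sv, Civ, drug_state[[ci]]$c_f,
                              dc$L_p_node, fl$p_v_Pa, fluid$p_i, dc$sigf_node)
          drug_state[[ci]] <- step_drug(drug_state[[ci]], fluid$v_f, Qs, mesh,
                                        drug_params[[ci]], hsub, ops = ops,
                                        chol_A = chol_drug[[ci]],
                                        conv = conv_drug)
          chol_drug[[ci]] <- attr(drug_state[[ci]], "chol_A")
        }
      }
    }
    vols_def <- mesh$vol * Jel
    hist[[s]] <- data.frame(
      time = t1,
      tumor_volume = sum(vols_def[tumor_elem]),
      mean_bulk_stress = region_stats(sigma_bulk, tumor_elem, vols_def)["mean"],
      mean_Sv = region_stats(node_to_elem(mesh, Sv), tumor_elem, vols_def)["mean"],
      mean_c_ox = region_stats(node_to_elem(mesh, c_ox), tumor_elem, vols_def)["mean"],
      mean_T_cel = region_stats(node_to_elem(mesh, T_cel), tumor_elem, vols_def)["mean"])
    if (verbose)
      message(sprintf("day %5.1f  V_tumor %8.1f mm^3  <tr sigma> %8.1f Pa",
                      t1, hist[[s]]$tumor_volume, hist[[s]]$mean_bulk_stress))
  }

  vols_def <- mesh$vol * Jel
  Sv_e <- node_to_elem(mesh, Sv)
  drug_summary <- do.call(rbind, lapply(seq_along(drug_cases), function(ci) {
    ci_e <- node_to_elem(mesh, drug_state[[ci]]$c_int)
    st <- region_stats(ci_e, tumor_elem, vols_def)
    data.frame(size_nm = drug_cases[[ci]]$size_nm,
               mean = st[["mean"]], sd = st[["sd"]],
               fraction_above = fraction_above(ci_e, tumor_elem, dr$threshold,
                                               vols_def),
               asymmetry = angular_asymmetry(ci_e, mesh, vols_def))
  }))
  summary <- list(
    vascular = region_stats(Sv_e, tumor_elem, vols_def),
    drug = c(mean = drug_summary$mean[1], sd = drug_summary$sd[1]),
    drug_table = drug_summary,
    fraction_above = drug_summary$fraction_above[1],
    drug_asymmetry = drug_summary$asymmetry[1],
    Sv_asymmetry = angular_asymmetry(Sv_e, mesh, vols_def))
  structure(list(
    mesh = mesh, config = config, patient = patient,
    constant_modulus = constant_modulus,
    u = u, sigma = sigma, sigma_bulk = sigma_bulk, lambda_g = lambda_g,
    J = Jel, p_i = fluid$p_i, v_f = fluid$v_f, T_cel = T_cel, c_ox = c_ox,
    Sv = Sv, drug = drug_state[[1]], drug_cases = drug_state,
    G_node = em$G_node,
    shape = tumor_shape(mesh, u),
    history = if (nsteps) do.call(rbind, hist) else NULL,
    summary = summary), class = "gm_sim")
}

#' @export
print.gm_sim <- function(x, ...) {
  cat(sprintf("<gm_sim> %s modulus, A = %g, %g simulated days\n",
              if (x$constant_modulus) "constant" else "heterogeneous",
              x$config$growth$A, x$config$time$duration_day))
  cat(sprintf("  tumor volume %.0f mm^3, sphericity %.3f\n",
              x$shape$volume, x$shape$sphericity))
  cat(sprintf("  S_v  mean %.2f /mm, sd %.2f\n",
              x$summary$vascular["mean"], x$summary$vascular["sd"]))
  cat(sprintf("  c_int mean %.4f, sd %.4f; fraction > %g: %.3f\n",
              x$summary$drug["mean"], x$summary$drug["sd"],
              x$config$drug$threshold, x$summary$fraction_above))
  invisible(x)
}
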