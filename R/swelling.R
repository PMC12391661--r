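# Flory-Rehner equilibrium-swelling mesh-size calculator. The mesh size xi
# is the nanometre-scale distance between polymer crosslinks, obtained from
# wet/dry masses of relaxed and swollen gels plus polymer constants; it is
# three orders of magnitude below the micron-scale pores the tracking modules
# measure.

#' Mass swelling ratio
#'
#' `Q_m = (m_wet - m_dry) / m_dry` from the wet and lyophilised (dry) masses
#' of a gel.
#'
#' @param m_wet,m_dry Masses in grams; `m_dry > 0`.
#' @return Dimensionless mass swelling ratio.
#' @export
mass_swelling_ratio <- function(m_wet, m_dry) {
  if (any(m_dry <= 0)) {
    ph_stop("`m_dry` must be positive", "porehull_domain_error")
  }
  (m_wet - m_dry) / m_dry
}

#' Volumetric swelling ratio
#'
#' `Q_v = 1 + (rho_p / rho_s) * (Q_m - 1)` converts the mass swelling ratio
#' into a volume ratio using the polymer and solvent densities.
#'
#' @param Q_m Mass swelling ratio.
#' @param rho_p Polymer density, g/cm^3 (1.125 for PEG).
#' @param rho_s Solvent density, g/cm^3 (1.011 for PBS).
#' @return Dimensionless volumetric swelling ratio.
#' @export
volumetric_swelling_ratio <- function(Q_m, rho_p = 1.125, rho_s = 1.011) {
  assert_positive(rho_p, "rho_p")
  assert_positive(rho_s, "rho_s")
  if (any(Q_m < 0)) {
    ph_stop("`Q_m` must be non-negative", "porehull_domain_error")
  }
  1 + (rho_p / rho_s) * (Q_m - 1)
}

#' Polymer volume fraction
#'
#' `v = 1 / Q_v`: the fraction of the swollen (or relaxed) gel volume
#' occupied by polymer.
#'
#' @param Q_v Volumetric swelling ratio, > 0.
#' @return Volume fraction in (0, 1] for `Q_v >= 1`.
#' @export
polymer_volume_fraction <- function(Q_v) {
  if (any(Q_v <= 0)) {
    ph_stop("`Q_v` must be positive", "porehull_domain_error")
  }
  1 / Q_v
}

#' Molecular weight between crosslinks (Flory-Rehner)
#'
#' Solves the Flory-Rehner equilibrium-swelling relation for the average
#' molecular weight between crosslinks:
#' `1/M_c = 2/M_n - (vbar/V_1) * [ln(1 - v_2s) + v_2s + chi_1 v_2s^2] /
#'   (v_2r * ((v_2s/v_2r)^(1/3) - (v_2s/v_2r)/2))`
#' with `vbar = 1/rho_p` the polymer specific volume (cm^3/g; consistent with
#' `V_1` in mL/mol since mL = cm^3). `M_n` is the number-average molecular
#' weight of the polymer before crosslinking.
#'
#' @param v_2r,v_2s Relaxed and equilibrium (swollen) polymer volume
#'   fractions, both in (0, 1).
#' @param M_n Polymer molecular weight before crosslinking, g/mol.
#' @param rho_p Polymer density, g/cm^3.
#' @param V_1 Molar volume of solvent, mL/mol (18 for water).
#' @param chi_1 Polymer-solvent interaction parameter (0.426 for PEG/water).
#' @return `M_c` in g/mol.
#' @export
flory_rehner_Mc <- function(v_2r, v_2s, M_n, rho_p = 1.125, V_1 = 18,
                            chi_1 = 0.426) {
  for (nm in c("v_2r", "v_2s")) {
    v <- get(nm)
    if (!is.numeric(v) || v <= 0 || v >= 1) {
      ph_stop(sprintf("`%s` must lie strictly between 0 and 1", nm),
              "porehull_domain_error")
    }
  }
  assert_positive(M_n, "M_n")
  assert_positive(rho_p, "rho_p")
  assert_positive(V_1, "V_1")
  vbar <- 1 / rho_p
  ratio <- v_2s / v_2r
  mixing <- log(1 - v_2s) + v_2s + chi_1 * v_2s^2
  elastic <- v_2r * (ratio^(1 / 3) - ratio / 2)
  inv_Mc <- 2 / M_n - (vbar / V_1) * mixing / elastic
  if (inv_Mc <= 0) {
    ph_stop("swelling inconsistent with network model (1/M_c <= 0)",
            "porehull_infeasible")
  }
  1 / inv_Mc
}

#' Mesh size from the crosslink molecular weight
#'
#' `xi = v_2s^(-1/3) * l * sqrt(2 C_n M_c / M_r)`: the root-mean-square
#' end-to-end distance of a network chain, dilated by the swelling.
#'
#' @param v_2s Equilibrium polymer volume fraction.
#' @param M_c Molecular weight between crosslinks, g/mol.
#' @param M_r Repeat-unit molecular weight, g/mol (44 for PEG).
#' @param l Backbone bond length, nm (0.15 for C-C).
#' @param C_n Flory characteristic ratio (4 for PEG).
#' @return Mesh size in nm.
#' @export
mesh_size <- function(v_2s, M_c, M_r = 44, l = 0.15, C_n = 4) {
  assert_positive(v_2s, "v_2s")
  assert_positive(M_c, "M_c")
  assert_positive(M_r, "M_r")
  assert_positive(l, "l")
  assert_positive(C_n, "C_n")
  v_2s^(-1 / 3) * l * sqrt(2 * C_n * M_c / M_r)
}

#' Swelling-assay input
#'
#' Masses of one gel in its relaxed (as-crosslinked) and swollen
#' (equilibrated) wet states plus the dry (lyophilised) masses, and the
#' polymer constants. Defaults are the usual PEG/PBS values.
#'
#' @param m_wet_relaxed,m_wet_swollen Wet masses, g.
#' @param m_dry_relaxed,m_dry_swollen Lyophilised masses of the same
#'   samples, g.
#' @param rho_polymer,rho_solvent Densities, g/cm^3.
#' @param M_n Polymer molecular weight before crosslinking, g/mol.
#' @param M_r Repeat-unit molecular weight, g/mol.
#' @param V_1 Solvent molar volume, mL/mol.
#' @param chi_1 Polymer-solvent interaction parameter.
#' @param bond_length_l Backbone bond length, nm.
#' @param C_n Flory characteristic ratio.
#' @return List of class `swelling_input`.
#' @export
swelling_input <- function(m_wet_relaxed, m_wet_swollen,
                           m_dry_relaxed, m_dry_swollen = m_dry_relaxed,
                           rho_polymer = 1.125, rho_solvent = 1.011,
                           M_n = 20000, M_r = 44, V_1 = 18, chi_1 = 0.426,
                           bond_length_l = 0.15, C_n = 4) {
  for (nm in c("m_wet_relaxed", "m_wet_swollen", "m_dry_relaxed",
               "m_dry_swollen")) {
    assert_positive(get(nm), nm)
  }
  if (m_wet_relaxed < m_dry_relaxed || m_wet_swollen < m_dry_swollen) {
    ph_stop("wet masses must be at least the dry masses",
            "porehull_domain_error")
  }
  structure(list(m_wet_relaxed = m_wet_relaxed, m_wet_swollen = m_wet_swollen,
                 m_dry_relaxed = m_dry_relaxed, m_dry_swollen = m_dry_swollen,
                 rho_polymer = rho_polymer, rho_solvent = rho_solvent,
                 M_n = M_n, M_r = M_r, V_1 = V_1, chi_1 = chi_1,
                 bond_length_l = bond_length_l, C_n = C_n),
            class = "swelling_input")
}

#' Full Flory-Rehner mesh-size chain
#'
#' Chains mass swelling ratio, volumetric swelling ratio and polymer volume
#' fraction for the relaxed and swollen states, then the Flory-Rehner
#' crosslink molecular weight and the mesh size. All intermediates are
#' returned; results depend only on mass ratios.
#'
#' @param input A [swelling_input()].
#' @return List of class `swelling_result` with `Q_m_relaxed`,
#'   `Q_m_swollen`, `Q_v_relaxed`, `Q_v_swollen`, `v_2r`, `v_2s`, `M_c`
#'   (g/mol) and `mesh_size_xi` (nm).
#' @export
mesh_size_pipeline <- function(input) {
  stopifnot(inherits(input, "swelling_input"))
  Qm_r <- mass_swelling_ratio(input$m_wet_relaxed, input$m_dry_relaxed)
  Qm_s <- mass_swelling_ratio(input$m_wet_swollen, input$m_dry_swollen)
  Qv_r <- volumetric_swelling_ratio(Qm_r, input$rho_polymer, input$rho_solvent)
  Qv_s <- volumetric_swelling_ratio(Qm_s, input$rho_polymer, input$rho_solvent)
  v_2r <- polymer_volume_fraction(Qv_r)
  v_2s <- polymer_volume_fraction(Qv_s)
  M_c <- flory_rehner_Mc(v_2r, v_2s, input$M_n, input$rho_polymer,
                         input$V_1, input$chi_1)
  xi <- mesh_size(v_2s, M_c, input$M_r, input$bond_length_l, input$C_n)
  structure(list(Q_m_relaxed = Qm_r, Q_m_swollen = Qm_s,
                 Q_v_relaxed = Qv_r, Q_v_swollen = Qv_s,
                 v_2r = v_2r, v_2s = v_2s, M_c = M_c, mesh_size_xi = xi),
            class = "swelling_result")
}

#' @export
print.swelling_result <- function(x, ...) {
  cat("<swelling_result>\n")
  cat(sprintf("  Q_m (relaxed/swollen): %.4g / %.4g\n",
              x$Q_m_relaxed, x$Q_m_swollen))
  cat(sprintf("  Q_v (relaxed/swollen): %.4g / %.4g\n",
              x$Q_v_relaxed, x$Q_v_swollen))
  cat(sprintf("  v_2r = %.4g, v_2s = %.4g\n", x$v_2r, x$v_2s))
  cat(sprintf("  M_c = %.6g g/mol, mesh size xi = %.4g nm\n",
              x$M_c, x$mesh_size_xi))
  invisible(x)
}
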