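#' Simulation bookkeeping arithmetic
#'
#' Closed-form conversions for the simulation campaign: peptide
#' concentration in a cubic box, discrete-molecular-dynamics (DMD) time
#' units, and Debye-Hueckel screening.  Physical constants are pinned to
#' CODATA 2018 values.
#'
#' @name bookkeeping
NULL

#' @describeIn bookkeeping Molar peptide concentration (mM) of
#'   \code{n_peptides} molecules in a cubic box of edge \code{box_edge_nm}
#'   nanometres: \code{1e3 * n / (N_A * V_dm3)}.
#' @param n_peptides number of peptides.
#' @param box_edge_nm cubic box edge, nm.
#' @return concentration in mM.
#' @examples
#' concentration_mM(20, 10.8)  # ~26 mM
#' @export
concentration_mM <- function(n_peptides, box_edge_nm) {
  if (any(n_peptides <= 0) || any(box_edge_nm <= 0))
    stop("n_peptides and box_edge_nm must be positive")
  v_dm3 <- (box_edge_nm * 1e-8)^3
  1e3 * n_peptides / (.const$N_A * v_dm3)
}

#' @describeIn bookkeeping Cubic box edge (nm) giving a target concentration
#'   for \code{n_peptides} molecules (exact inverse of
#'   \code{concentration_mM}).
#' @param target_mM target concentration, mM.
#' @export
box_edge_for_concentration <- function(n_peptides, target_mM) {
  if (any(n_peptides <= 0) || any(target_mM <= 0))
    stop("n_peptides and target_mM must be positive")
  (1e3 * n_peptides / (.const$N_A * target_mM))^(1 / 3) * 1e8
}

#' @describeIn bookkeeping Convert DMD time units to nanoseconds
#'   (\code{n_units * time_unit_fs * 1e-6}); the DMD time unit is
#'   approximately 50 fs.
#' @param n_units number of DMD time units.
#' @param time_unit_fs duration of one DMD time unit, fs.
#' @examples
#' dmd_units_to_ns(6e6)  # 300 ns
#' @export
dmd_units_to_ns <- function(n_units, time_unit_fs = 50) {
  if (any(n_units < 0)) stop("n_units must be non-negative")
  n_units * time_unit_fs * 1e-6
}

#' @describeIn bookkeeping Ionic strength (mM, 1:1 salt) corresponding to a
#'   Debye screening length: \code{I = eps_r eps_0 k_B T / (2 N_A e^2
#'   lambda^2)}.  A 10 Angstrom screening length at 300 K in water
#'   (eps_r 78.5) corresponds to roughly 93 mM, i.e. ~100 mM physiological
#'   salt.
#' @param screening_length_A Debye length, Angstrom.
#' @param temperature_K temperature, K.
#' @param rel_permittivity relative permittivity of the solvent.
#' @export
debye_ionic_strength <- function(screening_length_A, temperature_K = 300,
                                 rel_permittivity = 78.5) {
  if (any(screening_length_A <= 0) || any(temperature_K <= 0) ||
      any(rel_permittivity <= 0))
    stop("all inputs must be positive")
  lam <- screening_length_A * 1e-10
  i_mol_m3 <- rel_permittivity * .const$eps0 * .const$k_B_SI *
    temperature_K / (2 * .const$N_A * .const$e_charge^2 * lam^2)
  i_mol_m3  # mol/m^3 == mmol/L == mM
}

#' @describeIn bookkeeping Accumulated campaign sampling in microseconds:
#'   \code{n_runs * run_length_ns / 1000}.
#' @param n_runs number of independent runs.
#' @param run_length_ns length of each run, ns.
#' @examples
#' campaign_total_us(10, 300)  # 3 us
#' @export
campaign_total_us <- function(n_runs, run_length_ns) {
  if (any(n_runs <= 0) || any(run_length_ns < 0))
    stop("n_runs must be positive and run_length_ns non-negative")
  n_runs * run_length_ns / 1000
}

#' Campaign summary table
#'
#' Expands a campaign specification into a bookkeeping table: box edge,
#' concentration, per-run length and accumulated time per system.
#'
#' @param n_peptides vector of system sizes.
#' @param box_edge_nm vector of cubic box edges (nm), recycled.
#' @param n_runs runs per system, recycled.
#' @param run_length_ns run length (ns), recycled.
#' @return data.frame with one row per system.
#' @export
campaign_summary <- function(n_peptides, box_edge_nm, n_runs = 10,
                             run_length_ns = 300) {
  data.frame(
    n_peptides = n_peptides,
    box_edge_nm = box_edge_nm,
    concentration_mM = concentration_mM(n_peptides, box_edge_nm),
    n_runs = n_runs,
    run_length_ns = run_length_ns,
    total_us = campaign_total_us(n_runs, run_length_ns))
}
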