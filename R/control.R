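#' Analysis parameters
#'
#' Collects every numeric threshold used by the analysis stages in one place.
#' Defaults are the values used throughout the package: a backbone hydrogen
#' bond requires an N--O distance of at most 3.5 Angstrom and an N-H...O angle
#' (measured at the hydrogen) of at least 120 degrees; two peptides are in
#' contact when any inter-molecular heavy-atom pair is within 5.5 Angstrom
#' (0.55 nm); a beta-sheet pairing needs at least two consecutive strand
#' residues per chain linked by at least two backbone hydrogen bonds; a closed
#' beta-barrel needs at least four strands.
#'
#' @param equilibrium_fraction Fraction of the trajectory tail used as the
#'   equilibrium analysis window (default 0.5, i.e. the second half).
#' @param contact_cutoff Heavy-atom contact cutoff, Angstrom.
#' @param hbond_dist Maximum backbone N--O distance, Angstrom.
#' @param hbond_angle Minimum N-H...O angle at the hydrogen, degrees.
#' @param min_ladder_hbonds Minimum number of inter-chain backbone hydrogen
#'   bonds for a beta-sheet pairing between two chains.
#' @param min_consecutive_E Minimum run of consecutive strand (E) residues a
#'   chain must contribute to a pairing.
#' @param barrel_min_size Minimum strand count for a closed sheet to count as
#'   a barrel.
#' @param pmf_temperature Temperature for the free-energy transform, Kelvin.
#' @param pmf_beta_bin Bin width of the per-chain beta-content axis, residues.
#'
#' @return A list of class \code{"agg_control"}.
#' @examples
#' ctrl <- aggregation_control()
#' ctrl$hbond_dist
#' @export
aggregation_control <- function(equilibrium_fraction = 0.5,
                                contact_cutoff = 5.5,
                                hbond_dist = 3.5,
                                hbond_angle = 120,
                                min_ladder_hbonds = 2,
                                min_consecutive_E = 2,
                                barrel_min_size = 4,
                                pmf_temperature = 300,
                                pmf_beta_bin = 1.0) {
  ctrl <- list(
    equilibrium_fraction = equilibrium_fraction,
    contact_cutoff = contact_cutoff,
    hbond_dist = hbond_dist,
    hbond_angle = hbond_angle,
    min_ladder_hbonds = min_ladder_hbonds,
    min_consecutive_E = min_consecutive_E,
    barrel_min_size = barrel_min_size,
    pmf_temperature = pmf_temperature,
    pmf_beta_bin = pmf_beta_bin
  )
  num <- vapply(ctrl, function(x) is.numeric(x) && length(x) == 1L && is.finite(x),
                logical(1))
  if (!all(num))
    stop("all control parameters must be finite numeric scalars")
  pos <- unlist(ctrl) > 0
  pos["equilibrium_fraction"] <- ctrl$equilibrium_fraction > 0 &&
    ctrl$equilibrium_fraction <= 1
  if (!all(pos))
    stop("control parameters out of range: ",
         paste(names(ctrl)[!pos], collapse = ", "))
  class(ctrl) <- "agg_control"
  ctrl
}

as_agg_control <- function(control) {
  if (inherits(control, "agg_control")) return(control)
  if (is.null(control)) return(aggregation_control())
  do.call(aggregation_control, as.list(control))
}

# Physical constants (CODATA 2018), one table so the bookkeeping checks are
# reproducible to the digit.
.const <- list(
  N_A     = 6.02214076e23,    # 1/mol
  k_B_SI  = 1.380649e-23,     # J/K
  k_B_kcal = 0.0019872,       # kcal/(mol K), conventional value
  e_charge = 1.602176634e-19, # C
  eps0    = 8.8541878128e-12  # F/m
)
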