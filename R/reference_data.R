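# Published reference values for the POPC/DMPS + Abeta(25-35) assays.
# These printed structural parameters serve two roles: they are the stated
# conditions that the synthetic-data generator emulates, and they are the
# comparison values for the package's acceptance checks.

#' Published structural parameters of the membrane/peptide assays
#'
#' Reference structural parameters for POPC/DMPS (97:3) multibilayers
#' without and with 20 mol% Abeta(25-35), each also measured with 5 mol%
#' curcumin, acetylsalicylic acid (ASA) or melatonin.  Columns: lamellar
#' spacing `d_z` (A), area per acyl tail `A_T` (A^2), lipid tilt (deg),
#' Hermans order parameter `H` (percent), hydration water layer `d_W` (A),
#' head-head membrane width `d_HH` (A), cross-beta cluster size `L` (nm)
#' and cluster volume fraction `phi`.  `*_err` columns are the quoted
#' uncertainties.  `d_z = d_HH + d_W` holds on every row.
#'
#' @return A data.frame with 8 rows, one per (molecule, peptide) condition.
#' @export
reference_structure_table <- function() {
  df <- data.frame(
    molecule = rep(c("none", "curcumin", "ASA", "melatonin"), each = 2),
    abeta_mol_pct = rep(c(0, 20), 4),
    d_z   = c(69.5, 55.2, 56.2, 52.3, 52.7, 61.3, 61.7, 55.6),
    d_z_err = rep(0.1, 8),
    A_T   = c(22.6, 23.5, 23.1, 23.8, 22.9, 23.7, 22.8, 23.6),
    A_T_err = c(0.06, 0.1, 0.04, 0.1, 0.05, 0.1, 0.05, 0.1),
    lipid_tilt = c(20.3, 18.3, 20.3, 21.3, 17.3, 25, 17.3, 19.3),
    lipid_tilt_err = c(0.9, 0.2, 0.9, 1, 1.5, 2, 2, 0.2),
    H     = c(96.8, 75, 96.4, 88, 97.5, 86.6, 96.7, 87),
    H_err = c(0.2, 1, 0.1, 0.1, 0.2, 1, 0.1, 0.1),
    d_W   = c(27.7, 16.2, 20.4, 15.4, 15.7, 20.3, 22.3, 18),
    d_W_err = rep(0.8, 8),
    d_HH  = c(41.8, 39, 35.8, 36.9, 37, 41, 39.4, 37.6),
    d_HH_err = rep(0.8, 8),
    L     = c(NA, 21, NA, 14, NA, 106, NA, 12),
    L_err = c(NA, 3, NA, 10, NA, 2, NA, 2),
    phi   = c(NA, 0.14, NA, 0.04, NA, 0.15, NA, 0.16),
    phi_err = c(NA, 0.02, NA, 0.01, NA, 0.02, NA, 0.03),
    stringsAsFactors = FALSE
  )
  df
}
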