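#' Physical constants for keratin-mass estimation
#'
#' Defaults follow the experimentally determined mass per length of
#' intermediate filaments (25 kDa/nm, reported range 19-30), a bundling
#' factor of 19 single 10-nm filaments per imaged bundle, the 44-nm keratin
#' tetramer of combined molecular weight 228,165 Da (two K5 + two K14) and
#' about 6 protofilaments per filament cross-section.
#'
#' @param MPL mass per length of a single filament, kDa/nm.
#' @param Bf bundling factor: single filaments per imaged bundle.
#' @param N_a Avogadro constant, 1/mol.
#' @param tetramer_mw molecular weight of one tetramer, Da.
#' @param tetramer_length tetramer length, nm.
#' @param protofilaments protofilaments per 10-nm filament.
#' @return A list of class `mass_params`.
#' @export
mass_params <- function(MPL = 25, Bf = 19, N_a = 6.02214076e23,
                        tetramer_mw = 228165, tetramer_length = 44,
                        protofilaments = 6) {
  for (nm in c("MPL", "Bf", "N_a", "tetramer_mw", "tetramer_length",
               "protofilaments"))
    stopifnot_scalar(get(nm), nm)
  structure(list(MPL = MPL, Bf = Bf, N_a = N_a, tetramer_mw = tetramer_mw,
                 tetramer_length = tetramer_length,
                 protofilaments = protofilaments), class = "mass_params")
}

#' Keratin mass per cell from the mass-per-length formula
#'
#' `mass = MPL * L_tot * Bf / N_a`: the mass per unit length of a single
#' filament times the total imaged bundle length times the number of
#' filaments per bundle, converted from Daltons to picograms.
#'
#' @param L_tot_mm total keratin bundle length of the cell, millimetres.
#' @param params a [mass_params].
#' @return Mass in picograms.
#' @export
mass_mpl <- function(L_tot_mm, params = mass_params()) {
  if (L_tot_mm < 0) stop("negative total length", call. = FALSE)
  mpl_da_nm <- params$MPL * 1000            # kDa/nm -> Da/nm
  l_nm <- L_tot_mm * 1e6                    # mm -> nm
  total_da <- mpl_da_nm * l_nm * params$Bf
  total_da / params$N_a * 1e12              # g -> pg
}

#' Keratin mass per cell from tetramer dimensions
#'
#' Builds the filament molecular weight bottom-up: `1000 / tetramer_length`
#' tetramers per micrometre of protofilament, times the tetramer molecular
#' weight, times the protofilaments per filament, gives the per-micrometre
#' single-filament MW; multiplied by the total bundle length and bundling
#' factor this yields the total keratin MW, converted to picograms via the
#' Avogadro constant.
#'
#' @inheritParams mass_mpl
#' @return List with `total_mw_da` (Da) and `mass_pg` (pg).
#' @export
mass_tetramer <- function(L_tot_mm, params = mass_params()) {
  if (L_tot_mm < 0) stop("negative total length", call. = FALSE)
  per_um_mw <- (1000 / params$tetramer_length) * params$tetramer_mw *
    params$protofilaments                   # Da per um of single filament
  l_um <- L_tot_mm * 1e3
  total_mw <- per_um_mw * l_um * params$Bf
  list(total_mw_da = total_mw, mass_pg = total_mw / params$N_a * 1e12)
}

#' Tissue-scale extrapolation of keratin filament length
#'
#' Scales the per-cell total bundle length up to a cell population (for
#' example the roughly 0.14e12 epidermal cells of a human body) and to
#' single-filament length via the bundling factor.
#'
#' @param L_tot_mm total bundle length per cell, millimetres.
#' @param n_cells number of cells.
#' @param Bf bundling factor.
#' @return List with `bundle_km` and `single_filament_km`.
#' @export
tissue_extrapolation <- function(L_tot_mm, n_cells, Bf = 19) {
  if (L_tot_mm < 0 || n_cells < 0) stop("negative input", call. = FALSE)
  bundle_km <- n_cells * L_tot_mm * 1e-6    # mm -> km
  list(bundle_km = bundle_km, single_filament_km = bundle_km * Bf)
}

#' Keratin-mass report for a cell
#'
#' Runs both estimators and formats the picogram values at two significant
#' figures (three for the mass-per-length estimate), the precision
#' supported by the input constants.
#'
#' @inheritParams mass_mpl
#' @return A list of class `mass_report`.
#' @export
mass_report <- function(L_tot_mm, params = mass_params()) {
  tet <- mass_tetramer(L_tot_mm, params)
  structure(list(L_tot_mm = L_tot_mm,
                 mass_mpl_pg = mass_mpl(L_tot_mm, params),
                 mass_tetramer_pg = tet$mass_pg,
                 total_mw_da = tet$total_mw_da,
                 params = params), class = "mass_report")
}

#' @export
print.mass_report <- function(x, ...) {
  cat(sprintf("<mass_report> total bundle length %.3g mm\n", x$L_tot_mm))
  cat(sprintf("  mass-per-length estimate: %.3g pg\n",
              signif(x$mass_mpl_pg, 3)))
  cat(sprintf("  tetramer-based estimate:  %.2g pg (total MW %.3g Da)\n",
              signif(x$mass_tetramer_pg, 2), signif(x$total_mw_da, 3)))
  invisible(x)
}
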