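#' @include AllClasses.R
NULL

# Validate a registry DataFrame in place; returns it invisibly or stops.
.validateRegistry <- function(reg) {
  need <- c("id", "metabolite", "group", "multiplicity", "nominal_delta",
            "chemical_class")
  miss <- setdiff(need, colnames(reg))
  if (length(miss))
    .stopf("registry is missing field(s): %s", .commas(miss))
  if (anyDuplicated(reg$id))
    .stopf("duplicate spin-system id(s): %s",
           .commas(unique(reg$id[duplicated(reg$id)])))
  bad <- !is.finite(reg$nominal_delta) | reg$nominal_delta <= 0 |
    reg$nominal_delta >= 12
  if (any(bad))
    .stopf("nominal_delta outside (0, 12) ppm for: %s", .commas(reg$id[bad]))
  badm <- !reg$multiplicity %in% .MULTIPLICITIES
  if (any(badm))
    .stopf("unknown multiplicity for %s (allowed: %s)",
           .commas(reg$id[badm]), .commas(.MULTIPLICITIES))
  badc <- !reg$chemical_class %in% .CHEM_CLASSES
  if (any(badc))
    .stopf("unknown chemical_class for %s (allowed: %s)",
           .commas(reg$id[badc]), .commas(.CHEM_CLASSES))
  invisible(reg)
}

#' Read a spin-system registry
#'
#' A registry names the modelled spin systems: one entry per 1H NMR signal
#' with its metabolite, proton-group label, multiplicity (\code{singlet},
#' \code{doublet}, \code{triplet} or \code{multiplet}), nominal chemical
#' shift (ppm) and chemical class (\code{amino_acid}, \code{carboxylic_acid},
#' \code{sugar}, \code{alcohol}, \code{ketone}, \code{other}).
#'
#' @param path JSON file with a top-level \code{systems} array (or a bare
#'   array) of registry records.
#' @return \code{DataFrame} with one row per spin system, row names = ids.
#' @seealso \code{\link{serumSpinSystems}} for the registry shipped with the
#'   package.
#' @export
readSpinSystems <- function(path) {
  if (!file.exists(path)) .stopf("registry file not found: %s", path)
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  recs <- if (is.data.frame(obj)) obj else obj$systems
  if (is.null(recs)) .stopf("no 'systems' records in %s", path)
  reg <- S4Vectors::DataFrame(recs)
  rownames(reg) <- reg$id
  .validateRegistry(reg)
  reg
}

#' The 16-system serum/plasma panel registry
#'
#' Returns the spin-system registry of the serum/plasma shift-mapping panel:
#' 16 signals from 16 metabolites spanning amino acids (valine, alanine,
#' leucine, isoleucine, tyrosine, glycine, histidine, phenylalanine),
#' carboxylic acids (lactate, acetate, pyruvate, formate,
#' 3-hydroxybutyrate), glucose (anomeric proton), ethanol and acetone.
#'
#' @return \code{DataFrame}, one row per spin system.
#' @examples
#' reg <- serumSpinSystems()
#' table(reg$chemical_class)
#' @export
serumSpinSystems <- function() {
  readSpinSystems(system.file("extdata", "serum_panel_registry.json",
                              package = "shiftmap", mustWork = TRUE))
}
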