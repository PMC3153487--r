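#' Unit conversion between mM and molecules per cubic micrometer
#'
#' Concentration fields are stored in mM; reaction bookkeeping is done in
#' molecule counts. 1 mM = 1e-3 mol/L = 6.022e5 molecules per um^3.
#'
#' @param x numeric vector of concentrations.
#' @return the converted numeric vector.
#' @examples
#' mM_to_molecules_um3(1)        # 6.022e5
#' molecules_um3_to_mM(6.022e5)  # 1
#' @export
mM_to_molecules_um3 <- function(x) x * .molecules_per_um3_per_mM

#' @rdname mM_to_molecules_um3
#' @export
molecules_um3_to_mM <- function(x) x / .molecules_per_um3_per_mM

# Avogadro 6.02214076e23 / (1e15 um^3/L * 1e3 mM/M), i.e. 6.02214076e5.
.molecules_per_um3_per_mM <- 6.02214076e5
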