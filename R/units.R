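# Physical constants used throughout. Forces are stored in the GROMACS native
# unit kJ/mol/nm and converted to pN exactly once, so the conversion is
# testable in isolation; times are stored in ps and converted to seconds only
# inside the loading-rate computation.

# 1 kJ/mol/nm = 1000 / N_A J/nm = 1.66054e-12 N = 1.66054 pN
.KJ_MOL_NM_TO_PN <- 1.66054

# Boltzmann constant in pN nm / K (1.380649e-23 J/K)
.KB_PN_NM <- 0.0138065

.PS_PER_S <- 1e12

#' Convert forces between kJ/mol/nm and pN
#'
#' GROMACS pull code writes forces in kJ/mol/nm; the Bell-Evans analysis is
#' carried out in pN. The conversion is an exact linear bijection with
#' 1 kJ/mol/nm = 1.66054 pN.
#'
#' @param x numeric vector of forces.
#' @return numeric vector in the other unit.
#' @examples
#' kjmolnm_to_pn(1)          # 1.66054
#' pn_to_kjmolnm(kjmolnm_to_pn(3.7))
#' @export
kjmolnm_to_pn <- function(x) x * .KJ_MOL_NM_TO_PN

#' @rdname kjmolnm_to_pn
#' @export
pn_to_kjmolnm <- function(x) x / .KJ_MOL_NM_TO_PN
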