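#' Count hydrogen bonds between two atom selections
#'
#' Geometric hydrogen-bond criterion: donor-acceptor heavy-atom distance
#' `d_DA <= 3.5` angstroms and, when an explicit hydrogen is attached to
#' the donor, a D-H...A angle `>= 150` degrees.  When the frame carries no
#' hydrogens the routine falls back to the heavy-atom-only mode (distance
#' criterion alone) -- appropriate for structures stripped of protons.
#'
#' Donors and acceptors are given as logical masks over the frame (e.g.
#' the N/O atoms of two residues).  Each donor-acceptor pair satisfying the
#' criteria counts once; with hydrogens present, a pair counts if any of
#' the donor's hydrogens satisfies the angle criterion.
#'
#' @param frame an atom data.frame.
#' @param donors,acceptors logical masks selecting donor and acceptor heavy
#'   atoms.
#' @param d_DA maximal donor-acceptor distance, angstroms.
#' @param angle_min minimal D-H...A angle, degrees.
#' @param h_max maximal D-H covalent distance used to find attached
#'   hydrogens, angstroms.
#' @return integer number of hydrogen bonds.
#' @export
count_hbonds <- function(frame, donors, acceptors, d_DA = 3.5,
                         angle_min = 150, h_max = 1.25) {
  if (!any(donors) || !any(acceptors)) stop("empty donor or acceptor selection")
  D <- coords(frame, donors)
  A <- coords(frame, acceptors)
  hyd <- frame$element == "H"
  have_h <- any(hyd)
  H <- coords(frame, hyd)
  count <- 0L
  for (i in seq_len(nrow(D))) {
    dA <- sqrt(rowSums(sweep(A, 2, D[i, ])^2))
    close <- which(dA <= d_DA & dA > 1e-6)  # exclude self-pairs
    if (!length(close)) next
    if (!have_h) {
      count <- count + length(close)
      next
    }
    dH <- sqrt(rowSums(sweep(H, 2, D[i, ])^2))
    attached <- which(dH <= h_max)
    if (!length(attached)) {        # donor carries no proton: skip it
      next
    }
    for (j in close) {
      ok <- FALSE
      for (k in attached) {
        v1 <- D[i, ] - H[k, ]
        v2 <- A[j, ] - H[k, ]
        cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
        ang <- acos(pmin(pmax(cosang, -1), 1)) * 180 / pi
        if (ang >= angle_min) { ok <- TRUE; break }
      }
      if (ok) count <- count + 1L
    }
  }
  count
}
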