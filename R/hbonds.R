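#' Detect backbone hydrogen bonds
#'
#' A backbone N-H...O=C hydrogen bond is recorded when the donor N to
#' acceptor O distance is at most \code{control$hbond_dist} (3.5 Angstrom)
#' and the N-H...O angle measured at the hydrogen is at least
#' \code{control$hbond_angle} (120 degrees).  Both intra- and inter-chain
#' bonds are returned; pairs within the same residue or between adjacent
#' residues of the same chain (|i - j| < 2) are excluded.  Prolines and
#' residues without an amide hydrogen never donate.  The minimum-image
#' convention is applied when the frame has a box.
#'
#' @param frame an \code{agg_frame} whose amide hydrogens are present or
#'   reconstructed (\code{\link{reconstruct_amide_h}}).
#' @param control an \code{\link{aggregation_control}} list.
#' @return data.frame with one row per bond: \code{donor_chain, donor_res,
#'   acceptor_chain, acceptor_res, dist_no, angle_nho}.  Zero rows when no
#'   bond satisfies the rule.
#' @export
detect_hbonds <- function(frame, control = aggregation_control()) {
  control <- as_agg_control(control)
  a <- frame$atoms
  don <- a[a$atom == "H" & a$backbone, , drop = FALSE]
  nN <- a[a$atom == "N", , drop = FALSE]
  acc <- a[a$atom == "O", , drop = FALSE]
  empty <- data.frame(donor_chain = integer(), donor_res = integer(),
                      acceptor_chain = integer(), acceptor_res = integer(),
                      dist_no = numeric(), angle_nho = numeric())
  if (!nrow(don) || !nrow(acc)) return(empty)
  # match each amide H with its residue N
  key_h <- paste(don$chain, don$res)
  key_n <- paste(nN$chain, nN$res)
  don <- don[key_h %in% key_n, , drop = FALSE]
  if (!nrow(don)) return(empty)
  nmatch <- nN[match(paste(don$chain, don$res), key_n), , drop = FALSE]
  nd <- nrow(don); na <- nrow(acc)
  di <- rep(seq_len(nd), times = na)
  ai <- rep(seq_len(na), each = nd)
  same_res <- don$chain[di] == acc$chain[ai] & don$res[di] == acc$res[ai]
  adjacent <- don$chain[di] == acc$chain[ai] &
    abs(don$res[di] - acc$res[ai]) < 2L
  keep <- !(same_res | adjacent)
  di <- di[keep]; ai <- ai[keep]
  if (!length(di)) return(empty)
  Nxyz <- .xyz(nmatch)[di, , drop = FALSE]
  Hxyz <- .xyz(don)[di, , drop = FALSE]
  Oxyz <- .xyz(acc)[ai, , drop = FALSE]
  d_no <- .row_dist(Nxyz, Oxyz, frame$box)
  ok <- d_no <= control$hbond_dist
  di <- di[ok]; ai <- ai[ok]
  if (!length(di)) return(empty)
  ang <- .angle_at(Hxyz[ok, , drop = FALSE], Nxyz[ok, , drop = FALSE],
                   Oxyz[ok, , drop = FALSE], frame$box)
  d_no <- d_no[ok]
  ok2 <- ang >= control$hbond_angle
  data.frame(donor_chain = don$chain[di][ok2],
             donor_res = don$res[di][ok2],
             acceptor_chain = acc$chain[ai][ok2],
             acceptor_res = acc$res[ai][ok2],
             dist_no = d_no[ok2], angle_nho = ang[ok2])
}
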