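#' Assign per-residue secondary structure
#'
#' A four-state hydrogen-bond-pattern classifier in the Kabsch--Sander
#' tradition, driven entirely by the geometric bond set of
#' \code{\link{detect_hbonds}}.  Writing \code{Hb(x, y)} for a bond from the
#' amide of residue \code{y} to the carbonyl of residue \code{x}, a bridge
#' between residues \code{i} and \code{j} exists under any of the four ladder
#' patterns:
#' \itemize{
#'   \item antiparallel: \code{Hb(i,j) & Hb(j,i)}, or
#'     \code{Hb(i-1,j+1) & Hb(j-1,i+1)}
#'   \item parallel: \code{Hb(i-1,j) & Hb(j,i+1)}, or
#'     \code{Hb(j-1,i) & Hb(i,j+1)}
#' }
#' Bridged residues are labeled E (each bridge carries two backbone hydrogen
#' bonds between the two strand segments).  Runs of two or more consecutive
#' intra-chain i to i+4 bonds label residues H; isolated i to i+3/4/5 turn
#' bonds label the bracketed residues T; everything else is C.  Priority on
#' conflict is E > H > T > C.  Intra-chain bridges require |i - j| >= 3.
#'
#' @param frame an \code{agg_frame}.
#' @param hbonds bond table from \code{\link{detect_hbonds}} on the same
#'   frame (computed if missing).
#' @param control an \code{\link{aggregation_control}} list.
#' @return A character matrix of class \code{"agg_ss"} with one row per
#'   chain and one column per residue, entries in \{"E","H","T","C"\}.
#' @export
assign_secondary_structure <- function(frame, hbonds = NULL,
                                       control = aggregation_control()) {
  control <- as_agg_control(control)
  if (is.null(hbonds)) hbonds <- detect_hbonds(frame, control)
  nch <- n_peptides(frame)
  nres <- nchar(frame$sequences[1])
  ss <- matrix("C", nrow = nch, ncol = nres)
  if (nrow(hbonds)) {
    # Hb(x, y): acceptor residue x, donor residue y
    bond_key <- paste(hbonds$acceptor_chain, hbonds$acceptor_res,
                      hbonds$donor_chain, hbonds$donor_res)
    hb <- function(cx, rx, cy, ry) {
      rx >= 0 & ry >= 0 & rx < nres & ry < nres &
        paste(cx, rx, cy, ry) %in% bond_key
    }
    # candidate bridge pairs: for each bond, each pattern can implicate a
    # small set of (i, j) residue pairs; collect, dedupe, verify
    ci <- integer(0); ri <- integer(0); cj <- integer(0); rj <- integer(0)
    addc <- function(c1, r1, c2, r2) {
      ci <<- c(ci, c1); ri <<- c(ri, r1); cj <<- c(cj, c2); rj <<- c(rj, r2)
    }
    A <- hbonds$acceptor_chain; Ra <- hbonds$acceptor_res
    D <- hbonds$donor_chain; Rd <- hbonds$donor_res
    addc(A, Ra, D, Rd)            # AP narrow at (i,j) = (x, y)
    addc(D, Rd, A, Ra)
    addc(A, Ra + 1L, D, Rd - 1L)  # AP wide: bond is Hb(i-1, j+1)
    addc(D, Rd + 1L, A, Ra - 1L)  # AP wide: bond is Hb(j-1, i+1)
    addc(A, Ra + 1L, D, Rd)       # P1: bond is Hb(i-1, j)
    addc(D, Rd - 1L, A, Ra)       # P1: bond is Hb(j, i+1)
    addc(D, Rd, A, Ra + 1L)       # P2: bond is Hb(j-1, i)
    addc(A, Ra, D, Rd - 1L)       # P2: bond is Hb(i, j+1)
    cand <- unique(data.frame(ci = ci, ri = ri, cj = cj, rj = rj))
    cand <- cand[cand$ri >= 0 & cand$rj >= 0 &
                   cand$ri < nres & cand$rj < nres, , drop = FALSE]
    cand <- cand[cand$ci != cand$cj | abs(cand$ri - cand$rj) >= 3L, ,
                 drop = FALSE]
    if (nrow(cand)) {
      i <- cand$ri; j <- cand$rj; a <- cand$ci; b <- cand$cj
      bridge <-
        (hb(a, i, b, j) & hb(b, j, a, i)) |
        (hb(a, i - 1L, b, j + 1L) & hb(b, j - 1L, a, i + 1L)) |
        (hb(a, i - 1L, b, j) & hb(b, j, a, i + 1L)) |
        (hb(b, j - 1L, a, i) & hb(a, i, b, j + 1L))
      for (k in which(bridge)) {
        ss[a[k], i[k] + 1L] <- "E"
        ss[b[k], j[k] + 1L] <- "E"
      }
    }
    # helices and turns from intra-chain i -> i+n bonds (acceptor i, donor i+n)
    intra <- hbonds[hbonds$donor_chain == hbonds$acceptor_chain, ,
                    drop = FALSE]
    if (nrow(intra)) {
      sep <- intra$donor_res - intra$acceptor_res
      for (ch in unique(intra$donor_chain)) {
        inch <- intra$donor_chain == ch
        turn4 <- rep(FALSE, nres)
        t4 <- intra$acceptor_res[inch & sep == 4L] + 1L
        turn4[t4[t4 >= 1 & t4 <= nres]] <- TRUE
        helix <- rep(FALSE, nres)
        for (i in which(turn4[-nres] & turn4[-1]))  # turns at i and i+1
          helix[intersect(seq_len(nres), (i + 1L):(i + 4L))] <- TRUE
        ss[ch, helix & ss[ch, ] != "E"] <- "H"
        for (n in 3:5) {
          for (i0 in intra$acceptor_res[inch & sep == n]) {
            span <- intersect(seq_len(nres), (i0 + 2L):(i0 + n))
            sel <- span[ss[ch, span] == "C"]
            ss[ch, sel] <- "T"
          }
        }
      }
    }
  }
  rownames(ss) <- frame$chain_ids
  class(ss) <- c("agg_ss", class(ss))
  ss
}

#' Maximal strand segments per chain
#'
#' Runs of consecutive E residues; the run length is the beta-strand length
#' (number of continuous residues in a chain adopting the strand state).
#'
#' @param ss an \code{"agg_ss"} matrix from
#'   \code{\link{assign_secondary_structure}}.
#' @return A list with one data.frame per chain, columns \code{start}
#'   (0-based) and \code{length}; zero-row data.frames for all-coil chains.
#' @export
strand_segments <- function(ss) {
  lapply(seq_len(nrow(ss)), function(ch) {
    r <- rle(unclass(ss)[ch, ] == "E")
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    keep <- r$values
    data.frame(start = starts[keep] - 1L, length = r$lengths[keep])
  })
}

#' @export
print.agg_ss <- function(x, ...) {
  cat("<agg_ss> per-residue states (rows = chains):\n")
  s <- apply(unclass(x), 1, paste, collapse = "")
  for (i in seq_along(s)) cat(sprintf("  %s  %s\n", rownames(x)[i], s[i]))
  invisible(x)
}

#' Write a secondary-structure table as TSV
#'
#' Long-form table (frame, chain, residue, state) for one or more frames.
#'
#' @param ss_list list of \code{"agg_ss"} matrices (one per frame).
#' @param path output TSV path.
#' @return \code{path}, invisibly.
#' @export
write_ss_tsv <- function(ss_list, path) {
  rows <- do.call(rbind, lapply(seq_along(ss_list), function(fi) {
    ss <- ss_list[[fi]]
    data.frame(frame = fi,
               chain = rep(rownames(ss), each = ncol(ss)),
               residue = rep(seq_len(ncol(ss)) - 1L, times = nrow(ss)),
               state = as.vector(t(unclass(ss))))
  }))
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
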