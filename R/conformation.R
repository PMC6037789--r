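#' @title Peptide frames and trajectories
#' @description
#' A frame is one snapshot of a system of N identical-length peptide chains.
#' Internally it carries a single atom table with 0-based residue indices,
#' per-chain one-letter sequences, an optional cubic box edge (Angstrom) and
#' a time stamp (ns).  A trajectory is a time-ordered list of frames plus
#' free-form metadata.
#' @name conformation
NULL

.aa3 <- c(A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
          E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
          M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
          Y = "TYR", V = "VAL")
.aa1 <- structure(names(.aa3), names = .aa3)

.backbone_names <- c("N", "H", "CA", "C", "O")

.element_of <- function(atom_name) {
  # first alphabetic character of the stripped atom label; two-letter
  # elements never occur in the peptide chemistry supported here
  substr(gsub("[^A-Za-z]", "", atom_name), 1, 1)
}

#' Construct a frame from an atom table
#'
#' @param atoms data.frame with columns \code{chain} (1-based integer),
#'   \code{res} (0-based integer residue index within the chain),
#'   \code{atom} (atom name), \code{x,y,z} (Angstrom).
#' @param sequences character vector of one-letter sequences, one per chain.
#' @param time frame time in ns.
#' @param box cubic box edge in Angstrom, or NULL for open boundaries.
#' @param chain_ids optional chain labels (default LETTERS-style).
#' @return An object of class \code{"agg_frame"}.
#' @export
new_frame <- function(atoms, sequences, time = 0, box = NULL,
                      chain_ids = NULL) {
  stopifnot(is.data.frame(atoms),
            all(c("chain", "res", "atom", "x", "y", "z") %in% names(atoms)))
  if (length(sequences) < 1L) stop("a frame needs at least one peptide")
  if (length(unique(nchar(sequences))) != 1L)
    stop("all chains must share one sequence length")
  if (!all(is.finite(atoms$x) & is.finite(atoms$y) & is.finite(atoms$z)))
    stop("atom coordinates must be finite")
  atoms$chain <- as.integer(atoms$chain)
  atoms$res <- as.integer(atoms$res)
  atoms$atom <- as.character(atoms$atom)
  if (is.null(atoms$element)) atoms$element <- .element_of(atoms$atom)
  atoms$heavy <- atoms$element != "H"
  atoms$backbone <- atoms$atom %in% .backbone_names
  if (is.null(chain_ids)) chain_ids <- .default_chain_ids(length(sequences))
  structure(list(atoms = atoms, sequences = sequences,
                 chain_ids = chain_ids, time = time, box = box),
            class = "agg_frame")
}

.default_chain_ids <- function(n) {
  pool <- c(LETTERS, letters, 0:9)
  if (n > length(pool)) stop("too many chains for single-character chain ids")
  pool[seq_len(n)]
}

#' Assemble a trajectory from frames
#'
#' @param frames list of \code{agg_frame} objects with strictly increasing
#'   times.
#' @param metadata free-form named list (sequence name, run id, ...).
#' @return An object of class \code{"agg_trajectory"}.
#' @export
new_trajectory <- function(frames, metadata = list()) {
  if (length(frames) < 1L) stop("a trajectory needs at least one frame")
  times <- vapply(frames, function(f) f$time, numeric(1))
  if (any(diff(times) <= 0)) stop("frame times must be strictly increasing")
  structure(list(frames = frames, metadata = metadata),
            class = "agg_trajectory")
}

#' @export
print.agg_frame <- function(x, ...) {
  cat(sprintf("<agg_frame> %d chains x %d residues, %d atoms, t = %g ns%s\n",
              n_peptides(x), nchar(x$sequences[1]), nrow(x$atoms), x$time,
              if (is.null(x$box)) "" else sprintf(", box %.1f A", x$box)))
  invisible(x)
}

#' @export
print.agg_trajectory <- function(x, ...) {
  cat(sprintf("<agg_trajectory> %d frames, %d chains, t = [%g, %g] ns\n",
              length(x$frames), n_peptides(x$frames[[1]]),
              x$frames[[1]]$time, x$frames[[length(x$frames)]]$time))
  invisible(x)
}

#' Number of peptides in a frame
#' @param frame an \code{agg_frame}.
#' @return integer count.
#' @export
n_peptides <- function(frame) length(frame$sequences)

#' Extract one peptide from a frame
#'
#' @param frame an \code{agg_frame}.
#' @param chain 1-based chain index.
#' @return list of class \code{"agg_peptide"} with the chain id, sequence and
#'   atom table of that chain.
#' @export
peptide <- function(frame, chain) {
  stopifnot(chain >= 1L, chain <= n_peptides(frame))
  structure(list(chain_id = frame$chain_ids[chain],
                 sequence = frame$sequences[chain],
                 atoms = frame$atoms[frame$atoms$chain == chain, , drop = FALSE]),
            class = "agg_peptide")
}

# coordinates of one named atom per residue of one chain, ordered by residue;
# rows of residues lacking the atom are NA
.atom_per_residue <- function(frame, chain, atom_name) {
  nres <- nchar(frame$sequences[chain])
  sel <- frame$atoms[frame$atoms$chain == chain &
                       frame$atoms$atom == atom_name, , drop = FALSE]
  m <- matrix(NA_real_, nrow = nres, ncol = 3)
  if (nrow(sel)) m[sel$res + 1L, ] <- .xyz(sel)
  m
}

#' End-to-end distance of a peptide
#'
#' Euclidean distance between the first and last residue CA atoms.
#'
#' @param pep an \code{agg_peptide} (see \code{\link{peptide}}).
#' @return distance in Angstrom.
#' @export
end_to_end_distance <- function(pep) {
  stopifnot(inherits(pep, "agg_peptide"))
  ca <- pep$atoms[pep$atoms$atom == "CA", , drop = FALSE]
  ca <- ca[order(ca$res), , drop = FALSE]
  if (nrow(ca) < 2L) stop("end-to-end distance needs at least two residues")
  .norm3(as.numeric(ca[nrow(ca), c("x", "y", "z")]) -
           as.numeric(ca[1L, c("x", "y", "z")]))
}

#' Reconstruct missing amide hydrogens
#'
#' For every non-proline residue that has a predecessor and lacks an H atom,
#' the amide hydrogen is placed in the C(prev)-N-CA plane at 1.00 Angstrom
#' from N, along the bisector pointing away from both C(prev) and CA (the
#' standard planar amide construction).  Residues that already carry an H are
#' left untouched; chain N-terminal residues and prolines never receive one.
#'
#' @param frame an \code{agg_frame}.
#' @return A frame with H atoms added where needed.
#' @export
reconstruct_amide_h <- function(frame) {
  stopifnot(inherits(frame, "agg_frame"))
  add <- list()
  for (ch in seq_len(n_peptides(frame))) {
    seq1 <- strsplit(frame$sequences[ch], "")[[1]]
    nres <- length(seq1)
    N <- .atom_per_residue(frame, ch, "N")
    CA <- .atom_per_residue(frame, ch, "CA")
    C <- .atom_per_residue(frame, ch, "C")
    has_h <- (frame$atoms$res[frame$atoms$chain == ch &
                                frame$atoms$atom == "H"]) + 1L
    if (nres < 2L) next
    for (i in 2:nres) {
      if (i %in% has_h || seq1[i] == "P") next
      if (any(is.na(N[i, ])) || any(is.na(CA[i, ])))
        stop(sprintf("chain %s residue %d lacks N or CA; cannot place H",
                     frame$chain_ids[ch], i - 1L))
      if (any(is.na(C[i - 1L, ])))
        stop(sprintf("chain %s residue %d: predecessor lacks C",
                     frame$chain_ids[ch], i - 1L))
      u <- .unit(N[i, ] - C[i - 1L, ])
      v <- .unit(N[i, ] - CA[i, ])
      h <- N[i, ] + .unit(u + v) * 1.00
      add[[length(add) + 1L]] <- data.frame(
        chain = ch, res = i - 1L, atom = "H", element = "H",
        x = h[1], y = h[2], z = h[3], heavy = FALSE, backbone = TRUE)
    }
  }
  if (!length(add)) return(frame)
  atoms <- rbind(frame$atoms[names(add[[1]])], do.call(rbind, add))
  # keep a canonical order: chain, residue, then N/H first within the residue
  rank <- match(atoms$atom, c("N", "H", "CA", "C", "O"), nomatch = 99L)
  atoms <- atoms[order(atoms$chain, atoms$res, rank), , drop = FALSE]
  rownames(atoms) <- NULL
  out <- frame
  out$atoms <- atoms
  out
}

# apply a rigid motion (rotation matrix R then translation t) to a frame
transform_frame <- function(frame, R = diag(3), t = c(0, 0, 0)) {
  m <- .xyz(frame$atoms) %*% t(R)
  frame$atoms$x <- m[, 1] + t[1]
  frame$atoms$y <- m[, 2] + t[2]
  frame$atoms$z <- m[, 3] + t[3]
  frame
}
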