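#' Read a multi-model PDB trajectory
#'
#' Frames are delimited by MODEL/ENDMDL records; a file without MODEL records
#' is read as a single frame.  Chain and residue order are preserved; residue
#' indices are re-based to 0 per chain.  A \code{CRYST1} record with a cubic
#' cell sets the box edge; \code{REMARK 6 TIME_NS <t>} lines inside a model
#' set its time stamp (frames are otherwise stamped 0, 1, 2, ... ns).
#' Only ATOM records are interpreted; altloc and insertion codes are not
#' supported.
#'
#' @param path path to a PDB file.
#' @return An \code{agg_trajectory}.  Frames whose chains lack amide
#'   hydrogens carry attribute \code{needs_h = TRUE} (use
#'   \code{\link{reconstruct_amide_h}}).
#' @seealso \code{\link{write_multimodel_pdb}}
#' @export
read_multimodel_pdb <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  box <- NULL
  cry <- which(rec == "CRYST1")
  if (length(cry)) {
    abc <- suppressWarnings(as.numeric(c(substr(lines[cry[1]], 7, 15),
                                         substr(lines[cry[1]], 16, 24),
                                         substr(lines[cry[1]], 25, 33))))
    if (!any(is.na(abc)) && max(abc) - min(abc) < 1e-3 && abc[1] > 0)
      box <- abc[1]
  }
  starts <- which(rec == "MODEL ")
  ends <- which(rec == "ENDMDL")
  if (length(starts) == 0L) {
    blocks <- list(seq_along(lines))
  } else {
    if (length(ends) != length(starts))
      stop("unbalanced MODEL/ENDMDL records")
    blocks <- mapply(function(s, e) seq(s, e), starts, ends, SIMPLIFY = FALSE)
  }
  frames <- vector("list", length(blocks))
  ref_sig <- NULL
  for (bi in seq_along(blocks)) {
    idx <- blocks[[bi]]
    t_ns <- bi - 1
    rem <- idx[startsWith(lines[idx], "REMARK 6 TIME_NS")]
    if (length(rem)) {
      tv <- suppressWarnings(as.numeric(sub("REMARK 6 TIME_NS", "",
                                            lines[rem[1]])))
      if (!is.na(tv)) t_ns <- tv
    }
    ai <- idx[substr(lines[idx], 1, 6) == "ATOM  "]
    if (!length(ai)) stop(sprintf("model %d contains no ATOM records", bi))
    al <- lines[ai]
    name <- trimws(substr(al, 13, 16))
    resname <- trimws(substr(al, 18, 20))
    chain_ch <- substr(al, 22, 22)
    resseq <- suppressWarnings(as.integer(substr(al, 23, 26)))
    x <- suppressWarnings(as.numeric(substr(al, 31, 38)))
    y <- suppressWarnings(as.numeric(substr(al, 39, 46)))
    z <- suppressWarnings(as.numeric(substr(al, 47, 54)))
    bad <- which(is.na(x) | is.na(y) | is.na(z) | is.na(resseq) | name == "")
    if (length(bad))
      stop(sprintf("malformed ATOM record at line %d of %s",
                   ai[bad[1]], path))
    elem <- trimws(substr(al, 77, 78))
    elem[elem == ""] <- .element_of(name[elem == ""])
    # chains in order of first appearance
    chain_lv <- unique(chain_ch)
    chain <- match(chain_ch, chain_lv)
    res <- integer(length(al))
    seqs <- character(length(chain_lv))
    for (ch in seq_along(chain_lv)) {
      in_ch <- chain == ch
      key <- resseq[in_ch]
      ures <- unique(key)
      res[in_ch] <- match(key, ures) - 1L
      first <- !duplicated(key)
      aa <- .aa1[resname[in_ch][first]]
      if (any(is.na(aa)))
        stop(sprintf("unknown residue name '%s' in chain %s",
                     resname[in_ch][first][is.na(aa)][1], chain_lv[ch]))
      seqs[ch] <- paste(aa, collapse = "")
    }
    if (length(unique(nchar(seqs))) != 1L)
      stop("chains do not share a sequence length")
    sig <- paste(chain, res, name, collapse = ";")
    if (is.null(ref_sig)) ref_sig <- sig
    else if (!identical(sig, ref_sig))
      stop(sprintf("model %d has a different chain composition than model 1",
                   bi))
    atoms <- data.frame(chain = chain, res = res, atom = name,
                        element = elem, x = x, y = y, z = z)
    fr <- new_frame(atoms, seqs, time = t_ns, box = box,
                    chain_ids = chain_lv)
    attr(fr, "needs_h") <- !any(name == "H")
    frames[[bi]] <- fr
  }
  new_trajectory(frames, metadata = list(source = path))
}

#' Write a trajectory as multi-model PDB
#'
#' One MODEL block per frame with a \code{REMARK 6 TIME_NS} time stamp,
#' TER records between chains and a \code{CRYST1} record when a box is
#' present.  Coordinates are written at the standard 0.001 Angstrom PDB
#' precision.
#'
#' @param traj an \code{agg_trajectory} or single \code{agg_frame}.
#' @param path output path.
#' @return \code{path}, invisibly.
#' @export
write_multimodel_pdb <- function(traj, path) {
  if (inherits(traj, "agg_frame"))
    traj <- new_trajectory(list(traj))
  stopifnot(inherits(traj, "agg_trajectory"))
  con <- file(path, "w")
  on.exit(close(con))
  box <- traj$frames[[1]]$box
  if (!is.null(box))
    writeLines(sprintf(
      "CRYST1%9.3f%9.3f%9.3f%7.2f%7.2f%7.2f P 1           1",
      box, box, box, 90, 90, 90), con)
  for (bi in seq_along(traj$frames)) {
    fr <- traj$frames[[bi]]
    writeLines(sprintf("MODEL     %4d", bi), con)
    writeLines(sprintf("REMARK 6 TIME_NS %.6f", fr$time), con)
    a <- fr$atoms
    serial <- 0L
    out <- character(nrow(a) + n_peptides(fr))
    oi <- 0L
    seqs <- fr$sequences
    for (ch in seq_len(n_peptides(fr))) {
      rows <- which(a$chain == ch)
      aa3 <- .aa3[strsplit(seqs[ch], "")[[1]]]
      for (r in rows) {
        serial <- serial + 1L
        oi <- oi + 1L
        nm <- a$atom[r]
        nm_field <- if (nchar(nm) < 4L) sprintf(" %-3s", nm) else nm
        out[oi] <- sprintf(
          "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          serial %% 100000L, nm_field, aa3[a$res[r] + 1L],
          fr$chain_ids[ch], a$res[r] + 1L, a$x[r], a$y[r], a$z[r],
          1, 0, a$element[r])
      }
      oi <- oi + 1L
      out[oi] <- "TER"
    }
    writeLines(out, con)
    writeLines("ENDMDL", con)
  }
  writeLines("END", con)
  invisible(path)
}
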