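#' Plain-text trajectory dialect
#'
#' A minimal whitespace-separated format for frames of identical chains:
#' \preformatted{
#' natoms nchains nres_per_chain box_edge_A
#' SEQ <one-letter sequence>
#' t_ns
#' chain res atomname x y z     (natoms lines, chain 1-based, res 0-based)
#' t_ns
#' ...
#' }
#' A \code{box_edge_A} of 0 means open boundaries.  The \code{SEQ} line gives
#' the shared one-letter sequence (repeated per chain when chains differ).
#' Coordinates are written with six decimals.
#'
#' @param path file path.
#' @return \code{read_frames_txt} returns an \code{agg_trajectory};
#'   \code{write_frames_txt} returns \code{path} invisibly.
#' @name frames_txt
NULL

#' @rdname frames_txt
#' @param traj an \code{agg_trajectory} or single \code{agg_frame}.
#' @export
write_frames_txt <- function(traj, path) {
  if (inherits(traj, "agg_frame")) traj <- new_trajectory(list(traj))
  f1 <- traj$frames[[1]]
  natoms <- nrow(f1$atoms)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("%d %d %d %.6f", natoms, n_peptides(f1),
                     nchar(f1$sequences[1]),
                     if (is.null(f1$box)) 0 else f1$box), con)
  writeLines(paste("SEQ", paste(f1$sequences, collapse = " ")), con)
  for (fr in traj$frames) {
    if (nrow(fr$atoms) != natoms)
      stop("all frames must share one atom composition")
    writeLines(sprintf("%.6f", fr$time), con)
    writeLines(sprintf("%d %d %s %.6f %.6f %.6f",
                       fr$atoms$chain, fr$atoms$res, fr$atoms$atom,
                       fr$atoms$x, fr$atoms$y, fr$atoms$z), con)
  }
  invisible(path)
}

#' @rdname frames_txt
#' @export
read_frames_txt <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- as.numeric(strsplit(trimws(lines[1]), "\\s+")[[1]])
  if (length(hdr) != 4L || any(is.na(hdr)))
    stop("malformed header at line 1: expected 'natoms nchains nres box'")
  natoms <- as.integer(hdr[1]); nchains <- as.integer(hdr[2])
  box <- if (hdr[4] > 0) hdr[4] else NULL
  seq_line <- strsplit(trimws(lines[2]), "\\s+")[[1]]
  if (seq_line[1] != "SEQ") stop("malformed SEQ line at line 2")
  seqs <- seq_line[-1]
  if (length(seqs) == 1L) seqs <- rep(seqs, nchains)
  pos <- 3L
  frames <- list()
  while (pos <= length(lines)) {
    if (trimws(lines[pos]) == "") { pos <- pos + 1L; next }
    t_ns <- suppressWarnings(as.numeric(lines[pos]))
    if (is.na(t_ns)) stop(sprintf("malformed time stamp at line %d", pos))
    body <- lines[(pos + 1L):(pos + natoms)]
    parts <- strsplit(trimws(body), "\\s+")
    bad <- which(lengths(parts) != 6L)
    if (length(bad))
      stop(sprintf("malformed atom line at line %d", pos + bad[1]))
    m <- matrix(unlist(parts), ncol = 6, byrow = TRUE)
    atoms <- data.frame(chain = as.integer(m[, 1]),
                        res = as.integer(m[, 2]),
                        atom = m[, 3],
                        x = as.numeric(m[, 4]),
                        y = as.numeric(m[, 5]),
                        z = as.numeric(m[, 6]))
    frames[[length(frames) + 1L]] <- new_frame(atoms, seqs, time = t_ns,
                                               box = box)
    pos <- pos + 1L + natoms
  }
  new_trajectory(frames, metadata = list(source = path))
}
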