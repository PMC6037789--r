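# Independent brute-force oracles and tiny hand-built fixtures.  These stay
# deliberately separate from the package implementation: plain double loops
# and boolean matrix arithmetic only.

# all backbone N-H...O bonds by direct evaluation of the two-part rule
brute_force_hbonds <- function(frame, dist_max = 3.5, angle_min = 120) {
  a <- frame$atoms
  box <- frame$box
  dist3 <- function(p, q) {
    d <- p - q
    if (!is.null(box)) d <- d - box * round(d / box)
    sqrt(sum(d * d))
  }
  out <- NULL
  don <- a[a$atom == "H", , drop = FALSE]
  acc <- a[a$atom == "O", , drop = FALSE]
  for (i in seq_len(nrow(don))) {
    hN <- a[a$atom == "N" & a$chain == don$chain[i] & a$res == don$res[i], ]
    if (nrow(hN) != 1L) next
    for (j in seq_len(nrow(acc))) {
      if (don$chain[i] == acc$chain[j] &&
          abs(don$res[i] - acc$res[j]) < 2) next
      N <- c(hN$x, hN$y, hN$z)
      H <- c(don$x[i], don$y[i], don$z[i])
      O <- c(acc$x[j], acc$y[j], acc$z[j])
      if (dist3(N, O) > dist_max) next
      u <- N - H; v <- O - H
      if (!is.null(box)) {
        u <- u - box * round(u / box); v <- v - box * round(v / box)
      }
      ang <- acos(max(-1, min(1, sum(u * v) /
                                (sqrt(sum(u^2)) * sqrt(sum(v^2)))))) * 180 / pi
      if (ang < angle_min) next
      out <- rbind(out, data.frame(
        donor_chain = don$chain[i], donor_res = don$res[i],
        acceptor_chain = acc$chain[j], acceptor_res = acc$res[j]))
    }
  }
  out
}

# minimum inter-chain heavy-atom distance by explicit scan
brute_force_contacts <- function(frame, cutoff = 5.5) {
  a <- frame$atoms[frame$atoms$heavy, , drop = FALSE]
  n <- length(frame$sequences)
  box <- frame$box
  edges <- NULL
  for (p in seq_len(n - 1)) {
    ap <- a[a$chain == p, , drop = FALSE]
    for (q in (p + 1):n) {
      aq <- a[a$chain == q, , drop = FALSE]
      found <- FALSE
      for (i in seq_len(nrow(ap))) {
        dx <- aq$x - ap$x[i]; dy <- aq$y - ap$y[i]; dz <- aq$z - ap$z[i]
        if (!is.null(box)) {
          dx <- dx - box * round(dx / box)
          dy <- dy - box * round(dy / box)
          dz <- dz - box * round(dz / box)
        }
        if (any(dx * dx + dy * dy + dz * dz <= cutoff^2)) {
          found <- TRUE
          break
        }
      }
      if (found) edges <- rbind(edges, c(p, q))
    }
  }
  edges
}

# connected components by boolean transitive closure of the adjacency matrix
closure_components <- function(n, edges) {
  A <- diag(n) > 0
  if (!is.null(edges) && nrow(edges)) {
    A[edges] <- TRUE
    A[edges[, c(2, 1), drop = FALSE]] <- TRUE
  }
  repeat {
    A2 <- (A %*% A) > 0
    if (identical(A2, A)) break
    A <- A2
  }
  memb <- integer(n)
  cid <- 0L
  for (v in seq_len(n)) {
    if (memb[v] == 0L) {
      cid <- cid + 1L
      memb[A[v, ]] <- cid
    }
  }
  memb
}

# closed-barrel test by definition: >= min_size strands, connected, every
# strand with >= 2 neighbours, and no single pairing whose removal
# disconnects the sheet
brute_force_barrel <- function(n, edges, min_size = 4) {
  if (n < min_size) return(FALSE)
  if (is.null(edges) || nrow(edges) == 0L) return(FALSE)
  connected <- function(ed) {
    length(unique(closure_components(n, ed))) == 1L
  }
  deg <- tabulate(c(edges[, 1], edges[, 2]), nbins = n)
  if (any(deg < 2)) return(FALSE)
  if (!connected(edges)) return(FALSE)
  for (k in seq_len(nrow(edges)))
    if (!connected(edges[-k, , drop = FALSE])) return(FALSE)
  TRUE
}

# wrap an arbitrary graph as a sheet record for detect_barrels
graph_as_sheet <- function(n, edges) {
  ed <- if (is.null(edges) || nrow(edges) == 0L)
    data.frame(from = integer(), to = integer())
  else data.frame(from = edges[, 1], to = edges[, 2])
  list(members = seq_len(n), size = n, edges = ed, is_barrel = FALSE)
}

# relabel the chains of a frame by a permutation (invariance tests)
permute_chains <- function(frame, perm) {
  inv <- order(perm)
  atoms <- frame$atoms
  atoms$chain <- inv[atoms$chain]
  atoms <- atoms[order(atoms$chain, atoms$res), , drop = FALSE]
  new_frame(atoms, frame$sequences[perm], time = frame$time,
            box = frame$box)
}

# a donor residue (chain 1) and an acceptor O (chain 2) at a controlled
# N...O gap and N-H...O angle: N at the origin, H at (0,1,0), O on the ray
# from H that makes the requested angle at H
two_residue_probe <- function(gap, angle_deg = 180) {
  A <- angle_deg * pi / 180
  r <- cos(A) + sqrt(max(0, cos(A)^2 - 1 + gap^2))  # |H-O|
  O <- c(r * sin(A), 1 - r * cos(A), 0)
  a1 <- data.frame(
    chain = 1L, res = c(0L, 0L, 0L, 1L, 1L, 1L, 1L),
    atom = c("N", "CA", "C", "N", "H", "CA", "C"),
    x = c(-4.5, -3.9, -2.7, 0, 0, 0.6, 1.8),
    y = c(-1.4, -0.4, -0.6, 0, 1, -1.4, -1.0),
    z = 0)
  # chain 2 carries the acceptor O; its remaining atoms sit far from H so
  # the probe bond is the only candidate
  a2 <- data.frame(
    chain = 2L, res = c(0L, 0L, 0L, 0L, 1L, 1L, 1L),
    atom = c("N", "CA", "C", "O", "N", "CA", "C"),
    x = O[1] + c(6, 6.8, 8, 0, 9, 9.6, 10.8),
    y = O[2] + c(0.5, 1.3, 1.0, 0, 1.8, 0.8, 1.2),
    z = 0)
  new_frame(rbind(a1, a2), c("AA", "AA"))
}
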