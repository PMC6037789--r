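#' @title Synthetic conformation generator
#' @description
#' Deterministic builders for labeled test structures: random coils and
#' ideal helices from internal coordinates, and idealized flat beta-sheets,
#' double-layer sheets and closed beta-barrels from a strand template.
#'
#' The template lays each strand along an axis with 3.5 Angstrom rise per
#' residue and alternates the amide/carbonyl groups of successive residues
#' between the two lateral sides, offset toward the hydrogen-bonding partner
#' strand.  Strand placement (direction, axial offset and donor phase) is
#' solved per seam so that every intended ladder bond has an N--O distance of
#' 2.72 Angstrom and an N-H...O angle of 180 degrees before noise -- well
#' inside the 3.5 Angstrom / 120 degree detection rule.  On a barrel the
#' lateral offsets point along the chord to the partner strand, which makes
#' each seam geometrically identical to the flat case.
#' @name synthetic
NULL

.rise <- 3.5          # axial rise per residue, Angstrom
.strand_sep <- 4.85   # inter-strand spacing, Angstrom
.lat_N <- 0.45        # lateral offsets of the H-bonding unit
.lat_H <- 1.45
.lat_O <- 1.68
.ax_CA <- 1.05        # within-residue axial offsets
.ax_C <- 2.45
.ax_O <- 3.5

# default: the amyloidogenic islet amyloid polypeptide fragment 19-29
.default_sequence <- "SNNFGAILSST"

# one strand in local coordinates described by (axis, lat_plus, lat_minus,
# normal) unit vectors.  p: donor phase; e: strand direction; o: axial
# offset of residue 0's N; face: +1/-1/"alternate" side-chain face.
.build_strand <- function(sequence, origin, axis, lat_plus, lat_minus,
                          normal, e = 1, o = 0, p = 1, face = "alternate",
                          chain = 1L) {
  seq1 <- strsplit(sequence, "")[[1]]
  nres <- length(seq1)
  rows <- vector("list", nres)
  for (i in seq_len(nres) - 1L) {
    d <- p * (-1)^i
    lat <- if (d > 0) lat_plus else lat_minus
    w <- if (identical(face, "alternate")) (-1)^i else face
    ax_at <- function(s) origin + axis * (o + e * (.rise * i + s))
    pos <- list(N = ax_at(0) + lat * .lat_N,
                H = ax_at(0) + lat * .lat_H,
                CA = ax_at(.ax_CA),
                C = ax_at(.ax_C),
                O = ax_at(.ax_O) + lat * .lat_O)
    aa <- seq1[i + 1L]
    if (i == 0L || aa == "P") pos$H <- NULL
    if (!aa %in% c("G", "A")) {
      pos$CB <- ax_at(.ax_CA) + normal * (w * 1.53)
      pos$CG <- ax_at(.ax_CA) + normal * (w * 2.90)
    } else if (aa == "A") {
      pos$CB <- ax_at(.ax_CA) + normal * (w * 1.53)
    }
    m <- do.call(rbind, pos)
    rows[[i + 1L]] <- data.frame(chain = chain, res = i,
                                 atom = rownames(m),
                                 x = m[, 1], y = m[, 2], z = m[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# seam bookkeeping: given strand directions e[k] and the seam types, return
# axial offsets o[k] and donor phases p[k] such that every seam carries an
# exact hydrogen-bond registry.  nres-length strands; seams[k] connects
# strand k to k+1 ("ap" antiparallel with full-overlap registry, or "p"
# parallel with stagger beta (in residues)).
.solve_strand_placement <- function(e, seams, nres, beta = NULL) {
  ns <- length(e)
  o <- numeric(ns)
  p <- numeric(ns)
  p[1] <- 1
  for (k in seq_len(ns - 1)) {
    if (seams[k] == "ap") {
      o[k + 1] <- o[k] + e[k] * .rise * nres
      p[k + 1] <- p[k] * (-1)^nres
    } else {
      o[k + 1] <- o[k] + .rise * beta[k]
      p[k + 1] <- if (beta[k] %% 2 == 0) p[k] else -p[k]
    }
  }
  list(o = o, p = p)
}

.apply_noise <- function(atoms, sigma) {
  if (sigma > 0) {
    n <- nrow(atoms)
    atoms$x <- atoms$x + stats::rnorm(n, 0, sigma)
    atoms$y <- atoms$y + stats::rnorm(n, 0, sigma)
    atoms$z <- atoms$z + stats::rnorm(n, 0, sigma)
  }
  atoms
}

#' Build an idealized beta-sheet frame
#'
#' Strands are placed side by side at 4.85 Angstrom spacing with a
#' hydrogen-bond registry satisfying the 3.5 Angstrom / 120 degree rule with
#' margin; \code{"double_layer"} stacks two antiparallel sheets at
#' \code{layer_sep} with side chains facing.  Gaussian coordinate noise is
#' applied last.
#'
#' @param n_strands strand count (per layer for \code{"double_layer"}).
#' @param sequence one-letter peptide sequence shared by all chains.
#' @param motif \code{"antiparallel_sheet"}, \code{"parallel_sheet"} or
#'   \code{"double_layer"}.
#' @param noise_sigma i.i.d. Gaussian noise per coordinate, Angstrom.
#' @param seed RNG seed (noise only); fixed seed gives identical output.
#' @param registry inter-strand residue offset added to the default
#'   full-overlap registry (antiparallel seams).
#' @param layer_sep layer separation of the double layer, Angstrom.
#' @param box_edge optional cubic box edge, Angstrom.
#' @return list with \code{frame} (an \code{agg_frame}) and \code{truth},
#'   the ground-truth record: per-peptide motif labels, expected pairing
#'   \code{edges} (from, to, orientation), expected \code{sheet_sizes},
#'   \code{barrel} flag and barrel size, and expected beta-sheet-oligomer
#'   sizes \code{bso_sizes}.
#' @export
build_sheet <- function(n_strands, sequence = .default_sequence,
                        motif = c("antiparallel_sheet", "parallel_sheet",
                                  "double_layer"),
                        noise_sigma = 0, seed = NULL, registry = 0,
                        layer_sep = 10, box_edge = NULL) {
  motif <- match.arg(motif)
  stopifnot(n_strands >= 2)
  nres <- nchar(sequence)
  layer <- function(face, z0, chain0) {
    anti <- motif != "parallel_sheet"
    e <- if (anti) (-1)^(seq_len(n_strands) - 1) else rep(1, n_strands)
    seams <- rep(if (anti) "ap" else "p", max(n_strands - 1, 1))
    beta <- rep(c(1, -1), length.out = max(n_strands - 1, 1))
    nr_eff <- nres - 2 * registry
    pl <- .solve_strand_placement(e, seams, nr_eff, beta)
    do.call(rbind, lapply(seq_len(n_strands), function(k) {
      .build_strand(sequence,
                    origin = c(0, .strand_sep * (k - 1), z0),
                    axis = c(1, 0, 0),
                    lat_plus = c(0, 1, 0), lat_minus = c(0, -1, 0),
                    normal = c(0, 0, 1),
                    e = e[k], o = pl$o[k], p = pl$p[k], face = face,
                    chain = chain0 + k - 1L)
    }))
  }
  if (motif == "double_layer") {
    atoms <- rbind(layer(face = 1, z0 = 0, chain0 = 1L),
                   layer(face = -1, z0 = layer_sep,
                         chain0 = n_strands + 1L))
    nchains <- 2L * n_strands
    edges <- do.call(rbind, lapply(c(0L, n_strands), function(off)
      data.frame(from = off + seq_len(n_strands - 1),
                 to = off + seq_len(n_strands - 1) + 1L,
                 orientation = "antiparallel")))
    truth <- list(motif = motif, labels = rep("sheet", nchains),
                  edges = edges,
                  sheet_sizes = c(n_strands, n_strands),
                  barrel = FALSE, barrel_size = 0L,
                  bso_sizes = 2L * n_strands)
  } else {
    atoms <- layer(face = "alternate", z0 = 0, chain0 = 1L)
    nchains <- n_strands
    ori <- if (motif == "parallel_sheet") "parallel" else "antiparallel"
    truth <- list(motif = motif, labels = rep("sheet", nchains),
                  edges = data.frame(from = seq_len(n_strands - 1),
                                     to = seq_len(n_strands - 1) + 1L,
                                     orientation = ori),
                  sheet_sizes = n_strands,
                  barrel = FALSE, barrel_size = 0L,
                  bso_sizes = n_strands)
  }
  atoms <- with_seed(seed, .apply_noise(atoms, noise_sigma))
  fr <- new_frame(atoms, rep(sequence, nchains), box = box_edge)
  list(frame = fr, truth = truth)
}

#' Build an idealized closed beta-barrel frame
#'
#' Strands are placed on a cylinder of radius r = d / (2 sin(pi/n)) with
#' d = 4.85 Angstrom and their hydrogen-bonding groups aimed along the chord
#' to the partner strand, so every seam reproduces the flat-sheet bond
#' geometry exactly.  With \code{orientation = "antiparallel"} strand
#' directions alternate; for odd strand counts one seam is necessarily
#' parallel and is closed with a zero-stagger parallel registry.  A fully
#' parallel barrel is only realizable for even strand counts (the per-seam
#' one-residue stagger must cancel around the cycle); odd counts raise an
#' error.
#'
#' @param n_strands strand count, 4 to 12.
#' @param sequence one-letter peptide sequence.
#' @param orientation \code{"antiparallel"} (default) or \code{"parallel"}.
#' @param noise_sigma,seed,box_edge as in \code{\link{build_sheet}}.
#' @return list with \code{frame} and \code{truth} as in
#'   \code{\link{build_sheet}}; the expected pairing edges form the closed
#'   cycle and \code{barrel} is TRUE.
#' @export
build_barrel <- function(n_strands, sequence = .default_sequence,
                         orientation = c("antiparallel", "parallel"),
                         noise_sigma = 0, seed = NULL, box_edge = NULL) {
  orientation <- match.arg(orientation)
  if (n_strands < 4 || n_strands > 12)
    stop("barrel strand count must be between 4 and 12")
  nres <- nchar(sequence)
  n <- n_strands
  if (orientation == "parallel") {
    if (n %% 2 == 1)
      stop("a fully parallel closed barrel is geometrically infeasible ",
           "for an odd strand count (seam staggers cannot cancel)")
    e <- rep(1, n)
    seams <- rep("p", n - 1)
    beta <- rep(c(1, -1), length.out = n - 1)
  } else {
    e <- (-1)^(seq_len(n) - 1)
    seams <- rep("ap", n - 1)
    if (n %% 2 == 1) seams[n - 1] <- "ap"   # closure seam handled below
    beta <- rep(0, n - 1)
  }
  pl <- .solve_strand_placement(e, seams, nres, beta)
  r <- .strand_sep / (2 * sin(pi / n))
  theta <- 2 * pi * (seq_len(n) - 1) / n
  centers <- cbind(0, r * cos(theta), r * sin(theta))
  chord <- function(k) .unit(centers[(k %% n) + 1L, ] -
                               centers[((k - 1) %% n) + 1L, ])
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    .build_strand(sequence,
                  origin = centers[k, ],
                  axis = c(1, 0, 0),
                  lat_plus = chord(k),            # toward strand k+1
                  lat_minus = -chord(k - 1),      # toward strand k-1
                  normal = .unit(c(0, centers[k, 2], centers[k, 3])),
                  e = e[k], o = pl$o[k], p = pl$p[k], face = 1,
                  chain = k)
  }))
  atoms <- with_seed(seed, .apply_noise(atoms, noise_sigma))
  fr <- new_frame(atoms, rep(sequence, n), box = box_edge)
  edges <- data.frame(from = seq_len(n), to = c(seq_len(n - 1) + 1L, 1L))
  edges$orientation <- ifelse(e[edges$from] * e[edges$to] > 0,
                              "parallel", "antiparallel")
  truth <- list(motif = "barrel", labels = rep("barrel", n),
                edges = edges, sheet_sizes = n,
                barrel = TRUE, barrel_size = n, bso_sizes = n)
  list(frame = fr, truth = truth)
}

.phi_psi_basins <- list(
  beta = list(phi = c(-150, -90), psi = c(100, 150), w = 0.4),
  ppII = list(phi = c(-90, -60), psi = c(120, 170), w = 0.3),
  alphaR = list(phi = c(-80, -50), psi = c(-60, -30), w = 0.3))

#' Build a single chain from internal coordinates
#'
#' Backbone (N, H, CA, C, O) plus a CB side-chain proxy constructed from
#' ideal bond lengths and angles by internal-coordinate chain extension.
#' \code{phi = -120, psi = 120} gives an extended strand; \code{phi = -57,
#' psi = -47} an alpha-helix.  \code{mode = "coil"} draws per-residue
#' dihedrals from a uniform mixture over allowed basins
#' (beta/polyproline-II/alpha) with rejection of self-clashes below 2.5
#' Angstrom.
#'
#' @param sequence one-letter sequence.
#' @param phi,psi backbone dihedrals in degrees (fixed mode).
#' @param mode \code{"fixed"} or \code{"coil"}.
#' @param seed RNG seed (coil mode); same seed, same coordinates.
#' @param chain chain index stamped on the atom table.
#' @param max_restarts chain rebuild attempts before a generation error.
#' @return atom data.frame (chain, res, atom, x, y, z).
#' @export
build_chain <- function(sequence, phi = -120, psi = 120,
                        mode = c("fixed", "coil"), seed = NULL, chain = 1L,
                        max_restarts = 25L) {
  mode <- match.arg(mode)
  with_seed(seed, {
    for (attempt in seq_len(max_restarts)) {
      out <- .try_build_chain(sequence, phi, psi, mode, chain)
      if (!is.null(out)) return(out)
    }
    stop("coil generation failed: persistent self-clash after ",
         max_restarts, " restarts")
  })
}

.try_build_chain <- function(sequence, phi, psi, mode, chain) {
  seq1 <- strsplit(sequence, "")[[1]]
  nres <- length(seq1)
  draw <- function() {
    if (mode == "fixed") return(c(phi, psi))
    w <- vapply(.phi_psi_basins, `[[`, numeric(1), "w")
    b <- .phi_psi_basins[[sample.int(length(w), 1, prob = w)]]
    c(stats::runif(1, b$phi[1], b$phi[2]),
      stats::runif(1, b$psi[1], b$psi[2]))
  }
  N <- matrix(NA_real_, nres, 3); CA <- N; C <- N; O <- N
  N[1, ] <- c(0, 0, 0)
  CA[1, ] <- c(1.458, 0, 0)
  ang <- (180 - 111.2) * pi / 180
  C[1, ] <- CA[1, ] + 1.525 * c(cos(ang), sin(ang), 0)
  psis <- numeric(nres)
  phis <- numeric(nres)
  dd <- draw(); phis[1] <- dd[1]; psis[1] <- dd[2]
  for (i in 2:nres) {
    placed <- FALSE
    for (try in seq_len(30L)) {
      dd <- draw()
      Ni <- place_atom(C[i - 1, ], CA[i - 1, ], N[i - 1, ],
                       1.329, 116.2, psis[i - 1])
      CAi <- place_atom(Ni, C[i - 1, ], CA[i - 1, ], 1.458, 121.7, 180)
      Ci <- place_atom(CAi, Ni, C[i - 1, ], 1.525, 111.2, dd[1])
      Oi1 <- place_atom(C[i - 1, ], Ni, CAi, 1.231, 123.0, 0)
      if (mode == "coil" && i > 2) {
        # backbone self-clash rule: 2.5 A between atoms of residues at
        # sequence separation >= 2
        older <- function(r) {
          if (r < 1) return(NULL)
          rbind(N[1:r, , drop = FALSE], CA[1:r, , drop = FALSE],
                C[1:r, , drop = FALSE], O[1:r, , drop = FALSE])
        }
        prev_i <- older(i - 2)
        prev_o <- older(i - 3)
        clash <- .min_cross_dist(prev_i, rbind(Ni, CAi, Ci)) < 2.5 ||
          (!is.null(prev_o) && .min_cross_dist(prev_o, rbind(Oi1)) < 2.5)
        if (clash) next
      }
      N[i, ] <- Ni; CA[i, ] <- CAi; C[i, ] <- Ci
      phis[i] <- dd[1]; psis[i] <- dd[2]
      O[i - 1, ] <- Oi1
      placed <- TRUE
      break
    }
    if (!placed) return(NULL)
  }
  O[nres, ] <- place_atom(C[nres, ], CA[nres, ], N[nres, ],
                          1.231, 120.8, psis[nres] + 180)
  rows <- vector("list", nres)
  for (i in seq_len(nres)) {
    pos <- list(N = N[i, ])
    if (i > 1 && seq1[i] != "P") {
      u <- .unit(N[i, ] - C[i - 1, ])
      v <- .unit(N[i, ] - CA[i, ])
      pos$H <- N[i, ] + .unit(u + v)
    }
    pos$CA <- CA[i, ]; pos$C <- C[i, ]; pos$O <- O[i, ]
    if (seq1[i] != "G")
      pos$CB <- place_atom(CA[i, ], C[i, ], N[i, ], 1.53, 110.1, 122.6)
    m <- do.call(rbind, pos)
    rows[[i]] <- data.frame(chain = chain, res = i - 1L, atom = rownames(m),
                            x = m[, 1], y = m[, 2], z = m[, 3])
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Build a frame of isolated coil monomers
#'
#' Coil chains are generated independently and placed either on a wide grid
#' (\code{"dispersed"}: every peptide is its own monomeric oligomer) or at
#' random positions in a compact cube (\code{"packed"}: contacts form at
#' random, useful for contact-graph tests), each with a random rigid
#' rotation.
#'
#' @param n_peptides number of chains.
#' @param sequence one-letter sequence.
#' @param seed RNG seed.
#' @param arrangement \code{"dispersed"} or \code{"packed"}.
#' @param spacing grid spacing (dispersed), Angstrom.
#' @param cube_edge cube edge (packed), Angstrom.
#' @return list with \code{frame} and \code{truth} (labels "coil"; no
#'   expected sheets or barrels; dispersed truth lists all-monomer oligomer
#'   sizes).
#' @export
build_coil_frame <- function(n_peptides, sequence = .default_sequence,
                             seed = NULL,
                             arrangement = c("dispersed", "packed"),
                             spacing = 60, cube_edge = 40) {
  arrangement <- match.arg(arrangement)
  with_seed(seed, {
    atoms <- do.call(rbind, lapply(seq_len(n_peptides), function(k) {
      a <- build_chain(sequence, mode = "coil", chain = k)
      m <- .xyz(a)
      m <- sweep(m, 2, colMeans(m))
      m <- m %*% t(random_rotation())
      ctr <- if (arrangement == "dispersed") {
        c((k - 1) %% 4, ((k - 1) %/% 4) %% 4, (k - 1) %/% 16) * spacing
      } else {
        stats::runif(3, 0, cube_edge)
      }
      a$x <- m[, 1] + ctr[1]; a$y <- m[, 2] + ctr[2]; a$z <- m[, 3] + ctr[3]
      a
    }))
    fr <- new_frame(atoms, rep(sequence, n_peptides))
    truth <- list(motif = "coil", labels = rep("coil", n_peptides),
                  edges = data.frame(from = integer(), to = integer(),
                                     orientation = character()),
                  sheet_sizes = integer(0), barrel = FALSE,
                  barrel_size = 0L, bso_sizes = integer(0),
                  oligomer_sizes = if (arrangement == "dispersed")
                    rep(1L, n_peptides) else NULL)
    list(frame = fr, truth = truth)
  })
}

#' Compose a scene of well-separated components
#'
#' Each component (a sheet, barrel, double layer, or coil group) is built at
#' the origin and translated to its own slot on a wide lattice, so the
#' expected contact topology of the scene is exactly the union of the
#' components.  Components are lists with a \code{motif} entry
#' ("coil", "antiparallel_sheet", "parallel_sheet", "double_layer",
#' "barrel") plus the arguments of the corresponding builder
#' (\code{n_strands} or \code{n_peptides}, \code{orientation}, ...).
#'
#' @param components list of component specifications.
#' @param sequence shared sequence.
#' @param seed RNG seed.
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @param spacing lattice spacing between component centroids, Angstrom.
#' @return list with \code{frame} and \code{truth} (aggregated expected
#'   oligomer/sheet/barrel/beta-sheet-oligomer sizes).
#' @export
build_scene <- function(components, sequence = .default_sequence,
                        seed = NULL, noise_sigma = 0, spacing = 80) {
  with_seed(seed, {
    # expand coil groups into single dispersed monomers so each component
    # occupies one lattice slot
    expanded <- list()
    for (comp in components) {
      if (comp$motif == "coil") {
        np <- comp$n_peptides %||% 1L
        for (j in seq_len(np))
          expanded[[length(expanded) + 1L]] <- list(motif = "coil",
                                                    n_peptides = 1L)
      } else expanded[[length(expanded) + 1L]] <- comp
    }
    atoms <- NULL
    chain0 <- 0L
    olig <- integer(0); sheets <- integer(0); barrels <- integer(0)
    bso <- integer(0)
    edges <- NULL
    for (ci in seq_along(expanded)) {
      comp <- expanded[[ci]]
      built <- switch(comp$motif,
        coil = build_coil_frame(1L, sequence),
        barrel = build_barrel(comp$n_strands, sequence,
                              orientation = comp$orientation %||%
                                "antiparallel"),
        build_sheet(comp$n_strands, sequence, motif = comp$motif))
      a <- built$frame$atoms
      tr <- built$truth
      m <- .xyz(a)
      m <- sweep(m, 2, colMeans(m))
      slot <- c((ci - 1) %% 4, ((ci - 1) %/% 4) %% 4, (ci - 1) %/% 16)
      a$x <- m[, 1] + slot[1] * spacing
      a$y <- m[, 2] + slot[2] * spacing
      a$z <- m[, 3] + slot[3] * spacing
      nch <- length(built$frame$sequences)
      a$chain <- a$chain + chain0
      if (nrow(tr$edges)) {
        ed <- tr$edges
        ed$from <- ed$from + chain0; ed$to <- ed$to + chain0
        edges <- rbind(edges, ed)
      }
      olig <- c(olig, if (comp$motif == "coil") rep(1L, nch) else nch)
      sheets <- c(sheets, tr$sheet_sizes)
      if (tr$barrel) barrels <- c(barrels, tr$barrel_size)
      bso <- c(bso, tr$bso_sizes)
      chain0 <- chain0 + nch
      atoms <- rbind(atoms, a)
    }
    atoms <- .apply_noise(atoms, noise_sigma)
    fr <- new_frame(atoms, rep(sequence, chain0))
    truth <- list(oligomer_sizes = sort(olig, decreasing = TRUE),
                  sheet_sizes = sort(sheets, decreasing = TRUE),
                  barrel_sizes = barrels,
                  total_barrel_size = sum(barrels),
                  bso_sizes = sort(bso, decreasing = TRUE),
                  edges = edges,
                  largest_oligomer = max(olig),
                  largest_bso = if (length(bso)) max(bso) else 0L,
                  mw_sheet_size = if (length(sheets))
                    mass_weighted_mean(sheets) else NA_real_)
    list(frame = fr, truth = truth)
  })
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Build a scripted trajectory
#'
#' A staged, scripted (not simulated) sequence of scenes: each script entry
#' holds a \code{duration_ns} and a \code{components} list (see
#' \code{\link{build_scene}}); frames are emitted every \code{dt_ns} with
#' instantaneous scene transitions.  The per-frame ground truth carries the
#' expected time-series traces, making the script the oracle for end-to-end
#' analysis tests.
#'
#' @param script list of scenes.
#' @param sequence shared sequence.
#' @param dt_ns frame stride, ns.
#' @param seed base RNG seed; frame k uses seed + k, so a fixed seed gives
#'   byte-identical output.
#' @param noise_sigma Gaussian coordinate noise, Angstrom.
#' @return list with \code{trajectory} (an \code{agg_trajectory}) and
#'   \code{truth}, a data.frame of expected per-frame traces (time,
#'   largest_oligomer, largest_beta_sheet_oligomer,
#'   mass_weighted_mean_sheet_size, total_barrel_size).
#' @export
build_trajectory <- function(script, sequence = .default_sequence,
                             dt_ns = 1, seed = 1L, noise_sigma = 0) {
  stopifnot(length(script) >= 1L)
  frames <- list()
  truth <- NULL
  t <- 0
  fi <- 0L
  for (scene in script) {
    nfr <- max(1L, round(scene$duration_ns / dt_ns))
    for (j in seq_len(nfr)) {
      fi <- fi + 1L
      sc <- build_scene(scene$components, sequence,
                        seed = if (is.null(seed)) NULL else seed + fi,
                        noise_sigma = noise_sigma)
      fr <- sc$frame
      fr$time <- t
      frames[[fi]] <- fr
      truth <- rbind(truth, data.frame(
        time = t,
        largest_oligomer = sc$truth$largest_oligomer,
        largest_beta_sheet_oligomer = sc$truth$largest_bso,
        mass_weighted_mean_sheet_size = sc$truth$mw_sheet_size,
        total_barrel_size = sc$truth$total_barrel_size))
      t <- t + dt_ns
    }
  }
  list(trajectory = new_trajectory(frames,
                                   metadata = list(scripted = TRUE)),
       truth = truth)
}
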