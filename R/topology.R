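#' Inter-peptide heavy-atom contact graph
#'
#' Two peptides are in contact when any inter-molecular heavy-atom pair is
#' within \code{control$contact_cutoff} (5.5 Angstrom, i.e. 0.55 nm), with
#' minimum image when the frame has a box.
#'
#' @param frame an \code{agg_frame}.
#' @param control an \code{\link{aggregation_control}} list.
#' @return An undirected \pkg{igraph} graph with one vertex per peptide and
#'   edge attribute \code{min_dist}.
#' @export
build_contact_graph <- function(frame, control = aggregation_control()) {
  control <- as_agg_control(control)
  n <- n_peptides(frame)
  heavy <- frame$atoms[frame$atoms$heavy, , drop = FALSE]
  coords <- split.data.frame(heavy, factor(heavy$chain, levels = seq_len(n)))
  coords <- lapply(coords, .xyz)
  from <- integer(0); to <- integer(0); md <- numeric(0)
  if (n >= 2) {
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        d <- .min_cross_dist(coords[[p]], coords[[q]], frame$box)
        if (d <= control$contact_cutoff) {
          from <- c(from, p); to <- c(to, q); md <- c(md, d)
        }
      }
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), min_dist = md)
  g
}

#' Oligomers: connected components of the contact graph
#'
#' An isolated peptide is an oligomer of size one (a monomer); the number of
#' peptides in an oligomer is its size.
#'
#' @param contact_graph graph from \code{\link{build_contact_graph}}.
#' @return list with \code{members} (list of integer vectors, one per
#'   oligomer) and \code{sizes}.
#' @export
oligomers <- function(contact_graph) {
  comp <- igraph::components(contact_graph)
  members <- split(seq_len(igraph::vcount(contact_graph)), comp$membership)
  members <- unname(members)
  list(members = members, sizes = lengths(members))
}

# E-runs of at least min_len residues per chain, as a list of index vectors
.eligible_segments <- function(ss, min_len) {
  segs <- strand_segments(ss)
  lapply(segs, function(s) {
    s <- s[s$length >= min_len, , drop = FALSE]
    s
  })
}

#' Beta-sheet pairing graph
#'
#' Two chains form a beta-sheet pairing when each contributes at least
#' \code{control$min_consecutive_E} consecutive strand (E) residues and those
#' residues are linked by at least \code{control$min_ladder_hbonds}
#' inter-chain backbone hydrogen bonds.  Each edge carries the hydrogen-bond
#' count and an orientation label: parallel when the dot product of the two
#' chains' strand-segment direction vectors (first CA to last CA of the
#' longest E-run) is positive, antiparallel otherwise.
#'
#' @param frame an \code{agg_frame}.
#' @param ss secondary structure from
#'   \code{\link{assign_secondary_structure}}.
#' @param hbonds bond table from \code{\link{detect_hbonds}}.
#' @param control an \code{\link{aggregation_control}} list.
#' @return An undirected \pkg{igraph} graph on the peptides with edge
#'   attributes \code{hbonds} and \code{orientation}
#'   ("parallel"/"antiparallel").
#' @export
pair_strands <- function(frame, ss, hbonds,
                         control = aggregation_control()) {
  control <- as_agg_control(control)
  n <- n_peptides(frame)
  segs <- .eligible_segments(ss, control$min_consecutive_E)
  in_seg <- lapply(seq_len(n), function(ch) {
    s <- segs[[ch]]
    idx <- unlist(lapply(seq_len(nrow(s)),
                         function(k) s$start[k] + seq_len(s$length[k]) - 1L))
    if (is.null(idx)) integer(0) else idx
  })
  inter <- hbonds[hbonds$donor_chain != hbonds$acceptor_chain, , drop = FALSE]
  from <- integer(0); to <- integer(0)
  cnt <- integer(0); ori <- character(0)
  if (nrow(inter)) {
    ok <- mapply(function(dc, dr, ac, ar)
      (dr %in% in_seg[[dc]]) && (ar %in% in_seg[[ac]]),
      inter$donor_chain, inter$donor_res,
      inter$acceptor_chain, inter$acceptor_res)
    inter <- inter[ok, , drop = FALSE]
  }
  if (nrow(inter)) {
    p <- pmin(inter$donor_chain, inter$acceptor_chain)
    q <- pmax(inter$donor_chain, inter$acceptor_chain)
    key <- paste(p, q)
    tab <- table(key)
    for (k in names(tab)) {
      if (tab[[k]] < control$min_ladder_hbonds) next
      pq <- as.integer(strsplit(k, " ")[[1]])
      from <- c(from, pq[1]); to <- c(to, pq[2])
      cnt <- c(cnt, as.integer(tab[[k]]))
      ori <- c(ori, .segment_orientation(frame, segs, pq[1], pq[2]))
    }
  }
  g <- igraph::make_empty_graph(n = n, directed = FALSE)
  if (length(from))
    g <- igraph::add_edges(g, rbind(from, to), hbonds = cnt,
                           orientation = ori)
  g
}

# orientation of the longest E-segment direction vectors of two chains
.segment_orientation <- function(frame, segs, p, q) {
  dirvec <- function(ch) {
    s <- segs[[ch]]
    s <- s[which.max(s$length), ]
    ca <- .atom_per_residue(frame, ch, "CA")
    i0 <- s$start + 1L
    i1 <- s$start + s$length
    d <- ca[i1, ] - ca[i0, ]
    .min_image(d, frame$box)
  }
  if (sum(dirvec(p) * dirvec(q)) > 0) "parallel" else "antiparallel"
}

#' Sheets: connected components of the pairing graph
#'
#' Connected components with at least two chains become sheet records; the
#' sheet size is its strand (chain) count and the strand adjacency is the
#' induced pairing subgraph.
#'
#' @param pairing_graph graph from \code{\link{pair_strands}}.
#' @return list of sheet records, each a list with \code{members},
#'   \code{size}, \code{edges} (data.frame from, to, hbonds, orientation) and
#'   \code{is_barrel} (FALSE until \code{\link{detect_barrels}}).
#' @export
sheets_and_layers <- function(pairing_graph) {
  comp <- igraph::components(pairing_graph)
  out <- list()
  for (cid in seq_len(comp$no)) {
    members <- which(comp$membership == cid)
    if (length(members) < 2L) next
    sub <- igraph::induced_subgraph(pairing_graph, members)
    ed <- igraph::as_data_frame(sub, what = "edges")
    ed$from <- members[as.integer(ed$from)]
    ed$to <- members[as.integer(ed$to)]
    out[[length(out) + 1L]] <- list(members = members,
                                    size = length(members),
                                    edges = ed, is_barrel = FALSE)
  }
  out
}

#' Flag closed sheets as beta-barrels
#'
#' A sheet is a closed barrel when every strand has at least two
#' hydrogen-bonded neighbours and the strand adjacency graph is 2-edge
#' connected (a single cycle through all strands cannot be broken by
#' removing one pairing), with a minimum of
#' \code{control$barrel_min_size} strands.  Edge connectivity >= 2 implies
#' both the degree condition and connectedness.
#'
#' @param sheets list from \code{\link{sheets_and_layers}}.
#' @param control an \code{\link{aggregation_control}} list.
#' @return list with \code{sheets} (is_barrel filled in) and
#'   \code{total_barrel_size}, the summed size of all barrels in the frame.
#' @export
detect_barrels <- function(sheets, control = aggregation_control()) {
  control <- as_agg_control(control)
  for (i in seq_along(sheets)) {
    s <- sheets[[i]]
    sheets[[i]]$is_barrel <- s$size >= control$barrel_min_size &&
      .edge_connectivity_ok(s)
  }
  total <- sum(vapply(sheets, function(s) if (s$is_barrel) s$size else 0L,
                      numeric(1)))
  list(sheets = sheets, total_barrel_size = as.integer(total))
}

.edge_connectivity_ok <- function(sheet) {
  idx <- match(c(sheet$edges$from, sheet$edges$to), sheet$members)
  m <- length(sheet$members)
  g <- igraph::make_empty_graph(n = m, directed = FALSE)
  g <- igraph::add_edges(g, matrix(idx, nrow = 2, byrow = TRUE))
  igraph::edge_connectivity(g) >= 2
}

#' Beta-sheet oligomers
#'
#' Sheets whose member peptides are linked by direct heavy-atom contacts are
#' grouped; the size of a beta-sheet oligomer is the number of peptides in
#' beta-sheet conformation (sheet members) within the group.
#'
#' @param contact_graph graph from \code{\link{build_contact_graph}}.
#' @param sheets list from \code{\link{sheets_and_layers}}.
#' @return list with \code{members} (peptide sets) and \code{sizes}.
#' @export
beta_sheet_oligomers <- function(contact_graph, sheets) {
  ns <- length(sheets)
  if (ns == 0L) return(list(members = list(), sizes = integer(0)))
  adj <- igraph::as_adjacency_matrix(contact_graph, sparse = FALSE) > 0
  g <- igraph::make_empty_graph(n = ns, directed = FALSE)
  if (ns >= 2) {
    for (a in 1:(ns - 1)) {
      for (b in (a + 1):ns) {
        if (any(adj[sheets[[a]]$members, sheets[[b]]$members]))
          g <- igraph::add_edges(g, c(a, b))
      }
    }
  }
  comp <- igraph::components(g)
  groups <- unname(split(seq_len(ns), comp$membership))
  members <- lapply(groups, function(gr)
    sort(unique(unlist(lapply(sheets[gr], `[[`, "members")))))
  list(members = members, sizes = lengths(members))
}

#' Full per-frame aggregation topology
#'
#' Convenience orchestration: hydrogen bonds, secondary structure, contact
#' graph, oligomers, pairing graph, sheets with barrel flags, and beta-sheet
#' oligomers for one frame.  Amide hydrogens are reconstructed first when
#' absent.
#'
#' @param frame an \code{agg_frame}.
#' @param control an \code{\link{aggregation_control}} list.
#' @return list of class \code{"frame_topology"}.
#' @export
frame_topology <- function(frame, control = aggregation_control()) {
  control <- as_agg_control(control)
  if (!any(frame$atoms$atom == "H")) frame <- reconstruct_amide_h(frame)
  hb <- detect_hbonds(frame, control)
  ss <- assign_secondary_structure(frame, hb, control)
  cg <- build_contact_graph(frame, control)
  olig <- oligomers(cg)
  pg <- pair_strands(frame, ss, hb, control)
  sh <- sheets_and_layers(pg)
  bar <- detect_barrels(sh, control)
  bso <- beta_sheet_oligomers(cg, bar$sheets)
  structure(list(time = frame$time, n_peptides = n_peptides(frame),
                 hbonds = hb, ss = ss, contact_graph = cg,
                 oligomers = olig, pairing_graph = pg,
                 sheets = bar$sheets,
                 total_barrel_size = bar$total_barrel_size,
                 beta_sheet_oligomers = bso),
            class = "frame_topology")
}

#' Serialize a frame topology as JSON
#'
#' Oligomer membership, sheet records (members, edges, orientations, barrel
#' flags) and beta-sheet oligomers in a plain JSON structure.
#'
#' @param topo a \code{"frame_topology"}.
#' @param path output path; when NULL the JSON string is returned.
#' @return \code{path} (invisibly) or a JSON string.
#' @export
topology_json <- function(topo, path = NULL) {
  x <- list(
    time = topo$time,
    n_peptides = topo$n_peptides,
    oligomers = topo$oligomers$members,
    sheets = lapply(topo$sheets, function(s)
      list(members = s$members, size = s$size, is_barrel = s$is_barrel,
           edges = s$edges)),
    total_barrel_size = topo$total_barrel_size,
    beta_sheet_oligomers = topo$beta_sheet_oligomers$members
  )
  js <- jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
  if (is.null(path)) return(as.character(js))
  writeLines(as.character(js), path)
  invisible(path)
}
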