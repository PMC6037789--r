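#' Mass-weighted mean object size
#'
#' The mass-weighted average of a set of object sizes n_i is
#' (sum n_i^2) / (sum n_i): the expected size of the object containing a
#' randomly chosen peptide.
#'
#' @param object_sizes vector of positive integer sizes.
#' @return numeric mean.
#' @examples
#' mass_weighted_mean(c(6, 2))  # 5
#' @export
mass_weighted_mean <- function(object_sizes) {
  if (length(object_sizes) == 0L)
    stop("mass_weighted_mean needs at least one object")
  if (any(object_sizes <= 0)) stop("object sizes must be positive")
  sum(object_sizes^2) / sum(object_sizes)
}

#' Mass-weighted size distribution
#'
#' Probability of finding a peptide in an object (oligomer, sheet, barrel)
#' of a given size, pooled over an analysis window:
#' P(s) = s c(s) / sum_s' s' c(s') with c(s) the occurrence count of size-s
#' objects over all frames.
#'
#' @param sizes_by_frame list of per-frame integer size vectors (empty
#'   vectors allowed), or a single pooled vector.
#' @return data.frame with columns \code{size} and \code{probability}
#'   (zero rows when the window holds no objects); the probabilities sum
#'   to one.  Attribute \code{mw_mean} carries the mass-weighted mean of the
#'   pooled sizes.
#' @export
mass_weighted_distribution <- function(sizes_by_frame) {
  pooled <- if (is.list(sizes_by_frame)) unlist(sizes_by_frame)
            else sizes_by_frame
  if (length(pooled) == 0L) {
    out <- data.frame(size = integer(0), probability = numeric(0))
    attr(out, "mw_mean") <- NA_real_
    return(out)
  }
  cnt <- table(pooled)
  s <- as.integer(names(cnt))
  w <- s * as.integer(cnt)
  out <- data.frame(size = s, probability = w / sum(w))
  attr(out, "mw_mean") <- mass_weighted_mean(pooled)
  out
}

#' Per-residue beta propensity and secondary-structure content
#'
#' For each sequence position, the fraction of (frame x chain) observations
#' labeled E over a window; also the mean beta-sheet and coil contents.
#'
#' @param ss_list list of \code{"agg_ss"} matrices, one per frame.
#' @return list with \code{per_residue} (numeric vector, one entry per
#'   position), \code{beta_content} and \code{coil_content} (scalars).
#' @export
residue_beta_propensity <- function(ss_list) {
  stopifnot(length(ss_list) >= 1L)
  acc <- NULL
  nobs <- 0L
  e_tot <- 0L; c_tot <- 0L; all_tot <- 0L
  for (ss in ss_list) {
    m <- unclass(ss)
    e <- m == "E"
    if (is.null(acc)) acc <- colSums(e) else acc <- acc + colSums(e)
    nobs <- nobs + nrow(m)
    e_tot <- e_tot + sum(e)
    c_tot <- c_tot + sum(m == "C")
    all_tot <- all_tot + length(m)
  }
  list(per_residue = acc / nobs,
       beta_content = e_tot / all_tot,
       coil_content = c_tot / all_tot)
}

#' Antiparallel/parallel strand-alignment ratio
#'
#' Hydrogen-bond-count-weighted shares of antiparallel versus parallel
#' pairings over a window: each pairing edge contributes its bond count to
#' its orientation class.
#'
#' @param pairing_graphs list of pairing graphs from
#'   \code{\link{pair_strands}} (or a single graph).
#' @return named numeric vector \code{c(antiparallel=, parallel=)} summing
#'   to one, or \code{c(NA, NA)} when the window has no pairing edges.
#' @export
alignment_ratio <- function(pairing_graphs) {
  if (inherits(pairing_graphs, "igraph"))
    pairing_graphs <- list(pairing_graphs)
  anti <- 0; par <- 0
  for (g in pairing_graphs) {
    if (igraph::ecount(g) == 0L) next
    ed <- igraph::as_data_frame(g, what = "edges")
    anti <- anti + sum(ed$hbonds[ed$orientation == "antiparallel"])
    par <- par + sum(ed$hbonds[ed$orientation == "parallel"])
  }
  tot <- anti + par
  if (tot == 0) return(c(antiparallel = NA_real_, parallel = NA_real_))
  c(antiparallel = anti / tot, parallel = par / tot)
}

#' Beta-strand length distribution
#'
#' Normalized histogram of maximal E-run lengths over all chains and frames
#' in a window.
#'
#' @param ss_list list of \code{"agg_ss"} matrices.
#' @return data.frame with columns \code{length} and \code{probability}
#'   (zero rows when no strand is present).
#' @export
strand_length_distribution <- function(ss_list) {
  lens <- unlist(lapply(ss_list, function(ss)
    unlist(lapply(strand_segments(ss), `[[`, "length"))))
  if (length(lens) == 0L)
    return(data.frame(length = integer(0), probability = numeric(0)))
  cnt <- table(lens)
  data.frame(length = as.integer(names(cnt)),
             probability = as.numeric(cnt) / sum(cnt))
}

#' Barrel occupancy statistics over a window
#'
#' The per-peptide barrel probability is the fraction of (frame x peptide)
#' observations inside a closed barrel; the size distribution is the
#' mass-weighted probability over barrel occurrences.
#'
#' @param topologies list of \code{"frame_topology"} objects.
#' @return list with \code{probability} and \code{size_distribution}.
#' @export
barrel_statistics <- function(topologies) {
  stopifnot(length(topologies) >= 1L)
  inside <- 0L; denom <- 0L
  sizes <- integer(0)
  for (tp in topologies) {
    denom <- denom + tp$n_peptides
    for (s in tp$sheets) {
      if (s$is_barrel) {
        inside <- inside + s$size
        sizes <- c(sizes, s$size)
      }
    }
  }
  list(probability = inside / denom,
       size_distribution = mass_weighted_distribution(sizes))
}

#' Per-frame aggregation time series
#'
#' The four per-frame traces: largest oligomer size, largest beta-sheet
#' oligomer size, mass-weighted mean beta-sheet size (NA when the frame has
#' no sheet) and total beta-barrel size.
#'
#' @param topologies list of \code{"frame_topology"} objects.
#' @return data.frame with columns \code{time, largest_oligomer,
#'   largest_beta_sheet_oligomer, mass_weighted_mean_sheet_size,
#'   total_barrel_size}.
#' @export
aggregation_timeseries <- function(topologies) {
  do.call(rbind, lapply(topologies, function(tp) {
    sheet_sizes <- vapply(tp$sheets, `[[`, integer(1), "size")
    data.frame(
      time = tp$time,
      largest_oligomer = max(tp$oligomers$sizes),
      largest_beta_sheet_oligomer =
        if (length(tp$beta_sheet_oligomers$sizes))
          max(tp$beta_sheet_oligomers$sizes) else 0L,
      mass_weighted_mean_sheet_size =
        if (length(sheet_sizes)) mass_weighted_mean(sheet_sizes)
        else NA_real_,
      total_barrel_size = tp$total_barrel_size)
  }))
}

#' Inter-peptide residue contact-frequency maps
#'
#' Entry (i, j) is the fraction of (frame x ordered chain pair) observations
#' in which any heavy-atom pair of residues i and j on the two chains is
#' within the contact cutoff.  Two maps are returned: backbone-backbone and
#' side-chain-side-chain (glycine, having no side-chain heavy atom, is
#' represented by its CA).  Both matrices are symmetric.
#'
#' @param frames list of \code{agg_frame} objects (an analysis window).
#' @param control an \code{\link{aggregation_control}} list.
#' @return list with \code{backbone} and \code{sidechain} matrices
#'   (nres x nres).
#' @export
contact_frequency_maps <- function(frames, control = aggregation_control()) {
  control <- as_agg_control(control)
  stopifnot(length(frames) >= 1L)
  nres <- nchar(frames[[1]]$sequences[1])
  bb <- matrix(0, nres, nres)
  sc <- matrix(0, nres, nres)
  nobs <- 0L
  for (fr in frames) {
    n <- n_peptides(fr)
    if (n < 2L) { next }
    a <- fr$atoms[fr$atoms$heavy, , drop = FALSE]
    is_bb <- a$backbone
    gly <- substring(fr$sequences[a$chain], a$res + 1L, a$res + 1L) == "G"
    is_sc <- !a$backbone | (gly & a$atom == "CA")
    for (p in 1:(n - 1)) {
      for (q in (p + 1):n) {
        nobs <- nobs + 2L   # ordered pairs (p,q) and (q,p)
        bb <- bb + 2L * .res_contact_mat(a, is_bb, p, q, nres,
                                         control$contact_cutoff, fr$box)
        sc <- sc + 2L * .res_contact_mat(a, is_sc, p, q, nres,
                                         control$contact_cutoff, fr$box)
      }
    }
  }
  if (nobs == 0L) return(list(backbone = bb, sidechain = sc))
  list(backbone = bb / nobs, sidechain = sc / nobs)
}

# symmetric 0/1 residue-contact matrix between chains p and q for one
# atom-class mask
.res_contact_mat <- function(a, mask, p, q, nres, cutoff, box) {
  ap <- a[mask & a$chain == p, , drop = FALSE]
  aq <- a[mask & a$chain == q, , drop = FALSE]
  out <- matrix(0, nres, nres)
  if (!nrow(ap) || !nrow(aq)) return(out)
  d <- .cross_dist(.xyz(ap), .xyz(aq), box)
  hit <- which(d <= cutoff, arr.ind = TRUE)
  if (nrow(hit)) {
    ij <- unique(cbind(ap$res[hit[, 1]] + 1L, aq$res[hit[, 2]] + 1L))
    out[ij] <- 1
    out[ij[, c(2, 1), drop = FALSE]] <- 1
  }
  out
}
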