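#' Per-oligomer landscape observations
#'
#' One observation per oligomer per frame: the oligomer size and the average
#' number of residues in strand (E) conformation per chain within that
#' oligomer.  The full trajectory is used (no equilibrium window), so the
#' early assembly process is captured.
#'
#' @param topologies list of \code{"frame_topology"} objects.
#' @return data.frame with columns \code{n_oligomer} and \code{n_beta_sheet}.
#' @export
oligomer_observations <- function(topologies) {
  rows <- lapply(topologies, function(tp) {
    e_per_chain <- rowSums(unclass(tp$ss) == "E")
    do.call(rbind, lapply(tp$oligomers$members, function(mem)
      data.frame(n_oligomer = length(mem),
                 n_beta_sheet = sum(e_per_chain[mem]) / length(mem))))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Two-dimensional potential of mean force
#'
#' PMF(n_oligomer, n_beta_sheet) = -k_B T ln P over a 2D histogram of the
#' observations, with k_B = 0.0019872 kcal/(mol K).  Oligomer sizes bin as
#' exact integers; the per-chain beta-content axis uses left-closed bins of
#' width \code{bin_width} residues.  The surface is shifted so its global
#' minimum is zero; unsampled bins are reported as NA, never as infinities.
#'
#' @param observations data.frame from \code{\link{oligomer_observations}},
#'   or any data.frame with columns \code{n_oligomer}, \code{n_beta_sheet};
#'   optionally a \code{weight} column (e.g. oligomer size for per-peptide
#'   weighting, see Details).
#' @param temperature temperature in Kelvin.
#' @param bin_width beta-content bin width in residues.
#' @param weighting \code{"oligomer"} (default: each oligomer occurrence
#'   counts once) or \code{"peptide"} (occurrences weighted by oligomer
#'   size).
#' @return An object of class \code{"agg_landscape"}: a list with
#'   \code{n_oligomer} (axis values), \code{beta_breaks} (left bin edges),
#'   \code{counts}, \code{probability}, \code{pmf} (kcal/mol, NA where
#'   unsampled) and \code{temperature}.
#' @export
pmf_landscape <- function(observations, temperature = 300, bin_width = 1.0,
                          weighting = c("oligomer", "peptide")) {
  weighting <- match.arg(weighting)
  if (is.null(observations) || nrow(observations) == 0L)
    stop("the landscape needs at least one observation")
  stopifnot(temperature > 0, bin_width > 0)
  w <- if (weighting == "peptide") observations$n_oligomer
       else rep(1, nrow(observations))
  no_ax <- seq_len(max(observations$n_oligomer))
  bmax <- floor(max(observations$n_beta_sheet) / bin_width)
  beta_breaks <- (0:bmax) * bin_width
  counts <- matrix(0, nrow = length(no_ax), ncol = length(beta_breaks),
                   dimnames = list(no_ax, sprintf("%g", beta_breaks)))
  bi <- pmin(floor(observations$n_beta_sheet / bin_width), bmax) + 1L
  for (k in seq_len(nrow(observations)))
    counts[observations$n_oligomer[k], bi[k]] <-
      counts[observations$n_oligomer[k], bi[k]] + w[k]
  prob <- counts / sum(counts)
  pmf <- matrix(NA_real_, nrow = nrow(prob), ncol = ncol(prob),
                dimnames = dimnames(prob))
  occ <- prob > 0
  pmf[occ] <- -.const$k_B_kcal * temperature * log(prob[occ])
  pmf[occ] <- pmf[occ] - min(pmf[occ])
  structure(list(n_oligomer = no_ax, beta_breaks = beta_breaks,
                 counts = counts, probability = prob, pmf = pmf,
                 temperature = temperature, bin_width = bin_width,
                 weighting = weighting),
            class = "agg_landscape")
}

#' @export
print.agg_landscape <- function(x, ...) {
  occ <- which(!is.na(x$pmf), arr.ind = TRUE)
  gmin <- occ[which.min(x$pmf[occ]), , drop = FALSE]
  cat(sprintf(paste0(
    "<agg_landscape> %d observations, T = %g K, %d x %d bins\n",
    "  global minimum at n_oligomer = %s, n_beta_sheet in [%s, %s)\n"),
    sum(x$counts), x$temperature, nrow(x$pmf), ncol(x$pmf),
    rownames(x$pmf)[gmin[1]], colnames(x$pmf)[gmin[2]],
    as.numeric(colnames(x$pmf)[gmin[2]]) + x$bin_width))
  invisible(x)
}

#' @export
plot.agg_landscape <- function(x, ...) {
  z <- x$pmf
  graphics::image(x = x$n_oligomer, y = x$beta_breaks + x$bin_width / 2,
                  z = z, xlab = "oligomer size",
                  ylab = "beta residues per chain",
                  main = "free energy landscape (kcal/mol)",
                  col = grDevices::hcl.colors(24, "YlOrRd", rev = TRUE), ...)
  invisible(x)
}

#' Long-form landscape table
#'
#' @param x an \code{"agg_landscape"}.
#' @param path optional TSV output path.
#' @return data.frame (n_oligomer, n_beta_bin_left, count, probability,
#'   pmf_kcal_mol); unsampled bins are omitted.
#' @export
landscape_table <- function(x, path = NULL) {
  idx <- which(x$counts > 0, arr.ind = TRUE)
  out <- data.frame(
    n_oligomer = x$n_oligomer[idx[, 1]],
    n_beta_bin_left = x$beta_breaks[idx[, 2]],
    count = x$counts[idx],
    probability = x$probability[idx],
    pmf_kcal_mol = x$pmf[idx])
  out <- out[order(out$n_oligomer, out$n_beta_bin_left), ]
  rownames(out) <- NULL
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    return(invisible(out))
  }
  out
}
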