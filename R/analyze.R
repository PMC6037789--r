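#' Analyze a peptide aggregation trajectory
#'
#' The main entry point: runs the full per-frame analysis (hydrogen bonds,
#' secondary structure, contact and pairing graphs, oligomers, sheets,
#' barrels) over a trajectory and derives the ensemble statistics --
#' time-series traces, mass-weighted size distributions, per-residue beta
#' propensity, strand-alignment ratio, strand-length distribution, barrel
#' statistics, residue contact-frequency maps and the 2D free-energy
#' landscape.  Window statistics use the equilibrium window (the trailing
#' \code{control$equilibrium_fraction} of frames); the landscape uses the
#' full trajectory so the early assembly is captured.
#'
#' @param trajectory an \code{agg_trajectory} (or a single
#'   \code{agg_frame}).
#' @param control an \code{\link{aggregation_control}} list.
#' @return An object of class \code{"agg_analysis"}: a list with
#'   \code{topologies} (per-frame \code{\link{frame_topology}}),
#'   \code{timeseries}, \code{window} (frame indices used for equilibrium
#'   statistics), \code{beta_propensity}, \code{alignment},
#'   \code{strand_lengths}, \code{oligomer_distribution},
#'   \code{sheet_distribution}, \code{barrel}, \code{contact_maps},
#'   \code{landscape} and \code{control}.
#' @seealso \code{\link{run_analysis}} for the file-to-file pipeline.
#' @examples
#' sheet <- build_sheet(4, noise_sigma = 0)
#' traj <- new_trajectory(list(sheet$frame))
#' fit <- analyze_aggregation(traj)
#' summary(fit)
#' @export
analyze_aggregation <- function(trajectory,
                                control = aggregation_control()) {
  control <- as_agg_control(control)
  if (inherits(trajectory, "agg_frame"))
    trajectory <- new_trajectory(list(trajectory))
  stopifnot(inherits(trajectory, "agg_trajectory"))
  nfr <- length(trajectory$frames)
  topo <- lapply(trajectory$frames, frame_topology, control = control)
  win <- seq.int(max(1L, floor(nfr * (1 - control$equilibrium_fraction)) + 1L),
                 nfr)
  if (nfr == 1L) win <- 1L
  ss_win <- lapply(topo[win], `[[`, "ss")
  olig_sizes <- lapply(topo[win], function(tp) tp$oligomers$sizes)
  sheet_sizes <- lapply(topo[win], function(tp)
    vapply(tp$sheets, `[[`, integer(1), "size"))
  structure(list(
    topologies = topo,
    timeseries = aggregation_timeseries(topo),
    window = win,
    beta_propensity = residue_beta_propensity(ss_win),
    alignment = alignment_ratio(lapply(topo[win], `[[`, "pairing_graph")),
    strand_lengths = strand_length_distribution(ss_win),
    oligomer_distribution = mass_weighted_distribution(olig_sizes),
    sheet_distribution = mass_weighted_distribution(sheet_sizes),
    barrel = barrel_statistics(topo[win]),
    contact_maps = contact_frequency_maps(trajectory$frames[win], control),
    landscape = pmf_landscape(oligomer_observations(topo),
                              temperature = control$pmf_temperature,
                              bin_width = control$pmf_beta_bin),
    n_frames = nfr,
    n_peptides = topo[[1]]$n_peptides,
    sequence = trajectory$frames[[1]]$sequences[1],
    control = control), class = "agg_analysis")
}

#' @export
print.agg_analysis <- function(x, ...) {
  cat(sprintf("Aggregation analysis: %d frames, %d peptides of %s\n",
              x$n_frames, x$n_peptides, x$sequence))
  cat(sprintf("  equilibrium window: frames %d-%d\n",
              x$window[1], x$window[length(x$window)]))
  last <- x$timeseries[nrow(x$timeseries), ]
  cat(sprintf(paste0("  final frame: largest oligomer %d, largest ",
                     "beta-sheet oligomer %d, total barrel size %d\n"),
              last$largest_oligomer, last$largest_beta_sheet_oligomer,
              last$total_barrel_size))
  invisible(x)
}

#' @export
summary.agg_analysis <- function(object, ...) {
  x <- object
  cat(sprintf("Aggregation analysis of %d x %s over %d frames\n",
              x$n_peptides, x$sequence, x$n_frames))
  cat(sprintf("  beta content %.3f, coil content %.3f (window)\n",
              x$beta_propensity$beta_content,
              x$beta_propensity$coil_content))
  al <- x$alignment
  if (!any(is.na(al)))
    cat(sprintf("  strand alignment: %.2f antiparallel / %.2f parallel\n",
                al["antiparallel"], al["parallel"]))
  cat(sprintf("  per-peptide barrel probability %.3f\n",
              x$barrel$probability))
  mwm <- attr(x$oligomer_distribution, "mw_mean")
  if (!is.na(mwm))
    cat(sprintf("  mass-weighted mean oligomer size %.2f\n", mwm))
  invisible(x)
}

#' @export
as.data.frame.agg_analysis <- function(x, ...) x$timeseries

#' Plot method: the four aggregation traces
#'
#' Largest oligomer (black), largest beta-sheet oligomer (red),
#' mass-weighted mean beta-sheet size (blue) and total barrel size (purple)
#' against time.
#'
#' @param x an \code{"agg_analysis"}.
#' @param ... passed to \code{matplot}.
#' @export
plot.agg_analysis <- function(x, ...) {
  ts <- x$timeseries
  cols <- c("black", "red", "blue", "purple")
  graphics::matplot(ts$time, ts[, -1], type = "s", lty = 1, col = cols,
                    xlab = "time (ns)", ylab = "size", ...)
  graphics::legend("topleft", bty = "n", lty = 1, col = cols, cex = 0.8,
                   legend = c("largest oligomer", "largest beta-sheet oligomer",
                              "mass-weighted sheet size", "total barrel size"))
  invisible(x)
}

#' Run the analysis pipeline on a trajectory file
#'
#' Reads a trajectory (multi-model PDB, or the plain-text dialect for
#' \code{.txt} inputs), runs \code{\link{analyze_aggregation}} and writes the
#' result bundle: per-frame time series, size and strand-length
#' distributions, per-residue propensities, contact maps, the landscape
#' table, per-frame topology JSON and a run manifest echoing the
#' configuration, package version and input checksum.
#'
#' @param input path to a trajectory file.
#' @param out_dir output directory (created if needed).
#' @param config an \code{\link{aggregation_control}}, a named list of
#'   control overrides, or the path of a JSON file holding one.
#' @return The \code{"agg_analysis"} object, invisibly.
#' @export
run_analysis <- function(input, out_dir, config = NULL) {
  if (is.character(config) && length(config) == 1L && file.exists(config))
    config <- jsonlite::fromJSON(config)
  control <- as_agg_control(config)
  if (!file.exists(input)) stop("unreadable input: ", input)
  traj <- if (grepl("\\.txt$", input)) read_frames_txt(input)
          else read_multimodel_pdb(input)
  fit <- analyze_aggregation(traj, control)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  wtsv <- function(df, name)
    utils::write.table(df, file.path(out_dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wtsv(fit$timeseries, "timeseries.tsv")
  wtsv(fit$oligomer_distribution, "oligomer_size_distribution.tsv")
  wtsv(fit$sheet_distribution, "sheet_size_distribution.tsv")
  wtsv(fit$barrel$size_distribution, "barrel_size_distribution.tsv")
  wtsv(fit$strand_lengths, "strand_length_distribution.tsv")
  wtsv(data.frame(residue = seq_along(fit$beta_propensity$per_residue) - 1L,
                  beta_propensity = fit$beta_propensity$per_residue),
       "beta_propensity.tsv")
  wtsv(as.data.frame(fit$contact_maps$backbone), "contact_map_backbone.tsv")
  wtsv(as.data.frame(fit$contact_maps$sidechain),
       "contact_map_sidechain.tsv")
  landscape_table(fit$landscape, file.path(out_dir, "landscape.tsv"))
  writeLines(vapply(fit$topologies, topology_json, character(1)),
             file.path(out_dir, "topology.jsonl"))
  manifest <- list(
    package = "aggscape",
    version = as.character(utils::packageVersion("aggscape")),
    input = normalizePath(input),
    input_md5 = unname(tools::md5sum(input)),
    config = unclass(control))
  writeLines(as.character(jsonlite::toJSON(manifest, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             file.path(out_dir, "manifest.json"))
  invisible(fit)
}

#' Generate a synthetic structure bundle
#'
#' Builds the requested synthetic conformation (see
#' \code{\link{build_sheet}}, \code{\link{build_barrel}},
#' \code{\link{build_coil_frame}}) and writes a multi-model PDB plus a
#' ground-truth JSON sidecar.
#'
#' @param spec named list (or path of a JSON file): \code{motif} plus the
#'   builder arguments (\code{n_strands}/\code{n_peptides},
#'   \code{sequence}, \code{orientation}, \code{noise_sigma}, \code{seed}).
#' @param out_dir output directory.
#' @param name file stem (default the motif).
#' @return Paths of the written files, invisibly.
#' @export
run_generate <- function(spec, out_dir, name = NULL) {
  if (is.character(spec) && length(spec) == 1L && file.exists(spec))
    spec <- jsonlite::fromJSON(spec)
  if (is.null(spec$motif)) stop("spec needs a 'motif' entry")
  built <- switch(spec$motif,
    coil = build_coil_frame(spec$n_peptides %||% 8L,
                            spec$sequence %||% .default_sequence,
                            seed = spec$seed),
    barrel = build_barrel(spec$n_strands %||% 6L,
                          spec$sequence %||% .default_sequence,
                          orientation = spec$orientation %||% "antiparallel",
                          noise_sigma = spec$noise_sigma %||% 0,
                          seed = spec$seed),
    antiparallel_sheet = ,
    parallel_sheet = ,
    double_layer = build_sheet(spec$n_strands %||% 6L,
                               spec$sequence %||% .default_sequence,
                               motif = spec$motif,
                               noise_sigma = spec$noise_sigma %||% 0,
                               seed = spec$seed),
    stop("unknown motif: ", spec$motif))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (is.null(name)) name <- spec$motif
  pdb <- file.path(out_dir, paste0(name, ".pdb"))
  side <- file.path(out_dir, paste0(name, "_truth.json"))
  write_multimodel_pdb(built$frame, pdb)
  truth <- c(built$truth, list(spec = spec))
  writeLines(as.character(jsonlite::toJSON(truth, auto_unbox = TRUE,
                                           digits = NA, pretty = TRUE)),
             side)
  invisible(c(pdb = pdb, truth = side))
}
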