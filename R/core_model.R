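#' @keywords internal
"_PACKAGE"

# Atomic masses for the centre-of-mass "element" convention. Only elements
# that occur in protein / nucleotide / ion / water topologies are needed.
.element_masses <- c(
  H = 1.008, C = 12.011, N = 14.007, O = 15.999,
  P = 30.974, S = 32.06, MG = 24.305, NA. = 22.990, K = 39.098
)

#' Build an atom topology table
#'
#' A topology is the per-atom metadata shared by every frame of an ensemble:
#' atom name (PDB convention), residue name, 1-based residue number in the
#' thermophilic *Bacillus* PS3 frame of reference, chain id and element.
#'
#' @param atom_name character vector of PDB atom names (non-empty).
#' @param residue_name character vector of residue names (e.g. `"ARG"`,
#'   `"ATP"`, `"MG"`, `"HOH"`).
#' @param residue_id integer vector of residue numbers (>= 1).
#' @param chain_id chain identifier(s), recycled.
#' @param element element symbol(s); derived from the first letter of
#'   `atom_name` when missing.
#' @return a `data.frame` with one row per atom.
#' @export
atom_topology <- function(atom_name, residue_name, residue_id,
                          chain_id = "A", element = NULL) {
  atom_name <- as.character(atom_name)
  if (any(!nzchar(atom_name))) stop("atom_name must be non-empty")
  residue_id <- as.integer(residue_id)
  if (any(is.na(residue_id)) || any(residue_id < 1L))
    stop("residue_id must be integers >= 1")
  if (is.null(element)) {
    element <- sub("^[0-9]*([A-Za-z]).*$", "\\1", atom_name)
    element[toupper(atom_name) == "MG"] <- "MG"
  }
  data.frame(
    atom_name = atom_name,
    residue_name = as.character(residue_name),
    residue_id = residue_id,
    chain_id = rep_len(as.character(chain_id), length(atom_name)),
    element = toupper(as.character(element)),
    stringsAsFactors = FALSE
  )
}

#' Construct a single structural frame
#'
#' @param topology topology table from [atom_topology()].
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param frame_index integer frame index (>= 0).
#' @return an object of class `mdframe`.
#' @export
md_frame <- function(topology, xyz, frame_index = 0L) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  if (ncol(xyz) != 3L) stop("xyz must have three columns")
  if (nrow(xyz) != nrow(topology))
    stop("xyz rows (", nrow(xyz), ") do not match topology atoms (",
         nrow(topology), ")")
  if (any(!is.finite(xyz))) stop("non-finite coordinates in frame")
  structure(
    list(topology = topology, xyz = xyz, frame_index = as.integer(frame_index)),
    class = "mdframe"
  )
}

.topology_key <- function(topology) {
  paste(topology$atom_name, topology$residue_name, topology$residue_id,
        topology$chain_id, sep = "|")
}

#' Construct a structural ensemble
#'
#' An ensemble is a set of replicate runs, each an ordered series of frames
#' over one shared topology — the stand-in for a set of MD trajectories.
#' Frames of all runs must share identical atom ordering and naming
#' (topology constancy); violations are rejected at construction.
#'
#' @param topology shared topology table.
#' @param runs list of runs; each run is a list of coordinate matrices
#'   (atoms x 3) or `mdframe` objects.
#' @param equilibration_fraction fraction in `[0, 1)` of leading frames of
#'   every run discarded as equilibration before any statistic is computed
#'   (the frame-count analogue of discarding the first nanoseconds of a
#'   trajectory).
#' @param label free-text ensemble label, e.g. `"WT"` or `"R103A"`.
#' @return an object of class `mdensemble`.
#' @export
md_ensemble <- function(topology, runs, equilibration_fraction = 0,
                        label = "ensemble") {
  if (!is.list(runs) || length(runs) < 1L) stop("need at least one run")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must be in [0, 1)")
  key <- .topology_key(topology)
  runs <- lapply(runs, function(run) {
    if (length(run) < 1L) stop("every run must contain at least one frame")
    lapply(run, function(fr) {
      if (inherits(fr, "mdframe")) {
        if (!identical(.topology_key(fr$topology), key))
          stop("topology constancy violated: frame atoms differ from ensemble topology")
        fr <- fr$xyz
      }
      fr <- as.matrix(fr)
      storage.mode(fr) <- "double"
      if (nrow(fr) != nrow(topology) || ncol(fr) != 3L)
        stop("topology constancy violated: coordinate block is ",
             nrow(fr), "x", ncol(fr), ", expected ", nrow(topology), "x3")
      if (any(!is.finite(fr))) stop("non-finite coordinates in ensemble frame")
      fr
    })
  })
  n_keep <- vapply(runs, function(r) {
    m <- length(r)
    m - as.integer(floor(equilibration_fraction * m))
  }, integer(1))
  if (any(n_keep < 1L))
    stop("equilibration_fraction discards every frame of at least one run")
  structure(
    list(topology = topology, runs = runs,
         equilibration_fraction = equilibration_fraction, label = label),
    class = "mdensemble"
  )
}

#' @export
print.mdensemble <- function(x, ...) {
  cat("<mdensemble> ", x$label, ": ", length(x$runs), " run(s), ",
      paste(vapply(x$runs, length, integer(1)), collapse = "/"),
      " frames, ", nrow(x$topology), " atoms, equilibration fraction ",
      format(x$equilibration_fraction), "\n", sep = "")
  invisible(x)
}

#' Extract one frame of an ensemble
#'
#' @param ensemble an `mdensemble`.
#' @param run run number.
#' @param frame frame number within the run (1-based, pre-discard indexing).
#' @return an `mdframe`.
#' @export
get_frame <- function(ensemble, run = 1L, frame = 1L) {
  md_frame(ensemble$topology, ensemble$runs[[run]][[frame]],
           frame_index = frame - 1L)
}

#' Number of analysis frames per run after the equilibration discard
#' @param ensemble an `mdensemble`.
#' @return integer vector, one element per run.
#' @export
analysis_frames <- function(ensemble) {
  vapply(ensemble$runs, function(r) {
    m <- length(r)
    m - as.integer(floor(ensemble$equilibration_fraction * m))
  }, integer(1))
}

#' Named atom selection
#'
#' A selection names a set of atoms by residue number, atom name and/or
#' residue name; `NULL` components match everything. Selections referencing
#' residues absent from a topology (e.g. arginine side-chain atoms in an
#' alanine mutant) resolve empty unless `strict = TRUE` at resolution time.
#'
#' @param name selection label.
#' @param residue_ids integer vector of residue numbers, or `NULL`.
#' @param atom_names character vector of atom names, or `NULL`.
#' @param residue_names character vector of residue names, or `NULL`.
#' @return an object of class `atom_selection`.
#' @export
selection <- function(name, residue_ids = NULL, atom_names = NULL,
                      residue_names = NULL) {
  if (is.null(residue_ids) && is.null(atom_names) && is.null(residue_names))
    stop("selection '", name, "' is empty: give residue_ids, atom_names or residue_names")
  structure(
    list(name = name,
         residue_ids = if (!is.null(residue_ids)) as.integer(residue_ids),
         atom_names = atom_names, residue_names = residue_names),
    class = "atom_selection"
  )
}

#' Resolve a selection against a frame or topology
#'
#' @param spec an [selection()] object.
#' @param frame an `mdframe`, `mdensemble` or topology table.
#' @param strict error (naming the selection) when nothing matches.
#' @return ascending integer vector of atom indices.
#' @export
resolve_selection <- function(spec, frame, strict = FALSE) {
  topo <- if (inherits(frame, c("mdframe", "mdensemble"))) frame$topology else frame
  keep <- rep(TRUE, nrow(topo))
  if (!is.null(spec$residue_ids)) keep <- keep & topo$residue_id %in% spec$residue_ids
  if (!is.null(spec$atom_names)) keep <- keep & topo$atom_name %in% spec$atom_names
  if (!is.null(spec$residue_names)) keep <- keep & topo$residue_name %in% spec$residue_names
  idx <- which(keep)
  if (strict && length(idx) == 0L)
    stop("selection '", spec$name, "' resolves to no atoms")
  sort(idx)
}

#' Replicate summary statistic
#'
#' @param mean mean over replicate-run means.
#' @param sd standard deviation over replicate-run means (0 when `n_runs` is 1).
#' @param n_runs number of replicate runs.
#' @return an object of class `summary_stat`.
#' @export
summary_stat <- function(mean, sd, n_runs) {
  n_runs <- as.integer(n_runs)
  if (n_runs < 1L) stop("n_runs must be >= 1")
  if (is.na(sd) || sd < 0) stop("sd must be >= 0")
  if (n_runs == 1L && sd != 0) stop("sd must be 0 when n_runs is 1")
  structure(list(mean = mean, sd = sd, n_runs = n_runs), class = "summary_stat")
}

#' @export
print.summary_stat <- function(x, ...) {
  cat(format_stat(x), " (n_runs = ", x$n_runs, ")\n", sep = "")
  invisible(x)
}

#' Format a summary statistic as "mean +/- sd" to two decimals
#' @param x a `summary_stat`.
#' @return character scalar.
#' @export
format_stat <- function(x) {
  sprintf("%.2f ± %.2f", x$mean, x$sd)
}

#' Reduce per-frame values over replicate runs
#'
#' For each run the leading `floor(f * m)` frames are discarded as
#' equilibration (`f` = `equilibration_fraction`, `m` = frames in the run);
#' the run mean is taken over the remaining frames.  The reported mean is
#' the mean of the run means and the reported spread is the sample
#' (n - 1 denominator) standard deviation of the run means — zero when
#' there is a single run.
#'
#' @param per_run_values list with one numeric vector of per-frame values
#'   per run.
#' @param equilibration_fraction fraction in `[0, 1)` of leading frames
#'   discarded from every run.
#' @return a [summary_stat()].
#' @export
run_statistics <- function(per_run_values, equilibration_fraction = 0) {
  if (!is.list(per_run_values)) per_run_values <- list(per_run_values)
  if (length(per_run_values) < 1L) stop("need at least one run")
  if (equilibration_fraction < 0 || equilibration_fraction >= 1)
    stop("equilibration_fraction must be in [0, 1)")
  run_means <- vapply(per_run_values, function(v) {
    m <- length(v)
    if (m < 1L) stop("each run needs at least one frame")
    drop <- floor(equilibration_fraction * m)
    if (m - drop < 1L)
      stop("equilibration_fraction discards all frames of a run")
    mean(v[(drop + 1L):m])
  }, numeric(1))
  n <- length(run_means)
  summary_stat(mean = mean(run_means),
               sd = if (n == 1L) 0 else stats::sd(run_means),
               n_runs = n)
}
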