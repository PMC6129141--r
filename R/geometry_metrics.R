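.atom_masses_for <- function(topology, convention) {
  if (convention == "unit") return(rep(1, nrow(topology)))
  m <- .element_masses[topology$element]
  if (any(is.na(m)))
    stop("unknown element(s): ",
         paste(unique(topology$element[is.na(m)]), collapse = ", "))
  unname(m)
}

#' Centre-of-mass distance between two atom selections
#'
#' Distance between the (mass-weighted) centroids of two disjoint atom
#' sets, e.g. the two C-terminal alpha-helices of the epsilon subunit.
#' Unit masses are the default; element masses are available because the
#' choice is a convention, not a measurement.
#'
#' @param frame an `mdframe`.
#' @param sel_a,sel_b [selection()]s for the two groups.
#' @param mass `"unit"` or `"element"`.
#' @return distance in Angstrom.
#' @export
com_distance <- function(frame, sel_a, sel_b, mass = c("unit", "element")) {
  mass <- match.arg(mass)
  ia <- resolve_selection(sel_a, frame, strict = TRUE)
  ib <- resolve_selection(sel_b, frame, strict = TRUE)
  if (length(intersect(ia, ib)))
    stop("helix selections overlap")
  w <- .atom_masses_for(frame$topology, mass)
  com <- function(i) colSums(frame$xyz[i, , drop = FALSE] * w[i]) / sum(w[i])
  sqrt(sum((com(ia) - com(ib))^2))
}

#' Ensemble centre-of-mass distance statistics
#' @inheritParams com_distance
#' @param ensemble an [md_ensemble()].
#' @return list with `stat` (a [summary_stat()]) and `per_frame`.
#' @export
ensemble_com_distance <- function(ensemble, sel_a, sel_b,
                                  mass = c("unit", "element")) {
  mass <- match.arg(mass)
  per_run <- lapply(seq_along(ensemble$runs), function(k)
    vapply(seq_along(ensemble$runs[[k]]), function(m)
      com_distance(get_frame(ensemble, k, m), sel_a, sel_b, mass), numeric(1)))
  list(stat = run_statistics(per_run, ensemble$equilibration_fraction),
       per_frame = per_run)
}

#' Per-frame interaction distance series
#'
#' Tracks the distance between two atoms (or the minimum over a small
#' multi-atom group, e.g. an arginine NHx pair) over the post-discard
#' frames of an ensemble, with a histogram and the mean deviation from an
#' optional crystal-reference distance.
#'
#' @param ensemble an [md_ensemble()].
#' @param sel_a,sel_b [selection()]s; in `"single"` mode each must resolve
#'   to exactly one atom, in `"min"` mode the per-frame distance is the
#'   minimum over all atom pairs.
#' @param mode `"single"` or `"min"`.
#' @param reference optional reference distance in Angstrom (e.g. from the
#'   wild-type crystal structure).
#' @param bin_width histogram bin width in Angstrom.
#' @return list with `series` (per-run list of per-analysis-frame
#'   distances), `histogram` (data.frame `bin_left`, `bin_right`, `count`),
#'   `mean`, and `mean_deviation` (NA without a reference).
#' @export
interaction_distance_series <- function(ensemble, sel_a, sel_b,
                                        mode = c("single", "min"),
                                        reference = NULL, bin_width = 0.1) {
  mode <- match.arg(mode)
  ia <- resolve_selection(sel_a, ensemble, strict = TRUE)
  ib <- resolve_selection(sel_b, ensemble, strict = TRUE)
  if (mode == "single" && (length(ia) != 1L || length(ib) != 1L))
    stop("selections must resolve to exactly one atom each in 'single' mode")
  f <- ensemble$equilibration_fraction
  series <- lapply(seq_along(ensemble$runs), function(k) {
    m <- length(ensemble$runs[[k]])
    keep <- (floor(f * m) + 1L):m
    vapply(keep, function(i) {
      xyz <- ensemble$runs[[k]][[i]]
      dd <- sqrt(pmax(0, outer(rowSums(xyz[ia, , drop = FALSE]^2),
                               rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                        2 * xyz[ia, , drop = FALSE] %*%
                          t(xyz[ib, , drop = FALSE])))
      min(dd)
    }, numeric(1))
  })
  all_d <- unlist(series)
  lo <- floor(min(all_d) / bin_width) * bin_width
  hi <- ceiling(max(all_d) / bin_width) * bin_width
  if (hi <= lo) hi <- lo + bin_width
  breaks <- seq(lo, hi, by = bin_width)
  h <- graphics::hist(all_d, breaks = breaks, plot = FALSE, right = FALSE,
            include.lowest = TRUE)
  list(
    series = series,
    histogram = data.frame(bin_left = utils::head(h$breaks, -1),
                           bin_right = utils::tail(h$breaks, -1),
                           count = h$counts),
    mean = mean(all_d),
    mean_deviation = if (is.null(reference)) NA_real_ else
      mean(all_d - reference)
  )
}

# Kabsch optimal rotation of B onto A (both pre-centred), with a reflection
# guard: if the best orthogonal map is a reflection the smallest singular
# direction is flipped, so the returned matrix is a proper rotation
# (det = +1). Degenerate (collinear/planar) configurations follow the sign
# convention of base R's La.svd.
.kabsch_rotation <- function(A, B) {
  H <- t(B) %*% A
  s <- svd(H)
  d <- sign(det(s$u %*% t(s$v)))
  if (d == 0) d <- 1
  s$u %*% diag(c(1, 1, d)) %*% t(s$v)
}

#' Superposition RMSD between two frames
#'
#' Least-squares rigid-body superposition (optimal proper rotation plus
#' translation) of the selected atoms of `frame_b` onto `frame_a`, then
#' the root-mean-square deviation of the superposed coordinates.
#'
#' @param frame_a,frame_b `mdframe`s (or plain n x 3 coordinate matrices).
#' @param sel optional [selection()] applied to both frames; atom counts
#'   and ordering must correspond.
#' @return RMSD in Angstrom (0 iff the selections are congruent).
#' @export
superpose_rmsd <- function(frame_a, frame_b, sel = NULL) {
  get_xyz <- function(fr) {
    if (inherits(fr, "mdframe")) {
      idx <- if (is.null(sel)) seq_len(nrow(fr$xyz)) else
        resolve_selection(sel, fr, strict = TRUE)
      fr$xyz[idx, , drop = FALSE]
    } else as.matrix(fr)
  }
  A <- get_xyz(frame_a)
  B <- get_xyz(frame_b)
  if (nrow(A) != nrow(B))
    stop("selections resolve to different atom counts (",
         nrow(A), " vs ", nrow(B), ")")
  Ac <- sweep(A, 2, colMeans(A))
  Bc <- sweep(B, 2, colMeans(B))
  R <- .kabsch_rotation(Ac, Bc)
  sqrt(mean(rowSums((Bc %*% R - Ac)^2)))
}

#' Reference distances from a crystal structure
#'
#' A named table of interaction distances (e.g. measured in the wild-type
#' crystal structure) against which simulated distance series are compared.
#'
#' @param distances named numeric vector of distances in Angstrom (> 0).
#' @param source source label, e.g. a PDB identifier.
#' @return object of class `reference_distances`.
#' @export
reference_distances <- function(distances, source = "crystal") {
  distances <- unlist(distances)
  if (is.null(names(distances)) || any(!nzchar(names(distances))))
    stop("reference distances must be named")
  if (any(distances <= 0)) stop("reference distances must be positive")
  structure(list(distances = distances, source = source),
            class = "reference_distances")
}
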