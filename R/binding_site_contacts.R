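#' Repulsive electrostatic contact specification
#'
#' Repulsive contacts are co-locations (minimum inter-atom distance at or
#' below `cutoff`) of two positively charged moieties in the binding site:
#' arginine guanidinium groups and the Mg2+ ion.  Counting is at the level
#' of moiety pairs — two arginines in contact through several atom pairs
#' still count once.
#'
#' @param cutoff maximum contact distance in Angstrom (default 4.5).
#' @param groups list of [selection()]s, one per charged moiety.  Defaults
#'   to the guanidinium nitrogens (NE/NH1/NH2) of Arg 92, 99, 103, 115,
#'   122 and 126 plus the Mg2+ ion; selections for arginines that are
#'   mutated to alanine in a given variant simply resolve empty there.
#' @return an object of class `contact_spec`.
#' @export
contact_spec <- function(cutoff = 4.5, groups = default_contact_groups()) {
  if (cutoff <= 0) stop("cutoff must be positive")
  if (length(groups) < 2L) stop("need at least two groups")
  structure(list(cutoff = cutoff, groups = groups), class = "contact_spec")
}

#' Default charged-moiety groups of the epsilon-subunit binding site
#' @param arg_ids arginine residue numbers (PS3 numbering).
#' @return list of [selection()]s.
#' @export
default_contact_groups <- function(arg_ids = c(92L, 99L, 103L, 115L, 122L, 126L)) {
  groups <- lapply(arg_ids, function(r)
    selection(paste0("R", r), residue_ids = r,
              atom_names = c("NE", "NH1", "NH2"), residue_names = "ARG"))
  c(groups, list(selection("MG", residue_names = "MG")))
}

#' Count repulsive contacts in a frame
#'
#' @param frame an `mdframe`.
#' @param spec a [contact_spec()].
#' @return list with `count` (number of contacting unordered group pairs),
#'   `pairs` (data.frame: `group_a`, `group_b`, `min_dist`,
#'   `n_atom_pairs` — atom pairs within the cutoff, for transparency) and
#'   `n_atom_pairs` (atom-level total).
#' @export
count_repulsive_contacts <- function(frame, spec = contact_spec()) {
  idx <- lapply(spec$groups, resolve_selection, frame = frame)
  nonempty <- which(lengths(idx) > 0L)
  if (length(nonempty) < 2L) {
    warning("fewer than two resolvable charged groups; contact count is 0")
    return(list(count = 0L,
                pairs = data.frame(group_a = character(0),
                                   group_b = character(0),
                                   min_dist = numeric(0),
                                   n_atom_pairs = integer(0)),
                n_atom_pairs = 0L))
  }
  xyz <- frame$xyz
  rows <- list()
  for (a in seq_along(nonempty)) {
    for (b in seq_len(a - 1L)) {
      ia <- idx[[nonempty[a]]]; ib <- idx[[nonempty[b]]]
      dd <- sqrt(pmax(0, outer(rowSums(xyz[ia, , drop = FALSE]^2),
                               rowSums(xyz[ib, , drop = FALSE]^2), "+") -
                        2 * xyz[ia, , drop = FALSE] %*%
                          t(xyz[ib, , drop = FALSE])))
      md <- min(dd)
      if (md <= spec$cutoff) {
        rows[[length(rows) + 1L]] <- data.frame(
          group_a = spec$groups[[nonempty[b]]]$name,
          group_b = spec$groups[[nonempty[a]]]$name,
          min_dist = md, n_atom_pairs = sum(dd <= spec$cutoff),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  pairs <- if (length(rows)) do.call(rbind, rows) else
    data.frame(group_a = character(0), group_b = character(0),
               min_dist = numeric(0), n_atom_pairs = integer(0))
  list(count = nrow(pairs), pairs = pairs,
       n_atom_pairs = sum(pairs$n_atom_pairs))
}

#' Ensemble repulsive-contact statistics
#'
#' Per-frame pair-level contact counts reduced over replicate runs with
#' [run_statistics()].
#'
#' @param ensemble an [md_ensemble()].
#' @param spec a [contact_spec()].
#' @return list with `count` (a [summary_stat()]) and `per_frame` (list of
#'   per-run numeric vectors).
#' @export
ensemble_contact_stats <- function(ensemble, spec = contact_spec()) {
  per_run <- lapply(seq_along(ensemble$runs), function(k) {
    vapply(seq_along(ensemble$runs[[k]]), function(m)
      as.numeric(suppressWarnings(
        count_repulsive_contacts(get_frame(ensemble, k, m), spec)$count)),
      numeric(1))
  })
  list(count = run_statistics(per_run, ensemble$equilibration_fraction),
       per_frame = per_run)
}

.coordination_states <- c("FIRST_SPHERE_OA_OB", "FIRST_SPHERE_OB_OG",
                          "FIRST_SPHERE_OTHER", "SECOND_SPHERE", "UNBOUND")

#' Classify the Mg2+–ATP coordination state of a frame
#'
#' First-sphere states require direct Mg–phosphate-oxygen ligation: when at
#' least one alpha- and one beta-phosphate oxygen lie within
#' `first_sphere_cutoff` of the ion the state is `FIRST_SPHERE_OA_OB`
#' (symmetrically `FIRST_SPHERE_OB_OG` for beta+gamma);
#' `FIRST_SPHERE_OTHER` covers any other direct-ligation pattern.  With no
#' phosphate oxygen in the first sphere, `SECOND_SPHERE` requires a
#' bridging water: a water oxygen within `first_sphere_cutoff` of the ion
#' and within `water_bridge_cutoff` of some phosphate oxygen.  Anything
#' else is `UNBOUND`.
#'
#' @param frame an `mdframe` containing exactly one Mg2+ ion.
#' @param first_sphere_cutoff direct-ligation cutoff in Angstrom
#'   (default 2.6, standard Mg–O coordination geometry).
#' @param water_bridge_cutoff water-to-phosphate bridge cutoff in Angstrom
#'   (default 3.5).
#' @param oa_atoms,ob_atoms,og_atoms atom names of the alpha/beta/gamma
#'   phosphate oxygens (PDB chemical-component convention by default).
#' @param mg_selection selection identifying the ion.
#' @param water_o atom name(s) of water oxygen.
#' @return one of `"FIRST_SPHERE_OA_OB"`, `"FIRST_SPHERE_OB_OG"`,
#'   `"FIRST_SPHERE_OTHER"`, `"SECOND_SPHERE"`, `"UNBOUND"`.
#' @export
classify_mg_coordination <- function(frame, first_sphere_cutoff = 2.6,
                                     water_bridge_cutoff = 3.5,
                                     oa_atoms = c("O1A", "O2A", "O3A"),
                                     ob_atoms = c("O1B", "O2B", "O3B"),
                                     og_atoms = c("O1G", "O2G", "O3G"),
                                     mg_selection = selection("MG", residue_names = "MG"),
                                     water_o = c("O", "OW")) {
  mg <- resolve_selection(mg_selection, frame)
  if (length(mg) != 1L)
    stop("expected exactly one Mg2+ ion, found ", length(mg))
  topo <- frame$topology
  xyz <- frame$xyz
  dist_to_mg <- function(i) sqrt(rowSums((xyz[i, , drop = FALSE] -
    matrix(xyz[mg, ], length(i), 3, byrow = TRUE))^2))
  phos <- list(
    a = which(topo$residue_name == "ATP" & topo$atom_name %in% oa_atoms),
    b = which(topo$residue_name == "ATP" & topo$atom_name %in% ob_atoms),
    g = which(topo$residue_name == "ATP" & topo$atom_name %in% og_atoms)
  )
  near <- vapply(phos, function(i)
    length(i) > 0L && any(dist_to_mg(i) <= first_sphere_cutoff), logical(1))
  if (near[["a"]] && near[["b"]]) return("FIRST_SPHERE_OA_OB")
  if (near[["b"]] && near[["g"]]) return("FIRST_SPHERE_OB_OG")
  if (any(near)) return("FIRST_SPHERE_OTHER")
  wat <- which(topo$residue_name %in% c("HOH", "WAT", "SOL") &
                 topo$atom_name %in% water_o)
  all_phos <- unlist(phos, use.names = FALSE)
  if (length(wat) && length(all_phos)) {
    wat_near <- wat[dist_to_mg(wat) <= first_sphere_cutoff]
    if (length(wat_near)) {
      dd <- sqrt(pmax(0, outer(rowSums(xyz[wat_near, , drop = FALSE]^2),
                               rowSums(xyz[all_phos, , drop = FALSE]^2), "+") -
                        2 * xyz[wat_near, , drop = FALSE] %*%
                          t(xyz[all_phos, , drop = FALSE])))
      if (any(dd <= water_bridge_cutoff)) return("SECOND_SPHERE")
    }
  }
  "UNBOUND"
}

#' Mg2+ coordination-state occupancy of an ensemble
#'
#' Fraction of post-discard frames (pooled over runs) in each coordination
#' state; the fractions form a probability distribution.
#'
#' @param ensemble an [md_ensemble()].
#' @param ... passed to [classify_mg_coordination()].
#' @return named numeric vector over all five states, summing to 1.
#' @export
coordination_occupancy <- function(ensemble, ...) {
  states <- character(0)
  f <- ensemble$equilibration_fraction
  for (k in seq_along(ensemble$runs)) {
    m <- length(ensemble$runs[[k]])
    keep <- (floor(f * m) + 1L):m
    states <- c(states, vapply(keep, function(i)
      classify_mg_coordination(get_frame(ensemble, k, i), ...), character(1)))
  }
  counts <- table(factor(states, levels = .coordination_states))
  frac <- as.numeric(counts) / length(states)
  names(frac) <- .coordination_states
  frac
}
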