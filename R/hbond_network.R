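#' Geometric hydrogen-bond criteria
#'
#' A hydrogen bond is recorded when the hydrogen-to-acceptor distance is at
#' most `d_max` and the deviation from donor–H–acceptor linearity is at most
#' `angle_max` (0 degrees = perfectly linear).  Both cutoffs are inclusive.
#'
#' @param d_max maximum H...acceptor distance in Angstrom (default 2.7).
#' @param angle_max maximum deviation from linearity in degrees (default 30).
#' @return an object of class `hbond_criteria`.
#' @export
hbond_criteria <- function(d_max = 2.7, angle_max = 30) {
  if (d_max <= 0) stop("d_max must be positive")
  if (angle_max <= 0 || angle_max > 180) stop("angle_max must be in (0, 180]")
  structure(list(d_max = d_max, angle_max = angle_max),
            class = "hbond_criteria")
}

#' Donor/acceptor registry
#'
#' Declares, per residue name, which heavy atoms donate (with their attached
#' hydrogen, identified by atom-name convention) and which atoms accept.
#' The force field that supplies this chemistry in a simulation package is
#' out of scope here; the registry is plain data and fully configurable.
#'
#' @param donors `data.frame` with columns `residue_name`, `donor`
#'   (heavy-atom name) and `hydrogen` (attached hydrogen name).
#' @param acceptors `data.frame` with columns `residue_name` and `atom`.
#' @return an object of class `hbond_registry`.
#' @export
hbond_registry <- function(donors, acceptors) {
  stopifnot(all(c("residue_name", "donor", "hydrogen") %in% names(donors)),
            all(c("residue_name", "atom") %in% names(acceptors)))
  structure(list(donors = donors, acceptors = acceptors),
            class = "hbond_registry")
}

#' Default donor/acceptor registry
#'
#' Covers backbone amides, the polar side chains present in the epsilon
#' subunit's binding site (Arg, Ser, Thr, Tyr, Lys, His, Asn, Gln), water,
#' and the ATP acceptors (phosphate oxygens in PDB chemical-component
#' naming, ribose and adenine nitrogens/oxygens).
#'
#' @return an [hbond_registry()].
#' @export
default_registry <- function() {
  bb <- .standard_aa
  donors <- rbind(
    data.frame(residue_name = bb[bb != "PRO"], donor = "N", hydrogen = "H",
               stringsAsFactors = FALSE),
    data.frame(
      residue_name = c("ARG", "ARG", "ARG", "ARG", "ARG",
                       "SER", "THR", "TYR", "LYS", "LYS", "LYS",
                       "HIS", "HIS", "ASN", "ASN", "GLN", "GLN",
                       "TRP", "CYS", "HOH", "HOH"),
      donor = c("NE", "NH1", "NH1", "NH2", "NH2",
                "OG", "OG1", "OH", "NZ", "NZ", "NZ",
                "ND1", "NE2", "ND2", "ND2", "NE2", "NE2",
                "NE1", "SG", "O", "O"),
      hydrogen = c("HE", "HH11", "HH12", "HH21", "HH22",
                   "HG", "HG1", "HH", "HZ1", "HZ2", "HZ3",
                   "HD1", "HE2", "HD21", "HD22", "HE21", "HE22",
                   "HE1", "HG", "H1", "H2"),
      stringsAsFactors = FALSE
    ),
    data.frame(residue_name = c("ATP", "ATP", "ATP"),
               donor = c("O2'", "O3'", "N6"),
               hydrogen = c("HO2'", "HO3'", "H61"),
               stringsAsFactors = FALSE)
  )
  acceptors <- rbind(
    data.frame(residue_name = bb, atom = "O", stringsAsFactors = FALSE),
    data.frame(
      residue_name = c("ASP", "ASP", "GLU", "GLU", "ASN", "GLN",
                       "SER", "THR", "TYR", "HIS", "HIS", "HOH"),
      atom = c("OD1", "OD2", "OE1", "OE2", "OD1", "OE1",
               "OG", "OG1", "OH", "ND1", "NE2", "O"),
      stringsAsFactors = FALSE
    ),
    data.frame(
      residue_name = "ATP",
      atom = c("O1A", "O2A", "O3A", "O1B", "O2B", "O3B", "O1G", "O2G", "O3G",
               "O2'", "O3'", "O4'", "O5'", "N1", "N3", "N7"),
      stringsAsFactors = FALSE
    )
  )
  hbond_registry(donors, acceptors)
}

# Resolve donor (D, H) index pairs and acceptor indices in a frame.
.resolve_registry <- function(frame, registry) {
  topo <- frame$topology
  res_key <- paste(topo$residue_id, topo$chain_id)
  d <- registry$donors
  dk <- paste(topo$residue_name, topo$atom_name)
  h_rows <- match(dk, paste(d$residue_name, d$hydrogen))
  donors <- NULL
  h_idx <- which(!is.na(h_rows))
  if (length(h_idx)) {
    parent_name <- d$donor[h_rows[h_idx]]
    parent <- vapply(seq_along(h_idx), function(j) {
      i <- h_idx[j]
      cand <- which(res_key == res_key[i] & topo$atom_name == parent_name[j])
      if (length(cand) == 0L)
        stop("hydrogen ", topo$atom_name[i], " of ", topo$residue_name[i],
             topo$residue_id[i], " has no registered parent donor atom ",
             parent_name[j])
      cand[1]
    }, integer(1))
    donors <- data.frame(donor = parent, hydrogen = h_idx)
  }
  ak <- paste(topo$residue_name, topo$atom_name)
  acceptors <- which(ak %in% paste(registry$acceptors$residue_name,
                                   registry$acceptors$atom))
  list(donors = donors, acceptors = acceptors)
}

#' Detect hydrogen bonds in a frame
#'
#' Reports one event for every (hydrogen, acceptor) pair whose
#' H...acceptor distance and deviation-from-linearity angle both satisfy
#' the criteria, with the acceptor distinct from the donor heavy atom and
#' the hydrogen itself.  Per-event energies use the empirical exponential
#' distance relation of [espinosa_energy()].
#'
#' @param frame an `mdframe`.
#' @param registry an [hbond_registry()].
#' @param criteria an [hbond_criteria()].
#' @param donors,acceptors optional [selection()]s restricting which donor
#'   heavy atoms / acceptor atoms participate.
#' @param energy_distance which distance feeds the energy relation:
#'   `"H-A"` (hydrogen...acceptor, default) or `"D-A"` (donor...acceptor).
#' @param energy_const energy constants, see [espinosa_energy()].
#' @return `data.frame` of class `hbond_events` with columns `frame_index`,
#'   `donor`, `hydrogen`, `acceptor` (atom indices), `donor_label`,
#'   `acceptor_label`, `d_HA`, `angle_DHA`, `energy` (kJ/mol).
#' @export
detect_hbonds <- function(frame, registry = default_registry(),
                          criteria = hbond_criteria(),
                          donors = NULL, acceptors = NULL,
                          energy_distance = c("H-A", "D-A"),
                          energy_const = espinosa_constants()) {
  energy_distance <- match.arg(energy_distance)
  res <- .resolve_registry(frame, registry)
  dn <- res$donors
  ac <- res$acceptors
  if (!is.null(donors)) {
    keep <- resolve_selection(donors, frame)
    dn <- dn[dn$donor %in% keep, , drop = FALSE]
  }
  if (!is.null(acceptors)) {
    keep <- resolve_selection(acceptors, frame)
    ac <- ac[ac %in% keep]
  }
  empty <- data.frame(frame_index = integer(0), donor = integer(0),
                      hydrogen = integer(0), acceptor = integer(0),
                      donor_label = character(0), acceptor_label = character(0),
                      d_HA = numeric(0), angle_DHA = numeric(0),
                      energy = numeric(0), stringsAsFactors = FALSE)
  class(empty) <- c("hbond_events", "data.frame")
  if (is.null(dn) || nrow(dn) == 0L || length(ac) == 0L) return(empty)
  xyz <- frame$xyz
  out <- vector("list", nrow(dn))
  for (j in seq_len(nrow(dn))) {
    H <- dn$hydrogen[j]; D <- dn$donor[j]
    a_ok <- ac[ac != D & ac != H]
    if (length(a_ok) == 0L) next
    dv <- xyz[a_ok, , drop = FALSE] -
      matrix(xyz[H, ], length(a_ok), 3, byrow = TRUE)
    d <- sqrt(rowSums(dv^2))
    inside <- which(d <= criteria$d_max)
    if (length(inside) == 0L) next
    u <- xyz[H, ] - xyz[D, ]
    cosang <- (dv[inside, , drop = FALSE] %*% u) /
      (d[inside] * sqrt(sum(u^2)))
    ang <- acos(pmin(1, pmax(-1, cosang))) * 180 / pi
    hit <- which(ang <= criteria$angle_max)
    if (length(hit) == 0L) next
    a_hit <- a_ok[inside][hit]
    out[[j]] <- data.frame(
      frame_index = frame$frame_index, donor = D, hydrogen = H,
      acceptor = a_hit,
      d_HA = d[inside][hit], angle_DHA = as.numeric(ang[hit]),
      stringsAsFactors = FALSE
    )
  }
  out <- out[!vapply(out, is.null, logical(1))]
  if (length(out) == 0L) return(empty)
  ev <- do.call(rbind, out)
  topo <- frame$topology
  lab <- function(i) paste0(topo$residue_name[i], topo$residue_id[i], ":",
                            topo$atom_name[i])
  ev$donor_label <- lab(ev$donor)
  ev$acceptor_label <- lab(ev$acceptor)
  d_for_energy <- if (energy_distance == "H-A") ev$d_HA else
    sqrt(rowSums((xyz[ev$acceptor, , drop = FALSE] -
                    xyz[ev$donor, , drop = FALSE])^2))
  ev$energy <- espinosa_energy(d_for_energy, const = energy_const)
  ev <- ev[order(ev$hydrogen, ev$acceptor),
           c("frame_index", "donor", "hydrogen", "acceptor",
             "donor_label", "acceptor_label", "d_HA", "angle_DHA", "energy")]
  rownames(ev) <- NULL
  class(ev) <- c("hbond_events", "data.frame")
  ev
}

#' Constants of the empirical hydrogen-bond energy relation
#'
#' @param A prefactor in kJ/mol (default 25300).
#' @param B decay constant in 1/Angstrom (default 3.6).
#' @return named list.
#' @export
espinosa_constants <- function(A = 25300, B = 3.6) {
  if (A <= 0 || B <= 0) stop("energy constants must be positive")
  list(A = A, B = B)
}

#' Empirical hydrogen-bond energy from the H...acceptor distance
#'
#' The exponential relation `E(d) = -A * exp(-B * d)` maps a
#' hydrogen...acceptor distance to a (negative) bond energy: shorter bonds
#' are stronger, and the energy increases strictly towards zero with
#' distance.
#'
#' @param d_HA distance(s) in Angstrom, strictly positive.
#' @param const constants from [espinosa_constants()].
#' @return energy in kJ/mol (vectorised, always negative).
#' @export
espinosa_energy <- function(d_HA, const = espinosa_constants()) {
  if (any(d_HA <= 0)) stop("distance must be positive")
  -const$A * exp(-const$B * d_HA)
}

#' Total energy of a detected hydrogen-bond network
#'
#' @param events an `hbond_events` table (possibly empty).
#' @return sum of per-event energies in kJ/mol; 0 for an empty table.
#' @export
network_energy <- function(events) {
  if (nrow(events) == 0L) return(0)
  sum(events$energy)
}

# Detect in one or both directions between two atom subsets and
# de-duplicate on the (hydrogen, acceptor) pair.
.frame_hbonds_between <- function(frame, registry, criteria, set_a, set_b,
                                  bidirectional = TRUE, ...) {
  ev <- detect_hbonds(frame, registry, criteria,
                      donors = set_a, acceptors = set_b, ...)
  if (bidirectional) {
    ev2 <- detect_hbonds(frame, registry, criteria,
                         donors = set_b, acceptors = set_a, ...)
    ev <- rbind(ev, ev2)
    ev <- ev[!duplicated(ev[, c("hydrogen", "acceptor")]), , drop = FALSE]
  }
  ev
}

#' Ensemble hydrogen-bond statistics
#'
#' Counts hydrogen bonds (and sums their network energy) per frame between
#' two atom subsets, then reduces per-frame values over replicate runs with
#' [run_statistics()].  With `bidirectional = TRUE` (the default, matching
#' a protein–ligand analysis) bonds donated in either direction are merged;
#' set it to `FALSE` for a one-way analysis.
#'
#' @param ensemble an [md_ensemble()].
#' @param set_a,set_b [selection()]s for the two sides of the interface
#'   (`NULL` = all atoms).
#' @inheritParams detect_hbonds
#' @param bidirectional merge donor->acceptor events in both directions.
#' @return list with elements `count` and `energy`, both [summary_stat()]s,
#'   plus `per_frame` (list of per-run data.frames with `count`, `energy`).
#' @export
ensemble_hbond_stats <- function(ensemble, registry = default_registry(),
                                 criteria = hbond_criteria(),
                                 set_a = NULL, set_b = NULL,
                                 bidirectional = TRUE, ...) {
  per_run <- lapply(seq_along(ensemble$runs), function(k) {
    n <- length(ensemble$runs[[k]])
    counts <- numeric(n); energies <- numeric(n)
    for (m in seq_len(n)) {
      ev <- .frame_hbonds_between(get_frame(ensemble, k, m), registry,
                                  criteria, set_a, set_b,
                                  bidirectional = bidirectional, ...)
      counts[m] <- nrow(ev)
      energies[m] <- network_energy(ev)
    }
    data.frame(count = counts, energy = energies)
  })
  f <- ensemble$equilibration_fraction
  list(
    count = run_statistics(lapply(per_run, `[[`, "count"), f),
    energy = run_statistics(lapply(per_run, `[[`, "energy"), f),
    per_frame = per_run
  )
}
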