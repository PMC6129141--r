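# Synthetic ensembles with known ground truth.
#
# Geometry is placed, not simulated: every planted interaction lives in its
# own spatial block on a coarse 3-D grid (25 A spacing), so features cannot
# interfere, and planted events sit comfortably inside the detection
# cutoffs while non-events sit comfortably outside (configurable margins).
# Atoms of one residue may therefore be far apart in space; no stage of the
# analysis infers bonds from distances within a residue, so this is
# harmless and keeps the ground truth exact.

#' Declare a planted hydrogen bond
#'
#' @param donor_resid,acceptor_resid residue numbers of the donor and
#'   acceptor residues (must be distinct from each other and from all other
#'   planted residues).
#' @param p per-frame occupancy probability.
#' @param d_mean,d_sd H...acceptor distance distribution (normal, truncated
#'   to the allowed band) for frames where the bond is present.
#' @param donor_resname,donor_atom,h_atom,acceptor_resname,acceptor_atom
#'   names used in the topology; defaults give a serine hydroxyl donating
#'   to a water oxygen, both covered by [default_registry()].
#' @return list describing the bond.
#' @export
plant_hbond <- function(donor_resid, acceptor_resid, p = 1,
                        d_mean = 1.9, d_sd = 0.1,
                        donor_resname = "SER", donor_atom = "OG",
                        h_atom = "HG",
                        acceptor_resname = "HOH", acceptor_atom = "O") {
  if (p < 0 || p > 1) stop("occupancy p must be in [0, 1]")
  if (d_mean <= 0) stop("d_mean must be positive")
  list(donor_resid = as.integer(donor_resid),
       acceptor_resid = as.integer(acceptor_resid), p = p,
       d_mean = d_mean, d_sd = d_sd,
       donor_resname = donor_resname, donor_atom = donor_atom,
       h_atom = h_atom, acceptor_resname = acceptor_resname,
       acceptor_atom = acceptor_atom)
}

#' Declare a planted repulsive contact
#'
#' Two charged moieties (arginine guanidinium groups, by residue number,
#' or the ensemble's Mg2+ ion via `resid_b = "MG"`) placed inside the
#' contact cutoff with probability `p` and outside it otherwise.
#'
#' @param resid_a,resid_b residue numbers of the two arginines (or the
#'   string `"MG"` for the ion as second partner).
#' @param p per-frame contact probability.
#' @return list describing the contact.
#' @export
plant_contact <- function(resid_a, resid_b, p = 1) {
  if (p < 0 || p > 1) stop("occupancy p must be in [0, 1]")
  list(resid_a = resid_a, resid_b = resid_b, p = p)
}

.block_origin <- function(k, spacing = 25) {
  # deterministic grid walk: block k at integer lattice coordinates
  i <- (k - 1L) %% 10L
  j <- ((k - 1L) %/% 10L) %% 10L
  l <- (k - 1L) %/% 100L
  c(i, j, l) * spacing
}

# truncated-normal draw inside [lo, hi] by rejection with a clamp fallback
.rtrunc <- function(n, mean, sd, lo, hi) {
  x <- stats::rnorm(n, mean, sd)
  bad <- which(x < lo | x > hi)
  tries <- 0L
  while (length(bad) && tries < 50L) {
    x[bad] <- stats::rnorm(length(bad), mean, sd)
    bad <- which(x < lo | x > hi)
    tries <- tries + 1L
  }
  pmin(hi, pmax(lo, x))
}

#' Generate a synthetic structural ensemble with known ground truth
#'
#' Produces an [md_ensemble()] in replicate runs whose hydrogen bonds,
#' repulsive contacts and Mg2+ coordination states are planted per frame
#' with known occupancies, together with the realized per-frame truth.
#' Planted events satisfy the detection criteria with a safety margin and
#' non-events violate them by at least the same margin, so detector output
#' is predictable from the ground truth alone.  Each planted feature draws
#' from its own random stream (derived from `seed`), so adding a feature
#' never shifts another feature's draws.
#'
#' @param hbonds list of [plant_hbond()] specs.
#' @param contacts list of [plant_contact()] specs.
#' @param mg_states `NULL`, or a character vector of coordination states
#'   (recycled over frames) from `FIRST_SPHERE_OA_OB`,
#'   `FIRST_SPHERE_OB_OG`, `FIRST_SPHERE_OTHER`, `SECOND_SPHERE`,
#'   `UNBOUND`; adds an ATP fragment, one Mg2+ and four waters.
#' @param n_runs number of replicate runs (default 3, the study design).
#' @param frames_per_run frames per run.
#' @param n_decoys inert far-away atoms added per frame.
#' @param seed integer seed (mandatory: generation is a pure function of
#'   the spec).
#' @param label ensemble label.
#' @param equilibration_fraction leading-frame discard fraction recorded on
#'   the ensemble.
#' @param criteria [hbond_criteria()] the planted bonds must satisfy.
#' @param contact_cutoff repulsive-contact cutoff the planted contacts
#'   target.
#' @param margin distance margin (Angstrom) between events and their
#'   cutoff; `margin_angle` likewise in degrees.
#' @param margin_angle angular margin in degrees.
#' @return list with `ensemble` (an [md_ensemble()]) and `truth`: per-run
#'   lists with matrices `hbond_on`, `contact_on` (frames x features) and
#'   `mg_state` (character per frame).
#' @export
gen_ensemble <- function(hbonds = list(), contacts = list(), mg_states = NULL,
                         n_runs = 3L, frames_per_run = 20L, n_decoys = 10L,
                         seed, label = "synthetic",
                         equilibration_fraction = 0,
                         criteria = hbond_criteria(), contact_cutoff = 4.5,
                         margin = 0.1, margin_angle = 5) {
  if (missing(seed)) stop("seed is mandatory")
  if (margin <= 0 || margin_angle <= 0) stop("margins must be positive")
  if (criteria$d_max - margin <= 0.5)
    stop("margin leaves no feasible bond-distance band")
  d_hi <- criteria$d_max - margin
  ang_hi <- max(criteria$angle_max - margin_angle, 0)
  if (ang_hi <= 0) stop("margin_angle leaves no feasible angle band")

  # ---- topology assembly -------------------------------------------------
  topo_rows <- list()
  add <- function(atom_name, residue_name, residue_id, element = NULL) {
    topo_rows[[length(topo_rows) + 1L]] <<-
      atom_topology(atom_name, residue_name, residue_id, element = element)
  }
  block <- 0L
  hb_meta <- list()
  for (hb in hbonds) {
    block <- block + 1L
    o <- .block_origin(block)
    add(c(hb$donor_atom, hb$h_atom), hb$donor_resname, hb$donor_resid)
    add(hb$acceptor_atom, hb$acceptor_resname, hb$acceptor_resid)
    hb_meta[[length(hb_meta) + 1L]] <- list(spec = hb, origin = o)
  }
  arg_cluster <- function() {
    # guanidinium nitrogens in a tight triangle around the group centre
    rbind(NE = c(0, 0, 0), NH1 = c(0.3, 0, 0), NH2 = c(0, 0.3, 0))
  }
  ct_meta <- list()
  arg_seen <- integer(0)
  uses_mg_contact <- any(vapply(contacts, function(ct)
    identical(ct$resid_b, "MG") || identical(ct$resid_a, "MG"), logical(1)))
  for (ct in contacts) {
    block <- block + 1L
    o <- .block_origin(block)
    for (r in c(ct$resid_a, ct$resid_b)) {
      if (identical(r, "MG")) next
      r <- as.integer(r)
      if (!r %in% arg_seen) {
        add(c("NE", "NH1", "NH2"), "ARG", r, element = "N")
        arg_seen <- c(arg_seen, r)
      }
    }
    ct_meta[[length(ct_meta) + 1L]] <- list(spec = ct, origin = o)
  }
  mg_resid <- 151L
  if (!is.null(mg_states) || uses_mg_contact) {
    add("MG", "MG", mg_resid, element = "MG")
  }
  if (!is.null(mg_states)) {
    mg_states <- match.arg(mg_states, .coordination_states, several.ok = TRUE)
    block <- block + 1L
    mg_origin <- .block_origin(block)
    add(c("O1A", "O1B", "O1G"), "ATP", 150L, element = "O")
    for (w in 1:4) add("O", "HOH", 160L + w, element = "O")
  } else {
    mg_origin <- NULL
  }
  if (n_decoys > 0L) {
    block <- block + 1L
    decoy_origin <- .block_origin(block)
    add(rep("C", n_decoys), "DCY", 500L + seq_len(n_decoys) - 1L,
        element = "C")
  }
  if (length(topo_rows) == 0L)
    stop("nothing to generate: give at least one feature or decoy")
  topo <- do.call(rbind, topo_rows)
  aidx <- function(resid, atom) {
    i <- which(topo$residue_id == resid & topo$atom_name == atom)
    stopifnot(length(i) == 1L)
    i
  }

  # ---- per-feature random streams ---------------------------------------
  # each feature owns its own seed offset, run-major layout, so (run, frame)
  # indexing is stable and adding a feature never shifts another's draws
  n_frames_total <- n_runs * frames_per_run
  hb_on <- list(); hb_d <- list(); hb_ang <- list()
  for (j in seq_along(hb_meta)) {
    spec <- hb_meta[[j]]$spec
    set.seed((seed + 101L * j) %% .Machine$integer.max)
    hb_on[[j]] <- matrix(stats::runif(n_frames_total) < spec$p,
                         nrow = n_runs, byrow = TRUE)
    lo <- 0.8
    if (spec$d_mean > d_hi || spec$d_mean < lo)
      stop("planted d_mean ", spec$d_mean,
           " outside the feasible band [", lo, ", ", d_hi, "]")
    hb_d[[j]] <- matrix(.rtrunc(n_frames_total, spec$d_mean, spec$d_sd,
                                lo, d_hi),
                        nrow = n_runs, byrow = TRUE)
    hb_ang[[j]] <- matrix(stats::runif(n_frames_total, 0, ang_hi),
                          nrow = n_runs, byrow = TRUE)
  }
  ct_on <- list()
  for (j in seq_along(ct_meta)) {
    spec <- ct_meta[[j]]$spec
    set.seed((seed + 211L * j + 50000L) %% .Machine$integer.max)
    ct_on[[j]] <- matrix(stats::runif(n_frames_total) < spec$p,
                         nrow = n_runs, byrow = TRUE)
  }
  if (n_decoys > 0L) {
    set.seed((seed + 900001L) %% .Machine$integer.max)
    decoy_jitter <- array(stats::runif(n_frames_total * n_decoys * 3, -1, 1),
                          dim = c(n_runs, frames_per_run, n_decoys * 3))
  }

  # ---- frame construction ------------------------------------------------
  base <- matrix(0, nrow(topo), 3)
  runs <- vector("list", n_runs)
  truth <- vector("list", n_runs)
  for (k in seq_len(n_runs)) {
    frames <- vector("list", frames_per_run)
    t_hb <- matrix(FALSE, frames_per_run, max(1L, length(hb_meta)))
    t_ct <- matrix(FALSE, frames_per_run, max(1L, length(ct_meta)))
    t_mg <- rep(NA_character_, frames_per_run)
    for (m in seq_len(frames_per_run)) {
      xyz <- base
      for (j in seq_along(hb_meta)) {
        spec <- hb_meta[[j]]$spec
        o <- hb_meta[[j]]$origin
        on <- hb_on[[j]][k, m]
        t_hb[m, j] <- on
        D <- aidx(spec$donor_resid, spec$donor_atom)
        H <- aidx(spec$donor_resid, spec$h_atom)
        A <- aidx(spec$acceptor_resid, spec$acceptor_atom)
        xyz[D, ] <- o
        xyz[H, ] <- o + c(1.0, 0, 0)
        if (on) {
          d <- hb_d[[j]][k, m]
          theta <- hb_ang[[j]][k, m] * pi / 180
          # acceptor at distance d from H, deviating theta from the D->H axis
          xyz[A, ] <- xyz[H, ] + d * c(cos(theta), sin(theta), 0)
        } else {
          xyz[A, ] <- xyz[H, ] + c(criteria$d_max + margin + 1.0, 0, 0)
        }
      }
      for (j in seq_along(ct_meta)) {
        spec <- ct_meta[[j]]$spec
        o <- ct_meta[[j]]$origin
        on <- ct_on[[j]][k, m]
        t_ct[m, j] <- on
        gap <- if (on) contact_cutoff - 1.0 else contact_cutoff + 2.0
        place_group <- function(resid, origin) {
          if (identical(resid, "MG")) {
            xyz[aidx(mg_resid, "MG"), ] <<- origin
          } else {
            cl <- arg_cluster()
            for (nm in rownames(cl))
              xyz[aidx(as.integer(resid), nm), ] <<- origin + cl[nm, ]
          }
        }
        place_group(spec$resid_a, o)
        place_group(spec$resid_b, o + c(gap + 0.6, 0, 0))
      }
      if (!is.null(mg_states)) {
        st <- mg_states[((m - 1L) %% length(mg_states)) + 1L]
        t_mg[m] <- st
        o <- mg_origin
        mg_i <- aidx(mg_resid, "MG")
        # only place the ion here when no planted contact owns it
        if (!uses_mg_contact) xyz[mg_i, ] <- o
        mg_pos <- xyz[mg_i, ]
        oa <- aidx(150L, "O1A"); ob <- aidx(150L, "O1B"); og <- aidx(150L, "O1G")
        wat <- vapply(1:4, function(w) aidx(160L + w, "O"), integer(1))
        far <- function(i, d) xyz[i, ] <<- mg_pos + c(d, d, 0) / sqrt(2)
        if (st == "FIRST_SPHERE_OA_OB") {
          xyz[oa, ] <- mg_pos + c(2.0, 0, 0)
          xyz[ob, ] <- mg_pos + c(0, 2.0, 0)
          far(og, 6)
          for (w in seq_along(wat)) xyz[wat[w], ] <- mg_pos + c(0, 0, 2.05 + 0.01 * w)
        } else if (st == "FIRST_SPHERE_OB_OG") {
          xyz[ob, ] <- mg_pos + c(2.0, 0, 0)
          xyz[og, ] <- mg_pos + c(0, 2.0, 0)
          far(oa, 6)
          for (w in seq_along(wat)) xyz[wat[w], ] <- mg_pos + c(0, 0, 2.05 + 0.01 * w)
        } else if (st == "FIRST_SPHERE_OTHER") {
          xyz[oa, ] <- mg_pos + c(2.0, 0, 0)
          far(ob, 6); far(og, 7)
          for (w in seq_along(wat)) xyz[wat[w], ] <- mg_pos + c(0, 0, 2.05 + 0.01 * w)
        } else if (st == "SECOND_SPHERE") {
          xyz[ob, ] <- mg_pos + c(4.2, 0, 0)
          far(oa, 8); far(og, 9)
          xyz[wat[1], ] <- mg_pos + c(2.1, 0, 0)
          for (w in 2:4) xyz[wat[w], ] <- mg_pos + c(0, 0, 5 + w)
        } else { # UNBOUND
          far(oa, 10); far(ob, 11); far(og, 12)
          for (w in seq_along(wat)) xyz[wat[w], ] <- mg_pos + c(0, 0, 8 + w)
        }
      }
      if (n_decoys > 0L) {
        di <- which(topo$residue_name == "DCY")
        jit <- matrix(decoy_jitter[k, m, ], ncol = 3)
        for (q in seq_along(di))
          xyz[di[q], ] <- decoy_origin + c(0, 0, 9 * q) + jit[q, ]
      }
      frames[[m]] <- xyz
    }
    runs[[k]] <- frames
    truth[[k]] <- list(
      hbond_on = if (length(hb_meta)) t_hb[, seq_along(hb_meta), drop = FALSE]
        else t_hb[, 0, drop = FALSE],
      contact_on = if (length(ct_meta)) t_ct[, seq_along(ct_meta), drop = FALSE]
        else t_ct[, 0, drop = FALSE],
      mg_state = t_mg
    )
  }
  list(
    ensemble = md_ensemble(topo, runs,
                           equilibration_fraction = equilibration_fraction,
                           label = label),
    truth = truth
  )
}

#' Generate forward/backward TI window tables from a known integrand
#'
#' The window profile g(lambda) is a polynomial with the given
#' coefficients (constant term first); the analytic free energy is its
#' integral over `[0, 1]`.  Independent Gaussian noise of the stated SD is
#' added per window, with separate random streams for the forward and
#' backward tables.
#'
#' @param coef polynomial coefficients of g, constant term first.
#' @param n_windows number of lambda windows (default 85).
#' @param noise_sd per-window noise SD in kcal/mol.
#' @param seed integer seed (mandatory).
#' @return list with `forward`, `backward` ([ti_table()]s) and `true_dG`.
#' @export
gen_ti_tables <- function(coef, n_windows = 85L, noise_sd = 0, seed) {
  if (missing(seed)) stop("seed is mandatory")
  if (n_windows < 2L) stop("need at least two windows")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  lambda <- seq(0, 1, length.out = n_windows)
  powers <- seq_along(coef) - 1L
  g <- vapply(lambda, function(x) sum(coef * x^powers), numeric(1))
  set.seed(seed %% .Machine$integer.max)
  fwd_noise <- stats::rnorm(n_windows, 0, noise_sd)
  set.seed((seed + 1L) %% .Machine$integer.max)
  bwd_noise <- stats::rnorm(n_windows, 0, noise_sd)
  list(
    forward = ti_table(lambda, g + fwd_noise, direction = "forward"),
    backward = ti_table(lambda, g + bwd_noise, direction = "backward"),
    true_dG = sum(coef / (powers + 1))
  )
}

#' Generate an aligned-FASTA fixture with planted substitutions
#'
#' Builds a small alignment around a PS3-like reference sequence:
#' substitution rows (by reference residue number), near-duplicate rows
#' with an exact number of mismatches (for redundancy-filter tests) and
#' gap-column insertions that shift downstream alignment columns by a
#' known amount.  Deterministic given the seed.
#'
#' @param template reference sequence (ungapped); when `NULL` a
#'   deterministic 133-residue PS3-like sequence is built from `seed`,
#'   carrying E83, R92, R99, R103, R115, R122, R126.
#' @param substitutions data.frame with columns `id`, `position`
#'   (reference numbering), `residue`; several rows per id allowed.  Each
#'   substitution row additionally receives `n_background` mutations at
#'   random non-scored positions (seeded per row), mimicking the neutral
#'   divergence real homologs carry — without it every single-substitution
#'   row would be >95% identical to the reference and vanish in the
#'   redundancy filter.
#' @param n_background background mutations per substitution row
#'   (default 20); never touches the scored binding-site positions.
#' @param duplicates data.frame with columns `id` (new row id), `source`
#'   (id to copy, or `"REF"`), `n_mismatch` (number of positions mutated).
#' @param insertions data.frame with columns `after` (reference position)
#'   and `length`: gap columns inserted into the reference (and all
#'   substitution/duplicate rows), filled with `insert_char` in rows
#'   flagged by `insert_rows` (default: none, plain gap everywhere, which
#'   keeps every row's residue numbering intact).
#' @param reference_id id of the reference row (default `"PS3"`).
#' @param seed integer seed (mandatory when `template` is `NULL` or
#'   `duplicates` are requested).
#' @param path optional output path; when given, the alignment is written
#'   as aligned FASTA.
#' @return an [msa()] (invisibly also written to `path` when given).
#' @export
gen_alignment <- function(template = NULL, substitutions = NULL,
                          duplicates = NULL, insertions = NULL,
                          reference_id = "PS3", seed = NULL, path = NULL,
                          n_background = 20L) {
  if (is.null(template)) {
    if (is.null(seed)) stop("seed is mandatory when no template is given")
    set.seed(seed %% .Machine$integer.max)
    alphabet <- strsplit("ACDEFGHIKLMNPQSTVWY", "")[[1]] # no R: planted below
    template <- sample(alphabet, 133, replace = TRUE)
    fixed <- c(`83` = "E", `92` = "R", `99` = "R", `103` = "R",
               `115` = "R", `122` = "R", `126` = "R")
    template[as.integer(names(fixed))] <- fixed
    template <- paste(template, collapse = "")
  }
  n <- nchar(template)
  rows <- list()
  rows[[reference_id]] <- strsplit(template, "")[[1]]
  scored <- intersect(c(83L, 92L, 99L, 103L, 115L, 122L, 126L), seq_len(n))
  if (!is.null(substitutions)) {
    if (n_background > 0L && is.null(seed))
      stop("seed is mandatory when substitution rows carry background divergence")
    ids <- unique(substitutions$id)
    for (q in seq_along(ids)) {
      id <- ids[q]
      s <- rows[[reference_id]]
      sub_i <- substitutions[substitutions$id == id, , drop = FALSE]
      if (any(sub_i$position < 1L | sub_i$position > n))
        stop("substitution position out of range for '", id, "'")
      if (n_background > 0L) {
        set.seed((seed + 3000L + q) %% .Machine$integer.max)
        pos <- sample(setdiff(seq_len(n), c(scored, sub_i$position)),
                      min(n_background, n - length(scored)))
        for (p in pos) s[p] <- setdiff(c("A", "G", "V", "T"), s[p])[1]
      }
      s[sub_i$position] <- sub_i$residue
      rows[[id]] <- s
    }
  }
  if (!is.null(duplicates)) {
    if (is.null(seed)) stop("seed is mandatory when duplicates are requested")
    for (q in seq_len(nrow(duplicates))) {
      src <- duplicates$source[q]
      src_id <- if (identical(src, "REF")) reference_id else src
      if (is.null(rows[[src_id]])) stop("duplicate source '", src, "' unknown")
      s <- rows[[src_id]]
      set.seed((seed + 7000L + q) %% .Machine$integer.max)
      pos <- sample(setdiff(seq_len(n), c(83, 92, 99, 103, 115, 122, 126)),
                    duplicates$n_mismatch[q])
      for (p in pos) {
        cur <- s[p]
        s[p] <- setdiff(c("A", "G", "V", "T"), cur)[1]
      }
      rows[[duplicates$id[q]]] <- s
    }
  }
  if (!is.null(insertions)) {
    insertions <- insertions[order(insertions$after, decreasing = TRUE), ,
                             drop = FALSE]
    for (q in seq_len(nrow(insertions))) {
      at <- insertions$after[q]
      len <- insertions$length[q]
      rows <- lapply(rows, function(s)
        append(s, rep("-", len), after = at))
    }
  }
  out <- msa(ids = names(rows),
             seqs = vapply(rows, paste, character(1), collapse = ""))
  if (!is.null(path)) {
    lines <- as.vector(rbind(paste0(">", out$ids), out$seqs))
    writeLines(lines, path)
  }
  out
}
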