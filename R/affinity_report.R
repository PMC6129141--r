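#' Per-variant statistics bundle
#'
#' Collects the replicate-reduced statistics of one protein variant at one
#' Mg2+ coordination tag, as consumed by the comparative affinity ranking:
#' protein–ligand hydrogen-bond count and network energy, the internal
#' hydrogen bonds of the second C-terminal helix to the rest of the
#' protein, the repulsive-contact count and the helix centre-of-mass
#' distance.
#'
#' @param label variant label, e.g. `"WT"`, `"R103A"`, `"R103A/R115A"`.
#' @param coordination coordination tag, e.g. `"Oa/Ob"` or `"Ob/Og"`.
#' @param hbond_count,hbond_energy,helix_hbond_count,repulsive_contacts,com_distance
#'   [summary_stat()]s; `hbond_energy` in kJ/mol, `com_distance` in
#'   Angstrom; `helix_hbond_count` and `com_distance` may be `NULL`.
#' @return object of class `variant_stats`.
#' @export
variant_stats <- function(label, coordination = "Oa/Ob",
                          hbond_count, hbond_energy,
                          repulsive_contacts,
                          helix_hbond_count = NULL, com_distance = NULL) {
  for (s in list(hbond_count, hbond_energy, repulsive_contacts))
    if (!inherits(s, "summary_stat")) stop("statistics must be summary_stat objects")
  structure(
    list(label = label, coordination = coordination,
         hbond_count = hbond_count, hbond_energy = hbond_energy,
         helix_hbond_count = helix_hbond_count,
         repulsive_contacts = repulsive_contacts,
         com_distance = com_distance),
    class = "variant_stats"
  )
}

# Two means separated beyond their combined (quadrature-summed) SD?
.separated <- function(s1, s2) {
  abs(s1$mean - s2$mean) > sqrt(s1$sd^2 + s2$sd^2)
}

#' Preferred Mg2+ coordination state of one variant
#'
#' Between the two coordination tags of the same variant, the preferred
#' state is the one with the more favourable (more negative) hydrogen-bond
#' network energy; `"tie"` when the means are inseparable within the
#' combined SD.  When a TI placement comparison is supplied, the rationale
#' records whether the enthalpic preference agrees with the free-energy
#' verdict.
#'
#' @param stats_a,stats_b [variant_stats()] for the two coordination tags
#'   (same variant label).
#' @param ti_comparison optional [compare_placements()] result.
#' @return list with `tag` (the preferred coordination tag or `"tie"`) and
#'   `rationale` (character vector).
#' @export
preferred_coordination <- function(stats_a, stats_b, ti_comparison = NULL) {
  if (!identical(stats_a$label, stats_b$label))
    stop("coordination comparison requires the same variant label")
  if (identical(stats_a$coordination, stats_b$coordination))
    stop("both inputs carry coordination tag '", stats_a$coordination, "'")
  ea <- stats_a$hbond_energy; eb <- stats_b$hbond_energy
  rationale <- sprintf(
    "E_HB %s: %s kJ/mol vs %s: %s kJ/mol",
    stats_a$coordination, format_stat(ea), stats_b$coordination, format_stat(eb))
  if (!.separated(ea, eb)) {
    tag <- "tie"
  } else {
    tag <- if (ea$mean < eb$mean) stats_a$coordination else stats_b$coordination
  }
  if (!is.null(ti_comparison) && tag != "tie") {
    agrees <- identical(ti_comparison$most_favourable, tag)
    rationale <- c(rationale, paste0(
      "free-energy comparison prefers ", ti_comparison$most_favourable,
      if (agrees) " - in agreement with the enthalpic preference"
      else " - in disagreement with the enthalpic preference"))
  }
  list(tag = tag, rationale = rationale)
}

#' Rank variants by hydrogen-bond energetics and repulsive contacts
#'
#' Variants are ordered by mean hydrogen-bond network energy (most
#' negative, i.e. most favourable, first).  Relative to the reference
#' variant each other variant is classed `"higher-than-reference"` when
#' BOTH its network energy is more favourable AND its repulsive-contact
#' count is lower, each beyond the combined SD; `"lower"` symmetrically
#' when both criteria separate in the unfavourable direction; `"similar"`
#' otherwise.  The verdict is strictly ordinal: no dissociation constant
#' is computed, and any Kd values passed in are echoed as metadata only.
#'
#' @param stats list of [variant_stats()] (unique labels, all at their
#'   preferred coordination tag).
#' @param reference_label label of the reference variant (e.g. `"WT"`).
#' @param reference_kd optional named list/vector of experimental Kd
#'   strings (metadata, passed through untouched).
#' @return object of class `affinity_verdict` with `ranking` (labels, most
#'   favourable first), `classes`, `rationale` and `reference_kd`.
#' @export
rank_variants <- function(stats, reference_label, reference_kd = NULL) {
  labels <- vapply(stats, `[[`, character(1), "label")
  if (anyDuplicated(labels)) stop("duplicate variant labels")
  if (!reference_label %in% labels)
    stop("reference label '", reference_label, "' not among variants")
  names(stats) <- labels
  energies <- vapply(stats, function(s) s$hbond_energy$mean, numeric(1))
  # stable sort: ties keep input order
  ranking <- labels[order(energies)]
  ref <- stats[[reference_label]]
  classes <- character(0)
  rationale <- list()
  for (lab in labels) {
    if (lab == reference_label) {
      classes[lab] <- "reference"
      rationale[[lab]] <- sprintf("%s is the reference variant", lab)
      next
    }
    v <- stats[[lab]]
    e_sep <- .separated(v$hbond_energy, ref$hbond_energy)
    c_sep <- .separated(v$repulsive_contacts, ref$repulsive_contacts)
    e_better <- v$hbond_energy$mean < ref$hbond_energy$mean
    c_better <- v$repulsive_contacts$mean < ref$repulsive_contacts$mean
    fired <- character(0)
    if (e_sep)
      fired <- c(fired, sprintf(
        "E_HB %s (%s kJ/mol) is %s favourable than %s (%s kJ/mol)",
        lab, format_stat(v$hbond_energy),
        if (e_better) "more" else "less",
        reference_label, format_stat(ref$hbond_energy)))
    if (c_sep)
      fired <- c(fired, sprintf(
        "repulsive contacts %s (%s) are %s than %s (%s)",
        lab, format_stat(v$repulsive_contacts),
        if (c_better) "fewer" else "more",
        reference_label, format_stat(ref$repulsive_contacts)))
    cls <- if (e_sep && c_sep && e_better && c_better) {
      "higher-than-reference"
    } else if (e_sep && c_sep && !e_better && !c_better) {
      "lower"
    } else {
      "similar"
    }
    if (length(fired) == 0L)
      fired <- sprintf("no criterion separates %s from %s beyond the combined SD",
                       lab, reference_label)
    classes[lab] <- cls
    rationale[[lab]] <- fired
  }
  structure(
    list(ranking = ranking, classes = classes, rationale = rationale,
         reference_label = reference_label,
         reference_kd = reference_kd, stats = stats),
    class = "affinity_verdict"
  )
}

#' @export
print.affinity_verdict <- function(x, ...) {
  cat("<affinity_verdict> ranking (most favourable first): ",
      paste(x$ranking, collapse = " > "), "\n", sep = "")
  for (lab in x$ranking)
    cat("  ", lab, ": ", x$classes[[lab]], "\n", sep = "")
  invisible(x)
}

#' Render the comparative affinity report
#'
#' Deterministic human-readable (Markdown) and machine-readable (TSV /
#' JSON) rendering of an [rank_variants()] verdict, with statistics
#' formatted "mean ± sd" to two decimals.  When a single variant is given
#' the ranking section is omitted.
#'
#' @param verdict an `affinity_verdict`.
#' @param format one of `"markdown"`, `"tsv"`, `"json"`.
#' @return character scalar (Markdown/JSON) or data.frame (TSV rows).
#' @export
render_report <- function(verdict, format = c("markdown", "tsv", "json")) {
  format <- match.arg(format)
  stats <- verdict$stats
  tab <- do.call(rbind, lapply(stats[verdict$ranking], function(s) {
    data.frame(
      label = s$label, coordination = s$coordination,
      hbonds = format_stat(s$hbond_count),
      helix_hbonds = if (is.null(s$helix_hbond_count)) NA_character_ else
        format_stat(s$helix_hbond_count),
      energy_kJmol = format_stat(s$hbond_energy),
      repulsive_contacts = format_stat(s$repulsive_contacts),
      com_distance_A = if (is.null(s$com_distance)) NA_character_ else
        format_stat(s$com_distance),
      class = verdict$classes[[s$label]],
      stringsAsFactors = FALSE
    )
  }))
  rownames(tab) <- NULL
  if (format == "tsv") return(tab)
  if (format == "json") {
    payload <- list(ranking = verdict$ranking,
                    classes = as.list(verdict$classes),
                    table = tab,
                    rationale = verdict$rationale)
    if (!is.null(verdict$reference_kd))
      payload$reference_kd <- as.list(verdict$reference_kd)
    return(as.character(jsonlite::toJSON(payload, auto_unbox = TRUE,
                                         digits = NA, pretty = TRUE)))
  }
  lines <- c("# Comparative ATP-affinity report", "")
  hdr <- paste(names(tab), collapse = " | ")
  sep <- paste(rep("---", ncol(tab)), collapse = " | ")
  body <- apply(tab, 1, function(r) paste(ifelse(is.na(r), "-", r),
                                          collapse = " | "))
  lines <- c(lines, paste("|", hdr, "|"), paste("|", sep, "|"),
             paste("|", body, "|"), "")
  if (length(stats) > 1L) {
    lines <- c(lines, "## Ranking (most favourable first)", "",
               paste(seq_along(verdict$ranking), verdict$ranking,
                     sep = ". "), "",
               "## Rationale", "")
    for (lab in verdict$ranking)
      lines <- c(lines, paste0("- ", lab, ": ",
                               paste(verdict$rationale[[lab]],
                                     collapse = "; ")))
  }
  if (!is.null(verdict$reference_kd)) {
    lines <- c(lines, "", "## Reference dissociation constants (metadata)", "")
    for (lab in names(verdict$reference_kd))
      lines <- c(lines, paste0("- ", lab, ": ", verdict$reference_kd[[lab]]))
  }
  paste(lines, collapse = "\n")
}
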