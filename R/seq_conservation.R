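#' Read a multiple sequence alignment
#'
#' Aligned FASTA or Clustal input; Clustal consensus lines are ignored.
#' Sequences are upper-cased; ids must be unique and all rows equally long.
#'
#' @param path file path.
#' @param format `"fasta"` or `"clustal"`.
#' @return object of class `msa`: list with `ids`, `seqs` (character
#'   vectors) and `width`.
#' @export
read_alignment <- function(path, format = c("fasta", "clustal")) {
  format <- match.arg(format)
  aln <- tryCatch(
    seqinr::read.alignment(path, format = format, forceToLower = FALSE),
    error = function(e) {
      # seqinr's clustal reader needs >= 2 blocks; short alignments from
      # real tools come in one block, so parse those directly
      if (format != "clustal") stop(e)
      .read_clustal_single(path)
    })
  msa(ids = unlist(aln$nam), seqs = toupper(unlist(aln$seq)))
}

.read_clustal_single <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!startsWith(lines[1], "CLUSTAL")) stop("not a CLUSTAL file: ", path)
  lines <- lines[-1]
  keep <- nzchar(trimws(lines)) & !startsWith(lines, " ")
  fields <- regmatches(lines[keep],
                       regexec("^(\\S+)\\s+([A-Za-z.~-]+)\\s*\\d*$", lines[keep]))
  fields <- fields[lengths(fields) == 3L]
  nam <- vapply(fields, `[[`, character(1), 2)
  seqs <- vapply(fields, `[[`, character(1), 3)
  agg <- vapply(unique(nam), function(id)
    paste(seqs[nam == id], collapse = ""), character(1))
  list(nam = unique(nam), seq = unname(agg))
}

#' Construct an alignment object from vectors
#' @param ids sequence identifiers (unique).
#' @param seqs gapped sequences over the amino-acid alphabet plus `-`
#'   (uniform length).
#' @return object of class `msa`.
#' @export
msa <- function(ids, seqs) {
  ids <- as.character(ids)
  seqs <- toupper(as.character(seqs))
  if (length(ids) != length(seqs)) stop("ids and seqs differ in length")
  if (anyDuplicated(ids)) stop("duplicate sequence ids")
  w <- nchar(seqs)
  if (length(unique(w)) > 1L) {
    bad <- ids[which(w != w[1])[1]]
    stop("ragged alignment: sequence '", bad, "' has length ",
         nchar(seqs[ids == bad]), ", expected ", w[1])
  }
  structure(list(ids = ids, seqs = seqs, width = w[1]), class = "msa")
}

#' @export
print.msa <- function(x, ...) {
  cat("<msa> ", length(x$ids), " sequences x ", x$width, " columns\n", sep = "")
  invisible(x)
}

.char_matrix <- function(aln) {
  do.call(rbind, strsplit(aln$seqs, ""))
}

#' Pairwise percent identity of two gapped sequences
#'
#' Identity = matching residues / columns where both sequences are
#' ungapped (0 when no such column exists).  The alternative denominator
#' (full alignment length) is available for sensitivity checks.
#'
#' @param s1,s2 gapped sequence strings of equal length.
#' @param denominator `"mutual"` (mutually non-gap columns, default) or
#'   `"columns"` (alignment length).
#' @return fraction in `[0, 1]`.
#' @export
pair_identity <- function(s1, s2, denominator = c("mutual", "columns")) {
  denominator <- match.arg(denominator)
  a <- strsplit(toupper(s1), "")[[1]]
  b <- strsplit(toupper(s2), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in length")
  both <- a != "-" & b != "-"
  denom <- if (denominator == "mutual") sum(both) else length(a)
  if (denom == 0L) return(0)
  sum(a == b & both) / denom
}

#' Remove redundant sequences from an alignment
#'
#' Greedy first-come clustering: scanning in input order, a sequence is
#' kept only when its identity to every already-kept sequence is below the
#' threshold.  Idempotent; always keeps the first representative of each
#' cluster.
#'
#' @param aln an [msa()].
#' @param threshold identity threshold (default 0.95).
#' @param denominator see [pair_identity()].
#' @return the filtered [msa()].
#' @export
remove_redundant <- function(aln, threshold = 0.95,
                             denominator = c("mutual", "columns")) {
  denominator <- match.arg(denominator)
  keep <- integer(0)
  for (i in seq_along(aln$ids)) {
    redundant <- any(vapply(keep, function(j)
      pair_identity(aln$seqs[i], aln$seqs[j], denominator) >= threshold,
      logical(1)))
    if (!redundant) keep <- c(keep, i)
  }
  msa(aln$ids[keep], aln$seqs[keep])
}

#' Map reference residue numbers to alignment columns
#'
#' The k-th non-gap column of the reference sequence corresponds to
#' residue `k + offset` in the reference numbering (PS3 numbering for the
#' thermophilic *Bacillus* PS3 reference); the map is bijective on the
#' ungapped reference positions.
#'
#' @param aln an [msa()].
#' @param reference_id id of the reference sequence.
#' @param offset added to the ungapped rank to obtain the residue number
#'   (0 when the reference starts at residue 1).
#' @return object of class `position_map`: data.frame with `position` and
#'   `column`, plus attributes `reference_id`, `offset`.
#' @export
build_position_map <- function(aln, reference_id, offset = 0L) {
  i <- match(reference_id, aln$ids)
  if (is.na(i)) stop("reference '", reference_id, "' not in alignment")
  chars <- strsplit(aln$seqs[i], "")[[1]]
  cols <- which(chars != "-")
  structure(
    data.frame(position = seq_along(cols) + as.integer(offset),
               column = cols),
    class = c("position_map", "data.frame"),
    reference_id = reference_id, offset = as.integer(offset)
  )
}

#' Alignment column of a reference residue number
#' @param map a [build_position_map()] result.
#' @param position residue number(s).
#' @return alignment column(s); error for unmapped positions.
#' @export
position_to_column <- function(map, position) {
  i <- match(position, map$position)
  if (any(is.na(i)))
    stop("position(s) not mapped: ",
         paste(position[is.na(i)], collapse = ", "))
  map$column[i]
}

#' Reference residue number at an alignment column
#' @param map a [build_position_map()] result.
#' @param column alignment column(s).
#' @return residue number(s); error for columns gapped in the reference.
#' @export
column_to_position <- function(map, column) {
  i <- match(column, map$column)
  if (any(is.na(i)))
    stop("column(s) gapped in the reference: ",
         paste(column[is.na(i)], collapse = ", "))
  map$position[i]
}

#' Profile binding-site positions across an alignment
#'
#' Extracts, for every sequence, the residues at the PS3-numbered
#' binding-site positions and derives an ordinal affinity hypothesis from
#' the substitution pattern: a substitution at position 103 or 115 with
#' the ligand-binding set (E83, R92, R99, R122, R126) fully conserved
#' suggests `increased-affinity` (by analogy with the alanine mutants); a
#' 103/115 substitution co-occurring with a binding-set substitution is
#' `indeterminate`; everything else is `baseline`.  A gap at a scored
#' position counts as a substitution and flags the profile as confounded.
#' A histidine at 103 keeps the increased-affinity label but carries a
#' caveat: its imidazole ring is titratable near neutral pH, so the
#' substitution's effect may be pH-dependent.
#'
#' @param aln an [msa()].
#' @param map a [build_position_map()] for the PS3 reference.
#' @param positions scored residue numbers
#'   (default `c(83, 92, 99, 103, 115, 122, 126)`).
#' @param binding_set positions whose conservation defines the intact
#'   ligand-binding set (default `c(83, 92, 99, 122, 126)`).
#' @param variable_positions positions whose substitution drives the
#'   hypothesis (default `c(103, 115)`).
#' @return data.frame of class `binding_site_profiles`: one row per
#'   sequence with `id`, one `pos<k>` column per scored position, flags
#'   `binding_set_conserved`, `pos103_substituted`, `pos115_substituted`,
#'   `confound`, plus `hypothesis` and `caveats`.
#' @export
profile_binding_sites <- function(aln, map,
                                  positions = c(83L, 92L, 99L, 103L, 115L, 122L, 126L),
                                  binding_set = c(83L, 92L, 99L, 122L, 126L),
                                  variable_positions = c(103L, 115L)) {
  cols <- position_to_column(map, positions)
  chars <- .char_matrix(aln)
  ref_row <- match(attr(map, "reference_id"), aln$ids)
  if (is.na(ref_row)) stop("reference sequence missing from alignment")
  ref_res <- chars[ref_row, cols]
  names(ref_res) <- positions
  out <- lapply(seq_along(aln$ids), function(i) {
    res <- chars[i, cols]
    names(res) <- positions
    sub_at <- res != ref_res
    gap_at <- res == "-"
    bs <- as.character(binding_set)
    vp <- as.character(variable_positions)
    binding_conserved <- !any(sub_at[bs])
    var_sub <- sub_at[vp]
    confound <- any(sub_at[bs]) || any(gap_at)
    hypothesis <- if (any(var_sub) && binding_conserved) {
      "increased-affinity"
    } else if (any(var_sub)) {
      "indeterminate"
    } else {
      "baseline"
    }
    caveats <- character(0)
    if ("103" %in% vp && "103" %in% names(res) &&
        res[["103"]] == "H" && hypothesis == "increased-affinity")
      caveats <- c(caveats,
                   "histidine at 103: imidazole is titratable near neutral pH, effect may be pH-dependent")
    row <- data.frame(id = aln$ids[i], stringsAsFactors = FALSE)
    for (p in as.character(positions)) row[[paste0("pos", p)]] <- res[[p]]
    row$binding_set_conserved <- binding_conserved
    row$pos103_substituted <- isTRUE(unname(sub_at["103"]))
    row$pos115_substituted <- isTRUE(unname(sub_at["115"]))
    row$confound <- confound
    row$hypothesis <- hypothesis
    row$caveats <- paste(caveats, collapse = "; ")
    row
  })
  out <- do.call(rbind, out)
  class(out) <- c("binding_site_profiles", "data.frame")
  out
}
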