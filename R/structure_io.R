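# Multi-model PDB is the sole ensemble format: desk-scale, text-only and
# sufficient for geometric analysis. No binary trajectory formats.

.standard_aa <- c("ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY",
                  "HIS", "ILE", "LEU", "LYS", "MET", "PHE", "PRO", "SER",
                  "THR", "TRP", "TYR", "VAL")

# Validate MODEL/ATOM structure of a PDB file before handing it to the
# parser, so errors can name the file, model and line.
.precheck_pdb <- function(path) {
  lines <- readLines(path, warn = FALSE)
  rec <- substr(lines, 1, 6)
  is_atom <- rec %in% c("ATOM  ", "HETATM")
  model_no <- cumsum(rec == "MODEL ")
  if (max(model_no) == 0L) model_no <- rep(1L, length(lines))
  atom_lines <- which(is_atom)
  counts <- table(model_no[atom_lines])
  if (length(counts) > 1L && length(unique(as.integer(counts))) != 1L) {
    bad <- names(counts)[which(as.integer(counts) != as.integer(counts[1]))[1]]
    stop("inconsistent atom count across models in '", path,
         "': model ", bad, " has ", counts[[bad]], " atoms, model ",
         names(counts)[1], " has ", counts[[1]])
  }
  for (i in atom_lines) {
    xyz <- suppressWarnings(as.numeric(c(substr(lines[i], 31, 38),
                                         substr(lines[i], 39, 46),
                                         substr(lines[i], 47, 54))))
    if (any(is.na(xyz)))
      stop("unparseable coordinate in '", path, "' at line ", i)
  }
  invisible(TRUE)
}

#' Read a multi-model PDB ensemble
#'
#' Each file holds one replicate run as a multi-model PDB; MODEL/ENDMDL
#' records delimit frames.  Atom order is preserved and topology constancy
#' is enforced across models and across files.  Occupancy and B-factor
#' columns are ignored.
#'
#' @param paths character vector of PDB paths, one per replicate run.
#' @param equilibration_fraction leading-frame discard fraction recorded on
#'   the ensemble (see [md_ensemble()]).
#' @param label ensemble label.
#' @return an [md_ensemble()].
#' @export
read_ensemble <- function(paths, equilibration_fraction = 0, label = "ensemble") {
  if (length(paths) < 1L) stop("need at least one file")
  missing <- paths[!file.exists(paths)]
  if (length(missing)) stop("file not found: ", paste(missing, collapse = ", "))
  topo <- NULL
  runs <- vector("list", length(paths))
  for (k in seq_along(paths)) {
    .precheck_pdb(paths[k])
    pdb <- bio3d::read.pdb(paths[k], multi = TRUE, verbose = FALSE)
    t_k <- atom_topology(
      atom_name = pdb$atom$elety,
      residue_name = pdb$atom$resid,
      residue_id = pdb$atom$resno,
      chain_id = ifelse(is.na(pdb$atom$chain), "A", pdb$atom$chain),
      element = NULL
    )
    if (is.null(topo)) {
      topo <- t_k
    } else if (!identical(.topology_key(t_k), .topology_key(topo))) {
      stop("topology of '", paths[k], "' differs from '", paths[1], "'")
    }
    xyz <- pdb$xyz
    if (is.null(dim(xyz))) xyz <- matrix(xyz, nrow = 1)
    runs[[k]] <- lapply(seq_len(nrow(xyz)), function(m)
      matrix(xyz[m, ], ncol = 3, byrow = TRUE))
  }
  md_ensemble(topo, runs, equilibration_fraction = equilibration_fraction,
              label = label)
}

.pdb_atom_line <- function(record, serial, name, resname, chain, resid, xyz) {
  name_f <- if (nchar(name) <= 3L) sprintf(" %-3s", name) else sprintf("%-4s", name)
  elem <- sub("^[0-9]*([A-Za-z]+).*$", "\\1", name)
  if (toupper(name) == "MG") elem <- "MG" else elem <- substr(elem, 1, 1)
  sprintf("%-6s%5d %s %-3s %1s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
          record, serial, name_f, resname, chain, resid,
          xyz[1], xyz[2], xyz[3], 1.00, 0.00, elem)
}

#' Write an ensemble as multi-model PDB files
#'
#' One file per replicate run (`<prefix>_run<k>.pdb`), fixed-width PDB v3
#' columns, coordinates rounded to three decimals.  Occupancy and B-factor
#' are written as 1.00 / 0.00.
#'
#' @param ensemble an [md_ensemble()].
#' @param path_prefix path prefix for the output files.
#' @return invisibly, the character vector of written paths.
#' @export
write_ensemble <- function(ensemble, path_prefix) {
  if (!inherits(ensemble, "mdensemble")) stop("not an mdensemble")
  topo <- ensemble$topology
  record <- ifelse(topo$residue_name %in% .standard_aa, "ATOM", "HETATM")
  paths <- character(length(ensemble$runs))
  for (k in seq_along(ensemble$runs)) {
    run <- ensemble$runs[[k]]
    lines <- character(0)
    for (m in seq_along(run)) {
      xyz <- run[[m]]
      body <- vapply(seq_len(nrow(topo)), function(i)
        .pdb_atom_line(record[i], i, topo$atom_name[i], topo$residue_name[i],
                       topo$chain_id[i], topo$residue_id[i], xyz[i, ]),
        character(1))
      lines <- c(lines, sprintf("MODEL %8d", m), body, "ENDMDL")
    }
    lines <- c(lines, "END")
    path <- sprintf("%s_run%d.pdb", path_prefix, k)
    writeLines(lines, path)
    paths[k] <- path
  }
  invisible(paths)
}

#' Read a thermodynamic-integration window table
#'
#' Two-column numeric text (whitespace- or comma-delimited): the coupling
#' parameter lambda in `[0, 1]` and the window mean of dH/dlambda in
#' kcal/mol.  Lines starting with `#` are comments.  Rows are sorted by
#' lambda; duplicate lambda values are an error.
#'
#' @param path file path.
#' @param direction `"forward"` or `"backward"`.
#' @param discard_fraction per-window equilibration fraction already applied
#'   upstream by whatever produced the table; recorded as metadata only.
#' @return a `data.frame` of class `ti_table` with columns `lambda`, `dhdl`.
#' @export
read_ti_table <- function(path, direction = c("forward", "backward"),
                          discard_fraction = 0) {
  direction <- match.arg(direction)
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  fields <- strsplit(lines, "[,[:space:]]+")
  bad <- which(vapply(fields, length, integer(1)) != 2L)
  if (length(bad)) stop("expected two columns in '", path, "'")
  vals <- suppressWarnings(vapply(fields, as.numeric, numeric(2)))
  if (any(is.na(vals))) stop("non-numeric value in '", path, "'")
  ti_table(lambda = vals[1, ], dhdl = vals[2, ], direction = direction,
           discard_fraction = discard_fraction)
}

#' Construct a TI window table from vectors
#'
#' @param lambda coupling-parameter grid in `[0, 1]`.
#' @param dhdl window means of dH/dlambda (kcal/mol).
#' @param direction `"forward"` or `"backward"`.
#' @param discard_fraction upstream per-window equilibration fraction
#'   (metadata only).
#' @return a `data.frame` of class `ti_table`.
#' @export
ti_table <- function(lambda, dhdl, direction = c("forward", "backward"),
                     discard_fraction = 0) {
  direction <- match.arg(direction)
  if (discard_fraction < 0 || discard_fraction >= 1)
    stop("discard_fraction must be in [0, 1)")
  ord <- order(lambda)
  lambda <- lambda[ord]
  dhdl <- dhdl[ord]
  if (length(lambda) < 2L) stop("a TI table needs at least two windows")
  if (anyDuplicated(lambda)) stop("duplicate lambda values in TI table")
  if (any(lambda < 0 | lambda > 1)) stop("lambda values must lie in [0, 1]")
  structure(
    data.frame(lambda = lambda, dhdl = dhdl),
    class = c("ti_table", "data.frame"),
    direction = direction, discard_fraction = discard_fraction
  )
}

#' Write a TI window table as two-column text
#' @param table a `ti_table`.
#' @param path output path.
#' @return invisibly, `path`.
#' @export
write_ti_table <- function(table, path) {
  writeLines(c(sprintf("# direction: %s", attr(table, "direction")),
               sprintf("%.10g %.10g", table$lambda, table$dhdl)), path)
  invisible(path)
}
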