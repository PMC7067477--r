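#' Structure model: one chain's eligible residues and coordinates
#'
#' A `structure_model` holds the residues of a single chain that are
#' eligible for contact analysis, together with their heavy-atom
#' coordinates and the chain's SEQRES sequence. Eligibility follows the
#' method's rules: only residues with an empty insertion code and an ATOM
#' (non-hetero) record type are retained, hydrogens are dropped, and for
#' alternate locations only one conformer per atom is kept (highest
#' occupancy, ties broken by alternate-location identifier).
#'
#' @param pdb_id Four-character PDB identifier or a synthetic label.
#' @param chain_id Chain identifier (single character, typically).
#' @param residues `data.frame` with columns `resno` (author residue
#'   number, integer), `resname` (three-letter code) and `seqres_pos`
#'   (1-based position in `seqres`, `NA` when unmatched), one row per
#'   residue, in chain order.
#' @param atoms `data.frame` with columns `res_idx` (row index into
#'   `residues`), `name` (atom name, e.g. `"CA"`, `"OD1"`), `element`
#'   (element symbol) and `x`, `y`, `z` (Angstrom).
#' @param seqres Character vector of three-letter residue codes: the full
#'   deposited sequence of the chain.
#' @param seqres_derived Logical; `TRUE` when no SEQRES records were
#'   available and the sequence was reconstructed from observed residues.
#'
#' @return An object of class `structure_model`.
#' @seealso [parse_structure()], [read_structure()], [write_structure()]
#' @export
structure_model <- function(pdb_id, chain_id, residues, atoms, seqres,
                            seqres_derived = FALSE) {
  stopifnot(
    is.data.frame(residues),
    all(c("resno", "resname", "seqres_pos") %in% names(residues)),
    is.data.frame(atoms),
    all(c("res_idx", "name", "element", "x", "y", "z") %in% names(atoms)),
    is.character(seqres)
  )
  if (nrow(atoms) > 0L) {
    if (any(!is.finite(atoms$x) | !is.finite(atoms$y) | !is.finite(atoms$z)))
      stop("atom coordinates must be finite")
    atoms$name <- trimws(atoms$name)
    if (any(!nzchar(atoms$name))) stop("atom names must be non-empty")
    if (any(atoms$res_idx < 1L | atoms$res_idx > nrow(residues)))
      stop("atoms$res_idx out of range")
  }
  if (anyDuplicated(residues$resno))
    stop("duplicated residue number within chain (insertion codes are not retained)")
  rownames(residues) <- NULL
  rownames(atoms) <- NULL
  structure(
    list(
      pdb_id = as.character(pdb_id),
      chain_id = as.character(chain_id),
      residues = residues,
      atoms = atoms,
      seqres = as.character(seqres),
      seqres_derived = isTRUE(seqres_derived)
    ),
    class = "structure_model"
  )
}

#' @export
print.structure_model <- function(x, ...) {
  cat(sprintf(
    "<structure_model> %s chain %s: %d eligible residues, %d heavy atoms, SEQRES length %d%s\n",
    x$pdb_id, x$chain_id, nrow(x$residues), nrow(x$atoms), length(x$seqres),
    if (x$seqres_derived) " (derived from coordinates)" else ""
  ))
  invisible(x)
}

# three-letter -> one-letter, anything outside the alignment alphabet -> X
seq1 <- function(resnames) {
  aa <- suppressWarnings(bio3d::aa321(resnames))
  aa[is.na(aa) | !aa %in% rownames(blosum62())] <- "X"
  aa
}

blosum62 <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      e <- new.env()
      utils::data("BLOSUM62", package = "Biostrings", envir = e)
      cache <<- e$BLOSUM62
    }
    cache
  }
})

#' Parse one chain of a PDB file into a structure model
#'
#' Reads ATOM and SEQRES records for the requested chain and applies the
#' eligibility rules: HETATM records and residues with a non-empty
#' insertion code are dropped, hydrogens (and deuteriums) are removed, and
#' for atoms with alternate locations only the highest-occupancy conformer
#' is retained (ties broken by alternate-location identifier, so `"A"`
#' wins). Observed residues are assigned to SEQRES positions by a global
#' sequence alignment; when the file has no SEQRES records the sequence is
#' reconstructed from the observed residues with a warning.
#'
#' @param pdb_text Character scalar or vector: PDB-format text.
#' @param chain_id Chain to extract.
#' @param model For multi-model (e.g. NMR) files, which MODEL to read
#'   (default 1).
#' @param pdb_id Label to store; defaults to `"UNK"` for text input.
#'
#' @return A [structure_model()].
#' @examples
#' txt <- write_structure(toy <- structure_model(
#'   "TOY", "A",
#'   residues = data.frame(resno = 1L, resname = "ALA", seqres_pos = 1L),
#'   atoms = data.frame(res_idx = 1L, name = c("N", "CA", "C", "O", "CB"),
#'                      element = c("N", "C", "C", "O", "C"),
#'                      x = c(0, 0, 1, 2, 0), y = c(1, 0, 0, 0, 0),
#'                      z = c(0, 0, 0, 0, 1.5)),
#'   seqres = "ALA"
#' ))
#' parse_structure(txt, "A", pdb_id = "TOY")
#' @export
parse_structure <- function(pdb_text, chain_id, model = 1L, pdb_id = "UNK") {
  tf <- tempfile(fileext = ".pdb")
  on.exit(unlink(tf), add = TRUE)
  writeLines(pdb_text, tf)
  read_structure(tf, chain_id, model = model, pdb_id = pdb_id)
}

#' Read one chain of a PDB file into a structure model
#'
#' File-based counterpart of [parse_structure()]; see there for the
#' eligibility rules applied.
#'
#' @param path Path to a PDB file.
#' @param chain_id Chain to extract.
#' @param model Model number for multi-model files (default 1).
#' @param pdb_id Label to store; defaults to the file's base name.
#' @return A [structure_model()].
#' @export
read_structure <- function(path, chain_id, model = 1L, pdb_id = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(pdb_id))
    pdb_id <- toupper(sub("\\.(pdb|ent)$", "", basename(path), ignore.case = TRUE))

  check_atom_records(path)

  pdb <- suppressWarnings(
    bio3d::read.pdb(path, multi = TRUE, rm.alt = FALSE, rm.insert = FALSE,
                    verbose = FALSE)
  )
  at <- pdb$atom
  if (model < 1L || model > nrow(pdb$xyz))
    stop(sprintf("model %d requested but file has %d model(s)", model, nrow(pdb$xyz)))
  xyz <- matrix(pdb$xyz[model, ], ncol = 3L, byrow = TRUE)
  at$x <- xyz[, 1]; at$y <- xyz[, 2]; at$z <- xyz[, 3]

  chains <- unique(at$chain[at$type == "ATOM"])
  if (!chain_id %in% chains)
    stop(sprintf("chain '%s' not found; available chains: %s",
                 chain_id, paste(chains, collapse = ", ")))

  at <- at[at$type == "ATOM" & at$chain == chain_id, , drop = FALSE]
  # eligibility: empty insertion code, no hydrogens/deuteriums
  at <- at[is.na(at$insert) | at$insert == "", , drop = FALSE]
  elesy <- toupper(trimws(ifelse(is.na(at$elesy), "", at$elesy)))
  name <- trimws(at$elety)
  is_h <- elesy %in% c("H", "D") |
    (!nzchar(elesy) & grepl("^[0-9]*[HD]", name))
  at <- at[!is_h, , drop = FALSE]
  if (nrow(at) == 0L)
    stop(sprintf("no eligible residues in %s chain %s", pdb_id, chain_id))

  # altloc: keep highest occupancy per (residue, atom name); ties by altloc id
  alt <- ifelse(is.na(at$alt), "", at$alt)
  occ <- ifelse(is.na(at$o), 1, at$o)
  key <- paste(at$resno, trimws(at$elety), sep = "\r")
  ord <- order(match(key, unique(key)), -occ, alt)
  at <- at[ord, , drop = FALSE][!duplicated(key[ord]), , drop = FALSE]
  at <- at[order(match(paste(at$resno, trimws(at$elety), sep = "\r"),
                       unique(key))), , drop = FALSE]

  res_key <- at$resno
  res_first <- !duplicated(res_key)
  residues <- data.frame(
    resno = as.integer(at$resno[res_first]),
    resname = trimws(at$resid[res_first]),
    seqres_pos = NA_integer_,
    stringsAsFactors = FALSE
  )
  atoms <- data.frame(
    res_idx = match(res_key, res_key[res_first]),
    name = trimws(at$elety),
    element = toupper(trimws(ifelse(is.na(at$elesy) | at$elesy == "",
                                    substr(trimws(at$elety), 1, 1), at$elesy))),
    x = at$x, y = at$y, z = at$z,
    stringsAsFactors = FALSE
  )

  seqres <- pdb$seqres[names(pdb$seqres) == chain_id]
  seqres_derived <- FALSE
  if (length(seqres) == 0L) {
    warning(sprintf(
      "%s chain %s has no SEQRES records; sequence derived from observed residues",
      pdb_id, chain_id))
    seqres <- residues$resname
    seqres_derived <- TRUE
    residues$seqres_pos <- seq_len(nrow(residues))
  } else {
    seqres <- unname(as.character(seqres))
    residues$seqres_pos <- map_observed_to_seqres(residues$resname, seqres)
  }

  structure_model(pdb_id, chain_id, residues, atoms, seqres,
                  seqres_derived = seqres_derived)
}

# cheap format pre-check so malformed coordinate lines fail with a line number
check_atom_records <- function(path) {
  lines <- readLines(path, warn = FALSE)
  is_atom <- grepl("^(ATOM  |HETATM)", lines)
  for (i in which(is_atom)) {
    ln <- lines[i]
    bad <- nchar(ln) < 54L
    if (!bad) {
      xyz <- suppressWarnings(as.numeric(c(
        substr(ln, 31, 38), substr(ln, 39, 46), substr(ln, 47, 54))))
      bad <- any(is.na(xyz))
    }
    if (bad) stop(sprintf("malformed ATOM record at line %d: '%s'", i, ln))
  }
  invisible(TRUE)
}

# Assign each observed residue a SEQRES position via global alignment of the
# one-letter sequences. Residues aligned to a SEQRES gap stay NA (unmatched).
map_observed_to_seqres <- function(obs_resnames, seqres) {
  obs1 <- paste(seq1(obs_resnames), collapse = "")
  full1 <- paste(seq1(seqres), collapse = "")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(full1), Biostrings::AAString(obs1),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5
  )
  gp <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  gs <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  pos <- rep(NA_integer_, length(obs_resnames))
  ip <- 0L; is_ <- 0L
  for (k in seq_along(gp)) {
    if (gp[k] != "-") ip <- ip + 1L
    if (gs[k] != "-") {
      is_ <- is_ + 1L
      if (gp[k] != "-") pos[is_] <- ip
    }
  }
  pos
}

#' Write a structure model as PDB-format text
#'
#' Emits SEQRES and ATOM records (plus TER/END) such that parsing the
#' result recovers the model: residue names and numbers, atom names and
#' coordinates round-trip exactly at the PDB format's 3-decimal precision.
#'
#' @param model A [structure_model()] with at least one residue; every
#'   residue must carry at least one atom.
#' @return A character scalar of PDB-format text.
#' @export
write_structure <- function(model) {
  stopifnot(inherits(model, "structure_model"))
  if (nrow(model$residues) < 1L) stop("model has no residues")
  have_atoms <- tabulate(model$atoms$res_idx, nbins = nrow(model$residues))
  if (any(have_atoms == 0L))
    stop("residue(s) with zero atoms: ",
         paste(model$residues$resno[have_atoms == 0L], collapse = ", "))

  out <- character(0)
  n <- length(model$seqres)
  ser <- 0L
  for (start in seq(1L, n, by = 13L)) {
    ser <- ser + 1L
    chunk <- model$seqres[start:min(start + 12L, n)]
    out <- c(out, sprintf("SEQRES %3d %s %4d  %s", ser, model$chain_id, n,
                          paste(sprintf("%-3s", chunk), collapse = " ")))
  }
  a <- model$atoms
  r <- model$residues[a$res_idx, ]
  name_fmt <- ifelse(nchar(a$name) >= 4L, sprintf("%-4s", a$name),
                     sprintf(" %-3s", a$name))
  out <- c(out, sprintf(
    "ATOM  %5d %s %3s %s%4d    %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
    seq_len(nrow(a)), name_fmt, r$resname, model$chain_id, r$resno,
    a$x, a$y, a$z, 1, 0, a$element
  ))
  out <- c(out, "TER", "END")
  paste(out, collapse = "\n")
}
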