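#' Globally align two one-letter sequences
#'
#' Needleman-Wunsch global alignment (BLOSUM62, gap opening 10, gap
#' extension 0.5). The two models being compared come from the same
#' protein (point variants and construct-boundary differences at most), so
#' any reasonable global scheme recovers the same residue matching; the
#' parameters are recorded in the result for reproducibility.
#'
#' @param seq_a,seq_b Non-empty one-letter amino-acid sequences (character
#'   scalars). Letters outside the BLOSUM62 alphabet should be given as
#'   `"X"`.
#' @return A list of class `seq_alignment` with elements `a` and `b` (the
#'   gapped sequences, equal length; removing gaps recovers the inputs)
#'   plus `score` and `parameters`.
#' @examples
#' align_sequences("MKVA", "MKA")
#' @export
align_sequences <- function(seq_a, seq_b) {
  stopifnot(is.character(seq_a), length(seq_a) == 1L,
            is.character(seq_b), length(seq_b) == 1L)
  if (!nzchar(seq_a) || !nzchar(seq_b)) stop("sequences must be non-empty")
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(seq_a), Biostrings::AAString(seq_b),
    type = "global", substitutionMatrix = blosum62(),
    gapOpening = 10, gapExtension = 0.5
  )
  out <- list(
    a = as.character(Biostrings::alignedPattern(pa)),
    b = as.character(Biostrings::alignedSubject(pa)),
    score = Biostrings::score(pa),
    parameters = list(matrix = "BLOSUM62", gap_opening = 10, gap_extension = 0.5)
  )
  stopifnot(nchar(out$a) == nchar(out$b),
            gsub("-", "", out$a) == seq_a, gsub("-", "", out$b) == seq_b)
  class(out) <- "seq_alignment"
  out
}

#' @export
print.seq_alignment <- function(x, ...) {
  cat("<seq_alignment> score", x$score, "\n")
  cat(" ", x$a, "\n ", x$b, "\n")
  invisible(x)
}

#' Build the corrected residue pairing between two structure models
#'
#' Starting from the SEQRES-based global alignment, columns are dropped
#' when either side is a gap or when either side's SEQRES position has no
#' observed residue with coordinates in its model. The surviving columns
#' form an order-preserving one-to-one pairing of residues.
#'
#' @param aln A [align_sequences()] result over the two models' SEQRES
#'   sequences (one-letter). If `NULL`, it is computed here.
#' @param model_a,model_b [structure_model()] objects.
#' @return An object of class `residue_map`: a `data.frame` with columns
#'   `idx_a`, `idx_b` (row indices into each model's `residues`), plus
#'   attributes `n_pairs` and `n_name_mismatches` (paired residues whose
#'   three-letter names differ; an `"X"`/non-`"X"` one-letter pair also
#'   counts).
#' @export
build_residue_map <- function(aln, model_a, model_b) {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  sa <- paste(seq1(model_a$seqres), collapse = "")
  sb <- paste(seq1(model_b$seqres), collapse = "")
  if (is.null(aln)) aln <- align_sequences(sa, sb)
  stopifnot(inherits(aln, "seq_alignment"))
  if (gsub("-", "", aln$a) != sa || gsub("-", "", aln$b) != sb)
    stop("degapped alignment does not match the models' SEQRES sequences")

  ga <- strsplit(aln$a, "")[[1]]
  gb <- strsplit(aln$b, "")[[1]]
  # SEQRES position per alignment column (0 = gap)
  pos_a <- cumsum(ga != "-") * (ga != "-")
  pos_b <- cumsum(gb != "-") * (gb != "-")

  # observed residue index per SEQRES position (NA when no coordinates)
  obs_a <- seqres_to_residue(model_a)
  obs_b <- seqres_to_residue(model_b)

  keep <- pos_a > 0 & pos_b > 0
  ia <- ifelse(keep, obs_a[ifelse(keep, pos_a, 1L)], NA_integer_)
  ib <- ifelse(keep, obs_b[ifelse(keep, pos_b, 1L)], NA_integer_)
  ok <- keep & !is.na(ia) & !is.na(ib)

  rmap <- data.frame(idx_a = ia[ok], idx_b = ib[ok])
  na <- model_a$residues$resname[rmap$idx_a]
  nb <- model_b$residues$resname[rmap$idx_b]
  attr(rmap, "n_pairs") <- nrow(rmap)
  attr(rmap, "n_name_mismatches") <- sum(na != nb)
  class(rmap) <- c("residue_map", "data.frame")
  rmap
}

# inverse of residues$seqres_pos: SEQRES position -> residue row (or NA)
seqres_to_residue <- function(model) {
  out <- rep(NA_integer_, length(model$seqres))
  sp <- model$residues$seqres_pos
  ok <- !is.na(sp)
  out[sp[ok]] <- which(ok)
  out
}

#' @export
print.residue_map <- function(x, ...) {
  cat(sprintf("<residue_map> %d pairs, %d name mismatch(es)\n",
              attr(x, "n_pairs"), attr(x, "n_name_mismatches")))
  invisible(x)
}

#' Decide whether two models are similar enough to compare
#'
#' The pair is skipped when strictly more than `mismatch_tolerance`
#' (default 5%) of the paired residues differ in identity; exactly the
#' tolerated fraction still passes. The pairing is one-to-one by
#' construction, so the number of residues extracted from the two models
#' is always equal and is recorded in the verdict.
#'
#' @param rmap A [build_residue_map()] result.
#' @param model_a,model_b The two models the map was built from.
#' @param params A [dcm_params()] object (uses `mismatch_tolerance`).
#' @return A list of class `compatibility_verdict`: `compatible` (logical),
#'   `reason`, `mismatch_fraction`, `n_pairs`, `n_name_mismatches`.
#' @export
check_compatibility <- function(rmap, model_a, model_b, params = dcm_params()) {
  n <- attr(rmap, "n_pairs")
  m <- attr(rmap, "n_name_mismatches")
  if (is.null(n)) n <- nrow(rmap)
  if (n == 0L) {
    v <- list(compatible = FALSE, reason = "no aligned residues",
              mismatch_fraction = NA_real_, n_pairs = 0L,
              n_name_mismatches = 0L)
    class(v) <- "compatibility_verdict"
    return(v)
  }
  frac <- m / n
  ok <- frac <= params$mismatch_tolerance
  v <- list(
    compatible = ok,
    reason = if (ok) sprintf("%d/%d residues differ (%.4f <= %.4f)",
                             m, n, frac, params$mismatch_tolerance)
             else sprintf("more than %.0f%% of paired residues differ (%d/%d = %.4f)",
                          100 * params$mismatch_tolerance, m, n, frac),
    mismatch_fraction = frac,
    n_pairs = n,
    n_name_mismatches = m
  )
  class(v) <- "compatibility_verdict"
  v
}

#' @export
print.compatibility_verdict <- function(x, ...) {
  cat(sprintf("<compatibility_verdict> %s: %s\n",
              if (x$compatible) "compatible" else "INCOMPATIBLE", x$reason))
  invisible(x)
}
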