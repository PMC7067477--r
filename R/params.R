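#' Method parameters
#'
#' Bundles the thresholds of the difference-contact-map method. The defaults
#' are the method's canonical values: two residues are in contact when any
#' two of their side-chain heavy atoms are closer than 5 Angstrom, a
#' conformation-exclusive contact survives filtering only when its
#' inter-residue distance changes by more than 5 Angstrom between the two
#' conformations, and a pair of models is comparable when at most 5% of the
#' paired residues differ in identity.
#'
#' @param contact_threshold Contact distance cutoff in Angstrom. A residue
#'   pair is in contact when its minimum side-chain heavy-atom distance is
#'   strictly below this value.
#' @param delta_threshold Distance-difference cutoff in Angstrom. A
#'   conformation-exclusive contact is kept only when the absolute change in
#'   inter-residue distance is strictly above this value (a change less than
#'   or equal to it is removed).
#' @param mismatch_tolerance Maximum tolerated fraction of paired residues
#'   whose three-letter names differ between the two models. Strictly more
#'   than this fraction makes the pair incompatible.
#' @param min_seq_separation Minimum separation `j - i` (in mapped positions)
#'   for a pair to be eligible as a contact. The default 1 imposes no
#'   exclusion beyond `i != j`; 2 drops sequence-adjacent pairs.
#'
#' @return An object of class `dcm_params` (a named list).
#' @examples
#' dcm_params()
#' dcm_params(min_seq_separation = 2)
#' @export
dcm_params <- function(contact_threshold = 5.0,
                       delta_threshold = 5.0,
                       mismatch_tolerance = 0.05,
                       min_seq_separation = 1L) {
  stopifnot(
    is.numeric(contact_threshold), length(contact_threshold) == 1L,
    contact_threshold > 0,
    is.numeric(delta_threshold), length(delta_threshold) == 1L,
    delta_threshold > 0,
    is.numeric(mismatch_tolerance), length(mismatch_tolerance) == 1L,
    mismatch_tolerance > 0,
    is.numeric(min_seq_separation), length(min_seq_separation) == 1L,
    min_seq_separation >= 1
  )
  structure(
    list(
      contact_threshold  = as.numeric(contact_threshold),
      delta_threshold    = as.numeric(delta_threshold),
      mismatch_tolerance = as.numeric(mismatch_tolerance),
      min_seq_separation = as.integer(min_seq_separation)
    ),
    class = "dcm_params"
  )
}

#' @export
print.dcm_params <- function(x, ...) {
  cat("Difference contact map parameters:\n")
  cat(sprintf("  contact threshold    : < %.3f A\n", x$contact_threshold))
  cat(sprintf("  delta filter         : > %.3f A kept\n", x$delta_threshold))
  cat(sprintf("  mismatch tolerance   : %.3f\n", x$mismatch_tolerance))
  cat(sprintf("  min seq separation   : %d\n", x$min_seq_separation))
  invisible(x)
}

# single-line serialization embedded in output files
format_params_line <- function(params, fraction_mode = NULL) {
  s <- sprintf(
    "diffcontact %s; contact_threshold=%g; delta_threshold=%g; mismatch_tolerance=%g; min_seq_separation=%d",
    as.character(utils::packageVersion("diffcontact")),
    params$contact_threshold, params$delta_threshold,
    params$mismatch_tolerance, params$min_seq_separation
  )
  if (!is.null(fraction_mode)) s <- paste0(s, "; fraction_mode=", fraction_mode)
  s
}
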