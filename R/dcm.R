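#' Compare two conformations by difference contact map
#'
#' The package's central entry point. Runs the full method on two
#' structure models of (nearly) the same protein: SEQRES-based global
#' alignment, coordinate-corrected residue pairing, the sequence-identity
#' compatibility check, per-conformation side-chain contact maps, the
#' difference contact map, the distance-change filter and the resulting
#' differentially stabilizing residues (DSRs), plus summary metrics
#' (CA superposition RMSD, changed-contact fraction, optional
#' inter-domain classification).
#'
#' When the pair fails the compatibility check (more than
#' `params$mismatch_tolerance` of paired residues differ in identity) the
#' returned object carries the verdict and no maps; check `$compatible`.
#'
#' @param model_a,model_b [structure_model()] objects (conformations A
#'   and B).
#' @param params A [dcm_params()].
#' @param domains Optional domain annotation `data.frame`
#'   ([read_domains()]), in model A's author numbering.
#' @param fraction_mode Denominator for [changed_contact_fraction()].
#' @return An object of class `dcm`: list with `model_a`, `model_b`,
#'   `alignment`, `rmap`, `verdict`, `compatible`, and (when compatible)
#'   `cm_a`, `cm_b`, `dcm` (filtered difference map), `dsrs`, `rmsd`,
#'   `changed_fraction`, `interdomain` (or `NULL`), `params`,
#'   `fraction_mode`.
#' @examples
#' fx <- make_pair(fixture_spec(14, motion = "hinge", hinge_position = 7,
#'                              hinge_angle = 80, seed = 7))
#' cmp <- dcm_compare(parse_structure(fx$pdb_a, "A"),
#'                    parse_structure(fx$pdb_b, "A"))
#' summary(cmp)
#' @export
dcm_compare <- function(model_a, model_b, params = dcm_params(),
                        domains = NULL, fraction_mode = "union") {
  stopifnot(inherits(model_a, "structure_model"),
            inherits(model_b, "structure_model"))
  aln <- align_sequences(paste(seq1(model_a$seqres), collapse = ""),
                         paste(seq1(model_b$seqres), collapse = ""))
  rmap <- build_residue_map(aln, model_a, model_b)
  verdict <- check_compatibility(rmap, model_a, model_b, params)

  out <- list(model_a = model_a, model_b = model_b, alignment = aln,
              rmap = rmap, verdict = verdict,
              compatible = verdict$compatible, params = params,
              fraction_mode = fraction_mode)
  class(out) <- "dcm"
  if (!verdict$compatible) return(out)

  cm_a <- compute_contact_map(model_a, rmap, "A", params)
  cm_b <- compute_contact_map(model_b, rmap, "B", params)
  dm <- filter_difference_map(difference_map(cm_a, cm_b), params)

  out$cm_a <- cm_a
  out$cm_b <- cm_b
  out$dcm <- dm
  out$dsrs <- identify_dsrs(dm, model_a, model_b, rmap)
  out$rmsd <- tryCatch(superposition_rmsd(model_a, model_b, rmap),
                       error = function(e) NA_real_)
  out$changed_fraction <- changed_contact_fraction(cm_a, cm_b, dm,
                                                   mode = fraction_mode)
  out$interdomain <- if (!is.null(domains))
    classify_interdomain(dm, domains, model_a, rmap, side = "A") else NULL
  out
}

#' @export
print.dcm <- function(x, ...) {
  cat(sprintf("Difference contact map: %s:%s vs %s:%s\n",
              x$model_a$pdb_id, x$model_a$chain_id,
              x$model_b$pdb_id, x$model_b$chain_id))
  cat(sprintf("  %d residue pairs mapped, mismatch fraction %.4f\n",
              x$verdict$n_pairs, x$verdict$mismatch_fraction))
  if (!x$compatible) {
    cat("  pair INCOMPATIBLE:", x$verdict$reason, "\n")
    return(invisible(x))
  }
  e <- x$dcm$entries
  cat(sprintf("  contacts: %d (A) / %d (B); exclusive: %d; filtered: %d (%d A-only, %d B-only)\n",
              nrow(x$cm_a$contacts), nrow(x$cm_b$contacts), nrow(e),
              sum(e$filtered), sum(e$filtered & e$side == "A_only"),
              sum(e$filtered & e$side == "B_only")))
  cat(sprintf("  CA superposition RMSD: %.2f A; changed-contact fraction (%s): %.4f\n",
              x$rmsd, x$fraction_mode, x$changed_fraction))
  cat(sprintf("  DSRs: %d\n", nrow(x$dsrs)))
  invisible(x)
}

#' Summary statistics of a conformational comparison
#'
#' @param object A [dcm_compare()] result.
#' @param ... Unused.
#' @return An object of class `summary.dcm`: `rmsd`, `n_pairs`,
#'   `mismatch_fraction`, `compatible`, `n_contacts_a`, `n_contacts_b`,
#'   `n_diff`, `n_filtered`, `n_a_only_filtered`, `n_b_only_filtered`,
#'   `n_dsrs`, `changed_fraction`, `fraction_mode`, `params`.
#' @export
summary.dcm <- function(object, ...) {
  x <- object
  s <- list(
    id_a = paste0(x$model_a$pdb_id, ":", x$model_a$chain_id),
    id_b = paste0(x$model_b$pdb_id, ":", x$model_b$chain_id),
    compatible = x$compatible,
    n_pairs = x$verdict$n_pairs,
    mismatch_fraction = x$verdict$mismatch_fraction,
    rmsd = NA_real_, n_contacts_a = NA_integer_, n_contacts_b = NA_integer_,
    n_diff = NA_integer_, n_filtered = NA_integer_,
    n_a_only_filtered = NA_integer_, n_b_only_filtered = NA_integer_,
    n_dsrs = NA_integer_, changed_fraction = NA_real_,
    fraction_mode = x$fraction_mode, params = x$params
  )
  if (x$compatible) {
    e <- x$dcm$entries
    s$rmsd <- x$rmsd
    s$n_contacts_a <- nrow(x$cm_a$contacts)
    s$n_contacts_b <- nrow(x$cm_b$contacts)
    s$n_diff <- nrow(e)
    s$n_filtered <- sum(e$filtered)
    s$n_a_only_filtered <- sum(e$filtered & e$side == "A_only")
    s$n_b_only_filtered <- sum(e$filtered & e$side == "B_only")
    s$n_dsrs <- nrow(x$dsrs)
    s$changed_fraction <- x$changed_fraction
  }
  class(s) <- "summary.dcm"
  s
}

#' @export
print.summary.dcm <- function(x, ...) {
  cat(sprintf("%s vs %s: ", x$id_a, x$id_b))
  if (!x$compatible) {
    cat("incompatible pair\n")
    return(invisible(x))
  }
  cat(sprintf(
    "RMSD %.2f A | contacts %d/%d | exclusive %d | filtered %d (%d+%d) | DSRs %d | changed fraction %.4f\n",
    x$rmsd, x$n_contacts_a, x$n_contacts_b, x$n_diff, x$n_filtered,
    x$n_a_only_filtered, x$n_b_only_filtered, x$n_dsrs, x$changed_fraction))
  invisible(x)
}

#' Difference entries as a table
#'
#' One row per conformation-exclusive contact, in both models' author
#' numbering, sorted by mapped position pair — the tabular output shape
#' written by [run_pipeline()].
#'
#' @param x A [dcm_compare()] result (must be compatible).
#' @param ... Unused.
#' @return A `data.frame` with columns `i`, `j`, `resno_a_i`,
#'   `resname_a_i`, `resno_b_i`, `resname_b_i`, `resno_a_j`,
#'   `resname_a_j`, `resno_b_j`, `resname_b_j`, `side`, `dist_a`,
#'   `dist_b`, `delta`, `filtered`.
#' @export
as.data.frame.dcm <- function(x, ...) {
  if (!x$compatible) stop("incompatible pair has no difference entries")
  e <- x$dcm$entries
  ra <- x$model_a$residues; rb <- x$model_b$residues
  ia <- x$rmap$idx_a; ib <- x$rmap$idx_b
  data.frame(
    i = e$i, j = e$j,
    resno_a_i = ra$resno[ia[e$i]], resname_a_i = ra$resname[ia[e$i]],
    resno_b_i = rb$resno[ib[e$i]], resname_b_i = rb$resname[ib[e$i]],
    resno_a_j = ra$resno[ia[e$j]], resname_a_j = ra$resname[ia[e$j]],
    resno_b_j = rb$resno[ib[e$j]], resname_b_j = rb$resname[ib[e$j]],
    side = e$side, dist_a = e$dist_a, dist_b = e$dist_b,
    delta = e$delta, filtered = e$filtered
  )
}

#' Plot the filtered difference contact map
#'
#' Two-colour scatter over the mapped-position plane. By default the two
#' conformations occupy the two triangles (A-only contacts above the
#' diagonal, B-only below); with `style = "triangle"` all contacts are
#' drawn above the diagonal and distinguished by colour only.
#'
#' @param x A [dcm_compare()] result (must be compatible).
#' @param style `"mirror"` (default) or `"triangle"`.
#' @param unfiltered Also show, in light grey, exclusive contacts removed
#'   by the distance-change filter (default `TRUE`).
#' @param col Length-2 colour vector for A-only and B-only contacts.
#' @param ... Passed to [graphics::plot()].
#' @return Invisibly, `x`.
#' @export
plot.dcm <- function(x, style = c("mirror", "triangle"), unfiltered = TRUE,
                     col = c("red3", "dodgerblue3"), ...) {
  style <- match.arg(style)
  if (!x$compatible) stop("incompatible pair has no difference map to plot")
  e <- x$dcm$entries
  n <- x$dcm$size
  graphics::plot(NA, xlim = c(1, n), ylim = c(1, n), asp = 1,
                 xlab = "mapped residue position",
                 ylab = "mapped residue position",
                 main = sprintf("%s:%s (red) vs %s:%s (blue)",
                                x$model_a$pdb_id, x$model_a$chain_id,
                                x$model_b$pdb_id, x$model_b$chain_id), ...)
  graphics::abline(0, 1, col = "grey80")
  put <- function(rows, colr, pch) {
    if (!nrow(rows)) return(invisible())
    a_side <- rows$side == "A_only"
    if (style == "mirror") {
      xx <- ifelse(a_side, rows$i, rows$j)
      yy <- ifelse(a_side, rows$j, rows$i)
    } else {
      xx <- rows$i; yy <- rows$j
    }
    graphics::points(xx, yy, col = colr, pch = pch, cex = 0.8)
  }
  if (unfiltered)
    put(e[!e$filtered, , drop = FALSE], "grey75", 4)
  kept <- e[e$filtered, , drop = FALSE]
  put(kept[kept$side == "A_only", , drop = FALSE], col[1], 19)
  put(kept[kept$side == "B_only", , drop = FALSE], col[2], 19)
  invisible(x)
}
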