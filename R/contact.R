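BACKBONE_ATOMS <- c("N", "CA", "C", "O", "OXT")

#' Side-chain heavy atoms of a residue
#'
#' Returns the atoms used for contact measurement: all heavy atoms except
#' the backbone (N, CA, C, O and terminal OXT). Glycine has no side chain,
#' so its CA atom is used instead. A residue with none of these atoms
#' (side chain unresolved) yields an empty set and forms no contacts.
#'
#' @param model A [structure_model()].
#' @param i Residue row index into `model$residues`.
#' @return A `data.frame` of atoms (subset of `model$atoms`), possibly
#'   with zero rows.
#' @export
sidechain_heavy_atoms <- function(model, i) {
  a <- model$atoms[model$atoms$res_idx == i, , drop = FALSE]
  if (identical(model$residues$resname[i], "GLY")) {
    a[a$name == "CA", , drop = FALSE]
  } else {
    a[!a$name %in% BACKBONE_ATOMS, , drop = FALSE]
  }
}

#' Minimum side-chain heavy-atom distance between two residues
#'
#' The inter-residue distance used throughout the method: the minimum
#' Euclidean distance over all pairs of the two residues' side-chain heavy
#' atoms (glycine contributing its CA). `NA` when either residue has no
#' side-chain heavy atoms.
#'
#' @param model_a Model containing the first residue.
#' @param i Residue index in `model_a`.
#' @param model_b Model containing the second residue (may be the same
#'   model).
#' @param j Residue index in `model_b`.
#' @return Distance in Angstrom, or `NA_real_`.
#' @export
min_sidechain_distance <- function(model_a, i, model_b = model_a, j) {
  pa <- sidechain_heavy_atoms(model_a, i)
  pb <- sidechain_heavy_atoms(model_b, j)
  if (nrow(pa) == 0L || nrow(pb) == 0L) return(NA_real_)
  ca <- as.matrix(pa[, c("x", "y", "z")])
  cb <- as.matrix(pb[, c("x", "y", "z")])
  d2 <- outer(rowSums(ca^2), rep(1, nrow(cb))) +
    outer(rep(1, nrow(ca)), rowSums(cb^2)) - 2 * tcrossprod(ca, cb)
  sqrt(max(0, min(d2)))
}

# n x n matrix of pairwise minimum side-chain distances over the mapped
# residues of one model (NA where a residue has no side-chain heavy atoms)
pairwise_min_distances <- function(model, idx) {
  n <- length(idx)
  sc <- lapply(idx, function(i) {
    a <- sidechain_heavy_atoms(model, i)
    if (nrow(a) == 0L) NULL else as.matrix(a[, c("x", "y", "z")])
  })
  has <- !vapply(sc, is.null, logical(1))
  D <- matrix(NA_real_, n, n)
  if (!any(has)) return(D)
  coords <- do.call(rbind, sc[has])
  grp <- rep(which(has), vapply(sc[has], nrow, integer(1)))
  A <- as.matrix(stats::dist(coords))
  # aggregate atom-level distances to residue-level minima, column-wise
  # then row-wise
  cols <- split(seq_len(ncol(A)), grp)
  B <- vapply(cols, function(ix) {
    do.call(pmin, as.data.frame(A[, ix, drop = FALSE]))
  }, numeric(nrow(A)))
  if (is.null(dim(B))) B <- matrix(B, nrow = nrow(A))
  C <- t(vapply(cols, function(ix) {
    do.call(pmin, as.data.frame(t(B[ix, , drop = FALSE])))
  }, numeric(ncol(B))))
  D[which(has), which(has)] <- C
  D
}

#' Compute the contact map of one conformation
#'
#' Over the mapped residue pairs, a pair `(i, j)` with `i < j` is a
#' contact when its minimum side-chain heavy-atom distance is strictly
#' below `params$contact_threshold` and `j - i >=
#' params$min_seq_separation`. Pairs with undefined distance (a residue
#' without side-chain heavy atoms) are never contacts.
#'
#' @param model A [structure_model()].
#' @param rmap The [build_residue_map()] pairing the two models.
#' @param side `"A"` if `model` is the map's first model, `"B"` otherwise.
#' @param params A [dcm_params()].
#' @return An object of class `contact_map`: list with `size` (number of
#'   mapped positions), `contacts` (`data.frame` of `i`, `j`, `dist`,
#'   sorted by `(i, j)`), `dmat` (the full pairwise minimum-distance
#'   matrix), `side`, and `params`.
#' @export
compute_contact_map <- function(model, rmap, side = c("A", "B"),
                                params = dcm_params()) {
  side <- match.arg(side)
  idx <- if (side == "A") rmap$idx_a else rmap$idx_b
  n <- length(idx)
  D <- pairwise_min_distances(model, idx)
  pairs <- which(upper.tri(D), arr.ind = TRUE)
  sep_ok <- pairs[, 2] - pairs[, 1] >= params$min_seq_separation
  d <- D[pairs]
  hit <- sep_ok & !is.na(d) & d < params$contact_threshold
  contacts <- data.frame(i = pairs[hit, 1], j = pairs[hit, 2], dist = d[hit])
  contacts <- contacts[order(contacts$i, contacts$j), , drop = FALSE]
  rownames(contacts) <- NULL
  structure(
    list(size = n, contacts = contacts, dmat = D, side = side,
         params = params, rmap_id = rmap_fingerprint(rmap)),
    class = "contact_map"
  )
}

rmap_fingerprint <- function(rmap) {
  paste(nrow(rmap), sum(rmap$idx_a * seq_len(nrow(rmap))),
        sum(rmap$idx_b * seq_len(nrow(rmap))), sep = ":")
}

#' @export
print.contact_map <- function(x, ...) {
  cat(sprintf("<contact_map> side %s: %d contacts over %d mapped residues (< %g A)\n",
              x$side, nrow(x$contacts), x$size, x$params$contact_threshold))
  invisible(x)
}

#' Subtract two contact maps
#'
#' The difference contact map is the symmetric set difference of the two
#' conformations' contact sets: every pair in contact in exactly one
#' conformation, labelled `A_only` or `B_only`, with the inter-residue
#' distance in both conformations and their absolute difference `delta`
#' (undefined when a side-chain is unresolved on one side).
#'
#' @param cm_a,cm_b [compute_contact_map()] results over the same residue
#'   map (sides `"A"` and `"B"`).
#' @return An object of class `difference_map`: list with `entries`
#'   (`data.frame` of `i`, `j`, `side`, `dist_a`, `dist_b`, `delta`,
#'   `filtered`, sorted by `(i, j)`; `filtered` is `FALSE` until
#'   [filter_difference_map()] is applied), `size` and `params`.
#' @export
difference_map <- function(cm_a, cm_b) {
  stopifnot(inherits(cm_a, "contact_map"), inherits(cm_b, "contact_map"))
  if (cm_a$size != cm_b$size || !identical(cm_a$rmap_id, cm_b$rmap_id))
    stop("contact maps were computed over different residue maps")
  key_a <- paste(cm_a$contacts$i, cm_a$contacts$j)
  key_b <- paste(cm_b$contacts$i, cm_b$contacts$j)
  only_a <- cm_a$contacts[!key_a %in% key_b, c("i", "j"), drop = FALSE]
  only_b <- cm_b$contacts[!key_b %in% key_a, c("i", "j"), drop = FALSE]
  entries <- rbind(
    if (nrow(only_a)) cbind(only_a, side = "A_only") else NULL,
    if (nrow(only_b)) cbind(only_b, side = "B_only") else NULL
  )
  if (is.null(entries))
    entries <- data.frame(i = integer(), j = integer(), side = character())
  entries$dist_a <- cm_a$dmat[cbind(entries$i, entries$j)]
  entries$dist_b <- cm_b$dmat[cbind(entries$i, entries$j)]
  entries$delta <- abs(entries$dist_a - entries$dist_b)
  entries$filtered <- rep(FALSE, nrow(entries))
  entries <- entries[order(entries$i, entries$j), , drop = FALSE]
  rownames(entries) <- NULL
  structure(
    list(entries = entries, size = cm_a$size, params = cm_a$params,
         rmap_id = cm_a$rmap_id, filter_applied = FALSE),
    class = "difference_map"
  )
}

#' Filter a difference contact map by distance change
#'
#' Keeps only the conformation-exclusive contacts whose inter-residue
#' distance changes by strictly more than `params$delta_threshold` between
#' the two conformations; a change less than or equal to the threshold is
#' treated as a local fluctuation and removed. Entries whose change cannot
#' be evaluated (side chain unresolved in one conformation, `delta`
#' undefined) are never marked kept; a warning reports how many such
#' entries were set aside.
#'
#' @param dcm A [difference_map()] result.
#' @param params A [dcm_params()]; defaults to the parameters stored in
#'   `dcm`.
#' @return `dcm` with `entries$filtered` set (`TRUE` = survived) and
#'   `filter_applied = TRUE`.
#' @export
filter_difference_map <- function(dcm, params = dcm$params) {
  stopifnot(inherits(dcm, "difference_map"))
  e <- dcm$entries
  undef <- is.na(e$delta)
  if (any(undef))
    warning(sprintf(
      "%d difference entr%s with undefined distance change (unresolved side chain) excluded from the filtered map",
      sum(undef), if (sum(undef) == 1L) "y" else "ies"))
  e$filtered <- !undef & e$delta > params$delta_threshold
  dcm$entries <- e
  dcm$params <- params
  dcm$filter_applied <- TRUE
  dcm
}

#' @export
print.difference_map <- function(x, ...) {
  cat(sprintf("<difference_map> %d conformation-exclusive contact(s)", nrow(x$entries)))
  if (x$filter_applied)
    cat(sprintf("; %d survive the > %g A distance-change filter",
                sum(x$entries$filtered), x$params$delta_threshold))
  cat("\n")
  invisible(x)
}

#' Identify differentially stabilizing residues
#'
#' A differentially stabilizing residue (DSR) is any residue taking part
#' in at least one contact of the filtered difference map. Residues are
#' reported in both models' author numbering together with the number of
#' filtered contacts they participate in.
#'
#' @param dcm A filtered [difference_map()].
#' @param model_a,model_b The two models.
#' @param rmap The residue map used throughout.
#' @return An object of class `dsr_set`: a `data.frame` with one row per
#'   DSR (`pos` mapped position, `resno_a`, `resname_a`, `resno_b`,
#'   `resname_b`, `n_contacts`), sorted by `pos`.
#' @export
identify_dsrs <- function(dcm, model_a, model_b, rmap) {
  stopifnot(inherits(dcm, "difference_map"))
  if (!dcm$filter_applied) dcm <- filter_difference_map(dcm)
  kept <- dcm$entries[dcm$entries$filtered, , drop = FALSE]
  pos <- sort(unique(c(kept$i, kept$j)))
  counts <- table(factor(c(kept$i, kept$j), levels = pos))
  out <- data.frame(
    pos = pos,
    resno_a = model_a$residues$resno[rmap$idx_a[pos]],
    resname_a = model_a$residues$resname[rmap$idx_a[pos]],
    resno_b = model_b$residues$resno[rmap$idx_b[pos]],
    resname_b = model_b$residues$resname[rmap$idx_b[pos]],
    n_contacts = as.integer(counts)
  )
  class(out) <- c("dsr_set", "data.frame")
  out
}

#' @export
print.dsr_set <- function(x, ...) {
  cat(sprintf("<dsr_set> %d differentially stabilizing residue(s)\n", nrow(x)))
  if (nrow(x)) print.data.frame(x)
  invisible(x)
}
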