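#' C-alpha superposition RMSD between the two models
#'
#' Least-squares optimal rigid-body (Kabsch) superposition over the CA
#' atoms of the mapped residue pairs, followed by the root-mean-square
#' deviation of the superposed coordinates. Mapped pairs where either
#' residue lacks a CA atom are skipped; at least three usable pairs are
#' required.
#'
#' @param model_a,model_b [structure_model()] objects.
#' @param rmap The [build_residue_map()] pairing.
#' @return RMSD in Angstrom.
#' @export
superposition_rmsd <- function(model_a, model_b, rmap) {
  ca_a <- ca_coords(model_a, rmap$idx_a)
  ca_b <- ca_coords(model_b, rmap$idx_b)
  ok <- stats::complete.cases(ca_a) & stats::complete.cases(ca_b)
  if (sum(ok) < 3L)
    stop(sprintf("superposition needs >= 3 mapped CA pairs, found %d", sum(ok)))
  xa <- as.vector(t(ca_a[ok, , drop = FALSE]))
  xb <- as.vector(t(ca_b[ok, , drop = FALSE]))
  nd <- length(xa)
  fitted <- bio3d::fit.xyz(fixed = xa, mobile = xb,
                           fixed.inds = seq_len(nd),
                           mobile.inds = seq_len(nd))
  sqrt(mean(rowSums((matrix(fitted - xa, ncol = 3L, byrow = TRUE))^2)))
}

ca_coords <- function(model, idx) {
  out <- matrix(NA_real_, length(idx), 3L)
  a <- model$atoms[model$atoms$name == "CA", , drop = FALSE]
  m <- match(idx, a$res_idx)
  hit <- !is.na(m)
  out[hit, ] <- as.matrix(a[m[hit], c("x", "y", "z")])
  out
}

#' Fraction of contacts changed between the two conformations
#'
#' The number of conformation-exclusive contacts surviving the
#' distance-change filter, divided by the total number of contacts. The
#' denominator defaults to the size of the union of the two contact sets
#' (symmetric and bounded, so the fraction stays in `[0, 1]`); the mean or
#' minimum of the two per-conformation counts are available alternatives.
#' Zero when the denominator is empty.
#'
#' @param cm_a,cm_b The two [compute_contact_map()] results.
#' @param dcm The filtered [difference_map()].
#' @param mode Denominator: `"union"` (default), `"mean"` or `"min"`.
#' @return A fraction in `[0, 1]` (may exceed 1 for `mode = "min"` in
#'   pathological cases).
#' @export
changed_contact_fraction <- function(cm_a, cm_b, dcm,
                                     mode = c("union", "mean", "min")) {
  mode <- match.arg(mode)
  stopifnot(inherits(dcm, "difference_map"))
  if (!dcm$filter_applied) dcm <- filter_difference_map(dcm)
  if (cm_a$size != cm_b$size || !identical(cm_a$rmap_id, cm_b$rmap_id))
    stop("contact maps were computed over different residue maps")
  n_filtered <- sum(dcm$entries$filtered)
  key <- unique(c(paste(cm_a$contacts$i, cm_a$contacts$j),
                  paste(cm_b$contacts$i, cm_b$contacts$j)))
  denom <- switch(mode,
    union = length(key),
    mean = (nrow(cm_a$contacts) + nrow(cm_b$contacts)) / 2,
    min = min(nrow(cm_a$contacts), nrow(cm_b$contacts))
  )
  if (denom == 0) return(0)
  n_filtered / denom
}

#' Read domain annotations
#'
#' Domain definitions are a small CSV with columns `domain`, `start`,
#' `end`: one inclusive author-numbering interval per row, several rows
#' per domain allowed. Lines starting with `#` are ignored.
#'
#' @param path Path to the CSV file.
#' @return A `data.frame` with columns `domain`, `start`, `end`.
#' @export
read_domains <- function(path) {
  d <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  stopifnot(all(c("domain", "start", "end") %in% names(d)),
            all(d$start <= d$end))
  d
}

#' Classify filtered contacts by domain pair
#'
#' Assigns each contact of the filtered difference map to the unordered
#' pair of domains of its two residues (author numbering of the chosen
#' model); residues outside every annotated interval are labelled
#' `"other"`. Intervals belonging to different domains must not overlap.
#'
#' @param dcm The filtered [difference_map()].
#' @param domains A `data.frame` as returned by [read_domains()].
#' @param model The model whose author numbering the intervals refer to.
#' @param rmap The residue map.
#' @param side `"A"` or `"B"`: which side of the map `model` is.
#' @return A `data.frame` with columns `domain_1`, `domain_2` (sorted
#'   within row) and `n`, one row per observed domain pair; the `n` sum
#'   over rows equals the number of filtered contacts.
#' @export
classify_interdomain <- function(dcm, domains, model, rmap, side = c("A", "B")) {
  side <- match.arg(side)
  stopifnot(inherits(dcm, "difference_map"))
  if (!dcm$filter_applied) dcm <- filter_difference_map(dcm)
  # overlap check across different domains
  if (nrow(domains) > 1L) {
    for (r in seq_len(nrow(domains) - 1L)) for (s in (r + 1L):nrow(domains)) {
      if (domains$domain[r] != domains$domain[s] &&
          domains$start[r] <= domains$end[s] &&
          domains$start[s] <= domains$end[r])
        stop(sprintf("domains '%s' and '%s' have overlapping ranges",
                     domains$domain[r], domains$domain[s]))
    }
  }
  idx <- if (side == "A") rmap$idx_a else rmap$idx_b
  resno <- model$residues$resno[idx]
  label_of <- function(no) {
    hit <- domains$domain[domains$start <= no & no <= domains$end]
    if (length(hit) == 0L) "other" else hit[1L]
  }
  kept <- dcm$entries[dcm$entries$filtered, , drop = FALSE]
  if (nrow(kept) == 0L)
    return(data.frame(domain_1 = character(), domain_2 = character(),
                      n = integer()))
  li <- vapply(resno[kept$i], label_of, character(1))
  lj <- vapply(resno[kept$j], label_of, character(1))
  pair <- t(mapply(function(a, b) sort(c(a, b)), li, lj))
  tab <- as.data.frame(table(domain_1 = pair[, 1], domain_2 = pair[, 2]),
                       stringsAsFactors = FALSE)
  tab <- tab[tab$Freq > 0L, , drop = FALSE]
  names(tab)[3] <- "n"
  tab <- tab[order(tab$domain_1, tab$domain_2), , drop = FALSE]
  rownames(tab) <- NULL
  tab
}
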