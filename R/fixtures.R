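#' Specification of a synthetic two-conformation fixture
#'
#' Describes a synthetic single-chain protein pair: conformation A is a
#' jittered hairpin of alanines (with optional glycines to exercise the
#' CA fallback) whose two arms pack side chains against each other, so
#' cross-arm contacts exist to be made and broken; conformation B is
#' conformation A with a rigid motion applied to the residues past the
#' hinge point (the hairpin turn). Designated
#' probe contacts are planted by placing the CB pseudo-atom of the second
#' residue so that the pair's side-chain distance equals `dist_a` in
#' conformation A and `dist_b` in conformation B (both must be consistent
#' with the requested motion, otherwise generation fails naming the
#' pair).
#'
#' @param n_residues Number of residues (>= 4).
#' @param motion One of `"hinge"` (rotation of the distal segment about
#'   the z axis through the hinge CA), `"shear"` (translation of the
#'   distal segment; `hinge_angle` is then the displacement in Angstrom),
#'   `"rigid"` (one rigid rotation + translation of the whole chain) or
#'   `"none"`.
#' @param hinge_position Last residue of the fixed segment (ignored for
#'   `"rigid"`/`"none"`).
#' @param hinge_angle Rotation angle in degrees (hinge) or displacement
#'   in Angstrom (shear).
#' @param planted_contacts `data.frame` with columns `i`, `j`, `dist_a`,
#'   `dist_b` (Angstrom), or `NULL`. `j` must be unique across rows and
#'   distinct from every `i`; planted residues may not be glycines.
#' @param gly_positions Residue indices emitted as glycine.
#' @param seed Integer RNG seed; generation is deterministic given the
#'   seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(n_residues,
                         motion = c("hinge", "shear", "rigid", "none"),
                         hinge_position = floor(n_residues / 2),
                         hinge_angle = 60,
                         planted_contacts = NULL,
                         gly_positions = integer(0),
                         seed = 1L) {
  motion <- match.arg(motion)
  stopifnot(n_residues >= 4L, hinge_position >= 1L,
            hinge_position <= n_residues)
  if (!is.null(planted_contacts)) {
    stopifnot(is.data.frame(planted_contacts),
              all(c("i", "j", "dist_a", "dist_b") %in% names(planted_contacts)),
              all(planted_contacts$i < planted_contacts$j),
              all(planted_contacts$j <= n_residues),
              all(planted_contacts$i >= 1L),
              all(planted_contacts$dist_a > 0),
              all(planted_contacts$dist_b > 0))
    if (anyDuplicated(planted_contacts$j) ||
        any(planted_contacts$j %in% planted_contacts$i))
      stop("planted_contacts: each j must be unique and distinct from every i")
    if (any(planted_contacts$i %in% gly_positions) ||
        any(planted_contacts$j %in% gly_positions))
      stop("planted_contacts may not involve glycine positions")
  }
  structure(
    list(n_residues = as.integer(n_residues), motion = motion,
         hinge_position = as.integer(hinge_position),
         hinge_angle = as.numeric(hinge_angle),
         planted_contacts = planted_contacts,
         gly_positions = as.integer(gly_positions), seed = as.integer(seed)),
    class = "fixture_spec"
  )
}

rot_z <- function(deg) {
  th <- deg * pi / 180
  matrix(c(cos(th), sin(th), 0, -sin(th), cos(th), 0, 0, 0, 1), 3, 3)
}

#' Generate a synthetic conformational pair with ground truth
#'
#' Emits two valid single-chain PDB texts realizing the requested motion
#' and planted contacts, together with the machine-readable ground truth
#' at the default thresholds. The ground truth is not trusted from
#' construction: it is re-measured from the emitted PDB text by an
#' independent brute-force pass (line-level parsing, all-pairs
#' double-loop distances), so it reflects exactly what a consumer of the
#' files will see, including the 3-decimal coordinate precision of the
#' PDB format.
#'
#' @param spec A [fixture_spec()].
#' @return An object of class `fixture_pair`: list with `pdb_a`, `pdb_b`
#'   (PDB texts), `truth` (see [measure_ground_truth()]) and `spec`.
#' @examples
#' fx <- make_pair(fixture_spec(12, motion = "hinge", hinge_position = 6,
#'                              hinge_angle = 90, seed = 42))
#' nrow(fx$truth$expected_diff)
#' @export
make_pair <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()), add = TRUE)
  set.seed(spec$seed)

  n <- spec$n_residues
  h <- spec$hinge_position
  jit <- matrix(round(stats::runif(2L * n, -0.3, 0.3), 3), n, 2L)
  # hairpin: the proximal arm runs along +x, the distal arm folds back
  # above it, so cross-arm side chains form a band of contacts that a
  # hinge or shear motion can separate (a closed-to-open transition)
  k <- seq_len(n)
  arm2 <- k > h
  ca <- cbind(
    ifelse(arm2, 3.8 * (h - 1L) + 1.9 - 3.8 * (k - h), 3.8 * (k - 1L)),
    ifelse(arm2, 5.5, 0) + jit[, 1],
    jit[, 2]
  )

  is_gly <- k %in% spec$gly_positions
  resname <- ifelse(is_gly, "GLY", "ALA")

  # per-residue motion map for conformation B
  moving <- switch(spec$motion,
    none = rep(FALSE, n),
    rigid = rep(TRUE, n),
    hinge = , shear = seq_len(n) > spec$hinge_position
  )
  if (spec$motion == "hinge") {
    R <- rot_z(spec$hinge_angle); tv <- c(0, 0, 0)
    pivot <- ca[spec$hinge_position, ]
  } else if (spec$motion == "shear") {
    R <- diag(3); tv <- c(0, 0, spec$hinge_angle); pivot <- c(0, 0, 0)
  } else if (spec$motion == "rigid") {
    R <- rot_z(stats::runif(1, 10, 170)); pivot <- c(0, 0, 0)
    tv <- round(stats::runif(3, -8, 8), 3)
  } else {
    R <- diag(3); tv <- c(0, 0, 0); pivot <- c(0, 0, 0)
  }
  fwd <- function(p, mv) if (mv) as.vector(R %*% (p - pivot) + pivot + tv) else p
  inv <- function(p, mv) if (mv) as.vector(t(R) %*% (p - pivot - tv) + pivot) else p

  # default CB for non-glycine residues: both arms' side chains point
  # into the gap between the arms
  cb <- ca + cbind(0, ifelse(arm2, -1.5, 1.5), 0)

  # plant probe contacts by solving for the CB of residue j on the
  # intersection of the two distance spheres (conformation A and B)
  pc <- spec$planted_contacts
  if (!is.null(pc)) for (r in seq_len(nrow(pc))) {
    i <- pc$i[r]; j <- pc$j[r]
    c1 <- cb[i, ]                       # constraint in A
    c2 <- inv(fwd(c1, moving[i]), moving[j])  # constraint in B, pulled to A frame
    p <- solve_two_spheres(c1, pc$dist_a[r], c2, pc$dist_b[r])
    if (is.null(p))
      stop(sprintf("planted contact (%d, %d) is not realizable under motion '%s'",
                   i, j, spec$motion))
    cb[j, ] <- p
  }

  build <- function(conf) {
    atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
      mv <- if (conf == "B") moving[k] else FALSE
      pos <- rbind(
        N = fwd(ca[k, ] + c(-1.2, 0.9, 0), mv),
        CA = fwd(ca[k, ], mv),
        C = fwd(ca[k, ] + c(1.2, 0.9, 0), mv),
        O = fwd(ca[k, ] + c(1.2, 2.1, 0), mv),
        CB = if (is_gly[k]) NULL else fwd(cb[k, ], mv)
      )
      data.frame(res_idx = k, name = rownames(pos),
                 element = substr(rownames(pos), 1, 1),
                 x = pos[, 1], y = pos[, 2], z = pos[, 3])
    }))
    structure_model(
      pdb_id = paste0("SYN", conf), chain_id = "A",
      residues = data.frame(resno = seq_len(n), resname = resname,
                            seqres_pos = seq_len(n)),
      atoms = atoms, seqres = resname
    )
  }
  pdb_a <- write_structure(build("A"))
  pdb_b <- write_structure(build("B"))

  # realizability audit on planted pairs (before PDB rounding)
  if (!is.null(pc)) for (r in seq_len(nrow(pc))) {
    i <- pc$i[r]; j <- pc$j[r]
    da <- sqrt(sum((cb[i, ] - cb[j, ])^2))
    db <- sqrt(sum((fwd(cb[i, ], moving[i]) - fwd(cb[j, ], moving[j]))^2))
    if (abs(da - pc$dist_a[r]) > 1e-6 || abs(db - pc$dist_b[r]) > 1e-6)
      stop(sprintf("planted contact (%d, %d) failed the post-hoc distance audit",
                   i, j))
  }

  structure(
    list(pdb_a = pdb_a, pdb_b = pdb_b,
         truth = measure_ground_truth(pdb_a, pdb_b), spec = spec),
    class = "fixture_pair"
  )
}

# deterministic point on the intersection of two spheres, or NULL
solve_two_spheres <- function(c1, r1, c2, r2) {
  d <- sqrt(sum((c2 - c1)^2))
  if (d < 1e-9) {
    if (abs(r1 - r2) > 1e-9) return(NULL)
    return(c1 + r1 * c(0, 0.6, 0.8))
  }
  a <- (r1^2 - r2^2 + d^2) / (2 * d)
  h2 <- r1^2 - a^2
  if (h2 < -1e-9) return(NULL)
  h <- sqrt(max(h2, 0))
  u <- (c2 - c1) / d
  v <- c(u[2] * 1 - u[3] * 0, u[3] * 0 - u[1] * 1, u[1] * 0 - u[2] * 0) # u x ez
  if (sqrt(sum(v^2)) < 1e-9) v <- c(u[2], -u[1], 0)                      # u x ey fallback
  if (sqrt(sum(v^2)) < 1e-9) v <- c(0, 1, 0)
  v <- v / sqrt(sum(v^2))
  c1 + a * u + h * v
}

#' @export
print.fixture_pair <- function(x, ...) {
  cat(sprintf(
    "<fixture_pair> %d residues, motion '%s': %d/%d contacts, %d exclusive, %d filtered\n",
    x$spec$n_residues, x$spec$motion, nrow(x$truth$contacts_a),
    nrow(x$truth$contacts_b), nrow(x$truth$expected_diff),
    nrow(x$truth$expected_filtered)))
  invisible(x)
}

#' Generate a coordinate-identical pair with point mutations
#'
#' Both conformations share coordinates (motion is forced to `"none"`),
#' but the second model's residue identities are changed at the given
#' positions, with side-chain atom sets adjusted to the new type
#' (ALA -> SER gains an OG atom; GLY -> ALA gains a CB). This exercises
#' the compatibility skip rule.
#'
#' @param spec A [fixture_spec()] (its `motion` is ignored).
#' @param mutated_positions Residue indices to mutate in model B.
#' @return A `fixture_pair`; `truth` is measured on the emitted pair.
#' @export
make_mutation_pair <- function(spec, mutated_positions) {
  stopifnot(inherits(spec, "fixture_spec"))
  if (any(mutated_positions < 1L | mutated_positions > spec$n_residues))
    stop("mutated position out of range 1..", spec$n_residues)
  spec$motion <- "none"
  fx <- make_pair(spec)
  m <- parse_structure(fx$pdb_b, "A", pdb_id = "SYNB")
  for (k in mutated_positions) {
    from <- m$residues$resname[k]
    if (from == "ALA") {
      m$residues$resname[k] <- "SER"
      cbrow <- m$atoms[m$atoms$res_idx == k & m$atoms$name == "CB", ]
      m$atoms <- rbind(m$atoms, data.frame(
        res_idx = k, name = "OG", element = "O",
        x = cbrow$x + 0.9, y = cbrow$y + 0.9, z = cbrow$z + 0.5))
    } else if (from == "GLY") {
      m$residues$resname[k] <- "ALA"
      carow <- m$atoms[m$atoms$res_idx == k & m$atoms$name == "CA", ]
      m$atoms <- rbind(m$atoms, data.frame(
        res_idx = k, name = "CB", element = "C",
        x = carow$x, y = carow$y + 1.5, z = carow$z))
    } else {
      stop("unsupported mutation source residue: ", from)
    }
  }
  m$atoms <- m$atoms[order(m$atoms$res_idx), , drop = FALSE]
  m$seqres <- m$residues$resname
  fx$pdb_b <- write_structure(m)
  fx$truth <- measure_ground_truth(fx$pdb_a, fx$pdb_b)
  fx$mutated_positions <- as.integer(mutated_positions)
  fx
}

#' Re-measure the ground truth of a fixture pair by brute force
#'
#' Independent reference pass over two emitted PDB texts: ATOM records
#' are read by fixed-column substring extraction (no shared code with the
#' package parser), side-chain heavy-atom sets are formed per residue
#' (CA for glycine; backbone N/CA/C/O/OXT excluded elsewhere), and every
#' residue pair is measured with an exhaustive double loop. Contacts use
#' the default `< 5` Angstrom rule, the difference set is the symmetric
#' difference, and the filtered set keeps changes `> 5` Angstrom.
#' Residues are paired by position (fixture pairs share their residue
#' grid).
#'
#' @param pdb_a,pdb_b PDB texts of the two conformations.
#' @param params Thresholds (defaults to [dcm_params()]).
#' @return List with `contacts_a`, `contacts_b` (`data.frame`s of `i`,
#'   `j`, `dist`), `expected_diff` and `expected_filtered`
#'   (`data.frame`s of `i`, `j`, `side`, `dist_a`, `dist_b`, `delta`).
#' @export
measure_ground_truth <- function(pdb_a, pdb_b, params = dcm_params()) {
  sc_a <- brute_force_sidechains(pdb_a)
  sc_b <- brute_force_sidechains(pdb_b)
  stopifnot(length(sc_a) == length(sc_b))
  n <- length(sc_a)
  mind <- function(sc) {
    D <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      pa <- sc[[i]]; pb <- sc[[j]]
      if (is.null(pa) || is.null(pb)) next
      best <- Inf
      for (u in seq_len(nrow(pa))) for (v in seq_len(nrow(pb))) {
        dd <- sqrt(sum((pa[u, ] - pb[v, ])^2))
        if (dd < best) best <- dd
      }
      D[i, j] <- best
    }
    D
  }
  Da <- mind(sc_a); Db <- mind(sc_b)
  pairs <- which(upper.tri(Da), arr.ind = TRUE)
  sep <- pairs[, 2] - pairs[, 1] >= params$min_seq_separation
  in_a <- sep & !is.na(Da[pairs]) & Da[pairs] < params$contact_threshold
  in_b <- sep & !is.na(Db[pairs]) & Db[pairs] < params$contact_threshold
  mk <- function(sel, D) {
    out <- data.frame(i = pairs[sel, 1], j = pairs[sel, 2], dist = D[pairs[sel, , drop = FALSE]])
    out[order(out$i, out$j), , drop = FALSE]
  }
  diff_sel <- xor(in_a, in_b)
  ed <- data.frame(
    i = pairs[diff_sel, 1], j = pairs[diff_sel, 2],
    side = ifelse(in_a[diff_sel], "A_only", "B_only"),
    dist_a = Da[pairs[diff_sel, , drop = FALSE]],
    dist_b = Db[pairs[diff_sel, , drop = FALSE]]
  )
  ed$delta <- abs(ed$dist_a - ed$dist_b)
  ed <- ed[order(ed$i, ed$j), , drop = FALSE]
  rownames(ed) <- NULL
  ef <- ed[!is.na(ed$delta) & ed$delta > params$delta_threshold, , drop = FALSE]
  rownames(ef) <- NULL
  list(contacts_a = mk(in_a, Da), contacts_b = mk(in_b, Db),
       expected_diff = ed, expected_filtered = ef)
}

# minimal fixed-column ATOM reader used only by the ground-truth pass
brute_force_sidechains <- function(pdb_text) {
  lines <- strsplit(paste(pdb_text, collapse = "\n"), "\n")[[1]]
  lines <- lines[startsWith(lines, "ATOM  ")]
  name <- trimws(substr(lines, 13, 16))
  resname <- trimws(substr(lines, 18, 20))
  resno <- as.integer(substr(lines, 23, 26))
  x <- as.numeric(substr(lines, 31, 38))
  y <- as.numeric(substr(lines, 39, 46))
  z <- as.numeric(substr(lines, 47, 54))
  keep <- ifelse(resname == "GLY", name == "CA",
                 !name %in% c("N", "CA", "C", "O", "OXT"))
  keep <- keep & !grepl("^[0-9]*[HD]", name)
  res_ids <- unique(resno)
  lapply(res_ids, function(r) {
    sel <- keep & resno == r
    if (!any(sel)) NULL else cbind(x[sel], y[sel], z[sel])
  })
}

#' Write a fixture pair to disk
#'
#' Emits `a.pdb`, `b.pdb` and `ground_truth.csv` (the expected difference
#' entries with their filtered status) into a directory.
#'
#' @param fx A [make_pair()] result.
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_fixture <- function(fx, dir) {
  stopifnot(inherits(fx, "fixture_pair"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pa <- file.path(dir, "a.pdb"); pb <- file.path(dir, "b.pdb")
  pt <- file.path(dir, "ground_truth.csv")
  writeLines(fx$pdb_a, pa)
  writeLines(fx$pdb_b, pb)
  gt <- fx$truth$expected_diff
  gt$filtered <- paste(gt$i, gt$j) %in%
    paste(fx$truth$expected_filtered$i, fx$truth$expected_filtered$j)
  utils::write.csv(gt, pt, row.names = FALSE)
  invisible(c(a = pa, b = pb, truth = pt))
}
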