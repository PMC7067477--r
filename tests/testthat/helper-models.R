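# Builders and independent oracles shared by the tests. The oracles
# deliberately re-derive results with their own (naive) code paths so
# the package implementation is checked against something it does not
# share logic with.

# a residue_map pairing residue k with residue k, as build_residue_map
# would produce for two identical fully-observed models
identity_rmap <- function(n) {
  rmap <- data.frame(idx_a = seq_len(n), idx_b = seq_len(n))
  attr(rmap, "n_pairs") <- n
  attr(rmap, "n_name_mismatches") <- 0L
  class(rmap) <- c("residue_map", "data.frame")
  rmap
}

# structure model with one residue per row of `cb`: CB placed exactly at
# the given position (CA for glycines), CA/backbone offset nearby
pseudo_model <- function(cb, resnames = rep("ALA", nrow(cb)),
                         resno = seq_len(nrow(cb)), pdb_id = "TOY") {
  n <- nrow(cb)
  atoms <- do.call(rbind, lapply(seq_len(n), function(k) {
    p <- cb[k, ]
    if (resnames[k] == "GLY") {
      data.frame(res_idx = k, name = c("N", "CA", "C", "O"),
                 element = c("N", "C", "C", "O"),
                 x = p[1] + c(-1, 0, 1, 2), y = p[2] + c(1, 0, 0, 1),
                 z = p[3])
    } else {
      data.frame(res_idx = k, name = c("N", "CA", "C", "O", "CB"),
                 element = c("N", "C", "C", "O", "C"),
                 x = p[1] + c(-1, 0, 1, 2, 0), y = p[2] + c(-1, -1.5, -1, -2, 0),
                 z = c(p[3], p[3], p[3], p[3], p[3]))
    }
  }))
  structure_model(
    pdb_id = pdb_id, chain_id = "A",
    residues = data.frame(resno = resno, resname = resnames,
                          seqres_pos = seq_len(n)),
    atoms = atoms, seqres = resnames
  )
}

# two n-residue models differing only in chosen CB positions
pair_models <- function(cb_a, cb_b, resnames = rep("ALA", nrow(cb_a))) {
  list(a = pseudo_model(cb_a, resnames, pdb_id = "TOYA"),
       b = pseudo_model(cb_b, resnames, pdb_id = "TOYB"),
       rmap = identity_rmap(nrow(cb_a)))
}

# independent all-pairs contact oracle: its own side-chain selection and
# exhaustive double loops, no calls into the package's distance code
oracle_contacts <- function(model, idx, contact_threshold = 5,
                            min_seq_separation = 1L) {
  sc <- lapply(idx, function(i) {
    a <- model$atoms[model$atoms$res_idx == i, , drop = FALSE]
    if (model$residues$resname[i] == "GLY") {
      a <- a[a$name == "CA", , drop = FALSE]
    } else {
      a <- a[!(a$name %in% c("N", "CA", "C", "O", "OXT")), , drop = FALSE]
    }
    if (nrow(a) == 0) NULL else as.matrix(a[, c("x", "y", "z")])
  })
  n <- length(idx)
  hits <- list()
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    if (j - i < min_seq_separation) next
    if (is.null(sc[[i]]) || is.null(sc[[j]])) next
    best <- Inf
    for (u in seq_len(nrow(sc[[i]]))) for (v in seq_len(nrow(sc[[j]]))) {
      d <- sqrt(sum((sc[[i]][u, ] - sc[[j]][v, ])^2))
      best <- min(best, d)
    }
    if (best < contact_threshold)
      hits[[length(hits) + 1]] <- c(i, j, best)
  }
  if (length(hits) == 0)
    return(data.frame(i = integer(), j = integer(), dist = numeric()))
  out <- as.data.frame(do.call(rbind, hits))
  names(out) <- c("i", "j", "dist")
  out
}

# numeric-optimization RMSD oracle: minimize over rotations directly
# (Euler angles via optim from several starts), no SVD involved
oracle_rmsd <- function(X, Y) {
  cx <- colMeans(X); cy <- colMeans(Y)
  Xc <- sweep(X, 2, cx); Yc <- sweep(Y, 2, cy)
  rot <- function(ang) {
    cz <- cos(ang[1]); sz <- sin(ang[1])
    cyw <- cos(ang[2]); sy <- sin(ang[2])
    cxw <- cos(ang[3]); sx <- sin(ang[3])
    Rz <- matrix(c(cz, sz, 0, -sz, cz, 0, 0, 0, 1), 3, 3)
    Ry <- matrix(c(cyw, 0, -sy, 0, 1, 0, sy, 0, cyw), 3, 3)
    Rx <- matrix(c(1, 0, 0, 0, cxw, sx, 0, -sx, cxw), 3, 3)
    Rz %*% Ry %*% Rx
  }
  f <- function(ang) sqrt(mean(rowSums((Xc - Yc %*% t(rot(ang)))^2)))
  best <- Inf
  for (s in 1:8) {
    set.seed(s)
    r <- stats::optim(stats::runif(3, -pi, pi), f,
                      method = "Nelder-Mead",
                      control = list(maxit = 4000, reltol = 1e-12))
    best <- min(best, r$value)
  }
  best
}

contact_key <- function(df) paste(df$i, df$j)
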