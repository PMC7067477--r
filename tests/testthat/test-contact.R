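test_that("side-chain atom selection follows the Gly and backbone rules", {
  atoms <- data.frame(
    res_idx = c(rep(1L, 5), rep(2L, 4), rep(3L, 4)),
    name = c("N", "CA", "C", "O", "CB",      # ALA
             "N", "CA", "C", "O",            # GLY
             "N", "CA", "C", "OXT"),         # LYS backbone only
    element = "C", x = rep(c(0, 10, 20), c(5, 4, 4)), y = 0, z = 0)
  m <- structure_model(
    "TOY", "A",
    residues = data.frame(resno = 1:3, resname = c("ALA", "GLY", "LYS"),
                          seqres_pos = 1:3),
    atoms = atoms, seqres = c("ALA", "GLY", "LYS"))

  expect_identical(sidechain_heavy_atoms(m, 1)$name, "CB")
  expect_identical(sidechain_heavy_atoms(m, 2)$name, "CA")   # glycine rule
  expect_identical(nrow(sidechain_heavy_atoms(m, 3)), 0L)    # unresolved side chain

  # a residue without side-chain heavy atoms forms no contacts
  expect_true(is.na(min_sidechain_distance(m, 1, m, 3)))
  cm <- compute_contact_map(m, identity_rmap(3), "A",
                            dcm_params(contact_threshold = 100))
  expect_false(any(cm$contacts$i == 3 | cm$contacts$j == 3))
})

test_that("minimum side-chain distance matches brute force", {
  m <- pseudo_model(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(min_sidechain_distance(m, 1, m, 2), 3.0)

  # 4 vs 6 side-chain atoms at random coordinates: exhaustive minimum
  set.seed(31)
  pa <- matrix(rnorm(12, sd = 2), 4)
  pb <- matrix(rnorm(18, mean = 4, sd = 2), 6)
  atoms <- data.frame(
    res_idx = rep(1:2, c(4, 6)),
    name = c(paste0("C", 1:4), paste0("O", 1:6)),  # arbitrary non-backbone names
    element = "C", x = c(pa[, 1], pb[, 1]), y = c(pa[, 2], pb[, 2]),
    z = c(pa[, 3], pb[, 3]))
  m2 <- structure_model(
    "TOY", "A",
    residues = data.frame(resno = 1:2, resname = "ARG", seqres_pos = 1:2),
    atoms = atoms, seqres = c("ARG", "ARG"))
  brute <- min(sqrt(outer(rowSums(pa^2), rowSums(pb^2), "+") -
                      2 * pa %*% t(pb)))
  expect_equal(min_sidechain_distance(m2, 1, m2, 2), brute, tolerance = 1e-12)
})

test_that("contact definition is strictly below the threshold", {
  near <- pair_models(rbind(c(0, 0, 0), c(4.9, 0, 0)),
                      rbind(c(0, 0, 0), c(5.0, 0, 0)))
  cm_a <- compute_contact_map(near$a, near$rmap, "A")
  cm_b <- compute_contact_map(near$b, near$rmap, "B")
  expect_identical(nrow(cm_a$contacts), 1L)  # 4.9 A in contact
  expect_identical(nrow(cm_b$contacts), 0L)  # 5.0 A is not (strict <)
  expect_true(all(cm_a$contacts$dist < 5))

  # 10 residues spaced 10 A apart: no contacts at all
  line <- pseudo_model(cbind(10 * (0:9), 0, 0))
  cm <- compute_contact_map(line, identity_rmap(10), "A")
  expect_identical(nrow(cm$contacts), 0L)
})

test_that("contact maps equal the exhaustive all-pairs oracle", {
  for (seed in 1:3) {
    fx <- make_pair(fixture_spec(30, motion = "hinge", hinge_position = 14,
                                 hinge_angle = 70, gly_positions = c(4L, 22L),
                                 seed = seed))
    m <- parse_structure(fx$pdb_a, "A")
    rmap <- identity_rmap(30)
    cm <- compute_contact_map(m, rmap, "A")
    ora <- oracle_contacts(m, 1:30)
    expect_identical(contact_key(cm$contacts), contact_key(ora))
    expect_equal(cm$contacts$dist, ora$dist, tolerance = 1e-9)
  }
})

test_that("min_seq_separation excludes short-range pairs when asked", {
  chain <- pseudo_model(cbind(3.8 * (0:5), 0, 0))
  cm1 <- compute_contact_map(chain, identity_rmap(6), "A", dcm_params())
  cm2 <- compute_contact_map(chain, identity_rmap(6), "A",
                             dcm_params(min_seq_separation = 2))
  expect_true(any(cm1$contacts$j - cm1$contacts$i == 1))
  expect_false(any(cm2$contacts$j - cm2$contacts$i < 2))
  expect_true(all(contact_key(cm2$contacts) %in% contact_key(cm1$contacts)))
})

test_that("difference map is the labelled symmetric difference", {
  # identical conformations: empty
  same <- pair_models(cbind(10 * (0:4), 0, 0), cbind(10 * (0:4), 0, 0))
  cm_a <- compute_contact_map(same$a, same$rmap, "A")
  cm_b <- compute_contact_map(same$b, same$rmap, "B")
  expect_identical(nrow(difference_map(cm_a, cm_b)$entries), 0L)

  # one-sided case: contact only in A
  one <- pair_models(rbind(c(0, 0, 0), c(100, 0, 0), c(4, 0, 0)),
                     rbind(c(0, 0, 0), c(100, 0, 0), c(40, 0, 0)))
  d <- difference_map(compute_contact_map(one$a, one$rmap, "A"),
                      compute_contact_map(one$b, one$rmap, "B"))
  expect_identical(nrow(d$entries), 1L)
  expect_identical(d$entries$side, "A_only")
  expect_identical(c(d$entries$i, d$entries$j), c(1L, 3L))
  expect_equal(d$entries$delta, 36, tolerance = 1e-6)

  # randomized pairs: set-algebra oracle
  for (seed in 4:6) {
    fx <- make_pair(fixture_spec(24, motion = "shear", hinge_position = 12,
                                 hinge_angle = 8, seed = seed))
    ma <- parse_structure(fx$pdb_a, "A"); mb <- parse_structure(fx$pdb_b, "A")
    rmap <- build_residue_map(NULL, ma, mb)
    cm_a <- compute_contact_map(ma, rmap, "A")
    cm_b <- compute_contact_map(mb, rmap, "B")
    d <- difference_map(cm_a, cm_b)
    ka <- contact_key(cm_a$contacts); kb <- contact_key(cm_b$contacts)
    want <- sort(c(setdiff(ka, kb), setdiff(kb, ka)))
    expect_identical(sort(contact_key(d$entries)), want)
    expect_identical(d$entries$side[contact_key(d$entries) %in% ka],
                     rep("A_only", length(setdiff(ka, kb))))
  }

  # maps over different residue maps refuse to combine
  other <- compute_contact_map(same$a, identity_rmap(4), "A")
  expect_error(difference_map(cm_a, other), "different residue maps")
})

test_that("distance-change filter removes changes at or below threshold", {
  mk_entry <- function(db) {
    p <- pair_models(rbind(c(0, 0, 0), c(4, 0, 0)),
                     rbind(c(0, 0, 0), c(db, 0, 0)))
    d <- difference_map(compute_contact_map(p$a, p$rmap, "A"),
                        compute_contact_map(p$b, p$rmap, "B"))
    filter_difference_map(d)$entries
  }
  expect_false(mk_entry(8.0)$filtered)   # delta 4.0 <= 5: removed
  expect_true(mk_entry(9.5)$filtered)    # delta 5.5 > 5: kept
  expect_false(mk_entry(9.0)$filtered)   # delta 5.0 boundary: removed
  expect_true(mk_entry(9.001)$filtered)  # delta 5.001: kept
})

test_that("entries with undefined distance change are excluded with a warning", {
  a <- pseudo_model(rbind(c(0, 0, 0), c(4, 0, 0)))
  b <- pseudo_model(rbind(c(0, 0, 0), c(4, 0, 0)))
  # strip residue 2's side chain in B: contact exists only in A and the
  # change cannot be evaluated
  b$atoms <- b$atoms[!(b$atoms$res_idx == 2 & b$atoms$name == "CB"), ]
  rmap <- identity_rmap(2)
  d <- difference_map(compute_contact_map(a, rmap, "A"),
                      compute_contact_map(b, rmap, "B"))
  expect_identical(d$entries$side, "A_only")
  expect_true(is.na(d$entries$delta))
  expect_warning(df <- filter_difference_map(d), "undefined distance change")
  expect_false(df$entries$filtered)
})

test_that("DSRs are the union of filtered-contact residues with counts", {
  d <- structure(list(
    entries = data.frame(i = c(1L, 1L, 2L), j = c(5L, 9L, 3L),
                         side = "A_only", dist_a = 4, dist_b = 15,
                         delta = 11, filtered = c(TRUE, TRUE, FALSE)),
    size = 9L, params = dcm_params(), rmap_id = "x", filter_applied = TRUE),
    class = "difference_map")
  m <- pseudo_model(cbind(100 * (0:8), 0, 0))
  dsr <- identify_dsrs(d, m, m, identity_rmap(9))
  expect_identical(dsr$pos, c(1L, 5L, 9L))
  expect_identical(dsr$n_contacts, c(2L, 1L, 1L))
  expect_identical(dsr$resno_a, dsr$resno_b)

  d$entries$filtered <- FALSE
  expect_identical(nrow(identify_dsrs(d, m, m, identity_rmap(9))), 0L)
})

test_that("A/B swap flips labels but preserves deltas, filters and DSRs", {
  fx <- make_pair(fixture_spec(22, motion = "hinge", hinge_position = 11,
                               hinge_angle = 75, seed = 13))
  ma <- parse_structure(fx$pdb_a, "A"); mb <- parse_structure(fx$pdb_b, "A")
  fwd <- dcm_compare(ma, mb)
  rev <- dcm_compare(mb, ma)
  ef <- fwd$dcm$entries; er <- rev$dcm$entries
  expect_identical(contact_key(ef), contact_key(er))
  expect_identical(ifelse(ef$side == "A_only", "B_only", "A_only"), er$side)
  expect_equal(ef$delta, er$delta, tolerance = 1e-12)
  expect_identical(ef$filtered, er$filtered)
  expect_identical(fwd$dsrs$pos, rev$dsrs$pos)
  expect_equal(fwd$changed_fraction, rev$changed_fraction, tolerance = 1e-12)
})

test_that("raising thresholds is monotone", {
  fx <- make_pair(fixture_spec(26, motion = "hinge", hinge_position = 13,
                               hinge_angle = 65, seed = 17))
  m <- parse_structure(fx$pdb_a, "A")
  mb <- parse_structure(fx$pdb_b, "A")
  rmap <- build_residue_map(NULL, m, mb)
  for (ct in c(4, 5, 6, 8)) {
    lo <- compute_contact_map(m, rmap, "A", dcm_params(contact_threshold = ct))
    hi <- compute_contact_map(m, rmap, "A",
                              dcm_params(contact_threshold = ct + 1))
    expect_true(all(contact_key(lo$contacts) %in% contact_key(hi$contacts)))
  }
  cm_a <- compute_contact_map(m, rmap, "A")
  cm_b <- compute_contact_map(mb, rmap, "B")
  d <- difference_map(cm_a, cm_b)
  kept <- lapply(c(3, 5, 7, 10), function(dt) {
    e <- filter_difference_map(d, dcm_params(delta_threshold = dt))$entries
    contact_key(e[e$filtered, ])
  })
  for (k in seq_along(kept)[-1])
    expect_true(all(kept[[k]] %in% kept[[k - 1]]))
})

test_that("comparing a model with itself yields nothing", {
  fx <- make_pair(fixture_spec(16, motion = "hinge", seed = 21))
  m <- parse_structure(fx$pdb_a, "A")
  cmp <- dcm_compare(m, m)
  expect_identical(nrow(cmp$dcm$entries), 0L)
  expect_identical(nrow(cmp$dsrs), 0L)
  expect_equal(cmp$rmsd, 0, tolerance = 1e-9)
  expect_equal(cmp$changed_fraction, 0)
})
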