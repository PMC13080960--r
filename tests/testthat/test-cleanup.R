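# Dehydrogenation, bond perception, residue graph, connectivity filter,
# protonation backend contract, merging and formal charge.

test_that("strip_hydrogens removes H and is idempotent", {
  water <- test_structure(rbind(c(0, 0, 0), c(0.96, 0, 0), c(-0.24, 0.93, 0)),
                          element = c("O", "H", "H"), res_name = "HOH")
  s1 <- strip_hydrogens(water)
  expect_equal(s1$atoms$element, "O")
  expect_identical(strip_hydrogens(s1)$atoms, s1$atoms)

  noh <- test_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_identical(strip_hydrogens(noh)$atoms, noh$atoms)

  # 22-atom residue with 11 H -> 11 heavy atoms remain, order preserved
  el <- rep(c("C", "H"), 11)
  s <- test_structure(cbind(seq_len(22) * 2, 0, 0), element = el)
  out <- strip_hydrogens(s)
  expect_equal(n_atoms(out), 11)
  expect_equal(out$atoms$element, rep("C", 11))
  expect_true(all(diff(out$atoms$serial) > 0))
})

test_that("perceive_bonds applies the covalent-radius + tolerance rule", {
  near <- test_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)))
  expect_equal(nrow(perceive_bonds(near)$bonds), 1)   # C-C 1.5 A
  far <- test_structure(rbind(c(0, 0, 0), c(2.5, 0, 0)))
  expect_equal(nrow(perceive_bonds(far)$bonds), 0)
  lone <- test_structure(c(0, 0, 0))
  expect_equal(nrow(perceive_bonds(lone)$bonds), 0)
  # boundary: threshold for C-C is 0.76 + 0.76 + 0.45 = 1.97
  edge <- test_structure(rbind(c(0, 0, 0), c(1.969, 0, 0)))
  expect_equal(nrow(perceive_bonds(edge)$bonds), 1)
  over <- test_structure(rbind(c(0, 0, 0), c(1.971, 0, 0)))
  expect_equal(nrow(perceive_bonds(over)$bonds), 0)
  # unknown element excluded, with warning
  odd <- test_structure(rbind(c(0, 0, 0), c(1.5, 0, 0)),
                        element = c("C", ""))
  expect_warning(pb <- perceive_bonds(odd), "unknown element")
  expect_equal(nrow(pb$bonds), 0)
  # pre-existing CONECT bonds survive perception
  conect <- test_structure(rbind(c(0, 0, 0), c(5, 0, 0)),
                           bonds = data.frame(a = 1L, b = 2L, order = 1))
  expect_equal(nrow(perceive_bonds(conect)$bonds), 1)
})

test_that("build_residue_graph sees only inter-residue bonds", {
  # dipeptide: residues 1.33 A apart at the junction
  dip <- test_structure(rbind(c(0, 0, 0), c(1.5, 0, 0),
                              c(2.83, 0, 0), c(4.33, 0, 0)),
                        res_seq = c(1L, 1L, 2L, 2L),
                        element = c("C", "C", "N", "C"))
  g <- build_residue_graph(perceive_bonds(dip))
  expect_length(g$nodes, 2)
  expect_equal(nrow(g$edges), 1)

  disjoint <- test_structure(rbind(c(0, 0, 0), c(10, 0, 0)),
                             res_seq = c(1L, 2L))
  g2 <- build_residue_graph(perceive_bonds(disjoint))
  expect_equal(nrow(g2$edges), 0)
  expect_equal(unname(g2$degree), c(0L, 0L))

  # tripeptide chain -> path graph on 3 nodes
  tri <- test_structure(cbind(c(0, 1.5, 2.83, 4.33, 5.66, 7.16), 0, 0),
                        res_seq = c(1L, 1L, 2L, 2L, 3L, 3L),
                        element = c("C", "C", "N", "C", "N", "C"))
  g3 <- build_residue_graph(perceive_bonds(tri))
  expect_length(g3$nodes, 3)
  expect_equal(nrow(g3$edges), 2)
  expect_equal(sort(unname(g3$degree)), c(1L, 1L, 2L))
})

test_that("filter_connected_residues drops floaters, keeps linked chains", {
  # 5 chained residues (2 atoms each) + 1 floating water
  xs <- c(0, 1.5, 2.83, 4.33, 5.66, 7.16, 8.49, 9.99, 11.32, 12.82)
  prot <- test_structure(rbind(cbind(xs, 0, 0), c(30, 0, 0)),
                         res_seq = c(rep(1:5, each = 2), 6L),
                         res_name = c(rep("GLY", 10), "HOH"),
                         element = c(rep(c("C", "N"), 5), "O"))
  out <- filter_connected_residues(perceive_bonds(prot))
  expect_equal(n_atoms(out), 10)
  expect_false("HOH" %in% out$atoms$res_name)
  # fully connected input -> identity on atoms
  expect_identical(filter_connected_residues(out)$atoms, out$atoms)
  # minimum degree >= 1 property
  g <- build_residue_graph(out)
  expect_true(all(g$degree >= 1))

  # two disjoint dipeptides: all four residues kept (degree 1 each)
  dip <- function(x0, rs) test_structure(
    rbind(c(x0, 0, 0), c(x0 + 1.4, 0, 0)),
    res_seq = rs, element = c("C", "N"))
  both <- structure3d(rbind(dip(0, 1L)$atoms,
                            within(dip(50, 3L)$atoms, serial <- serial + 2L)))
  both$atoms$res_seq <- c(1L, 2L, 3L, 4L)
  out2 <- filter_connected_residues(perceive_bonds(both))
  expect_equal(n_atoms(out2), 4)

  # every residue isolated -> empty structure + loud warning
  iso <- test_structure(rbind(c(0, 0, 0), c(30, 0, 0)), res_seq = c(1L, 2L))
  expect_warning(out3 <- filter_connected_residues(perceive_bonds(iso)),
                 "EMPTY")
  expect_equal(n_atoms(out3), 0)
})

test_that("builtin protonation fills valences deterministically", {
  # lone water oxygen -> O + 2 H
  o <- test_structure(c(0, 0, 0), element = "O", res_name = "HOH")
  p <- protonate(o)
  expect_equal(sum(p$atoms$element == "H"), 2)
  expect_equal(sum(p$atoms$element == "O"), 1)
  # heavy atoms unchanged
  expect_equal(coords(p)[p$atoms$element == "O", , drop = FALSE],
               coords(o), ignore_attr = TRUE)
  # determinism
  expect_identical(protonate(o), p)

  # methane-like carbon: 4 H
  c1 <- test_structure(c(0, 0, 0), element = "C")
  expect_equal(sum(protonate(c1)$atoms$element == "H"), 4)

  # carboxylate at pH 7.4 stays deprotonated; at pH 2 it is protonated
  acetate <- perceive_bonds(test_structure(
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.05, 0), c(2.1, -1.05, 0)),
    element = c("C", "C", "O", "O"), res_name = "ACE"))
  p74 <- protonate(acetate, ph = 7.4)
  expect_equal(sum(p74$atoms$element == "H"), 3)   # only the methyl H
  p20 <- protonate(acetate, ph = 2.0)
  expect_equal(sum(p20$atoms$element == "H"), 4)   # acid H present

  # primary amine picks up three hydrogens at pH 7.4
  amine <- perceive_bonds(test_structure(
    rbind(c(0, 0, 0), c(1.47, 0, 0)), element = c("C", "N")))
  pa <- protonate(amine)
  expect_equal(sum(pa$atoms$element == "H"), 6)    # CH3 + NH3+
})

test_that("protonation happens after filtering, never before", {
  fx <- make_complex(fixture_spec(seed = 71, shell_counts = c("3" = 72),
                                  n_waters = 1))
  pre <- prepare_fixture(fx)
  ps <- suppressWarnings(extract_pocket(pre$protein, pre$ligand))
  s <- perceive_bonds(strip_hydrogens(ps$structure))
  filtered <- filter_connected_residues(s)
  expect_false(any(filtered$atoms$element == "H"))
  p <- suppressWarnings(protonate(filtered))
  expect_gt(sum(p$atoms$element == "H"), 0)
  # every hydrogen belongs to a surviving residue
  expect_true(all(residue_ids(p)[p$atoms$element == "H"] %in%
                    unique(residue_ids(filtered))))
})

test_that("obabel backend errors actionably when the binary is absent", {
  skip_if(nzchar(Sys.which("obabel")), "obabel unexpectedly present")
  o <- test_structure(c(0, 0, 0), element = "O")
  expect_error(protonate(o, backend = protonation_backend_obabel),
               "obabel")
})

test_that("merge_structures concatenates, renumbers and tags the ligand", {
  pocket <- test_structure(cbind(seq_len(100) * 2, 0, 0), res_seq = 1L)
  lig <- ligand_spec("XYZ", test_structure(cbind(seq_len(30) * 2, 10, 0),
                                           record = "HETATM",
                                           res_name = "XYZ"))
  m <- merge_structures(pocket, lig)
  expect_equal(n_atoms(m), 130)
  expect_equal(m$atoms$serial, 1:130)
  expect_equal(which(m$atoms$res_name == "XYZ"), 101:130)

  # empty pocket + ligand -> ligand only
  m0 <- merge_structures(structure3d(), lig)
  expect_equal(n_atoms(m0), 30)

  # split by res_name recovers both atom counts
  expect_equal(sum(m$atoms$res_name != "XYZ"), 100)

  # name collision -> suffixed with warning
  pocket2 <- test_structure(c(0, 0, 0), res_name = "XYZ")
  expect_warning(m2 <- merge_structures(pocket2, lig), "collides")
  expect_equal(length(unique(m2$atoms$res_name)), 2)
})

test_that("formal charge: neutral, carboxylate, zwitterion cases", {
  # neutral capped dipeptide-like chain, all valences filled
  chain <- perceive_bonds(test_structure(
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.83, 0, 0), c(4.33, 0, 0)),
    element = c("C", "C", "N", "C"), res_seq = c(1L, 1L, 2L, 2L)))
  neutral <- protonate(chain)
  expect_equal(compute_formal_charge(neutral)$total, 0L)

  # deprotonated carboxylate -> -1
  acetate <- protonate(perceive_bonds(test_structure(
    rbind(c(0, 0, 0), c(1.5, 0, 0), c(2.1, 1.05, 0), c(2.1, -1.05, 0)),
    element = c("C", "C", "O", "O"), res_name = "ACE")))
  rep1 <- compute_formal_charge(acetate)
  expect_equal(rep1$total, -1L)
  expect_equal(sum(rep1$per_residue), rep1$total)

  # carboxylate + protonated amine in one system -> 0
  zwit <- structure3d(rbind(
    acetate$atoms,
    within(protonate(perceive_bonds(test_structure(
      rbind(c(0, 20, 0), c(1.47, 20, 0)), element = c("C", "N"),
      res_seq = 2L, res_name = "AMN")))$atoms,
      serial <- serial + nrow(acetate$atoms))))
  zb <- perceive_bonds(structure3d(zwit$atoms))
  expect_equal(compute_formal_charge(zb)$total, 0L)

  # invariant under atom reordering
  perm <- rev(seq_len(n_atoms(acetate)))
  reordered <- structure3d(acetate$atoms[perm, ], acetate$bonds)
  expect_equal(compute_formal_charge(reordered)$total, -1L)
})
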