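# Pocket extraction: size gate, shell selection, expansion, residue
# completion, cap extension, isolation cleanup, and their properties.

test_that("check_ligand_size gates at the configured atom count", {
  cfg <- pipeline_config()
  mk <- function(n) ligand_spec("LIG", test_structure(
    cbind(seq_len(n) * 2, 0, 0), record = "HETATM", res_name = "LIG"))
  expect_true(check_ligand_size(mk(30), cfg)$pass)
  expect_true(check_ligand_size(mk(120), cfg)$pass)
  expect_false(check_ligand_size(mk(121), cfg)$pass)
  zero <- ligand_spec("LIG", structure3d())
  res <- check_ligand_size(zero, cfg)
  expect_false(res$pass)
  expect_match(res$message, "not present")
})

test_that("select_shell has an inclusive boundary and excludes the ligand", {
  lig <- point_ligand()
  prot <- test_structure(rbind(c(2.99, 0, 0), c(3.01, 0, 0)),
                         res_seq = c(1L, 2L))
  expect_equal(select_shell(prot, lig, 3.0), 1L)
  # radius 0, no coincident atoms -> empty
  expect_length(select_shell(prot, lig, 0), 0)
  # ligand-named residues never selected
  prot2 <- test_structure(rbind(c(1, 0, 0), c(1.5, 0, 0)),
                          res_name = c("LIG", "GLY"), res_seq = c(1L, 2L))
  expect_equal(select_shell(prot2, lig, 3.0), 2L)
})

test_that("iterative_expand stops at the atom target without overshoot", {
  # 70 atoms inside 3 A -> no expansion needed
  fx70 <- make_complex(fixture_spec(seed = 21, shell_counts = c("3" = 70)))
  pre <- prepare_fixture(fx70)
  r <- iterative_expand(pre$protein, pre$ligand)
  expect_equal(r$iterations_used, 0L)
  expect_equal(r$final_radius, 3.0)
  expect_gte(length(r$idx), 70)

  # 69 inside 3 A plus one in (3, 3.5] -> exactly one expansion
  fx69 <- make_complex(fixture_spec(seed = 22,
                                    shell_counts = c("3" = 69, "3.2" = 70)))
  pre <- prepare_fixture(fx69)
  r <- iterative_expand(pre$protein, pre$ligand)
  expect_equal(r$iterations_used, 1L)
  expect_equal(r$final_radius, 3.5)
  expect_false(r$starved)

  # starved protein: terminates after exactly the maximum attempts
  fx10 <- make_complex(fixture_spec(seed = 23, shell_counts = c("3" = 10)))
  pre <- prepare_fixture(fx10)
  expect_warning(r <- iterative_expand(pre$protein, pre$ligand),
                 "exhausted")
  expect_equal(r$iterations_used, 50L)
  expect_equal(r$final_radius, 3.0 + 0.5 * 50)
  expect_true(r$starved)

  # empty protein -> empty selection plus warning
  expect_warning(r0 <- iterative_expand(structure3d(), point_ligand()),
                 "empty")
  expect_length(r0$idx, 0)
})

test_that("iterative_expand uses the minimal iteration count (linear-scan oracle)", {
  for (seed in c(31, 32)) {
    fx <- make_complex(fixture_spec(
      seed = seed, shell_counts = c("3" = 40, "3.5" = 55, "4" = 75)))
    pre <- prepare_fixture(fx)
    cfg <- pipeline_config()
    r <- iterative_expand(pre$protein, pre$ligand, cfg)
    # independent linear scan over radii
    expected_it <- NA
    for (it in 0:cfg$max_expansion_attempts) {
      n <- length(select_shell(pre$protein, pre$ligand,
                               cfg$initial_radius + cfg$radius_step * it))
      if (n >= cfg$min_pocket_atoms) { expected_it <- it; break }
    }
    expect_equal(r$iterations_used, expected_it)
    if (expected_it > 0) {
      expect_lt(length(select_shell(pre$protein, pre$ligand,
                                    r$final_radius - cfg$radius_step)),
                cfg$min_pocket_atoms)
    }
  }
})

test_that("select_shell is monotone in the radius and matches a loop oracle", {
  fx <- make_complex(fixture_spec(seed = 41, shell_counts = c("3" = 30),
                                  n_waters = 2))
  pre <- prepare_fixture(fx)
  lig_xyz <- coords(pre$ligand$structure)
  prev <- integer(0)
  for (r in c(1.5, 2.5, 3, 3.7, 5)) {
    idx <- select_shell(pre$protein, pre$ligand, r)
    expect_true(all(prev %in% idx))   # monotone nesting
    # explicit all-pairs oracle
    oracle <- which(vapply(seq_len(n_atoms(pre$protein)), function(i) {
      p <- unlist(pre$protein$atoms[i, c("x", "y", "z")])
      best <- Inf
      for (j in seq_len(nrow(lig_xyz))) {
        best <- min(best, sqrt(sum((p - lig_xyz[j, ])^2)))
      }
      best <= r
    }, logical(1)))
    expect_identical(idx, oracle)
    prev <- idx
  }
})

test_that("complete_residues is extensive, idempotent and exact on a census", {
  # one 10-atom residue plus a 2-atom one
  xyz <- cbind(seq_len(12) * 2, 0, 0)
  prot <- test_structure(xyz, res_seq = c(rep(1L, 10), rep(2L, 2)))
  got <- complete_residues(prot, 3L)       # one backbone atom touched
  expect_equal(got, 1:10)                  # whole residue
  expect_equal(complete_residues(prot, got), got)  # fixed point
  expect_length(complete_residues(prot, integer(0)), 0)
  expect_true(all(5L %in% complete_residues(prot, 5L)))  # extensive
})

test_that("extend_caps adds nearby atoms but not waters or far atoms", {
  cfg <- pipeline_config()
  lig <- point_ligand()
  # pocket residue 1 at x=3; neighbours at 2.5 (add), 2.7 (no), water at 2.0 (no)
  prot <- test_structure(
    rbind(c(3, 0, 0), c(5.5, 0, 0), c(5.7, 0, 0), c(3, 2.0, 0)),
    res_seq = 1:4,
    res_name = c("GLY", "ALA", "ALA", "HOH"))
  got <- extend_caps(prot, 1L, lig, cfg)
  expect_true(2L %in% got)    # 2.5 A away
  expect_false(3L %in% got)   # 2.7 A away
  expect_false(4L %in% got)   # water at 2.0 A
})

test_that("remove_isolated_atoms drops loners, keeps mutually-near pairs", {
  cfg <- pipeline_config()
  prot <- test_structure(rbind(
    c(0, 0, 0), c(1.5, 0, 0),    # pair 1.5 A apart
    c(10, 0, 0)),                # loner
    res_seq = 1:3)
  kept <- remove_isolated_atoms(prot, 1:3, cfg)
  expect_equal(kept, 1:2)
  expect_length(remove_isolated_atoms(prot, integer(0), cfg), 0)
  # post-hoc brute-force property: no kept atom has NN distance > cutoff
  fx <- make_complex(fixture_spec(seed = 55, shell_counts = c("3" = 40),
                                  n_isolated_atoms = 3))
  pre <- prepare_fixture(fx)
  all_idx <- seq_len(n_atoms(pre$protein))
  kept <- remove_isolated_atoms(pre$protein, all_idx, cfg)
  xyz <- coords(pre$protein)
  for (i in kept) {
    nn <- min(sqrt(colSums((t(xyz[setdiff(kept, i), , drop = FALSE]) -
                              xyz[i, ])^2)))
    expect_lte(nn, cfg$isolation_cutoff)
  }
})

test_that("extract_pocket composes the stages and never keeps ligand or water", {
  fx <- make_complex(fixture_spec(seed = 61, shell_counts = c("3" = 72),
                                  n_waters = 3, n_isolated_atoms = 2))
  pre <- prepare_fixture(fx)
  td <- withr::local_tempdir()
  ps <- suppressWarnings(extract_pocket(pre$protein, pre$ligand,
                                        outdir = td))
  expect_true(file.exists(file.path(td, "test_pocket_extended.pdb")))
  expect_identical(sort(pre$protein$atoms$serial[ps$idx]),
                   brute_force_pocket(pre$protein, pre$ligand))
  expect_false(any(toupper(ps$structure$atoms$res_name) %in%
                     c("LIG", pipeline_config()$water_res_names)))
  expect_equal(ps$final_radius,
               3.0 + 0.5 * ps$iterations_used)

  # oversized ligand aborts before selection
  big <- ligand_spec("BIG", test_structure(cbind(seq_len(121) * 2, 0, 0),
                                           record = "HETATM",
                                           res_name = "BIG"))
  expect_error(extract_pocket(pre$protein, big), "121")

  # degenerate: no protein atoms in any radius -> empty pocket, no crash
  far <- test_structure(c(1000, 0, 0))
  expect_warning(ps0 <- extract_pocket(far, point_ligand()), "exhausted")
  expect_equal(n_atoms(ps0$structure), 0)
})
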