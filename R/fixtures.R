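# Deterministic synthetic protein-ligand complex generator and the
# brute-force pocket oracle.
#
# The generator's central trick: every controlled protein atom is placed
# so that its minimum Euclidean distance to the ligand atom set equals a
# prescribed target EXACTLY (solved by 1-D root finding), so shell
# counts at the configured radii hold by construction.  Atoms are laid
# down as connected chains (1.45 A steps, residues of four atoms with
# peptide-like N/CA/C/O naming) walking tangentially around the ligand,
# so that distance-based bond perception and the connected-residue
# filter behave as they would on a real pocket.

#' Fixture specification
#'
#' @param seed RNG seed; generation is a pure function of the spec.
#' @param shell_counts named numeric vector: cumulative number of
#'   protein chain atoms required within each radius (names are radii in
#'   Angstrom, e.g. `c("3" = 69, "3.5" = 70)`).  Pathology atoms
#'   (waters, isolated atoms, floating residues) are placed beyond the
#'   largest listed radius so the counts stay exact.
#' @param ligand_atom_count atoms in the synthetic ligand.
#' @param ligand_name substructure name written to the MOL2.
#' @param n_altloc_pairs chain atoms duplicated as altLoc A/B pairs.
#' @param n_blank_elements chain atoms written without an element column.
#' @param n_isolated_atoms stray single atoms (> 2 A from everything).
#' @param n_waters water molecules (single O, residue HOH).
#' @param n_disconnected_residues floating 3-atom residues with no
#'   covalent link to any other residue.
#' @param residue_size atoms per chain residue.
#' @return object of class `fixture_spec`.
#' @export
fixture_spec <- function(seed = 1L,
                         shell_counts = c("3" = 70),
                         ligand_atom_count = 17L,
                         ligand_name = "LIG",
                         n_altloc_pairs = 0L,
                         n_blank_elements = 0L,
                         n_isolated_atoms = 0L,
                         n_waters = 0L,
                         n_disconnected_residues = 0L,
                         residue_size = 4L) {
  radii <- as.numeric(names(shell_counts))
  counts <- as.numeric(shell_counts)
  stopifnot(!anyNA(radii), all(diff(radii) > 0), all(diff(counts) >= 0),
            all(counts >= 0), ligand_atom_count >= 0)
  structure(
    list(seed = as.integer(seed), shell_radii = radii,
         shell_cum_counts = counts, ligand_atom_count = as.integer(ligand_atom_count),
         ligand_name = ligand_name,
         n_altloc_pairs = as.integer(n_altloc_pairs),
         n_blank_elements = as.integer(n_blank_elements),
         n_isolated_atoms = as.integer(n_isolated_atoms),
         n_waters = as.integer(n_waters),
         n_disconnected_residues = as.integer(n_disconnected_residues),
         residue_size = as.integer(residue_size)),
    class = "fixture_spec"
  )
}

rand_unit <- function() {
  repeat {
    v <- stats::rnorm(3)
    n <- sqrt(sum(v^2))
    if (n > 1e-6) return(v / n)
  }
}

# minimum distance from point p to the rows of matrix m
.mind <- function(p, m) {
  sqrt(min(colSums((t(m) - p)^2)))
}

# Place a point with exact min-distance `target` to `lig` along ray u
# (optionally offset), by root finding on the scale parameter.
place_on_ray <- function(lig, target, u) {
  f <- function(t) .mind(t * u, lig) - target
  hi <- target + max(sqrt(rowSums(lig^2))) + 1
  if (f(0) > 0) return(NULL)          # ray starts already too far (rare)
  t <- stats::uniroot(f, c(0, hi), tol = 1e-10)$root
  t * u
}

# One step of the tangential chain walk: a point at distance `step` from
# `p_prev` whose min-ligand-distance equals `target` exactly.
walk_step <- function(lig, p_prev, target, step = 1.45, others = NULL,
                      max_tries = 120L) {
  d_prev <- .mind(p_prev, lig)
  nearest <- lig[which.min(colSums((t(lig) - p_prev)^2)), ]
  r_hat <- p_prev - nearest
  r_hat <- r_hat / max(sqrt(sum(r_hat^2)), 1e-9)
  for (try in seq_len(max_tries)) {
    w <- rand_unit()
    w <- w - sum(w * r_hat) * r_hat
    nw <- sqrt(sum(w^2))
    if (nw < 1e-3) next
    w <- w / nw
    g <- function(theta) {
      .mind(p_prev + step * (cos(theta) * w + sin(theta) * r_hat), lig) -
        target
    }
    lo <- g(-pi / 2); hi <- g(pi / 2)
    if (is.na(lo) || is.na(hi) || lo * hi > 0) next
    th <- stats::uniroot(g, c(-pi / 2, pi / 2), tol = 1e-10)$root
    p <- p_prev + step * (cos(th) * w + sin(th) * r_hat)
    if (!is.null(others) && nrow(others) > 0 &&
        .mind(p, others) < 1.80) next
    return(p)
  }
  NULL
}

# Sample exact per-atom target distances for every annulus.
annulus_targets <- function(radii, cum_counts) {
  lo_bounds <- c(0, radii[-length(radii)])
  per <- diff(c(0, cum_counts))
  out <- list()
  for (k in seq_along(radii)) {
    if (per[k] == 0) { out[[k]] <- numeric(0); next }
    lo <- max(lo_bounds[k], 1.7) + 0.05
    hi <- radii[k] - 0.05
    if (hi <= lo) {
      stop(sprintf(
        "fixture: annulus (%.2f, %.2f] too narrow for exact placement",
        lo_bounds[k], radii[k]))
    }
    out[[k]] <- sort(stats::runif(per[k], lo, hi))
  }
  out
}

chain_atom_names <- c(" N  ", " CA ", " C  ", " O  ")
chain_atom_elements <- c("N", "C", "C", "O")

#' Generate a synthetic protein-ligand complex
#'
#' Returns PDB text for the protein, TRIPOS MOL2 text for the ligand,
#' and a ground-truth record (per-atom exact minimum distances to the
#' ligand, category labels and residue assignment).  Same spec, same
#' seed: byte-identical files.
#'
#' @param spec [fixture_spec()].
#' @return list: `protein_pdb` (text), `ligand_mol2` (text), `truth`.
#' @export
make_complex <- function(spec) {
  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                   envir = globalenv())
  }, add = TRUE)
  set.seed(spec$seed, kind = "Mersenne-Twister", normal.kind = "Inversion")

  # --- ligand: self-avoiding random walk near the origin -------------
  n_lig <- spec$ligand_atom_count
  lig <- matrix(0, nrow = max(n_lig, 1), ncol = 3)
  r_ball <- max(1.8, 1.25 * max(n_lig, 1)^(1 / 3) * 1.45)
  if (n_lig > 1) {
    for (i in 2:n_lig) {
      placed <- FALSE
      for (try in 1:300) {
        cand <- lig[i - 1, ] + 1.45 * rand_unit()
        if (sqrt(sum(cand^2)) > r_ball) next
        if (i > 2 && .mind(cand, lig[seq_len(i - 2), , drop = FALSE]) < 0.9)
          next
        lig[i, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) stop("fixture: could not place ligand atom ", i)
    }
  }
  if (n_lig == 0) lig <- matrix(numeric(0), ncol = 3)

  placed_pts <- matrix(numeric(0), ncol = 3)
  atoms <- list()
  truth_rows <- list()
  res_counter <- 0L
  serial_counter <- 0L

  emit_atom <- function(record, name_raw, res_name, chain, res_seq, p,
                        element, category, target, blank_element = FALSE,
                        alt_loc = " ") {
    serial_counter <<- serial_counter + 1L
    atoms[[length(atoms) + 1L]] <<- list(
      record = record, serial = serial_counter, name_raw = name_raw,
      alt_loc = alt_loc, res_name = res_name, chain = chain,
      res_seq = res_seq, x = p[1], y = p[2], z = p[3],
      element = if (blank_element) "" else element
    )
    truth_rows[[length(truth_rows) + 1L]] <<- data.frame(
      serial = serial_counter, category = category,
      res_seq = res_seq, chain = chain, res_name = res_name,
      target_dist = target, alt_loc = alt_loc, stringsAsFactors = FALSE
    )
  }

  # --- shell chains: one connected chain per annulus -----------------
  targets_by_annulus <- annulus_targets(spec$shell_radii,
                                        spec$shell_cum_counts)
  blank_left <- spec$n_blank_elements
  altloc_left <- spec$n_altloc_pairs
  seed_chain <- function(tgt) {
    # prefer well-separated seeds; relax the separation when crowded
    for (sep in c(2.4, 1.85, 1.2, 1.0)) {
      for (try in 1:250) {
        cand <- place_on_ray(lig, tgt, rand_unit())
        if (is.null(cand)) next
        if (nrow(placed_pts) > 0 && .mind(cand, placed_pts) < sep) next
        return(cand)
      }
    }
    stop("fixture: could not seed a shell chain; spec infeasible")
  }
  for (targets in targets_by_annulus) {
    if (length(targets) == 0) next
    p_prev <- NULL
    pos_in_res <- 0L
    for (j in seq_along(targets)) {
      tgt <- targets[j]
      if (is.null(p_prev)) {
        p <- seed_chain(tgt)
        pos_in_res <- 0L
      } else {
        # the immediate predecessor sits at bond distance by design and
        # must not count as a clash
        others <- placed_pts[-nrow(placed_pts), , drop = FALSE]
        p <- walk_step(lig, p_prev, tgt, others = others)
        if (is.null(p)) {
          # walk trapped itself: break the chain and start a new one
          p <- seed_chain(tgt)
          pos_in_res <- 0L
        }
      }
      pos_in_res <- pos_in_res + 1L
      if (pos_in_res > spec$residue_size) pos_in_res <- 1L
      if (pos_in_res == 1L) res_counter <- res_counter + 1L
      slot <- ((pos_in_res - 1L) %% 4L) + 1L
      blank <- blank_left > 0L
      if (blank) blank_left <- blank_left - 1L
      emit_atom("ATOM", chain_atom_names[slot], "GLY", "A", res_counter, p,
                chain_atom_elements[slot], "chain", tgt,
                blank_element = blank)
      if (altloc_left > 0L) {
        altloc_left <- altloc_left - 1L
        # rewrite the atom just emitted as altLoc A and add a B twin
        atoms[[length(atoms)]]$alt_loc <- "A"
        truth_rows[[length(truth_rows)]]$alt_loc <- "A"
        emit_atom("ATOM", chain_atom_names[slot], "GLY", "A", res_counter,
                  p + c(0.25, 0, 0), chain_atom_elements[slot], "altlocB",
                  NA_real_, alt_loc = "B")
      }
      placed_pts <- rbind(placed_pts, matrix(p, ncol = 3))
      p_prev <- p
    }
  }

  r_max <- if (length(spec$shell_radii) > 0) max(spec$shell_radii) else 3
  place_extra <- function(min_sep) {
    for (try in 1:200) {
      tgt <- stats::runif(1, r_max + 0.25, r_max + 2.5)
      cand <- place_on_ray(lig, tgt, rand_unit())
      if (is.null(cand)) next
      if (nrow(placed_pts) > 0 && .mind(cand, placed_pts) < min_sep) next
      return(list(p = cand, target = tgt))
    }
    stop("fixture: could not place pathology atom; spec infeasible")
  }

  # --- stray isolated atoms ------------------------------------------
  for (k in seq_len(spec$n_isolated_atoms)) {
    got <- place_extra(2.05)
    res_counter <- res_counter + 1L
    emit_atom("HETATM", " C  ", "ACE", "A", res_counter, got$p, "C",
              "isolated", got$target)
    placed_pts <- rbind(placed_pts, matrix(got$p, ncol = 3))
  }

  # --- floating (disconnected) 3-atom residues -----------------------
  for (k in seq_len(spec$n_disconnected_residues)) {
    got <- place_extra(2.05)
    res_counter <- res_counter + 1L
    pts <- matrix(got$p, ncol = 3)
    tg <- got$target
    for (j in 1:3) {
      if (j > 1) {
        p <- walk_step(lig, pts[j - 1, ], tg + 0.1 * (j - 1),
                       others = placed_pts)
        if (is.null(p)) stop("fixture: floating residue walk stuck")
        pts <- rbind(pts, matrix(p, ncol = 3))
      }
      emit_atom("ATOM", chain_atom_names[j], "UNK", "B", res_counter,
                pts[j, ], chain_atom_elements[j], "disconnected",
                tg + 0.1 * (j - 1))
    }
    placed_pts <- rbind(placed_pts, pts)
  }

  # --- waters ---------------------------------------------------------
  for (k in seq_len(spec$n_waters)) {
    got <- place_extra(2.05)
    res_counter <- res_counter + 1L
    emit_atom("HETATM", " O  ", "HOH", "W", res_counter, got$p, "O",
              "water", got$target)
    placed_pts <- rbind(placed_pts, matrix(got$p, ncol = 3))
  }

  # --- serialize protein PDB -----------------------------------------
  pdb_lines <- vapply(atoms, function(a) {
    sprintf(
      "%-6s%5d %-4s%1s%-4s%1s%4d%1s   %8.3f%8.3f%8.3f%6.2f%6.2f          %2s",
      a$record, a$serial, a$name_raw, a$alt_loc,
      substr(paste0(a$res_name, "    "), 1, 4), a$chain, a$res_seq, " ",
      a$x, a$y, a$z, 1.00, 0.00, toupper(a$element))
  }, character(1))
  protein_pdb <- paste0(paste(c("TITLE     synthetic complex fixture",
                                pdb_lines, "END"), collapse = "\n"), "\n")

  # --- serialize ligand MOL2 -----------------------------------------
  n_bonds <- max(n_lig - 1L, 0L)
  mol2 <- c(
    "@<TRIPOS>MOLECULE",
    "synthetic_ligand",
    sprintf(" %d %d 1 0 0", n_lig, n_bonds),
    "SMALL",
    "NO_CHARGES",
    "@<TRIPOS>ATOM"
  )
  if (n_lig > 0) {
    mol2 <- c(mol2, vapply(seq_len(n_lig), function(i) {
      sprintf("%7d %-4s %9.4f %9.4f %9.4f %-5s %3d %-4s %9.4f",
              i, paste0("C", i), lig[i, 1], lig[i, 2], lig[i, 3],
              "C.3", 1L, spec$ligand_name, 0.0)
    }, character(1)))
  }
  mol2 <- c(mol2, "@<TRIPOS>BOND")
  if (n_bonds > 0) {
    mol2 <- c(mol2, vapply(seq_len(n_bonds), function(i) {
      sprintf("%6d %5d %5d %s", i, i, i + 1L, "1")
    }, character(1)))
  }
  mol2 <- c(mol2, "@<TRIPOS>SUBSTRUCTURE",
            sprintf("     1 %s         1 GROUP             0       ****    0 ROOT",
                    spec$ligand_name))
  ligand_mol2 <- paste0(paste(mol2, collapse = "\n"), "\n")

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  list(
    protein_pdb = protein_pdb,
    ligand_mol2 = ligand_mol2,
    truth = list(atoms = truth,
                 shell_radii = spec$shell_radii,
                 shell_cum_counts = spec$shell_cum_counts,
                 ligand_xyz = lig,
                 spec = spec)
  )
}

#' Brute-force pocket oracle
#'
#' Re-implements the pocket-extraction algorithm with naive all-pairs
#' distance loops and no shared code with [extract_pocket()]:
#' shell expansion, residue completion, cap extension (excluding ligand
#' and water residues), then single-pass isolated-atom removal.  Used
#' only in tests, on fixture-scale inputs.
#'
#' @param protein structure3d (preprocessed).
#' @param ligand [ligand_spec()].
#' @param cfg [pipeline_config()].
#' @return sorted integer vector of pocket atom serial numbers.
#' @export
brute_force_pocket <- function(protein, ligand, cfg = pipeline_config()) {
  pa <- protein$atoms
  la <- ligand$structure$atoms
  if (nrow(pa) == 0 || nrow(la) == 0) return(integer(0))
  lig_res <- toupper(substr(ligand$name, 1, 4))
  cand <- which(toupper(pa$res_name) != lig_res)

  mind_lig <- function(i) {
    best <- Inf
    for (j in seq_len(nrow(la))) {
      d <- sqrt((pa$x[i] - la$x[j])^2 + (pa$y[i] - la$y[j])^2 +
                  (pa$z[i] - la$z[j])^2)
      if (d < best) best <- d
    }
    best
  }
  dl <- vapply(cand, mind_lig, numeric(1))

  sel <- integer(0)
  for (it in 0:cfg$max_expansion_attempts) {
    r <- cfg$initial_radius + cfg$radius_step * it
    sel <- cand[dl <= r]
    if (length(sel) >= cfg$min_pocket_atoms) break
  }

  # residue completion
  rid <- paste(pa$chain_id, pa$res_seq, pa$i_code, pa$res_name, sep = "|")
  in_res <- rid %in% unique(rid[sel])
  sel <- which(in_res)

  # cap extension, atom level, excluding ligand-named and water residues
  added <- integer(0)
  for (i in setdiff(cand, sel)) {
    if (toupper(pa$res_name[i]) %in% cfg$water_res_names) next
    best <- Inf
    for (j in sel) {
      d <- sqrt((pa$x[i] - pa$x[j])^2 + (pa$y[i] - pa$y[j])^2 +
                  (pa$z[i] - pa$z[j])^2)
      if (d < best) best <- d
    }
    if (best <= cfg$cap_extension_radius) added <- c(added, i)
  }
  sel <- sort(c(sel, added))

  # single-pass isolated-atom removal
  keep <- logical(length(sel))
  for (u in seq_along(sel)) {
    i <- sel[u]
    best <- Inf
    for (v in seq_along(sel)) {
      if (u == v) next
      j <- sel[v]
      d <- sqrt((pa$x[i] - pa$x[j])^2 + (pa$y[i] - pa$y[j])^2 +
                  (pa$z[i] - pa$z[j])^2)
      if (d < best) best <- d
    }
    keep[u] <- best <= cfg$isolation_cutoff
  }
  sort(pa$serial[sel[keep]])
}

#' Canned multi-frame XYZ for the mock CREST runner
#'
#' Deterministic sinusoidal perturbations of the template coordinates,
#' with an energy-like comment line per frame.
#'
#' @param template structure3d (the merged complex).
#' @param n_frames number of conformer frames.
#' @param amplitude displacement amplitude, Angstrom.
#' @return XYZ text.
#' @export
make_mock_xyz <- function(template, n_frames = 3L, amplitude = 0.05) {
  a <- template$atoms
  n <- nrow(a)
  out <- character(0)
  for (f in seq_len(n_frames)) {
    dx <- amplitude * sin(f * seq_len(n))
    dy <- amplitude * cos(f * seq_len(n))
    dz <- amplitude * sin(f + seq_len(n))
    out <- c(out, as.character(n),
             sprintf(" %12.8f", -15 - 0.01 * f),
             sprintf("%-2s %14.8f %14.8f %14.8f",
                     ifelse(nzchar(a$element), a$element, "C"),
                     a$x + dx, a$y + dy, a$z + dz))
  }
  paste0(paste(out, collapse = "\n"), "\n")
}
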