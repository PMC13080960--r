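# Chemical cleanup of the carved pocket: dehydrogenation, distance-based
# bond perception, connected-residue filtering, protonation at a target
# pH via a pluggable backend, merging with the ligand, and formal-charge
# bookkeeping.

#' Remove all hydrogen atoms
#'
#' Drops every element-H (and D) atom together with its bonds; heavy-atom
#' order is preserved.  Idempotent.
#'
#' @param s structure3d with populated elements.
#' @return structure3d.
#' @export
strip_hydrogens <- function(s) {
  if (n_atoms(s) == 0) return(s)
  keep <- !(s$atoms$element %in% c("H", "D"))
  subset_structure(s, which(keep))
}

#' Distance-based bond perception
#'
#' Adds a bond between atoms i and j whenever their distance does not
#' exceed the sum of their covalent radii plus `tolerance` (0.45 A, a
#' common heuristic).  Existing bonds (e.g. from CONECT records) are
#' kept.  Atoms whose element has no tabulated covalent radius are
#' excluded from perception with a warning.
#'
#' @param s structure3d with populated elements.
#' @param tolerance slack added to the covalent-radius sum, Angstrom.
#' @return structure3d with bonds.
#' @export
perceive_bonds <- function(s, tolerance = 0.45) {
  n <- n_atoms(s)
  if (n < 2) return(s)
  el <- s$atoms$element
  known <- el %in% names(COVALENT_RADII)
  if (any(!known & nzchar(el))) {
    warning("perceive_bonds: no covalent radius for element(s) ",
            paste(unique(el[!known & nzchar(el)]), collapse = ", "),
            "; excluded from perception")
  }
  if (any(!nzchar(el))) {
    warning("perceive_bonds: atoms with unknown element excluded ",
            "from perception")
  }
  idx <- which(known)
  if (length(idx) >= 2) {
    r <- COVALENT_RADII[el[idx]]
    xyz <- coords(s)[idx, , drop = FALSE]
    d <- as.matrix(stats::dist(xyz))
    cut <- outer(r, r, "+") + tolerance
    hit <- which(d <= cut & upper.tri(d), arr.ind = TRUE)
    if (nrow(hit) > 0) {
      new_bonds <- data.frame(
        a = s$atoms$serial[idx[hit[, 1]]],
        b = s$atoms$serial[idx[hit[, 2]]],
        order = 1
      )
      # normalize_bonds keeps the first record on duplicates, so
      # pre-existing bonds (and their orders) win over perceived ones
      s$bonds <- normalize_bonds(rbind(s$bonds, new_bonds))
    }
  }
  s
}

#' Residue connectivity graph
#'
#' Nodes are residue identities; an edge joins two residues sharing at
#' least one covalent bond.  Intra-residue bonds are ignored.
#'
#' @param s structure3d with bonds.
#' @return list: `nodes` (residue keys), `edges` (two-column character
#'   matrix), `degree` (named integer vector).
#' @export
build_residue_graph <- function(s) {
  rid <- residue_ids(s)
  nodes <- unique(rid)
  degree <- stats::setNames(integer(length(nodes)), nodes)
  edges <- matrix(character(0), ncol = 2)
  if (nrow(s$bonds) > 0 && length(nodes) > 0) {
    by_serial <- stats::setNames(rid, as.character(s$atoms$serial))
    ra <- by_serial[as.character(s$bonds$a)]
    rb <- by_serial[as.character(s$bonds$b)]
    inter <- which(ra != rb)
    if (length(inter) > 0) {
      e <- cbind(pmin(ra[inter], rb[inter]), pmax(ra[inter], rb[inter]))
      e <- unique(e)
      edges <- e
      tab <- table(c(e[, 1], e[, 2]))
      degree[names(tab)] <- as.integer(tab)
    }
  }
  list(nodes = nodes, edges = edges, degree = degree)
}

#' Keep only covalently connected residues
#'
#' Residues with no covalent bond to any other residue (graph degree 0)
#' are discarded: they are floating fragments - stray waters, isolated
#' side-chain debris - that would be protonated nonsensically.  Bonds are
#' restricted to the surviving atoms.  If every residue is isolated the
#' result is an empty structure and a loud warning is emitted (the
#' pipeline treats an empty pocket as a stage failure).
#'
#' @param s structure3d with bonds (run [perceive_bonds()] first).
#' @return structure3d.
#' @export
filter_connected_residues <- function(s) {
  if (n_atoms(s) == 0) return(s)
  g <- build_residue_graph(s)
  keep_res <- g$nodes[g$degree[g$nodes] >= 1]
  if (length(keep_res) == 0) {
    warning("filter_connected_residues: every residue is isolated; ",
            "the filtered structure is EMPTY")
    return(structure3d(title = s$title))
  }
  rid <- residue_ids(s)
  subset_structure(s, which(rid %in% keep_res))
}

# ---------------------------------------------------------------------
# Bond-order assignment (valence bookkeeping support)
# ---------------------------------------------------------------------

# Greedy promotion of single bonds to double bonds wherever both
# endpoints still have unfilled standard valence.  Promotion is
# restricted to bonds with exactly one oxygen endpoint (C=O, S=O, P=O,
# N=O): that recovers carbonyls and carboxylates from a
# distance-perceived single-bond skeleton without inventing C=C or C=N
# double bonds that valence deficits alone cannot distinguish from
# missing hydrogens.  Deterministic: bonds are visited in normalized
# (a, b) order, repeatedly until a fixed point.
assign_bond_orders <- function(s) {
  if (nrow(s$bonds) == 0 || n_atoms(s) == 0) return(s)
  el <- stats::setNames(s$atoms$element, as.character(s$atoms$serial))
  valence_sum <- function(bonds) {
    vs <- stats::setNames(numeric(n_atoms(s)), as.character(s$atoms$serial))
    if (nrow(bonds) > 0) {
      for (k in seq_len(nrow(bonds))) {
        a <- as.character(bonds$a[k]); b <- as.character(bonds$b[k])
        vs[a] <- vs[a] + bonds$order[k]
        vs[b] <- vs[b] + bonds$order[k]
      }
    }
    vs
  }
  partner_ok <- c("C", "N", "S", "P")
  bonds <- s$bonds
  repeat {
    vs <- valence_sum(bonds)
    changed <- FALSE
    for (k in seq_len(nrow(bonds))) {
      a <- as.character(bonds$a[k]); b <- as.character(bonds$b[k])
      if (bonds$order[k] != 1) next
      one_oxygen <- (el[a] == "O") != (el[b] == "O")
      partner <- if (el[a] == "O") el[b] else el[a]
      if (!one_oxygen || !(partner %in% partner_ok)) next
      da <- STANDARD_VALENCE[el[a]] - vs[a]
      db <- STANDARD_VALENCE[el[b]] - vs[b]
      if (!is.na(da) && !is.na(db) && da >= 1 && db >= 1) {
        bonds$order[k] <- 2
        vs[a] <- vs[a] + 1; vs[b] <- vs[b] + 1
        changed <- TRUE
      }
    }
    if (!changed) break
  }
  s$bonds <- bonds
  s
}

# Per-atom sum of bond orders (explicit hydrogens included as order-1
# bonds like any other).
atom_valence_sums <- function(s) {
  vs <- stats::setNames(numeric(n_atoms(s)), as.character(s$atoms$serial))
  if (nrow(s$bonds) > 0) {
    for (k in seq_len(nrow(s$bonds))) {
      a <- as.character(s$bonds$a[k]); b <- as.character(s$bonds$b[k])
      vs[a] <- vs[a] + s$bonds$order[k]
      vs[b] <- vs[b] + s$bonds$order[k]
    }
  }
  vs
}

# ---------------------------------------------------------------------
# Protonation backends
# ---------------------------------------------------------------------

#' Built-in deterministic protonation backend
#'
#' Adds hydrogens by valence bookkeeping on the heavy-atom skeleton
#' (after greedy bond-order assignment), with two pH-dependent rules
#' evaluated against typical pKa values: carboxylate oxygens stay
#' deprotonated when pH > 4.8, and primary sp3 amines are protonated
#' (three hydrogens, +1) when pH < 10.6.  Hydrogen positions are
#' deterministic: each H is placed at a fixed bond length from its
#' parent, directed away from the mean of the parent's neighbour
#' directions.  Histidine tautomers, guanidinium groups and tautomer
#' enumeration are out of scope.
#'
#' @param s structure3d (hydrogens absent, bonds present or perceivable).
#' @param ph target pH.
#' @return protonated structure3d; hydrogens are inserted directly after
#'   their parent atom and serials are renumbered contiguously.
#' @export
protonation_backend_builtin <- function(s, ph = 7.4) {
  if (n_atoms(s) == 0) return(s)
  if (nrow(s$bonds) == 0) s <- perceive_bonds(s)
  s <- assign_bond_orders(s)
  vs <- atom_valence_sums(s)
  el <- s$atoms$element
  ser <- as.character(s$atoms$serial)

  neighbours <- function(serial) {
    b <- s$bonds
    c(b$b[b$a == serial], b$a[b$b == serial])
  }
  order_of <- function(sa, sb) {
    b <- s$bonds
    k <- which((b$a == sa & b$b == sb) | (b$a == sb & b$b == sa))
    if (length(k) == 0) 0 else b$order[k[1]]
  }

  n_h <- integer(n_atoms(s))
  for (i in seq_len(n_atoms(s))) {
    e <- el[i]
    v <- STANDARD_VALENCE[e]
    if (is.na(v)) next  # metals and unknowns: no hydrogens
    deficit <- v - vs[ser[i]]
    nh <- max(0L, as.integer(round(deficit)))
    nb <- neighbours(s$atoms$serial[i])
    if (e == "O" && nh == 1 && length(nb) == 1) {
      # carboxylate pattern: O(-C) where the C carries a C=O partner
      cnb <- nb[1]
      if (el[match(cnb, s$atoms$serial)] == "C") {
        c_part <- neighbours(cnb)
        has_carbonyl <- any(vapply(c_part, function(p) {
          el[match(p, s$atoms$serial)] == "O" && order_of(cnb, p) == 2
        }, logical(1)))
        if (has_carbonyl && ph > 4.8) nh <- 0L
      }
    }
    if (e == "N" && length(nb) == 1 && deficit >= 2) {
      # primary sp3 amine (single heavy neighbour, all-single bonds)
      if (order_of(s$atoms$serial[i], nb[1]) == 1 && ph < 10.6) {
        nh <- 3L
      }
    }
    n_h[i] <- nh
  }

  add_rows <- list()
  add_bonds <- list()
  xyz <- coords(s)
  h_len <- c(O = 0.96, N = 1.01, C = 1.09, S = 1.34)
  for (i in which(n_h > 0)) {
    p <- xyz[i, ]
    nb <- neighbours(s$atoms$serial[i])
    if (length(nb) > 0) {
      vecs <- vapply(nb, function(sn) {
        q <- xyz[match(sn, s$atoms$serial), ]
        v <- q - p
        v / max(sqrt(sum(v^2)), 1e-9)
      }, numeric(3))
      away <- -rowMeans(matrix(vecs, nrow = 3))
      if (sqrt(sum(away^2)) < 1e-6) away <- c(0, 0, 1)
    } else {
      away <- c(0, 0, 1)
    }
    away <- away / sqrt(sum(away^2))
    # deterministic local frame
    refv <- if (abs(away[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
    u1 <- refv - sum(refv * away) * away
    u1 <- u1 / sqrt(sum(u1^2))
    u2 <- c(away[2] * u1[3] - away[3] * u1[2],
            away[3] * u1[1] - away[1] * u1[3],
            away[1] * u1[2] - away[2] * u1[1])
    blen <- h_len[el[i]]
    if (is.na(blen)) blen <- 1.00
    dirs <- list()
    k <- n_h[i]
    # spread k hydrogens on a cone around 'away'
    if (k == 1) {
      dirs[[1]] <- away
    } else {
      for (j in seq_len(k)) {
        ang <- 2 * pi * (j - 1) / k
        dirs[[j]] <- 0.5 * away +
          sqrt(1 - 0.25) * (cos(ang) * u1 + sin(ang) * u2)
      }
    }
    for (j in seq_len(k)) {
      d <- dirs[[j]] / sqrt(sum(dirs[[j]]^2))
      hp <- p + blen * d
      add_rows[[length(add_rows) + 1]] <- data.frame(
        record = s$atoms$record[i], serial = NA_integer_,
        atom_name = if (k == 1) "H" else paste0("H", j),
        name_raw = NA_character_, alt_loc = " ",
        res_name = s$atoms$res_name[i], chain_id = s$atoms$chain_id[i],
        res_seq = s$atoms$res_seq[i], i_code = s$atoms$i_code[i],
        x = hp[1], y = hp[2], z = hp[3], occupancy = 1, b_factor = 0,
        element = "H", stringsAsFactors = FALSE
      )
      add_bonds[[length(add_bonds) + 1]] <- i  # parent row
    }
  }

  if (length(add_rows) == 0) return(s)

  # interleave: each hydrogen directly after its parent heavy atom
  parent_rows <- unlist(add_bonds)
  new_order <- list()
  for (i in seq_len(n_atoms(s))) {
    new_order[[length(new_order) + 1]] <- list(type = "heavy", i = i)
    for (k in which(parent_rows == i)) {
      new_order[[length(new_order) + 1]] <- list(type = "H", i = k)
    }
  }
  rows <- lapply(new_order, function(o) {
    if (o$type == "heavy") s$atoms[o$i, , drop = FALSE] else add_rows[[o$i]]
  })
  atoms <- do.call(rbind, rows)
  rownames(atoms) <- NULL
  # renumber; remap heavy-atom bonds and add H-parent bonds
  old_serial <- atoms$serial
  atoms$serial <- seq_len(nrow(atoms))
  map <- stats::setNames(atoms$serial[!is.na(old_serial)],
                         as.character(old_serial[!is.na(old_serial)]))
  bonds <- s$bonds
  if (nrow(bonds) > 0) {
    bonds$a <- as.integer(map[as.character(bonds$a)])
    bonds$b <- as.integer(map[as.character(bonds$b)])
  }
  h_rows <- which(is.na(old_serial))
  hb <- data.frame(a = integer(0), b = integer(0), order = numeric(0))
  for (r in h_rows) {
    # parent is the nearest preceding heavy atom row
    pr <- max(which(!is.na(old_serial[seq_len(r - 1)])))
    hb <- rbind(hb, data.frame(a = atoms$serial[pr], b = atoms$serial[r],
                               order = 1))
  }
  structure3d(atoms, rbind(bonds, hb), s$title)
}

#' Open Babel protonation backend
#'
#' Shells out to `obabel` to add hydrogens at the requested pH.  Errors
#' with an actionable message when the executable is not on the PATH.
#'
#' @inheritParams protonation_backend_builtin
#' @export
protonation_backend_obabel <- function(s, ph = 7.4) {
  exe <- Sys.which("obabel")
  if (!nzchar(exe)) {
    stop("protonation backend 'obabel' requires the Open Babel executable ",
         "'obabel' on the PATH; install Open Babel or use ",
         "backend = protonation_backend_builtin")
  }
  fin <- tempfile(fileext = ".pdb"); fout <- tempfile(fileext = ".pdb")
  on.exit(unlink(c(fin, fout)), add = TRUE)
  write_pdb(s, fin)
  status <- system2(exe, c(fin, "-O", fout, "-p", format(ph)),
                    stdout = FALSE, stderr = FALSE)
  if (status != 0 || !file.exists(fout)) {
    stop("obabel protonation failed (exit status ", status, ")")
  }
  parse_pdb(paste(readLines(fout), collapse = "\n"))
}

#' Protonate a structure at a target pH
#'
#' Thin dispatcher over a pluggable backend.  The default is the
#' deterministic built-in valence-based protonator; pass
#' [protonation_backend_obabel] to delegate to Open Babel.
#'
#' @param s structure3d (hydrogens should have been stripped).
#' @param ph target pH (default 7.4).
#' @param backend function(structure, ph) -> structure.
#' @return protonated structure3d.
#' @export
protonate <- function(s, ph = 7.4, backend = protonation_backend_builtin) {
  backend(s, ph)
}

# ---------------------------------------------------------------------
# Merging and formal charge
# ---------------------------------------------------------------------

#' Merge the prepared pocket with the ligand
#'
#' Pocket atoms come first, ligand atoms after; serials are renumbered
#' contiguously from 1.  Ligand atoms carry the ligand name as residue
#' name (truncated to 4 characters); a collision with a pocket residue
#' name is resolved by suffixing, with a warning.
#'
#' @param pocket structure3d (protonated pocket).
#' @param ligand [ligand_spec()].
#' @return merged structure3d; the ligand residue name actually used is
#'   attached as attribute "ligand_res_name".
#' @export
merge_structures <- function(pocket, ligand) {
  lig <- ligand$structure
  lig_res <- toupper(substr(ligand$name, 1, 4))
  if (lig_res %in% toupper(pocket$atoms$res_name)) {
    new_res <- paste0(substr(lig_res, 1, 3), "Z")
    warning(sprintf(
      "merge_structures: ligand name '%s' collides with a pocket residue; using '%s'",
      lig_res, new_res))
    lig_res <- new_res
  }
  la <- lig$atoms
  if (nrow(la) > 0) {
    la$res_name <- lig_res
    la$record <- "HETATM"
    la$name_raw <- NA_character_
  }
  atoms <- rbind(pocket$atoms, la)
  rownames(atoms) <- NULL
  n_pocket <- nrow(pocket$atoms)
  old_p <- pocket$atoms$serial
  old_l <- la$serial
  atoms$serial <- seq_len(nrow(atoms))
  pb <- pocket$bonds
  if (nrow(pb) > 0) {
    map <- stats::setNames(seq_len(n_pocket), as.character(old_p))
    pb$a <- as.integer(map[as.character(pb$a)])
    pb$b <- as.integer(map[as.character(pb$b)])
  }
  lb <- lig$bonds
  if (nrow(lb) > 0) {
    map <- stats::setNames(n_pocket + seq_len(nrow(la)), as.character(old_l))
    lb$a <- as.integer(map[as.character(lb$a)])
    lb$b <- as.integer(map[as.character(lb$b)])
  }
  out <- structure3d(atoms, rbind(pb, lb), pocket$title)
  attr(out, "ligand_res_name") <- lig_res
  out
}

#' Formal charge of a protonated structure
#'
#' Valence bookkeeping: after greedy bond-order assignment, each atom's
#' formal charge follows from its summed bond orders (explicit hydrogens
#' included) against the element's standard valence.  Covers H, C, N, O,
#' S, P and the halogens; metals contribute 0 with a warning.  Aromatic
#' (order 1.5) bonds are accommodated by treating valence sums within
#' 0.6 of a neutral state as neutral.
#'
#' @param s structure3d, protonated, with bonds.
#' @return list of class `charge_report`: `total` (integer) and
#'   `per_residue` (named integer vector).
#' @export
compute_formal_charge <- function(s) {
  if (n_atoms(s) == 0) {
    return(structure(list(total = 0L,
                          per_residue = stats::setNames(integer(0), character(0))),
                     class = "charge_report"))
  }
  if (nrow(s$bonds) == 0) s <- perceive_bonds(s)
  s <- assign_bond_orders(s)
  vs <- atom_valence_sums(s)
  el <- s$atoms$element
  q <- numeric(n_atoms(s))
  warned_metal <- FALSE
  bad <- character(0)
  for (i in seq_len(n_atoms(s))) {
    e <- el[i]
    v <- vs[as.character(s$atoms$serial[i])]
    q[i] <- switch(
      e,
      "H" = 0,
      "C" = 0,
      "N" = if (v >= 3.6) 1 else if (v <= 2.4) -1 else 0,
      "O" = if (v <= 1.4) -1 else if (v >= 2.6) 1 else 0,
      "S" = if (v <= 1.4) -1 else 0,   # 2/4/6 are neutral valence states
      "P" = 0,                          # 3/5 neutral
      "F" = , "Cl" = , "Br" = , "I" = if (v < 0.5) -1 else 0,
      {
        if (e %in% METAL_ELEMENTS) {
          warned_metal <- TRUE
        }
        0
      }
    )
    if (e == "C" && abs(v - 4) > 0.6) bad <- c(bad, sprintf(
      "%s %s%d (valence %.1f)", s$atoms$atom_name[i], s$atoms$res_name[i],
      s$atoms$res_seq[i], v))
  }
  if (warned_metal) {
    warning("compute_formal_charge: metal atoms assigned charge 0 ",
            "(no annotation available)")
  }
  if (length(bad) > 0) {
    warning("compute_formal_charge: unusual carbon valence at ",
            paste(utils::head(bad, 5), collapse = "; "))
  }
  rid <- residue_ids(s)
  per <- vapply(split(q, rid), function(z) as.integer(round(sum(z))),
                integer(1))
  # preserve first-appearance residue order
  per <- per[unique(rid)]
  structure(list(total = as.integer(round(sum(q))), per_residue = per),
            class = "charge_report")
}

#' @export
print.charge_report <- function(x, ...) {
  cat(sprintf("charge_report: total formal charge %+d over %d residue(s)\n",
              x$total, length(x$per_residue)))
  invisible(x)
}
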