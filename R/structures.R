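# Structure parsing, residue contacts, solvent accessibility and interface
# classification for heterodimeric protein complexes.

# Standard amino-acid residue names retained as polymer; everything else
# (waters, ions, ligands) is treated as non-polymer and dropped.
AA3 <- c(
  "ALA", "ARG", "ASN", "ASP", "CYS", "GLN", "GLU", "GLY", "HIS", "ILE",
  "LEU", "LYS", "MET", "PHE", "PRO", "SER", "THR", "TRP", "TYR", "VAL",
  "MSE", "SEC", "PYL"
)

# Van der Waals radii (Angstrom) by element, Bondi-style values as used by
# common SASA implementations; unknown elements fall back to carbon.
VDW_RADII <- c(
  H = 1.20, D = 1.20, C = 1.70, N = 1.55, O = 1.52, S = 1.80,
  P = 1.80, SE = 1.90, F = 1.47, CL = 1.75, BR = 1.85, I = 1.98
)
VDW_DEFAULT <- 1.70

#' Parse a protein complex structure into an atom table
#'
#' Reads an mmCIF or legacy PDB file and returns one row per polymer heavy
#' or hydrogen atom of the first model. Non-polymer entities (waters, ions,
#' ligands) are removed. When alternate locations are present, the highest
#' occupancy altloc is kept (ties broken in favour of altloc "A").
#'
#' @param file Path to a structure file.
#' @param dialect One of `"auto"`, `"mmcif"`, `"pdb"`. With `"auto"` the
#'   dialect is chosen from the file extension (`.cif` / `.mmcif` vs others).
#' @param structure_id Identifier recorded in the output; defaults to the
#'   file name without extension.
#'
#' @return A tibble with columns `structure_id`, `chain`, `resno`, `insert`,
#'   `resid`, `atom`, `element`, `x`, `y`, `z`, `occupancy`, `is_heavy`.
#'   Residues within a chain are uniquely identified by `(resno, insert)`.
#' @export
read_structure <- function(file, dialect = c("auto", "mmcif", "pdb"),
                           structure_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(file)) {
    abort(paste0("structure file not found: ", file))
  }
  if (dialect == "auto") {
    dialect <- if (grepl("\\.(cif|mmcif)$", file, ignore.case = TRUE)) {
      "mmcif"
    } else {
      "pdb"
    }
  }
  structure_id <- structure_id %||%
    sub("\\.[^.]*$", "", basename(file))

  pdb <- tryCatch(
    if (dialect == "mmcif") {
      suppressWarnings(bio3d::read.cif(file))
    } else {
      suppressWarnings(bio3d::read.pdb(file, multi = FALSE,
                                       rm.alt = FALSE))
    },
    error = function(e) {
      abort(paste0("failed to parse ", dialect, " file '", file, "': ",
                   conditionMessage(e)))
    }
  )
  at <- as_tibble(pdb$atom)

  # element: prefer the element symbol column, fall back to the first
  # alphabetic character of the atom name
  elesy <- toupper(trimws(as.character(at$elesy %||% NA_character_)))
  from_name <- toupper(substr(gsub("[^A-Za-z].*$", "",
                                   gsub("^[0-9]+", "", at$elety)), 1, 1))
  element <- ifelse(is.na(elesy) | elesy == "", from_name, elesy)

  out <- tibble(
    structure_id = structure_id,
    chain = as.character(at$chain),
    resno = as.integer(at$resno),
    insert = ifelse(is.na(at$insert), "", as.character(at$insert)),
    resid = as.character(at$resid),
    atom = as.character(at$elety),
    element = element,
    x = as.numeric(at$x),
    y = as.numeric(at$y),
    z = as.numeric(at$z),
    occupancy = as.numeric(at$o),
    alt = ifelse(is.na(at$alt), "", as.character(at$alt))
  )

  out <- filter(out, .data$resid %in% AA3)
  if (nrow(out) == 0) {
    abort(paste0("no polymer (amino-acid) chains in '", file, "'"))
  }
  if (any(!is.finite(out$x) | !is.finite(out$y) | !is.finite(out$z))) {
    abort("non-finite atom coordinates in structure file")
  }

  # mmCIF multi-model files concatenate models with repeated atom
  # identities; keep the first occurrence (model 1)
  key <- paste(out$chain, out$resno, out$insert, out$atom, out$alt)
  out <- out[!duplicated(key), ]

  # altloc: keep the highest-occupancy location per (residue, atom name),
  # ties resolved toward altloc "A" (then alphabetically)
  if (any(out$alt != "")) {
    out <- out |>
      group_by(.data$chain, .data$resno, .data$insert, .data$atom) |>
      arrange(dplyr::desc(.data$occupancy),
              .data$alt != "A", .data$alt, .by_group = TRUE) |>
      dplyr::slice(1) |>
      ungroup() |>
      arrange(.data$chain, .data$resno, .data$insert)
  }
  out |>
    mutate(is_heavy = !(.data$element %in% c("H", "D"))) |>
    select(-"alt")
}

#' Count structurally resolved residues per chain
#'
#' @param atoms Atom table from [read_structure()].
#' @return A tibble with `structure_id`, `chain`, `n_residues`.
#' @export
resolved_residues <- function(atoms) {
  atoms |>
    distinct(.data$structure_id, .data$chain, .data$resno, .data$insert) |>
    count(.data$structure_id, .data$chain, name = "n_residues")
}

#' Select one representative structure per protein pair
#'
#' Among alternative structures of the same (unordered) protein pair, keeps
#' the one with the largest total number of structurally resolved residues.
#' Ties are broken by the lexicographically smallest structure identifier,
#' so the selection is deterministic.
#'
#' @param candidates A tibble with columns `structure_id`, `protein_a`,
#'   `protein_b`, `resolved` (total resolved residues in the structure).
#' @return One row per unordered protein pair with the winning
#'   `structure_id`.
#' @export
select_representative_structure <- function(candidates) {
  stopifnot(all(c("structure_id", "protein_a", "protein_b", "resolved") %in%
                  names(candidates)))
  if (nrow(candidates) == 0) {
    abort("no candidate structures supplied")
  }
  if (any(candidates$resolved < 0)) {
    abort("resolved residue counts must be nonnegative")
  }
  candidates |>
    mutate(
      pair_1 = pmin(.data$protein_a, .data$protein_b),
      pair_2 = pmax(.data$protein_a, .data$protein_b)
    ) |>
    group_by(.data$pair_1, .data$pair_2) |>
    arrange(dplyr::desc(.data$resolved), .data$structure_id,
            .by_group = TRUE) |>
    dplyr::slice(1) |>
    ungroup() |>
    select("pair_1", "pair_2", "structure_id", "resolved") |>
    rename(protein_a = "pair_1", protein_b = "pair_2")
}

#' Inter-chain residue contacts at a heavy-atom distance cutoff
#'
#' Two residues from different chains are in contact when any pair of their
#' heavy (non-hydrogen) atoms lies within `cutoff` Angstrom. Each contacting
#' residue pair is reported once, with the minimum heavy-atom distance.
#'
#' @param atoms Atom table from [read_structure()].
#' @param chain_a,chain_b Chain identifiers; must differ.
#' @param cutoff Distance cutoff in Angstrom (default 6).
#' @return A tibble `chain_a`, `resno_a`, `insert_a`, `chain_b`, `resno_b`,
#'   `insert_b`, `distance`, sorted by residue numbers.
#' @export
residue_contacts <- function(atoms, chain_a, chain_b, cutoff = 6) {
  stopifnot(cutoff > 0, chain_a != chain_b)
  a <- filter(atoms, .data$chain == chain_a, .data$is_heavy)
  b <- filter(atoms, .data$chain == chain_b, .data$is_heavy)
  if (nrow(a) == 0 || nrow(b) == 0) {
    abort("both chains must contain at least one heavy atom")
  }
  pa <- as.matrix(a[, c("x", "y", "z")])
  pb <- as.matrix(b[, c("x", "y", "z")])
  # squared pairwise distances, atoms of A in rows
  d2 <- outer(rowSums(pa^2), rowSums(pb^2), "+") - 2 * tcrossprod(pa, pb)
  d2[d2 < 0] <- 0
  hit <- which(d2 <= cutoff^2, arr.ind = TRUE)
  if (nrow(hit) == 0) {
    return(tibble(
      chain_a = character(), resno_a = integer(), insert_a = character(),
      chain_b = character(), resno_b = integer(), insert_b = character(),
      distance = numeric()
    ))
  }
  tibble(
    chain_a = chain_a,
    resno_a = a$resno[hit[, 1]],
    insert_a = a$insert[hit[, 1]],
    chain_b = chain_b,
    resno_b = b$resno[hit[, 2]],
    insert_b = b$insert[hit[, 2]],
    distance = sqrt(d2[hit])
  ) |>
    group_by(.data$chain_a, .data$resno_a, .data$insert_a,
             .data$chain_b, .data$resno_b, .data$insert_b) |>
    summarise(distance = min(.data$distance), .groups = "drop") |>
    arrange(.data$resno_a, .data$insert_a, .data$resno_b, .data$insert_b)
}

# deterministic quasi-uniform points on the unit sphere (golden spiral)
sphere_points <- function(n) {
  k <- seq_len(n) - 0.5
  z <- 1 - 2 * k / n
  r <- sqrt(pmax(0, 1 - z^2))
  phi <- (seq_len(n) - 1) * pi * (3 - sqrt(5))
  cbind(x = r * cos(phi), y = r * sin(phi), z = z)
}

vdw_radius <- function(element) {
  r <- VDW_RADII[toupper(element)]
  r[is.na(r)] <- VDW_DEFAULT
  unname(r)
}

#' Shrake-Rupley solvent-accessible surface area
#'
#' Numeric SASA by rolling a probe sphere over each heavy atom, testing a
#' deterministic quasi-uniform point set against neighbouring atom spheres.
#' Hydrogens are ignored.
#'
#' @param atoms Atom table from [read_structure()] (any subset of chains).
#' @param probe_radius Probe radius in Angstrom (water, default 1.4).
#' @param n_points Sphere test points per atom (default 960).
#' @return A tibble `chain`, `resno`, `insert`, `sasa` (Angstrom squared),
#'   one row per residue present in `atoms`.
#' @export
sasa <- function(atoms, probe_radius = 1.4, n_points = 960) {
  stopifnot(probe_radius > 0, n_points >= 100)
  at <- filter(atoms, .data$is_heavy)
  if (nrow(at) == 0) abort("no heavy atoms for SASA computation")
  pts <- sphere_points(n_points)
  xyz <- as.matrix(at[, c("x", "y", "z")])
  rad <- vdw_radius(at$element) + probe_radius
  n <- nrow(at)
  area <- numeric(n)
  # neighbour prefilter via squared distances
  d2 <- outer(rowSums(xyz^2), rowSums(xyz^2), "+") - 2 * tcrossprod(xyz)
  for (i in seq_len(n)) {
    nb <- which(d2[i, ] < (rad[i] + rad)^2 & seq_len(n) != i)
    p <- pts * rad[i]
    p <- sweep(p, 2, xyz[i, ], "+")
    acc <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(acc)) break
      dj2 <- (p[, 1] - xyz[j, 1])^2 + (p[, 2] - xyz[j, 2])^2 +
        (p[, 3] - xyz[j, 3])^2
      acc <- acc & dj2 > rad[j]^2
    }
    area[i] <- 4 * pi * rad[i]^2 * sum(acc) / n_points
  }
  tibble(
    chain = at$chain, resno = at$resno, insert = at$insert, sasa = area
  ) |>
    group_by(.data$chain, .data$resno, .data$insert) |>
    summarise(sasa = sum(.data$sasa), .groups = "drop")
}

#' Interface residues of a chain pair by solvent-accessibility loss
#'
#' A residue is on the interface when its SASA computed in the isolated
#' chain strictly exceeds its SASA in the two-chain complex (delta-SASA
#' greater than zero). The buried interface area
#' `(SASA_A + SASA_B - SASA_AB) / 2` is attached as attribute
#' `interface_area`.
#'
#' @inheritParams residue_contacts
#' @inheritParams sasa
#' @return A tibble `chain`, `resno`, `insert`, `sasa_isolated`,
#'   `sasa_complex`, `delta_sasa` restricted to residues with positive
#'   delta-SASA, with attribute `interface_area` (Angstrom squared).
#' @export
interface_residues <- function(atoms, chain_a, chain_b,
                               probe_radius = 1.4, n_points = 960) {
  chains <- unique(atoms$chain)
  if (!all(c(chain_a, chain_b) %in% chains)) {
    abort("chain pair not present in structure")
  }
  a <- filter(atoms, .data$chain == chain_a)
  b <- filter(atoms, .data$chain == chain_b)
  ab <- bind_rows(a, b)
  s_a <- sasa(a, probe_radius, n_points)
  s_b <- sasa(b, probe_radius, n_points)
  s_ab <- sasa(ab, probe_radius, n_points)
  iso <- bind_rows(s_a, s_b) |> rename(sasa_isolated = "sasa")
  cpx <- rename(s_ab, sasa_complex = "sasa")
  res <- inner_join(iso, cpx, by = c("chain", "resno", "insert")) |>
    mutate(delta_sasa = .data$sasa_isolated - .data$sasa_complex)
  area <- (sum(s_a$sasa) + sum(s_b$sasa) - sum(s_ab$sasa)) / 2
  out <- filter(res, .data$delta_sasa > 0) |>
    arrange(.data$chain, .data$resno, .data$insert)
  attr(out, "interface_area") <- area
  out
}

#' Classify an interface by buried surface area
#'
#' Applies the area component of evolutionary interface classification:
#' interfaces burying more than 2200 A^2 are called biologically relevant
#' (`"bio"`), interfaces below 440 A^2 crystal-packing artifacts
#' (`"xtal"`); the band in between is `"indeterminate"` and requires an
#' external evolutionary call.
#'
#' @param area Buried interface area(s), Angstrom squared, nonnegative.
#' @param bio_threshold,xtal_threshold Classification thresholds (defaults
#'   2200 and 440).
#' @return Character vector in `{"bio", "xtal", "indeterminate"}`.
#' @export
classify_interface_area <- function(area, bio_threshold = 2200,
                                    xtal_threshold = 440) {
  if (any(is.na(area)) || any(area < 0)) {
    abort("interface area must be nonnegative")
  }
  dplyr::case_when(
    area > bio_threshold ~ "bio",
    area < xtal_threshold ~ "xtal",
    TRUE ~ "indeterminate"
  )
}

#' Read interface bio-relevance calls
#'
#' Reads externally produced interface classifications (solvation-energy or
#' evolutionary), one row per method per chain pair.
#'
#' @param file TSV with columns `structure_id`, `chain_a`, `chain_b`,
#'   `method` (`energy` or `evolution`), `bio_relevant` (0/1), and optional
#'   `area_A2`, `probability`.
#' @return A tibble with `bio_relevant` as logical.
#' @export
read_interface_calls <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE)
  stopifnot(all(c("structure_id", "chain_a", "chain_b", "method",
                  "bio_relevant") %in% names(x)))
  if (!all(x$method %in% c("energy", "evolution"))) {
    abort("interface call method must be 'energy' or 'evolution'")
  }
  if ("probability" %in% names(x) &&
      any(!is.na(x$probability) & (x$probability < 0 | x$probability > 1))) {
    abort("interface call probability must lie in [0, 1]")
  }
  mutate(x, bio_relevant = as.logical(.data$bio_relevant))
}

#' Write residue contacts as TSV
#'
#' @param contacts Output of [residue_contacts()].
#' @param file Output path.
#' @param structure_id Structure identifier written in the first column.
#' @export
write_contacts <- function(contacts, file, structure_id = "structure") {
  contacts |>
    mutate(structure_id = structure_id, .before = 1) |>
    readr::write_tsv(file)
  invisible(file)
}
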