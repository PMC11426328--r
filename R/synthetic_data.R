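# Synthetic-data generators emulating the full input stack: two-chain
# complexes with designed interfaces plus matching annotation, paired
# healthy/cancer exon counts with negative-binomial noise and planted
# gained/lost edges, and proportional-hazards survival linked to edge
# presence.

CODON_BY_AA <- local({
  gc <- Biostrings::GENETIC_CODE
  split(names(gc), unname(gc))
})

random_cds <- function(aa_seq) {
  aas <- strsplit(aa_seq, "")[[1]]
  paste(vapply(aas, function(a) {
    cod <- CODON_BY_AA[[a]]
    cod[sample.int(length(cod), 1)]
  }, character(1)), collapse = "")
}

AA1TO3 <- c(
  A = "ALA", R = "ARG", N = "ASN", D = "ASP", C = "CYS", Q = "GLN",
  E = "GLU", G = "GLY", H = "HIS", I = "ILE", L = "LEU", K = "LYS",
  M = "MET", F = "PHE", P = "PRO", S = "SER", T = "THR", W = "TRP",
  Y = "TYR", V = "VAL"
)

#' Write an atom table as a minimal mmCIF file
#'
#' Emits an `_atom_site` loop readable by [read_structure()].
#'
#' @param atoms Atom tibble (`chain`, `resno`, `resid`, `atom`, `element`,
#'   `x`, `y`, `z`).
#' @param file Output path.
#' @param structure_id Data block name.
#' @export
write_mmcif <- function(atoms, file, structure_id = "SYNTH") {
  hdr <- c(
    paste0("data_", structure_id), "#", "loop_",
    "_atom_site.group_PDB", "_atom_site.id", "_atom_site.type_symbol",
    "_atom_site.label_atom_id", "_atom_site.label_alt_id",
    "_atom_site.label_comp_id", "_atom_site.label_asym_id",
    "_atom_site.label_entity_id", "_atom_site.label_seq_id",
    "_atom_site.pdbx_PDB_ins_code", "_atom_site.Cartn_x",
    "_atom_site.Cartn_y", "_atom_site.Cartn_z", "_atom_site.occupancy",
    "_atom_site.B_iso_or_equiv", "_atom_site.pdbx_formal_charge",
    "_atom_site.auth_seq_id", "_atom_site.auth_comp_id",
    "_atom_site.auth_asym_id", "_atom_site.auth_atom_id",
    "_atom_site.pdbx_PDB_model_num"
  )
  ent <- as.integer(factor(atoms$chain, levels = unique(atoms$chain)))
  rows <- sprintf(
    "ATOM %d %s %s . %s %s %d %d ? %.3f %.3f %.3f 1.00 0.00 ? %d %s %s %s 1",
    seq_len(nrow(atoms)), atoms$element, atoms$atom, atoms$resid,
    atoms$chain, ent, atoms$resno, atoms$x, atoms$y, atoms$z,
    atoms$resno, atoms$resid, atoms$chain, atoms$atom
  )
  writeLines(c(hdr, rows, "#"), file)
  invisible(file)
}

gtf_row <- function(seqname, feature, start, end, strand, attrs) {
  paste(seqname, "synthetic", feature, start, end, ".", strand, ".",
        attrs, sep = "\t")
}

# split 1..n into k contiguous segments with random interior cut points
# (cuts may fall inside codons, exercising the boundary-codon rule)
random_segments <- function(n, k) {
  if (k == 1) return(tibble(start = 1L, end = as.integer(n)))
  cuts <- sort(sample(seq_len(n - 1), k - 1))
  tibble(start = as.integer(c(1, cuts + 1)), end = as.integer(c(cuts, n)))
}

#' Generate a two-chain complex with a designed interface
#'
#' Builds a C-alpha-trace heterodimer in which exactly the requested
#' residue pairs lie within 6 Angstrom heavy-atom distance (the designed
#' contacts sit at 5 A) while every other inter-chain atom pair exceeds
#' 7 A (guard band against floating-point boundary effects). Alongside
#' the structure it writes the matching transcript annotation (GTF over a
#' synthetic genome), protein FASTA, an identity residue crosswalk, and
#' interface bio-relevance calls for the energy and evolution methods, so
#' the complete mapping pipeline can run on the output.
#'
#' @param dir Output directory (created if needed).
#' @param interface_pairs Tibble with `res_a`, `res_b`: residue numbers in
#'   chains A and B to place in contact.
#' @param chain_lengths Integer vector of length 2: residues per chain.
#' @param exons_per_chain Integer vector of length 2: exons per gene; exon
#'   boundaries are drawn at random nucleotide positions, so codons may
#'   straddle exons.
#' @param strands Character vector of length 2 (`"+"` or `"-"`): genomic
#'   strand of each gene.
#' @param structure_id Identifier used in file and record names.
#' @param seed Random seed.
#' @return A list with the file `paths` (structure, gtf, genome_fasta,
#'   protein_fasta, crosswalk, interface_calls) and the ground `truth`
#'   (protein sequences, exon maps, designed contact pairs).
#' @export
synthetic_complex <- function(dir, interface_pairs,
                              chain_lengths = c(30, 30),
                              exons_per_chain = c(3, 3),
                              strands = c("+", "+"),
                              structure_id = "SYN1", seed = 1) {
  stopifnot(length(chain_lengths) == 2, length(exons_per_chain) == 2,
            all(strands %in% c("+", "-")))
  if (nrow(interface_pairs) > 0) {
    stopifnot(all(interface_pairs$res_a >= 1),
              all(interface_pairs$res_a <= chain_lengths[1]),
              all(interface_pairs$res_b >= 1),
              all(interface_pairs$res_b <= chain_lengths[2]),
              !anyDuplicated(interface_pairs$res_b))
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(seed)

  chains <- c("A", "B")
  genes <- paste0("G", chains)
  prots <- paste0("P", chains)
  aa_seqs <- vapply(chain_lengths, function(L) {
    paste(sample(names(AA1TO3), L, replace = TRUE), collapse = "")
  }, character(1))

  # geometry: chain A along x at 8 A spacing; chain B parallel at y = 40,
  # except designed interface residues of B, dropped to y = 5 above their
  # chain-A partner (5 A contact; nearest off-target pair is
  # sqrt(8^2 + 5^2) ~ 9.4 A, beyond the 7 A guard band)
  pos_a <- cbind(8 * seq_len(chain_lengths[1]), 0, 0)
  pos_b <- cbind(8 * seq_len(chain_lengths[2]), 40, 0)
  if (nrow(interface_pairs) > 0) {
    pos_b[interface_pairs$res_b, 1] <- 8 * interface_pairs$res_a
    pos_b[interface_pairs$res_b, 2] <- 5
  }
  res3 <- function(seq) AA1TO3[strsplit(seq, "")[[1]]]
  atoms <- bind_rows(
    tibble(chain = "A", resno = seq_len(chain_lengths[1]),
           resid = res3(aa_seqs[1]), atom = "CA", element = "C",
           x = pos_a[, 1], y = pos_a[, 2], z = pos_a[, 3]),
    tibble(chain = "B", resno = seq_len(chain_lengths[2]),
           resid = res3(aa_seqs[2]), atom = "CA", element = "C",
           x = pos_b[, 1], y = pos_b[, 2], z = pos_b[, 3])
  )
  # validate the designed geometry against a direct distance scan
  da <- atoms[atoms$chain == "A", c("x", "y", "z")]
  db <- atoms[atoms$chain == "B", c("x", "y", "z")]
  dmat <- sqrt(outer(rowSums(da^2), rowSums(db^2), "+") -
                 2 * tcrossprod(as.matrix(da), as.matrix(db)))
  want <- matrix(FALSE, nrow(da), nrow(db))
  if (nrow(interface_pairs) > 0) {
    want[cbind(interface_pairs$res_a, interface_pairs$res_b)] <- TRUE
  }
  if (any(dmat[want] > 6) || any(dmat[!want] <= 7)) {
    abort("unrealizable interface geometry")
  }

  paths <- list(
    structure = file.path(dir, paste0(structure_id, ".cif")),
    gtf = file.path(dir, "annotation.gtf"),
    genome_fasta = file.path(dir, "genome.fa"),
    protein_fasta = file.path(dir, "proteins.fa"),
    crosswalk = file.path(dir, "crosswalk.tsv"),
    interface_calls = file.path(dir, "interface_calls.tsv")
  )
  write_mmcif(atoms, paths$structure, structure_id)

  # genome + annotation: each gene on its own synthetic contig, CDS only
  # (no UTRs, Ensembl-style CDS without the stop codon)
  gtf_lines <- character()
  genome <- character()
  exon_maps <- list()
  for (i in 1:2) {
    cds <- random_cds(aa_seqs[i])
    n_nt <- nchar(cds)
    segs <- random_segments(n_nt, exons_per_chain[i])
    segs$exon_id <- sprintf("%s.e%d", genes[i], seq_len(nrow(segs)))
    offset <- 100L
    contig <- paste0("chr", chains[i])
    pad <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                    replace = TRUE), collapse = "")
    if (strands[i] == "+") {
      genome[contig] <- paste0(pad(offset), cds, pad(50))
      g_start <- offset + segs$start
      g_end <- offset + segs$end
    } else {
      genome[contig] <- paste0(
        pad(offset),
        as.character(Biostrings::reverseComplement(
          Biostrings::DNAString(cds))),
        pad(50)
      )
      g_start <- offset + n_nt - segs$end + 1
      g_end <- offset + n_nt - segs$start + 1
    }
    tid <- paste0("T", genes[i])
    attr0 <- sprintf('gene_id "%s"; transcript_id "%s";', genes[i], tid)
    gtf_lines <- c(
      gtf_lines,
      gtf_row(contig, "gene", min(g_start), max(g_end), strands[i],
              sprintf('gene_id "%s";', genes[i])),
      gtf_row(contig, "transcript", min(g_start), max(g_end), strands[i],
              attr0),
      unlist(purrr::map(seq_len(nrow(segs)), function(k) {
        at <- sprintf('%s exon_id "%s";', attr0, segs$exon_id[k])
        c(gtf_row(contig, "exon", g_start[k], g_end[k], strands[i], at),
          gtf_row(contig, "CDS", g_start[k], g_end[k], strands[i], at))
      }))
    )
    # ground-truth exon map by the middle-base rule
    nt_exon <- rep(segs$exon_id, segs$end - segs$start + 1)
    mid_exon <- nt_exon[3 * seq_len(nchar(aa_seqs[i])) - 1]
    exon_maps[[chains[i]]] <- tibble(residue = seq_along(mid_exon),
                                     exon_id = mid_exon)
  }
  writeLines(unlist(purrr::map(names(genome), function(s) {
    c(paste0(">", s), genome[[s]])
  })), paths$genome_fasta)
  writeLines(gtf_lines, paths$gtf)
  writeLines(unlist(purrr::map(1:2, function(i) {
    c(paste0(">", prots[i]), aa_seqs[i])
  })), paths$protein_fasta)

  bind_rows(purrr::map(1:2, function(i) {
    tibble(structure_id = structure_id, chain = chains[i],
           resno = seq_len(chain_lengths[i]), insert = "",
           protein_accession = prots[i],
           protein_position = seq_len(chain_lengths[i]))
  })) |>
    readr::write_tsv(paths$crosswalk)

  n_iface <- max(1, nrow(interface_pairs))
  tibble(
    structure_id = structure_id, chain_a = "A", chain_b = "B",
    method = c("energy", "evolution"),
    bio_relevant = as.integer(nrow(interface_pairs) > 0),
    area_A2 = round(n_iface * 55.0, 1),
    probability = c(0.1, NA)
  ) |>
    readr::write_tsv(paths$interface_calls)

  list(
    paths = paths,
    truth = list(
      structure_id = structure_id, chains = chains, genes = genes,
      proteins = prots, sequences = aa_seqs,
      interface_pairs = interface_pairs, exon_maps = exon_maps
    )
  )
}

#' Generate a paired healthy/cancer exon count cohort with planted edges
#'
#' Counts follow a negative-binomial model with per-exon baseline means
#' (log-normal across exons) scaled by per-sample log-normal library
#' factors. Planted edges override their endpoint exons: a `gained` edge
#' has both endpoints silent (zero mean) in every healthy sample and
#' active at the baseline mean in the cancer samples of its perturbed
#' patients; `lost` is the mirror image. A `prognostic` edge follows the
#' gained pattern but is activated in the cancer samples of a `frac`
#' fraction of all patients (paired or not), so a survival scan can split
#' the full cohort on its presence.
#'
#' @param network Global edge tibble; planted edges must be edges of it.
#' @param planted Tibble with `exon_a`, `exon_b`,
#'   `effect` (`gained` / `lost` / `prognostic`), `frac` (fraction of
#'   eligible patients perturbed / carrying the edge).
#' @param n_bg_genes,exons_per_bg_gene Background genes outside the
#'   network and exons per such gene (defaults 50 and 4). Background
#'   exons give every sample a realistic library and anchor the TMM
#'   reference.
#' @param n_patients Cohort size (default 200, a mid-size tumor cohort).
#' @param paired_fraction Fraction of patients with a matched healthy
#'   sample (default 0.2; paired subsets are the minority in tumor
#'   cohorts).
#' @param baseline_meanlog,baseline_sdlog Log-normal parameters of
#'   per-exon baseline means (defaults `log(5000)` and 1, giving library
#'   sizes near one million reads over a ~100-exon panel so CPM
#'   thresholds sit in their intended range).
#' @param dispersion Negative-binomial dispersion (default 0.3, typical
#'   RNA-seq biological variability).
#' @param libsize_sdlog Spread of the per-sample library factor (default
#'   0.3).
#' @param seed Random seed.
#' @return A list: `counts` (tibble), `sample_sheet` (tibble), `truth`
#'   (per planted edge, the perturbed patients and the patients carrying
#'   the edge in the cancer sample), and `lib_factors` (planted
#'   per-sample factors).
#' @export
synthetic_expression <- function(network, planted = NULL,
                                 n_bg_genes = 50, exons_per_bg_gene = 4,
                                 n_patients = 200, paired_fraction = 0.2,
                                 baseline_meanlog = log(5000),
                                 baseline_sdlog = 1, dispersion = 0.3,
                                 libsize_sdlog = 0.3, seed = 1) {
  set.seed(seed)
  bg_exons <- if (n_bg_genes > 0) {
    as.vector(outer(seq_len(exons_per_bg_gene),
                    sprintf("bgG%03d", seq_len(n_bg_genes)),
                    function(e, g) paste0(g, ".e", e)))
  } else {
    character()
  }
  exons <- sort(unique(c(network$exon_a, network$exon_b, bg_exons)))
  patients <- sprintf("p%03d", seq_len(n_patients))
  n_paired <- max(1, round(paired_fraction * n_patients))
  paired <- patients[seq_len(n_paired)]

  sample_sheet <- bind_rows(
    tibble(sample_id = paste0(paired, "_H"), patient_id = paired,
           tissue = "healthy"),
    tibble(sample_id = paste0(patients, "_C"), patient_id = patients,
           tissue = "cancer")
  )

  mu_exon <- setNames(rlnorm(length(exons), baseline_meanlog,
                             baseline_sdlog), exons)
  lib_factor <- setNames(rlnorm(nrow(sample_sheet), 0, libsize_sdlog),
                         sample_sheet$sample_id)

  # per-exon, per-sample target means; planted edges override endpoints
  mu <- matrix(mu_exon, nrow = length(exons),
               ncol = nrow(sample_sheet),
               dimnames = list(exons, sample_sheet$sample_id))
  truth <- NULL
  if (!is.null(planted) && nrow(planted) > 0) {
    keys <- edge_key(network$exon_a, network$exon_b)
    pk <- edge_key(planted$exon_a, planted$exon_b)
    if (!all(pk %in% keys)) {
      abort("planted edges must exist in the global network")
    }
    if (anyDuplicated(c(planted$exon_a, planted$exon_b)) > 0) {
      abort("planted edges must not share endpoint exons")
    }
    h_cols <- sample_sheet$sample_id[sample_sheet$tissue == "healthy"]
    truth <- purrr::map(seq_len(nrow(planted)), function(i) {
      ex <- c(planted$exon_a[i], planted$exon_b[i])
      eff <- planted$effect[i]
      frac <- planted$frac[i]
      if (eff %in% c("gained", "prognostic")) {
        pool <- if (eff == "gained") paired else patients
        hit <- sort(sample(pool, max(1, round(frac * length(pool)))))
        mu[ex, h_cols] <<- 0
        mu[ex, paste0(patients, "_C")] <<- 0
        mu[ex, paste0(hit, "_C")] <<- mu_exon[ex]
      } else if (eff == "lost") {
        hit <- sort(sample(paired, max(1, round(frac * length(paired)))))
        mu[ex, paste0(hit, "_C")] <<- 0
      } else {
        abort(paste0("unknown planted effect: ", eff))
      }
      tibble(edge = pk[i], effect = eff,
             perturbed_patients = list(intersect(hit, paired)),
             present_cancer = list(
               if (eff == "lost") setdiff(patients, hit) else hit))
    }) |> bind_rows()
  }

  mu <- sweep(mu, 2, lib_factor, "*")
  cnt <- matrix(rnbinom(length(mu), mu = mu, size = 1 / dispersion),
                nrow = nrow(mu), dimnames = dimnames(mu))
  counts <- bind_cols(tibble(exon_id = exons), as_tibble(cnt))
  list(counts = counts, sample_sheet = sample_sheet, truth = truth,
       lib_factors = lib_factor)
}

#' Generate exponential survival linked to edge presence
#'
#' Event times are exponential with hazard
#' `baseline_hazard * hazard_ratio^present`; censoring times are uniform
#' on `(0, b)` with `b` calibrated so the expected censoring fraction of
#' the cohort matches the target.
#'
#' @param present Named logical vector: edge presence per patient id.
#' @param baseline_hazard Baseline event rate per day (default 1/1500).
#' @param hazard_ratio Multiplicative hazard of carriers (default 3).
#' @param censoring_fraction Target fraction censored (default 0.3; use 0
#'   for fully observed cohorts).
#' @param seed Random seed.
#' @return A clinical tibble `patient_id`, `time`, `event`.
#' @export
synthetic_survival <- function(present, baseline_hazard = 1 / 1500,
                               hazard_ratio = 3, censoring_fraction = 0.3,
                               seed = 1) {
  stopifnot(baseline_hazard > 0, hazard_ratio > 0,
            censoring_fraction >= 0, censoring_fraction < 1)
  set.seed(seed)
  rate <- baseline_hazard * hazard_ratio^as.numeric(present)
  t_event <- rexp(length(present), rate)
  if (censoring_fraction > 0) {
    # E[censored | C ~ U(0,b)] for rate r is (1 - exp(-r b)) / (r b),
    # averaged over the cohort's rates; solve for b
    cens_frac <- function(b) {
      mean((1 - exp(-rate * b)) / (rate * b)) - censoring_fraction
    }
    b <- stats::uniroot(cens_frac, lower = 1e-6, upper = 1e9,
                        tol = 1e-9)$root
    t_cens <- runif(length(present), 0, b)
  } else {
    t_cens <- rep(Inf, length(present))
  }
  tibble(
    patient_id = names(present),
    time = pmin(t_event, t_cens),
    event = as.integer(t_event <= t_cens)
  )
}

#' Generate a complete synthetic study on disk
#'
#' Chains the three generators into a full input bundle: a designed
#' two-chain complex (with annotation, crosswalk and interface calls), a
#' paired expression cohort with planted edges over the exon pairs the
#' interface realizes, and a survival table tied to the prognostic
#' plant. All files use the exact dialects the pipeline readers expect.
#'
#' @param dir Output directory.
#' @param seed Random seed (stages use fixed offsets of it).
#' @param n_patients,paired_fraction,censoring_fraction,hazard_ratio
#'   Cohort parameters (see [synthetic_expression()] and
#'   [synthetic_survival()]).
#' @param prognostic_frac Fraction of patients carrying the prognostic
#'   edge (default 0.5).
#' @param null_cohort If `TRUE`, survival is generated with hazard ratio
#'   1 (no survival-edge association) while everything else is kept.
#' @return A manifest list of file paths plus the generator `truth`.
#' @export
synthetic_study <- function(dir, seed = 1, n_patients = 200,
                            paired_fraction = 0.2,
                            censoring_fraction = 0.3, hazard_ratio = 3,
                            prognostic_frac = 0.5, null_cohort = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  # interface spanning three exon pairs: residues chosen inside distinct
  # exons of 30-residue chains
  cx <- synthetic_complex(
    dir,
    interface_pairs = tibble(res_a = c(3, 15, 27), res_b = c(4, 16, 26)),
    chain_lengths = c(30, 30), exons_per_chain = c(3, 3),
    strands = c("+", "-"), seed = seed
  )
  # derive the edges those contacts induce, using the generator's own
  # ground-truth exon maps
  map_a <- cx$truth$exon_maps$A
  map_b <- cx$truth$exon_maps$B
  edges <- tibble(
    exon_a = map_a$exon_id[cx$truth$interface_pairs$res_a],
    exon_b = map_b$exon_id[cx$truth$interface_pairs$res_b],
    gene_a = "GA", gene_b = "GB", method = "contact"
  )
  network <- build_global_networks(edges)

  # plant on exon-disjoint edges only: overlapping endpoints would let a
  # later plant overwrite the expression pattern of an earlier one
  free <- rep(TRUE, nrow(network))
  take_disjoint <- function() {
    i <- which(free)[1]
    if (is.na(i)) return(NULL)
    used <- c(network$exon_a[i], network$exon_b[i])
    free <<- free & !(network$exon_a %in% used |
                        network$exon_b %in% used)
    network[i, ]
  }
  e1 <- take_disjoint()
  e2 <- take_disjoint()
  e3 <- take_disjoint()
  planted <- bind_rows(
    tibble(exon_a = e1$exon_a, exon_b = e1$exon_b,
           effect = "prognostic", frac = prognostic_frac),
    if (!is.null(e2)) tibble(exon_a = e2$exon_a, exon_b = e2$exon_b,
                             effect = "gained", frac = 0.5),
    if (!is.null(e3)) tibble(exon_a = e3$exon_a, exon_b = e3$exon_b,
                             effect = "lost", frac = 0.5)
  )
  ex <- synthetic_expression(network, planted, n_patients = n_patients,
                             paired_fraction = paired_fraction,
                             seed = seed + 1)
  patients <- unique(ex$sample_sheet$patient_id)
  carriers <- ex$truth$present_cancer[[1]]
  present <- setNames(patients %in% carriers, patients)
  clinical <- synthetic_survival(
    present,
    hazard_ratio = if (null_cohort) 1 else hazard_ratio,
    censoring_fraction = censoring_fraction, seed = seed + 2
  )

  paths <- cx$paths
  paths$counts <- file.path(dir, "counts.tsv")
  paths$sample_sheet <- file.path(dir, "samples.tsv")
  paths$clinical <- file.path(dir, "clinical.tsv")
  readr::write_tsv(ex$counts, paths$counts)
  readr::write_tsv(ex$sample_sheet, paths$sample_sheet)
  clinical |>
    dplyr::transmute(patient_id = .data$patient_id,
                     time_days = .data$time, event = .data$event) |>
    readr::write_tsv(paths$clinical)

  list(paths = paths,
       truth = c(cx$truth,
                 list(network = network, planted = planted,
                      expression = ex$truth,
                      lib_factors = ex$lib_factors,
                      prognostic_present = present)))
}
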