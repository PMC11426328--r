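# End-to-end orchestration: structures -> exon mapping -> global EEINs ->
# expression calls -> perturbation -> survival scan -> biomarkers ->
# enrichment, with deterministic TSV outputs.

#' Pipeline configuration
#'
#' Collects every tunable of the analysis with its default operating
#' point: 6 A contact cutoff (5 A robustness variant via
#' `contact_cutoff`), minimum 1 supporting contact (5 as the strict
#' variant), CPM threshold 0.5 (sweep 0.05-2), the HIGH confidence tier,
#' survival alpha 0.05 (0.01 variant), minimum group size 10, 100
#' permutations per randomization scheme, biomarker p cutoff 0.05,
#' enrichment q cutoff 0.05 and gene |Z| cutoff 1.96.
#'
#' @param contact_cutoff Heavy-atom contact cutoff, Angstrom.
#' @param min_contacts Minimum residue contacts per edge.
#' @param cpm_threshold Expression threshold (CPM).
#' @param tier Network tier: `"HIGH"`, `"MEDIUM"` or `"LOW"`.
#' @param alpha Logrank significance cutoff for the CRPE scan.
#' @param min_group Minimum patients per survival group.
#' @param n_rand Permutations per biomarker randomization scheme.
#' @param biomarker_alpha Real-p cutoff of the biomarker test.
#' @param q_cutoff Enrichment significance cutoff.
#' @param z_cutoff Absolute Cox Z cutoff for external gene lists.
#' @param sasa_points Sphere points of the SASA computation.
#' @param base_seed Base seed of all randomized stages.
#' @param scan_all Scan all evaluable edges instead of the cohort's
#'   perturbed edges only.
#' @return A named list of class `eein_config`.
#' @export
pipeline_config <- function(contact_cutoff = 6, min_contacts = 1,
                            cpm_threshold = 0.5, tier = "HIGH",
                            alpha = 0.05, min_group = 10, n_rand = 100,
                            biomarker_alpha = 0.05, q_cutoff = 0.05,
                            z_cutoff = 1.96, sasa_points = 960,
                            base_seed = 1, scan_all = FALSE) {
  cfg <- list(
    contact_cutoff = contact_cutoff, min_contacts = min_contacts,
    cpm_threshold = cpm_threshold, tier = tier, alpha = alpha,
    min_group = min_group, n_rand = n_rand,
    biomarker_alpha = biomarker_alpha, q_cutoff = q_cutoff,
    z_cutoff = z_cutoff, sasa_points = sasa_points,
    base_seed = base_seed, scan_all = scan_all
  )
  stopifnot(cfg$contact_cutoff > 0, cfg$min_contacts >= 1,
            cfg$cpm_threshold > 0, cfg$tier %in% c("HIGH", "MEDIUM", "LOW"),
            cfg$alpha > 0, cfg$alpha < 1, cfg$min_group >= 0)
  class(cfg) <- c("eein_config", "list")
  cfg
}

load_study <- function(manifest) {
  need <- c("structure", "gtf", "genome_fasta", "protein_fasta",
            "crosswalk", "counts", "sample_sheet", "clinical")
  missing <- setdiff(need, names(manifest))
  if (length(missing) > 0) {
    abort(paste0("manifest lacks: ", paste(missing, collapse = ", ")))
  }
  for (f in unlist(manifest[need])) {
    if (!file.exists(f)) abort(paste0("manifest path not found: ", f))
  }
  list(
    structures = purrr::map(manifest$structure, read_structure),
    transcripts = read_transcripts(manifest$gtf, manifest$genome_fasta),
    proteins = read_protein_fasta(manifest$protein_fasta),
    crosswalk = read_crosswalk(manifest$crosswalk),
    interface_calls = if (!is.null(manifest$interface_calls)) {
      read_interface_calls(manifest$interface_calls)
    },
    counts = read_counts(manifest$counts),
    sample_sheet = read_sample_sheet(manifest$sample_sheet),
    clinical = read_clinical(manifest$clinical),
    annotation = if (!is.null(manifest$annotation)) {
      read_pathway_annotation(manifest$annotation)
    }
  )
}

# exon labels of every crosswalked residue of each chain of a structure
label_chains <- function(atoms, study) {
  sid <- atoms$structure_id[1]
  cw <- filter(study$crosswalk, .data$structure_id == sid)
  chains <- intersect(unique(atoms$chain), unique(cw$chain))
  purrr::map(setNames(chains, chains), function(ch) {
    acc <- cw$protein_accession[cw$chain == ch][1]
    prot <- study$proteins$sequence[study$proteins$protein_accession == acc]
    if (length(prot) == 0) return(NULL)
    tid <- select_matching_transcript(study$transcripts, prot)
    if (is.na(tid)) return(NULL)
    tr <- study$transcripts[study$transcripts$transcript_id == tid, ]
    emap <- map_exons_to_residues(tr)
    labels <- label_structure_residues(emap, study$crosswalk, sid, ch)
    labels$gene_id <- tr$gene_id
    labels$protein_accession <- acc
    labels
  })
}

build_network_stage <- function(study, config) {
  edge_lists <- list()
  all_contacts <- list()
  iface_exons <- list()
  for (atoms in study$structures) {
    sid <- atoms$structure_id[1]
    labels <- label_chains(atoms, study)
    labels <- labels[!vapply(labels, is.null, logical(1))]
    chains <- names(labels)
    if (length(chains) < 2) next
    pairs <- utils::combn(sort(chains), 2, simplify = FALSE)
    for (pr in pairs) {
      ca <- pr[1]; cb <- pr[2]
      con <- residue_contacts(atoms, ca, cb, config$contact_cutoff)
      la <- labels[[ca]]; lb <- labels[[cb]]
      lab_con <- con |>
        left_join(select(la, "resno", "insert", exon_a = "exon_id",
                         gene_a = "gene_id"),
                  by = c(resno_a = "resno", insert_a = "insert")) |>
        left_join(select(lb, "resno", "insert", exon_b = "exon_id",
                         gene_b = "gene_id"),
                  by = c(resno_b = "resno", insert_b = "insert"))
      all_contacts[[paste(sid, ca, cb)]] <- mutate(
        lab_con, structure_id = sid, .before = 1)
      edge_lists[[paste(sid, ca, cb, "contact")]] <-
        contact_eeis(lab_con, config$min_contacts)
      # interface exons for the externally classified interface methods
      if (!is.null(study$interface_calls)) {
        calls <- filter(study$interface_calls,
                        .data$structure_id == sid,
                        .data$chain_a == ca, .data$chain_b == cb)
        if (nrow(calls) > 0) {
          ir <- interface_residues(atoms, ca, cb,
                                   n_points = config$sasa_points)
          ex_of <- function(lab) {
            ir |>
              inner_join(lab, by = c("chain", "resno", "insert")) |>
              distinct(.data$exon_id, .data$gene_id)
          }
          ia <- ex_of(la); ib <- ex_of(lb)
          iface_exons[[paste(sid, ca, cb)]] <-
            list(chain_a = ia, chain_b = ib,
                 area = attr(ir, "interface_area"))
          for (k in seq_len(nrow(calls))) {
            edge_lists[[paste(sid, ca, cb, calls$method[k])]] <-
              interface_eeis(calls[k, ], ia, ib)
          }
        }
      }
    }
  }
  network <- do.call(build_global_networks, unname(edge_lists))
  list(network = network, contacts = bind_rows(all_contacts),
       interface_exons = iface_exons)
}

expression_stage <- function(counts, sample_sheet, threshold) {
  sheet <- dedupe_samples(sample_sheet, counts)
  keep <- c("exon_id", sheet$sample_id)
  counts <- counts[, intersect(names(counts), keep)]
  norm <- tmm_factors(counts)
  calls <- expressed_exons(cpm(counts, norm), threshold)
  list(sheet = sheet, norm = norm, calls = calls)
}

#' Run the full analysis pipeline
#'
#' Executes every stage on one cohort (one cancer type per invocation)
#' and writes each stage's table under `out_dir`. Reruns with the same
#' manifest and configuration produce byte-identical TSV outputs.
#'
#' @param manifest Named list of input paths: `structure` (one or more
#'   structure files), `gtf`, `genome_fasta`, `protein_fasta`,
#'   `crosswalk`, optional `interface_calls`, `counts`, `sample_sheet`,
#'   `clinical`, optional `annotation` (exon-to-pathway TSV).
#' @param config A [pipeline_config()].
#' @param out_dir Output directory for stage TSVs (created; `NULL`
#'   skips writing).
#' @return A list with `network`, `tier_network`, `tier_sizes`,
#'   `categories`, `scan`, `biomarkers`, `enrichment` (or `NULL`) and a
#'   one-row `summary` tibble.
#' @export
run_pipeline <- function(manifest, config = pipeline_config(),
                         out_dir = NULL) {
  study <- load_study(manifest)
  net <- build_network_stage(study, config)
  tier_net <- eein_tier(net$network, config$tier)

  expr <- expression_stage(study$counts, study$sample_sheet,
                           config$cpm_threshold)
  statuses <- edge_status(tier_net, expr$calls, expr$sheet)
  cats <- cohort_category(statuses)
  pert <- perturbed_edges(cats)

  cancer <- filter(expr$sheet, .data$tissue == "cancer")
  pres <- edge_presence(tier_net, expr$calls, cancer$sample_id)
  colnames(pres) <- cancer$patient_id[match(colnames(pres),
                                            cancer$sample_id)]
  scan_edges <- if (config$scan_all) NULL else pert$edge
  scan <- crpe_scan(pres, study$clinical, alpha = config$alpha,
                    min_group = config$min_group, edges = scan_edges)
  bios <- biomarker_scan(scan, pres, study$clinical,
                         n_rand = config$n_rand,
                         seed = config$base_seed,
                         alpha = config$biomarker_alpha)

  enr <- NULL
  if (!is.null(study$annotation) && any(scan$is_crpe)) {
    crpe_exons <- unique(unlist(strsplit(scan$edge[scan$is_crpe],
                                         "|", fixed = TRUE)))
    bg <- unique(c(tier_net$exon_a, tier_net$exon_b))
    enr <- enrich_pathways(intersect(crpe_exons, bg), bg,
                           study$annotation, config$q_cutoff)
  }

  sizes <- tier_sizes(net$network)
  summary <- tibble(
    n_edges_global = nrow(net$network),
    n_edges_tier = nrow(tier_net),
    n_paired_patients = length(unique(statuses$patient_id)),
    n_perturbed = nrow(pert),
    n_tested = sum(scan$tested),
    n_crpe = sum(scan$is_crpe),
    n_biomarker = if (nrow(bios) > 0) sum(bios$is_biomarker) else 0L
  )

  out <- list(network = net$network, tier_network = tier_net,
              tier_sizes = sizes, normalization = expr$norm,
              categories = cats, scan = scan, biomarkers = bios,
              enrichment = enr, summary = summary, config = config)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    w <- function(x, f) if (!is.null(x) && nrow(x) > 0)
      readr::write_tsv(x, file.path(out_dir, f))
    w(net$network, "network_global.tsv")
    w(sizes, "tier_sizes.tsv")
    w(expr$norm, "normalization.tsv")
    w(cats, "edge_categories.tsv")
    w(scan, "survival_scan.tsv")
    if (nrow(bios) > 0) {
      w(select(bios, -"p_rand_presence", -"p_rand_survival"),
        "biomarkers.tsv")
    }
    w(enr, "enrichment.tsv")
    w(summary, "summary.tsv")
    cfg <- tibble(key = names(unclass(config)),
                  value = vapply(unclass(config), as.character,
                                 character(1)))
    readr::write_tsv(cfg, file.path(out_dir, "config.tsv"))
  }
  out
}

#' Sweep the CPM expression threshold
#'
#' Recomputes expression calls, per-sample induced edge counts,
#' perturbed edges and the CRPE scan at each threshold. Per-sample edge
#' counts are non-increasing in the threshold; the perturbed and CRPE
#' counts need not be monotone.
#'
#' @param manifest Input manifest (see [run_pipeline()]).
#' @param config A [pipeline_config()]; its `cpm_threshold` is ignored.
#' @param thresholds CPM thresholds to evaluate (default the six
#'   canonical values 0.05, 0.1, 0.2, 0.5, 1, 2).
#' @return A tibble, one row per threshold: `threshold`,
#'   `mean_edges_healthy`, `mean_edges_cancer`, `n_perturbed`,
#'   `n_crpe`.
#' @export
threshold_sweep <- function(manifest, config = pipeline_config(),
                            thresholds = c(0.05, 0.1, 0.2, 0.5, 1, 2)) {
  stopifnot(length(thresholds) > 0)
  study <- load_study(manifest)
  net <- build_network_stage(study, config)
  tier_net <- eein_tier(net$network, config$tier)
  purrr::map(sort(thresholds), function(tau) {
    expr <- expression_stage(study$counts, study$sample_sheet, tau)
    pres_all <- edge_presence(tier_net, expr$calls,
                              expr$sheet$sample_id)
    tissue <- expr$sheet$tissue[match(colnames(pres_all),
                                      expr$sheet$sample_id)]
    statuses <- edge_status(tier_net, expr$calls, expr$sheet)
    pert <- perturbed_edges(cohort_category(statuses))
    cancer <- filter(expr$sheet, .data$tissue == "cancer")
    pres <- pres_all[, cancer$sample_id, drop = FALSE]
    colnames(pres) <- cancer$patient_id
    scan <- crpe_scan(pres, study$clinical, alpha = config$alpha,
                      min_group = config$min_group, edges = pert$edge)
    tibble(
      threshold = tau,
      mean_edges_healthy = mean(colSums(
        pres_all[, tissue == "healthy", drop = FALSE])),
      mean_edges_cancer = mean(colSums(
        pres_all[, tissue == "cancer", drop = FALSE])),
      n_perturbed = nrow(pert),
      n_crpe = sum(scan$is_crpe)
    )
  }) |> bind_rows()
}
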