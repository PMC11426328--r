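# Transcript-to-protein matching and exon -> residue coordinate mapping.
#
# Genomic coordinates are 1-based inclusive throughout (GTF convention);
# protein positions are 1-based.

parse_gtf_attr <- function(attr, key) {
  m <- stringr::str_match(attr, paste0(key, ' "([^"]*)"'))[, 2]
  m
}

#' Read transcript models from a GTF file and genome FASTA
#'
#' Parses `exon` and `CDS` features and extracts the coding sequence of each
#' transcript from the genome, reverse-complementing minus-strand
#' transcripts. Exons and CDS segments are stored in transcription order
#' (5' to 3').
#'
#' @param gtf_file GTF annotation path (gene/transcript/exon/CDS features;
#'   only exon and CDS rows are used).
#' @param genome_fasta FASTA of the genomic sequence the GTF refers to.
#' @return A tibble with one row per transcript: `gene_id`,
#'   `transcript_id`, `strand`, list-columns `exons` and `cds` (tibbles
#'   with `exon_id`, `start`, `end` in transcription order), and `cds_seq`
#'   (coding nucleotide string).
#' @export
read_transcripts <- function(gtf_file, genome_fasta) {
  gtf <- readr::read_tsv(
    gtf_file,
    comment = "#",
    col_names = c("seqname", "source", "feature", "start", "end", "score",
                  "strand", "frame", "attributes"),
    col_types = "ccciicccc",
    show_col_types = FALSE
  )
  genome <- Biostrings::readDNAStringSet(genome_fasta)
  names(genome) <- sub("\\s.*$", "", names(genome))

  feats <- gtf |>
    filter(.data$feature %in% c("exon", "CDS")) |>
    mutate(
      gene_id = parse_gtf_attr(.data$attributes, "gene_id"),
      transcript_id = parse_gtf_attr(.data$attributes, "transcript_id"),
      exon_id = parse_gtf_attr(.data$attributes, "exon_id")
    )
  if (any(is.na(feats$transcript_id))) {
    abort("GTF exon/CDS rows must carry transcript_id attributes")
  }

  one_transcript <- function(df) {
    strand <- df$strand[1]
    # transcription order: ascending genomic start on +, descending on -
    ord <- if (strand == "-") order(-df$start) else order(df$start)
    df <- df[ord, ]
    exons <- df |>
      filter(.data$feature == "exon") |>
      select("exon_id", "start", "end")
    cds <- df |>
      filter(.data$feature == "CDS") |>
      select("exon_id", "start", "end")
    seqname <- df$seqname[1]
    if (!seqname %in% names(genome)) {
      abort(paste0("GTF seqname '", seqname, "' absent from genome FASTA"))
    }
    segs <- purrr::map_chr(seq_len(nrow(cds)), function(i) {
      s <- Biostrings::subseq(genome[[seqname]], cds$start[i], cds$end[i])
      if (strand == "-") s <- Biostrings::reverseComplement(s)
      as.character(s)
    })
    tibble(
      gene_id = df$gene_id[1],
      transcript_id = df$transcript_id[1],
      strand = strand,
      exons = list(exons),
      cds = list(cds),
      cds_seq = paste(segs, collapse = "")
    )
  }

  feats |>
    dplyr::group_split(.data$transcript_id) |>
    purrr::map(one_transcript) |>
    bind_rows() |>
    arrange(.data$transcript_id)
}

#' Read protein sequences from FASTA
#'
#' @param file Amino-acid FASTA path.
#' @return A tibble `protein_accession`, `sequence`.
#' @export
read_protein_fasta <- function(file) {
  aa <- Biostrings::readAAStringSet(file)
  tibble(
    protein_accession = sub("\\s.*$", "", names(aa)),
    sequence = unname(as.character(aa))
  )
}

translate_cds <- function(cds_seq) {
  if (nchar(cds_seq) %% 3 != 0) return(NA_character_)
  aa <- as.character(suppressWarnings(Biostrings::translate(
    Biostrings::DNAString(cds_seq), if.fuzzy.codon = "X",
    no.init.codon = TRUE
  )))
  # trailing stop codon, if annotated, is not part of the protein
  sub("\\*$", "", aa)
}

#' Select the transcript whose coding sequence matches a protein exactly
#'
#' Translates each candidate transcript's CDS (terminal stop removed) and
#' keeps transcripts identical to the query protein sequence: an exact
#' match under global alignment is sequence equality, so no alignment
#' scoring is needed. Among several exact matches the lexicographically
#' smallest `transcript_id` is returned; proteins with no matching
#' transcript yield `NA` and are excluded from interface mapping
#' downstream.
#'
#' @param transcripts Tibble from [read_transcripts()].
#' @param protein_sequence Amino-acid string to match.
#' @return A single `transcript_id`, or `NA_character_` when no transcript
#'   translates to the protein. Transcripts whose CDS length is not a
#'   multiple of three are skipped with a warning.
#' @export
select_matching_transcript <- function(transcripts, protein_sequence) {
  stopifnot(nchar(protein_sequence) > 0)
  bad <- nchar(transcripts$cds_seq) %% 3 != 0
  if (any(bad)) {
    warn(paste0("skipping transcript(s) with CDS length not divisible by 3: ",
                paste(transcripts$transcript_id[bad], collapse = ", ")))
  }
  cand <- transcripts[!bad, ]
  if (nrow(cand) == 0) return(NA_character_)
  prot <- purrr::map_chr(cand$cds_seq, translate_cds)
  hits <- cand$transcript_id[!is.na(prot) & prot == protein_sequence]
  if (length(hits) == 0) return(NA_character_)
  sort(hits)[1]
}

#' Map exons of a transcript to protein residue ranges
#'
#' Concatenates CDS segments in transcription order so that codon `i`
#' occupies coding nucleotides `3i-2..3i`. Residue `i` is assigned to the
#' exon containing the codon's middle base (nucleotide `3i-1`), which gives
#' every residue exactly one exon even when a codon spans an exon
#' boundary. A trailing annotated stop codon is left unassigned.
#'
#' @param transcript One row of [read_transcripts()] output (or a list with
#'   fields `cds`, `cds_seq`, `strand`).
#' @return A tibble `exon_id`, `residue_start`, `residue_end` (1-based,
#'   inclusive); ranges are contiguous and partition `1..L` of the protein.
#' @export
map_exons_to_residues <- function(transcript) {
  cds <- transcript$cds[[1]]
  cds_seq <- transcript$cds_seq
  if (length(cds_seq) != 1 || nchar(cds_seq) %% 3 != 0) {
    abort("transcript CDS length must be a positive multiple of 3")
  }
  seg_len <- cds$end - cds$start + 1
  if (any(seg_len <= 0)) abort("CDS segment with nonpositive length")
  n_nt <- sum(seg_len)
  # exon of each coding nucleotide, in transcription order
  nt_exon <- rep(cds$exon_id, seg_len)
  aa <- translate_cds(cds_seq)
  n_res <- nchar(aa)
  if (n_res == 0) abort("CDS translates to an empty protein")
  mid <- 3 * seq_len(n_res) - 1
  if (max(mid) > n_nt) abort("CDS shorter than its translation requires")
  res_exon <- nt_exon[mid]
  tibble(residue = seq_len(n_res), exon_id = res_exon) |>
    group_by(.data$exon_id) |>
    summarise(
      residue_start = min(.data$residue),
      residue_end = max(.data$residue),
      .groups = "drop"
    ) |>
    arrange(.data$residue_start)
}

#' Read a residue-level structure-to-protein crosswalk
#'
#' @param file TSV with columns `structure_id`, `chain`, `resno`, `insert`
#'   (empty when absent), `protein_accession`, `protein_position`.
#' @return A tibble of the crosswalk rows.
#' @export
read_crosswalk <- function(file) {
  x <- readr::read_tsv(file, show_col_types = FALSE,
                       col_types = readr::cols(
                         resno = readr::col_integer(),
                         protein_position = readr::col_integer(),
                         .default = readr::col_character()
                       ))
  stopifnot(all(c("structure_id", "chain", "resno", "insert",
                  "protein_accession", "protein_position") %in% names(x)))
  mutate(x, insert = ifelse(is.na(.data$insert), "", .data$insert))
}

#' Label structure residues with exon identifiers
#'
#' Joins an exon-to-residue map to a structure via the residue crosswalk:
#' each crosswalked residue of the chain receives the exon owning its
#' protein position. Residues absent from the crosswalk stay unlabeled and
#' take no part in interaction attribution.
#'
#' @param exon_map Tibble from [map_exons_to_residues()].
#' @param crosswalk Tibble from [read_crosswalk()], already filtered or not
#'   (filtering by `structure_id`/`chain` happens here).
#' @param structure_id,chain Structure and chain to label.
#' @return A tibble `chain`, `resno`, `insert`, `protein_position`,
#'   `exon_id`, one row per crosswalked residue.
#' @export
label_structure_residues <- function(exon_map, crosswalk, structure_id,
                                     chain) {
  cw <- filter(crosswalk, .data$structure_id == !!structure_id,
               .data$chain == !!chain)
  if (nrow(cw) == 0) {
    abort(paste0("no crosswalk rows for structure ", structure_id,
                 " chain ", chain))
  }
  if (anyDuplicated(cw[, c("resno", "insert")]) > 0) {
    abort("crosswalk is not injective for this chain")
  }
  max_res <- max(exon_map$residue_end)
  bad <- cw$protein_position < 1 | cw$protein_position > max_res
  if (any(bad)) {
    abort(paste0("crosswalk protein_position outside exon map cover (1..",
                 max_res, ")"))
  }
  idx <- purrr::map_int(cw$protein_position, function(p) {
    which(exon_map$residue_start <= p & p <= exon_map$residue_end)[1]
  })
  tibble(
    chain = cw$chain,
    resno = cw$resno,
    insert = cw$insert,
    protein_position = cw$protein_position,
    exon_id = exon_map$exon_id[idx]
  )
}
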