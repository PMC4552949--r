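# Standard-format IO: FASTA via Biostrings, GFF3/BED via rtracklayer,
# tabular files as documented TSVs.

#' Write a synthetic world to standard-format files
#'
#' @param world A `synthetic_world` from [generate_world()].
#' @param dir Output directory (created recursively).
#' @return `dir`, invisibly.
#' @export
write_world <- function(world, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(dir, "panels"), showWarnings = FALSE)
  dir.create(file.path(dir, "truth"), showWarnings = FALSE)

  gn <- Biostrings::DNAStringSet(stats::setNames(world$genome, world$chrom))
  Biostrings::writeXStringSet(gn, file.path(dir, "genome.fa"), width = 60)

  write_gene_models_gff3(world$models, file.path(dir, "genes.gff3"))
  write_protein_fasta(world$proteome, file.path(dir, "proteome.fa"))

  panel_files <- list()
  for (clade in names(world$panels)) {
    files <- character(0)
    for (sp in names(world$panels[[clade]])) {
      f <- file.path(dir, "panels", paste0(clade, "_", sp, ".fa"))
      seqs <- world$panels[[clade]][[sp]]
      if (clade == "outgroup_proteins")
        seqs <- c(seqs, world$outgroup_focal_leak)
      write_protein_fasta(seqs, f)
      files <- c(files, file.path("panels", paste0(clade, "_", sp, ".fa")))
      rm(seqs)
    }
    panel_files[[clade]] <- as.list(files)
  }
  yaml::write_yaml(panel_files, file.path(dir, "panels.yaml"))

  write_bed_track(world$te_track, file.path(dir, "te.bed"))
  write_bed_track(world$paralog_track, file.path(dir, "paralogs.bed"))

  if (length(world$transcripts))
    Biostrings::writeXStringSet(
      Biostrings::DNAStringSet(world$transcripts),
      file.path(dir, "transcripts.fa"), width = 60)
  else
    file.create(file.path(dir, "transcripts.fa"))
  .write_tsv(world$mappings, file.path(dir, "mappings.tsv"))
  .write_tsv(world$reads, file.path(dir, "reads.tsv"))

  .write_tsv(world$truth$genes, file.path(dir, "truth", "genes.tsv"))
  .write_tsv(world$truth$retro, file.path(dir, "truth", "retro.tsv"))
  .write_tsv(world$truth$expression, file.path(dir, "truth", "expression.tsv"))
  invisible(dir)
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

.read_tsv <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  utils::read.delim(path, stringsAsFactors = FALSE)
}

write_protein_fasta <- function(seqs, path) {
  if (!length(seqs)) { file.create(path); return(invisible(path)) }
  Biostrings::writeXStringSet(Biostrings::AAStringSet(seqs), path, width = 60)
  invisible(path)
}

#' Read a protein FASTA into a named character vector
#' @param path FASTA file path.
#' @return Named character vector of sequences.
#' @export
read_protein_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  if (file.size(path) == 0) return(character(0))
  ss <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Read a genome FASTA
#' @param path FASTA file path.
#' @return Named character vector of contig sequences.
#' @export
read_genome_fasta <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  ss <- Biostrings::readDNAStringSet(path)
  stats::setNames(as.character(ss), sub("\\s.*$", "", names(ss)))
}

#' Write gene models as GFF3
#'
#' Emits one `gene` feature per gene and one `CDS` feature per exon
#' (1-based inclusive coordinates, per the GFF3 convention).
#'
#' @param models A [gene_models()] object.
#' @param path Output path.
#' @export
write_gene_models_gff3 <- function(models, path) {
  g <- models$genes; e <- models$exons
  if (!nrow(g)) {
    writeLines("##gff-version 3", path)
    return(invisible(path))
  }
  gr_gene <- GenomicRanges::GRanges(
    g$chrom, IRanges::IRanges(g$start, g$end), strand = g$strand,
    type = "gene", ID = g$gene_id, Parent = NA_character_)
  chrom <- g$chrom[match(e$gene_id, g$gene_id)]
  strand <- g$strand[match(e$gene_id, g$gene_id)]
  gr_cds <- GenomicRanges::GRanges(
    chrom, IRanges::IRanges(e$start, e$end), strand = strand,
    type = "CDS", ID = NA_character_, Parent = e$gene_id)
  # all planted CDS are phase 0; the exporter warns about absent phase only
  suppressWarnings(rtracklayer::export(c(gr_gene, gr_cds), path,
                                       format = "gff3"))
  invisible(path)
}

#' Read gene models from a GFF3 file
#'
#' Expects `gene` features with `ID` and `CDS` (or `exon`) features with
#' `Parent` attributes, as written by [write_gene_models_gff3()].
#'
#' @param path GFF3 file path.
#' @return A [gene_models()] object.
#' @export
read_gene_models_gff3 <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  gr <- rtracklayer::import(path, format = "gff3")
  md <- S4Vectors::mcols(gr)
  is_gene <- md$type == "gene"
  is_part <- md$type %in% c("CDS", "exon")
  parent <- as.character(md$Parent)
  parent[!lengths(md$Parent)] <- NA_character_
  g <- gr[is_gene]
  genes <- data.frame(
    gene_id = as.character(S4Vectors::mcols(g)$ID),
    chrom = as.character(GenomicRanges::seqnames(g)),
    strand = as.character(GenomicRanges::strand(g)),
    start = GenomicRanges::start(g), end = GenomicRanges::end(g),
    stringsAsFactors = FALSE)
  p <- gr[is_part]
  exons <- data.frame(
    gene_id = parent[is_part],
    start = GenomicRanges::start(p), end = GenomicRanges::end(p),
    stringsAsFactors = FALSE)
  exons <- exons[order(exons$gene_id, exons$start), , drop = FALSE]
  genes$exon_count <- as.integer(table(exons$gene_id)[genes$gene_id])
  gene_models(genes, exons)
}

#' Write an annotation track as BED
#'
#' Converts the internal 1-based inclusive intervals to BED's 0-based
#' half-open convention (handled by rtracklayer).
#'
#' @param track data.frame with chrom, start, end (1-based inclusive).
#' @param path Output path.
#' @export
write_bed_track <- function(track, path) {
  if (!nrow(track)) { file.create(path); return(invisible(path)) }
  gr <- GenomicRanges::GRanges(track$chrom,
                               IRanges::IRanges(track$start, track$end))
  rtracklayer::export(gr, path, format = "bed")
  invisible(path)
}

#' Read a BED annotation track
#' @param path BED file path.
#' @return data.frame with chrom, start, end in 1-based inclusive coordinates.
#' @export
read_bed_track <- function(path) {
  if (!file.exists(path)) stop("missing input file: ", path)
  if (file.size(path) == 0)
    return(data.frame(chrom = character(0), start = integer(0),
                      end = integer(0)))
  gr <- rtracklayer::import(path, format = "bed")
  data.frame(chrom = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr), end = GenomicRanges::end(gr),
             stringsAsFactors = FALSE)
}

#' Load clade panels from a panels.yaml manifest
#'
#' The manifest maps each clade name to a list of FASTA paths (relative to
#' its own directory). Sequence names follow the `species|protein` convention;
#' records tagged with the focal species are excluded, so a focal-species
#' entry inside the outgroup protein set can never create a spurious hit.
#'
#' @param yaml_path Path to panels.yaml.
#' @param focal_species Species tag to exclude (default `"c_elegans"`).
#' @return Named list: clade -> list of species -> named character vectors.
#' @export
load_panels <- function(yaml_path, focal_species = "c_elegans") {
  if (!file.exists(yaml_path)) stop("missing input file: ", yaml_path)
  base <- dirname(yaml_path)
  manifest <- yaml::read_yaml(yaml_path)
  panels <- list()
  for (clade in names(manifest)) {
    sp_list <- list()
    for (f in unlist(manifest[[clade]])) {
      seqs <- read_protein_fasta(file.path(base, f))
      sp <- sub("\\|.*$", "", names(seqs))
      seqs <- seqs[sp != focal_species]
      sp_list[[sub("\\.fa$", "", basename(f))]] <- seqs
    }
    panels[[clade]] <- sp_list
  }
  panels
}

#' Read a transcript-to-genome mapping table
#'
#' Tab-separated with header: transcript_id, chrom, strand, mapped_start,
#' mapped_end, mapped_length, identity_pct, coverage_in_mapping_pct,
#' coverage_whole_pct, score (PSL-convertible).
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_mapping_table <- function(path) {
  need <- c("transcript_id", "chrom", "strand", "mapped_start", "mapped_end",
            "mapped_length", "identity_pct", "coverage_in_mapping_pct",
            "coverage_whole_pct", "score")
  tab <- .read_tsv(path)
  if (!all(need %in% names(tab)))
    stop("mapping table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}

#' Read a read-placement table
#'
#' Tab-separated with header: read_id, stage, chrom, start, end.
#'
#' @param path TSV file path.
#' @return data.frame.
#' @export
read_placements <- function(path) {
  need <- c("read_id", "stage", "chrom", "start", "end")
  tab <- .read_tsv(path)
  if (!all(need %in% names(tab)))
    stop("read-placement table lacks columns: ",
         paste(setdiff(need, names(tab)), collapse = ", "))
  tab
}
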