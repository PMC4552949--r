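test_that("identical seeds yield byte-identical worlds", {
  cfg <- world_config(seed = 5L,
                      n_genes_per_class = c(SSG = 2L, GSG = 2L, EC = 2L),
                      n_species_per_clade = c(congeners = 1L,
                                              other_nematodes = 1L,
                                              invertebrates = 1L,
                                              vertebrates = 1L),
                      genome_size = 30000L, n_retrogenes = 1L,
                      n_chimeras = 0L, decoys_per_species = 1L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  generate_world(cfg, d1)
  generate_world(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     info = f)
})

test_that("an all-zero gene count produces a valid but empty world", {
  cfg <- world_config(seed = 1L,
                      n_genes_per_class = c(SSG = 0L, GSG = 0L, EC = 0L),
                      genome_size = 20000L, n_retrogenes = 0L,
                      n_chimeras = 0L)
  d <- withr::local_tempdir()
  w <- generate_world(cfg, d)
  expect_equal(nrow(w$models$genes), 0)
  expect_equal(nchar(w$genome), 20000)
  expect_true(file.exists(file.path(d, "genome.fa")))
  expect_equal(nrow(read_gene_models_gff3(file.path(d, "genes.gff3"))$genes), 0)
})

test_that("gene counts in the GFF3 equal planted class counts plus chimera hosts", {
  w <- small_world()
  cfg <- w$config
  expect_equal(nrow(w$models$genes),
               sum(cfg$n_genes_per_class) + cfg$n_chimeras)
  # labels are exhaustive and mutually consistent
  expect_equal(sum(table(w$truth$genes$class)), nrow(w$models$genes))
  expect_equal(anyDuplicated(w$truth$genes$gene_id), 0)
  # retro truth: every insert has a multi-exon parent
  parents <- w$truth$retro$parent_id
  pc <- w$models$genes$exon_count[match(parents, w$models$genes$gene_id)]
  expect_true(all(pc >= 3))
})

test_that("contradictory configurations are rejected", {
  expect_error(world_config(n_genes_per_class = c(SSG = -1L, GSG = 0L,
                                                  EC = 0L)),
               "configuration error")
  expect_error(world_config(mutation_rates = c(congener = 0.5,
                                               other_nematode = 0.1,
                                               invertebrate = 0.6,
                                               vertebrate = 0.7)),
               "non-decreasing")
  # more retrocopies than available multi-exon parents
  expect_error(world_config(n_genes_per_class = c(SSG = 2L, GSG = 2L,
                                                  EC = 1L),
                            n_retrogenes = 3L, n_chimeras = 0L),
               "configuration error")
})

test_that("planted retrocopies are exact spliced CDS copies at zero divergence", {
  # hand-built 3-exon gene: 90 bp exons, 50 bp introns
  set.seed(13)
  exon_seq <- vapply(1:3, function(i) {
    p <- paste(sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 30,
                      replace = TRUE), collapse = "")
    lsgscan:::reverse_translate(p)
  }, character(1))
  introns <- vapply(1:2, function(i) lsgscan:::random_dna(50), character(1))
  gene_seq <- paste0(exon_seq[1], introns[1], exon_seq[2], introns[2],
                     exon_seq[3])
  lead <- lsgscan:::random_dna(100)
  genome <- paste0(lead, gene_seq, lsgscan:::random_dna(100))
  starts <- 101L + c(0L, 140L, 280L)
  models <- gene_models(
    data.frame(gene_id = "p1", chrom = "chrI", strand = "+", start = 101L,
               end = 100L + nchar(gene_seq), exon_count = 3L),
    data.frame(gene_id = "p1", start = starts, end = starts + 89L))
  res <- plant_retrogene(genome, "p1", models)
  ins <- substr(res$genome, res$retro_locus["start"], res$retro_locus["end"])
  expect_identical(ins, paste(exon_seq, collapse = ""))  # 270 bp spliced copy
  expect_equal(unname(res$retro_locus["end"] - res$retro_locus["start"] + 1L),
               270L)
  expect_equal(nchar(res$genome), nchar(genome) + 270L)

  # a 2-exon parent is rejected
  models2 <- gene_models(models$genes,
                         models$exons[1:2, ])
  expect_error(plant_retrogene(genome, "p1", models2), ">= 3 exons")

  # divergence only changes the planted codons
  res2 <- plant_retrogene(genome, "p1", models, mutation_rate = 0.1)
  ins2 <- substr(res2$genome, res2$retro_locus["start"],
                 res2$retro_locus["end"])
  expect_equal(nchar(ins2), 270L)
  expect_false(identical(ins2, ins))
})

test_that("world files round-trip through the standard formats", {
  w <- small_world()
  d <- withr::local_tempdir()
  write_world(w, d)
  gn <- read_genome_fasta(file.path(d, "genome.fa"))
  expect_identical(unname(gn[1]), w$genome)
  models <- read_gene_models_gff3(file.path(d, "genes.gff3"))
  expect_equal(models$genes[order(models$genes$gene_id),
                            c("gene_id", "start", "end", "exon_count")],
               w$models$genes[order(w$models$genes$gene_id),
                              c("gene_id", "start", "end", "exon_count")],
               ignore_attr = TRUE)
  te <- read_bed_track(file.path(d, "te.bed"))
  expect_equal(te[order(te$start), ], w$te_track[order(w$te_track$start), ],
               ignore_attr = TRUE)
  prot <- read_protein_fasta(file.path(d, "proteome.fa"))
  expect_identical(prot[names(w$proteome)], w$proteome)
})

test_that("panel loading excludes focal-species records by species tag", {
  w <- small_world()
  d <- withr::local_tempdir()
  write_world(w, d)
  # the written outgroup panel carries a verbatim focal-species SSG record
  raw <- read_protein_fasta(
    file.path(d, "panels", "outgroup_proteins_uniprot.fa"))
  expect_true(any(grepl("^c_elegans\\|", names(raw))))
  loaded <- load_panels(file.path(d, "panels.yaml"))
  expect_false(any(grepl("^c_elegans\\|",
                         names(loaded$outgroup_proteins$outgroup_proteins_uniprot))))
})
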