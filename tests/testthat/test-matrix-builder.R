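test_that("translation follows table 5 with the gap rule", {
  code <- genetic_code("5")
  aln <- gene_alignment("COX1", "PCG_nt", c(t1 = "ATGTTT", t2 = "AT-GTT"))
  tr <- translate_alignment(aln, code)
  expect_equal(unname(tr$seqs["t1"]), "MF")
  expect_equal(unname(tr$seqs["t2"]), "-V")   # gap codon, then GTT = V
  # AGA is serine under the invertebrate mitochondrial code
  aga <- translate_alignment(gene_alignment("ND2", "PCG_nt", c(x = "AGA")), code)
  expect_equal(unname(aga$seqs["x"]), "S")
  expect_equal(unname(Biostrings::getGeneticCode("1")[["AGA"]]), "R")
  # internal stops warn and become X
  expect_warning(
    tr2 <- translate_alignment(gene_alignment("ND1", "PCG_nt", c(x = "TAAATG")), code),
    "internal stop")
  expect_equal(unname(tr2$seqs["x"]), "XM")
  expect_error(translate_alignment(gene_alignment("ND1", "PCG_nt", c(x = "ATGT"))),
               "divisible")
})

test_that("third-position stripping removes every third column once", {
  aln <- gene_alignment("COX1", "PCG_nt", c(t1 = "ATGTTTTAA", t2 = "ATGAAATAG"))
  s <- strip_third_positions(aln)
  expect_equal(s$width, 6)
  expect_equal(unname(s$seqs["t1"]), "ATTTTA")
  expect_error(strip_third_positions(s), "already")
})

test_that("bundle widths follow the declared identities", {
  alns <- list(
    gene_alignment("COX1", "PCG_nt", c(a = "ATGTTT", b = "ATGTTC", c = "ATGCTT")),
    gene_alignment("ND2", "PCG_nt",
                   c(a = "ATTAAATTT", b = "ATTAAATTC", c = "ATTAAACTT")),
    gene_alignment("rrnL", "rRNA_nt",
                   c(a = "ACGTACGTAA", b = "ACGTACGTAT", c = "ACGTACGTAG")))
  b <- build_bundle(alns)
  g <- glance(b)
  w <- stats::setNames(g$width, g$matrix)
  expect_equal(unname(w["cds_fna"]), 15L)
  expect_equal(unname(w["cds12_fna"]), 10L)
  expect_equal(unname(w["cds_rrna"]), 25L)
  expect_equal(unname(w["cds12_rrna"]), 20L)
  expect_equal(unname(w["cds_faa"]), 5L)
  expect_equal(unname(w["cds12_fna"]) * 3L, unname(w["cds_fna"]) * 2L)
  # partitions tile each matrix without overlap
  parts <- tidy(b)
  for (m in unique(parts$matrix)) {
    p <- parts[parts$matrix == m, ]
    expect_equal(p$start, c(1L, utils::head(p$end, -1) + 1L))
    expect_equal(max(p$end), unname(w[m]))
  }
  # genes are concatenated in ancestral genomic order: ND2 precedes COX1
  expect_equal(parts$gene[parts$matrix == "cds_fna"], c("ND2", "COX1"))
})

test_that("a single-gene bundle is degenerate but valid", {
  b <- build_bundle(list(gene_alignment("COX1", "PCG_nt", c(a = "ATGTTT"))))
  parts <- tidy(b)
  expect_equal(nrow(parts[parts$matrix == "cds_fna", ]), 1)
  expect_equal(unname(glance(b)$width[glance(b)$matrix == "cds_rrna"]), 6L)
})

test_that("rows are the concatenation of per-gene rows, and ops commute", {
  set.seed(7)
  mk_seq <- function(n) paste(sample(c("A", "T", "G", "C"), n, TRUE), collapse = "")
  taxa <- c("t1", "t2", "t3")
  genes <- c("COX1", "ND2", "CYTB")
  alns <- lapply(genes, function(g) {
    gene_alignment(g, "PCG_nt",
                   stats::setNames(vapply(taxa, function(x) mk_seq(12), ""), taxa))
  })
  b <- build_bundle(alns)
  ord <- match(c("ND2", "COX1", "CYTB"), genes)  # ancestral genomic order
  for (tx in taxa) {
    expect_equal(unname(b$matrices$cds_fna[tx]),
                 paste(vapply(alns[ord], function(a) unname(a$seqs[tx]), ""),
                       collapse = ""))
    # strip-then-concat equals concat-then-strip
    stripped <- paste(vapply(alns[ord], function(a)
      unname(strip_third_positions(a)$seqs[tx]), ""), collapse = "")
    expect_equal(unname(b$matrices$cds12_fna[tx]), stripped)
    whole <- gene_alignment("COX1", "PCG_nt",
                            stats::setNames(b$matrices$cds_fna[tx], tx))
    expect_equal(unname(strip_third_positions(whole)$seqs[tx]), stripped)
  }
})

test_that("taxon-set mismatches are fatal unless gaps are requested", {
  alns <- list(
    gene_alignment("COX1", "PCG_nt", c(a = "ATGTTT", b = "ATGTTC")),
    gene_alignment("ND2", "PCG_nt", c(a = "ATTAAA")))
  expect_error(build_bundle(alns), "b")
  w <- capture_warnings(b <- build_bundle(alns, fill = "gaps"))
  expect_true(any(grepl("filled with gaps", w)))
  expect_equal(unname(b$matrices$cds_fna["b"]), "------ATGTTC")
})

test_that("a 13 PCG + 2 rRNA set from the generator has the bookkept widths", {
  genomes <- lapply(1:3, function(s) generate_genome(synthetic_spec(seed = s))$genome)
  taxa <- vapply(genomes, function(g) g$id, character(1))
  pcg_alns <- lapply(pcg_tokens(), function(tok) {
    seqs <- vapply(genomes, function(g) {
      s <- region_sequence(g, tok)
      substr(s, 1, nchar(s) - nchar(s) %% 3)  # trim incomplete stop
    }, character(1))
    gene_alignment(tok, "PCG_nt", stats::setNames(seqs, taxa))
  })
  rrna_alns <- lapply(rrna_tokens(), function(tok) {
    gene_alignment(tok, "rRNA_nt", stats::setNames(
      vapply(genomes, function(g) region_sequence(g, tok), character(1)), taxa))
  })
  b <- build_bundle(c(pcg_alns, rrna_alns))
  g <- glance(b)
  w <- stats::setNames(g$width, g$matrix)
  pcg_w <- sum(vapply(pcg_alns, function(a) a$width, integer(1)))
  rrna_w <- sum(vapply(rrna_alns, function(a) a$width, integer(1)))
  expect_equal(unname(w["cds_fna"]), pcg_w)
  expect_equal(unname(w["cds_rrna"]), pcg_w + rrna_w)
  expect_equal(unname(w["cds12_fna"]), 2L * pcg_w %/% 3L)
  expect_equal(unname(w["cds12_rrna"]), 2L * pcg_w %/% 3L + rrna_w)
  expect_equal(nrow(tidy(b)[tidy(b)$matrix == "cds_rrna", ]), 15)
})

test_that("bundle files are written in FASTA, PHYLIP and partition formats", {
  out <- withr::local_tempdir()
  b <- build_bundle(list(
    gene_alignment("COX1", "PCG_nt", c(a = "ATGTTT", b = "ATGCTT")),
    gene_alignment("rrnS", "rRNA_nt", c(a = "ACGT", b = "AGGT"))))
  write_bundle(b, out, codon_subpartitions = TRUE)
  for (nm in names(b$matrices)) {
    expect_true(file.exists(file.path(out, paste0(nm, ".fasta"))))
    phy <- readLines(file.path(out, paste0(nm, ".phy")))
    expect_match(phy[1], "^2 \\d+$")
    expect_true(file.exists(file.path(out, paste0(nm, ".partitions.txt"))))
    nex <- readLines(file.path(out, paste0(nm, ".sets.nex")))
    expect_equal(nex[1], "#NEXUS")
  }
  rax <- readLines(file.path(out, "cds12_fna.partitions.txt"))
  expect_match(rax[1], "pos1")
})
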