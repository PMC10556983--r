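test_that("VCF round-trip preserves dosages, positions and missingness", {
  cfg <- sim_config(n_per_cluster = c(5, 4), n_loci = 80, seed = 31)
  g <- simulate_genotypes(cfg)
  g$dosage[2, 5] <- NA
  g$dosage[1, 10] <- 1
  path <- withr::local_tempfile(fileext = ".vcf")
  write_vcf(g, path)
  back <- read_vcf(path)
  expect_equal(unname(back$dosage), unname(g$dosage))
  expect_equal(back$loci$pos, g$loci$pos)
  expect_equal(back$samples$sample, g$samples$sample)
})

test_that("missing genotypes and multiallelic records are handled as stated", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\ts1\ts2",
    "chr1\t100\t.\tA\tT\t.\tPASS\t.\tGT\t0/1\t./.",
    "chr1\t200\t.\tG\tC,T\t.\tPASS\t.\tGT\t1/1\t0/0",
    "chr1\t300\t.\tC\tG\t.\tPASS\t.\tGT\t1|1\t0/0"
  ), path)
  g <- suppressMessages(read_vcf(path))
  expect_equal(attr(g, "n_multiallelic_skipped"), 1L)
  expect_equal(g$loci$pos, c(100L, 300L))
  expect_equal(unname(g$dosage["s1", ]), c(1, 2))  # het, then phased hom-alt
  expect_true(is.na(g$dosage["s2", 1]))
})

test_that("site filters enforce the heterozygosity, missingness and MAC rules", {
  # 25 samples: 1 het call = 4% het -> dropped at the 3.6% cutoff
  dos_het <- matrix(rep(c(0, 2), c(13, 12)), ncol = 1)
  dos_het[1, 1] <- 1
  # MAC 2 site; and a 30%-missing site
  dos_mac <- matrix(c(2, rep(0, 24)), ncol = 1)        # MAC 2
  dos_mis <- matrix(rep(c(NA, 0, 2), c(8, 9, 8)), ncol = 1)  # 32% missing
  dos_ok <- matrix(rep(c(0, 2), c(12, 13)), ncol = 1)
  dos <- cbind(dos_het, dos_mac, dos_mis, dos_ok)
  g <- genotype_matrix(
    dos, tibble::tibble(chrom = "c", pos = c(10L, 20L, 30L, 40L),
                        ref = "A", alt = "T"),
    tibble::tibble(sample = sprintf("s%02d", 1:25)))
  out <- filter_sites(g)
  expect_equal(out$loci$pos, 40L)
  rep <- attr(out, "filter_report")
  expect_equal(rep$dropped[rep$rule == "heterozygosity"], 1L)
  expect_equal(rep$dropped[rep$rule == "missing"], 1L)
  expect_equal(rep$dropped[rep$rule == "mac"], 1L)
  # idempotence
  out2 <- filter_sites(out)
  expect_equal(out2$loci, out$loci)
  expect_equal(out2$dosage, out$dosage)
})

test_that("region subsetting uses 0-based half-open intervals", {
  dos <- matrix(0, 2, 3)
  dos[1, ] <- 2
  g <- genotype_matrix(
    dos, tibble::tibble(chrom = "c", pos = c(101L, 200L, 250L),
                        ref = "A", alt = "T"),
    tibble::tibble(sample = c("a", "b")))
  r <- region_set(chrom = "c", start = 100L, end = 200L)
  # BED [100, 200) covers 1-based positions 101..200 (pos - 1 in [start, end))
  kept <- subset_by_regions(g, r, "keep")
  expect_equal(kept$loci$pos, c(101L, 200L))
  excl <- subset_by_regions(g, r, "exclude")
  expect_equal(excl$loci$pos, 250L)
  expect_equal(excl$provenance, "region-purged")
  # empty region set in exclude mode is the identity
  id <- subset_by_regions(g, region_set(tibble::tibble(
    chrom = character(), start = integer(), end = integer(),
    label = character())), "exclude")
  expect_equal(id$loci, g$loci)
})

test_that("promoters are the 2 kb upstream of the TSS, strand-aware", {
  feats <- tibble::tibble(
    chrom = "c", start = c(5001L, 1001L, 2000L), end = c(6000L, 1500L, 8000L),
    strand = c("+", "+", "-"), gene_id = c("gA", "gB", "gC"))
  pr <- promoter_regions(feats, length = 2000)
  pa <- pr[pr$label == "gA", ]
  expect_equal(c(pa$start, pa$end), c(3000L, 5000L))
  pb <- pr[pr$label == "gB", ]
  expect_equal(c(pb$start, pb$end), c(0L, 1000L))     # truncated at chrom start
  pc <- pr[pr$label == "gC", ]
  expect_equal(c(pc$start, pc$end), c(8000L, 10000L)) # minus strand mirror
  expect_error(promoter_regions(dplyr::mutate(feats, strand = "."), 2000),
               "strand")
})

test_that("GFF3 gene models and BED regions read into the expected layout", {
  gff <- withr::local_tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\tsrc\tgene\t5001\t6000\t.\t+\t.\tID=gene1",
    "chr1\tsrc\tCDS\t5101\t5400\t.\t+\t0\tID=cds1;Parent=gene1"
  ), gff)
  feats <- read_gff3(gff)
  expect_setequal(feats$type, c("gene", "CDS"))
  expect_equal(feats$gene_id[feats$type == "CDS"], "gene1")
  bed <- withr::local_tempfile(fileext = ".bed")
  writeLines(c("chr1\t100\t200\thot", "chr1\t150\t300\thot"), bed)
  r <- read_bed(bed)
  expect_equal(nrow(r), 1L)  # overlapping intervals merged
  expect_equal(c(r$start, r$end), c(100L, 300L))
  out <- withr::local_tempfile(fileext = ".bed")
  write_bed(r, out)
  expect_equal(read_bed(out), r)
})
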