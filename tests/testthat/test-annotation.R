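write_tmp <- function(lines, ext) {
  path <- withr::local_tempfile(fileext = ext, .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("GFF3 genes convert to 0-based half-open with strand-aware promoters", {
  path <- write_tmp(c("##gff-version 3",
                      "chr1\tsrc\tgene\t5001\t8000\t.\t+\t.\tID=gA"), ".gff3")
  g <- load_annotation(path, flank = 1000)
  expect_equal(g$start, 5000)
  expect_equal(g$end, 8000)
  expect_equal(g$tss, 5000)
  expect_equal(g$promoter_start, 4000)
  expect_equal(g$promoter_end, 6001)
})

test_that("BED genes keep their coordinates; minus strand uses the right TSS", {
  path <- write_tmp("chr1\t5000\t8000\tgB\t0\t-", ".bed")
  g <- load_annotation(path, flank = 1000)
  expect_equal(g$start, 5000)
  expect_equal(g$end, 8000)
  expect_equal(g$tss, 7999)
  expect_equal(g$promoter_start, 6999)
  expect_equal(g$promoter_end, 9000)
  # zero flank degenerates to the single TSS position
  g0 <- load_annotation(path, flank = 0)
  expect_equal(g0$promoter_end - g0$promoter_start, 1)
  expect_equal(g0$promoter_start, 7999)
})

test_that("records with unknown strand are skipped with a warning", {
  path <- write_tmp(c("chr1\t100\t200\tgA\t0\t+", "chr1\t300\t400\tgB\t0\t."),
                    ".bed")
  expect_warning(g <- load_annotation(path), "unknown strand")
  expect_equal(g$gene_id, "gA")
})

test_that("malformed annotation fails loudly", {
  path <- write_tmp(c("##gff-version 3", "chr1\tonly-two-fields"), ".gff3")
  expect_error(load_annotation(path), "malformed")
  expect_error(load_annotation("x.bam"), "dialect")
})

test_that("the generator's GFF3 and BED writers are read back identically", {
  g <- simulate_genome(tiny_config())
  gff <- withr::local_tempfile(fileext = ".gff3")
  bed <- withr::local_tempfile(fileext = ".bed")
  write_genes_gff3(g$genes, gff)
  write_genes_bed(g$genes, bed)
  from_gff <- load_annotation(gff, flank = 1000)
  from_bed <- load_annotation(bed, flank = 1000)
  cols <- c("gene_id", "chrom", "start", "end", "strand", "tss",
            "promoter_start", "promoter_end")
  expect_equal(from_gff[cols], from_bed[cols])
  expect_equal(from_gff$start, g$genes$start)
  expect_equal(from_gff$tss, g$genes$tss)
})

demo_genes <- function() {
  tibble::tibble(gene_id = "gA", chrom = "chr1", start = 5000, end = 8000,
                 strand = "+", tss = 5000, promoter_start = 4000,
                 promoter_end = 6001)
}

region <- function(start, end, direction = "hyper") {
  tibble::tibble(pair = "consensus", chrom = "chr1", start = start, end = end,
                 direction = direction, n_sites = 3L, region_z = 3)
}

test_that("region-to-feature hits follow half-open overlap semantics", {
  genes <- demo_genes()
  h1 <- assign_regions(region(3900, 4100), genes)
  expect_equal(h1$feature, "promoter")
  expect_equal(h1$direction, "hyper")
  # a region starting exactly at the body end does not touch it
  h2 <- assign_regions(region(8000, 8100), genes)
  expect_equal(nrow(h2), 0)
  # spanning the promoter/body boundary hits both features
  h3 <- assign_regions(region(5900, 6200), genes)
  expect_setequal(h3$feature, c("promoter", "body"))
})

test_that("regions on unannotated chromosomes are reported, not lost silently", {
  r <- dplyr::bind_rows(region(4100, 4200),
                        region(100, 200) |> dplyr::mutate(chrom = "chrU"))
  expect_message(h <- assign_regions(r, demo_genes()), "no annotation")
  expect_equal(nrow(h), 1)
})

test_that("gene classification separates unique from mixed body signals", {
  genes <- dplyr::bind_rows(
    demo_genes(),
    demo_genes() |> dplyr::mutate(gene_id = c("gB")),
    demo_genes() |> dplyr::mutate(gene_id = c("gC"))
  )
  hits <- tibble::tibble(
    gene_id = c("gA", "gA", "gB", "gB", "gC"),
    feature = c("body", "body", "body", "body", "promoter"),
    direction = c("hyper", "hypo", "hypo", "hypo", "hyper"),
    region_id = sprintf("r%d", 1:5), chrom = "chr1",
    region_start = 0, region_end = 10
  )
  st <- classify_genes(hits, genes)
  expect_equal(st$body_status[st$gene_id == "gA"], "mixed")
  expect_equal(st$body_status[st$gene_id == "gB"], "unique_hypo")
  expect_equal(st$promoter_status[st$gene_id == "gC"], "hyper")
  expect_equal(st$body_status[st$gene_id == "gC"], "none")
  # unique_hyper, unique_hypo and mixed are pairwise disjoint by construction
  expect_equal(anyDuplicated(st$gene_id), 0)
})

test_that("every region overlapping a feature appears in at least one hit", {
  cfg <- tiny_config(seed = 13)
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  pu <- simulate_methylation(g, tr, cfg)
  cons <- reconcile_pairs(segment_regions(flag_sites(site_contrasts(pu))))
  hits <- assign_regions(cons, g$genes)
  feats <- dplyr::bind_rows(
    g$genes |> dplyr::transmute(chrom, start, end),
    g$genes |> dplyr::transmute(chrom, start = promoter_start,
                                end = promoter_end)
  )
  overlaps_any <- vapply(seq_len(nrow(cons)), function(i) {
    any(feats$chrom == cons$chrom[i] & feats$start < cons$end[i] &
          cons$start[i] < feats$end)
  }, logical(1))
  expect_setequal(sprintf("r%05d", which(overlaps_any)), unique(hits$region_id))
})
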