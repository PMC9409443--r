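#' Write and read per-sample cytosine reports
#'
#' The on-disk format is a headerless five-column TSV: chromosome, 1-based
#' position, strand, methylated-call read count, total coverage — one file
#' per sample. `read_cytosine_report()` attaches the sample metadata needed
#' downstream and applies the methylation-call convention: `"as_printed"`
#' keeps column four as the methylated count (C>T alignments on +, A>G
#' on -); `"inverted"` uses coverage minus column four, the conventional
#' bisulfite reading in which unconverted cytosines are the methylated ones.
#'
#' @param pileup Tibble with columns `chrom`, `pos`, `strand`, `meth`,
#'   `cov` for a single sample.
#' @param path Output/input file path.
#' @return `write_cytosine_report()` returns `path` invisibly.
#' @export
write_cytosine_report <- function(pileup, path) {
  stopifnot(all(c("chrom", "pos", "strand", "meth", "cov") %in% names(pileup)))
  readr::write_tsv(pileup[, c("chrom", "pos", "strand", "meth", "cov")],
                   path, col_names = FALSE)
  invisible(path)
}

#' @rdname write_cytosine_report
#' @param pileups Long tibble with a `sample` column (as produced by
#'   [simulate_methylation()]).
#' @param dir Output directory for one file per sample.
#' @return `write_cytosine_reports()` returns a named vector of paths.
#' @export
write_cytosine_reports <- function(pileups, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  samples <- unique(pileups$sample)
  paths <- setNames(file.path(dir, paste0(samples, ".cytosine.tsv")), samples)
  for (s in samples) {
    write_cytosine_report(pileups[pileups$sample == s, ], paths[[s]])
  }
  paths
}

#' @rdname write_cytosine_report
#' @param sample,pair,group Sample metadata to attach (`pair` is
#'   male|female, `group` is ctrl|as).
#' @param call_convention `"as_printed"` or `"inverted"`, see Details.
#' @return `read_cytosine_report()` returns a tibble `sample`, `pair`,
#'   `group`, `chrom`, `pos`, `strand`, `meth`, `cov`, sorted by position,
#'   with the convention recorded in attribute `call_convention`.
#' @export
read_cytosine_report <- function(path, sample, pair, group,
                                 call_convention = c("as_printed", "inverted")) {
  call_convention <- match.arg(call_convention)
  x <- readr::read_tsv(
    path, col_names = c("chrom", "pos", "strand", "meth", "cov"),
    col_types = readr::cols(
      chrom = readr::col_character(), pos = readr::col_double(),
      strand = readr::col_character(), meth = readr::col_double(),
      cov = readr::col_double()
    ),
    progress = FALSE
  )
  bad <- which(is.na(x$pos) | is.na(x$meth) | is.na(x$cov) |
                 x$meth > x$cov | x$meth < 0)
  if (length(bad) > 0) {
    abort(sprintf("malformed cytosine report %s at line %d", path, bad[1]))
  }
  if (call_convention == "inverted") x$meth <- x$cov - x$meth
  out <- tibble(sample = sample, pair = pair, group = group) %>%
    dplyr::bind_cols(x) %>%
    arrange(.data$chrom, .data$pos)
  attr(out, "call_convention") <- call_convention
  out
}

#' Read a Bismark-style CpG report
#'
#' Maps the six/seven-column Bismark cytosine report (chrom, position,
#' strand, count methylated, count unmethylated, context and optionally
#' the trinucleotide)
#' onto the internal (`meth`, `cov`) pileup, where coverage is the sum of
#' the methylated and unmethylated counts.
#'
#' @inheritParams read_cytosine_report
#' @export
read_bismark_report <- function(path, sample, pair, group) {
  x <- readr::read_tsv(path, col_names = FALSE, progress = FALSE,
                       col_types = readr::cols(.default = readr::col_character()))
  if (ncol(x) < 5) abort(sprintf("not a Bismark CpG report: %s", path))
  out <- tibble(
    sample = sample, pair = pair, group = group,
    chrom = x[[1]], pos = as.numeric(x[[2]]), strand = x[[3]],
    meth = as.numeric(x[[4]]),
    cov = as.numeric(x[[4]]) + as.numeric(x[[5]])
  ) %>% arrange(.data$chrom, .data$pos)
  attr(out, "call_convention") <- "bismark"
  out
}

#' Write gene annotation as GFF3 or BED6
#'
#' Gene intervals are stored internally as 0-based half-open; GFF3 output
#' is 1-based inclusive, BED output is 0-based half-open.
#'
#' @param genes Gene tibble with `gene_id`, `chrom`, `start`, `end`,
#'   `strand`.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_genes_gff3 <- function(genes, path) {
  lines <- c("##gff-version 3",
             sprintf("%s\tmethexpr\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                     genes$chrom, as.integer(genes$start) + 1L,
                     as.integer(genes$end), genes$strand, genes$gene_id))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_genes_gff3
#' @export
write_genes_bed <- function(genes, path) {
  lines <- sprintf("%s\t%d\t%d\t%s\t0\t%s",
                   genes$chrom, as.integer(genes$start),
                   as.integer(genes$end), genes$gene_id, genes$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write methylation regions as BED6
#'
#' Name carries the direction, score is |region z| * 100 clamped to
#' \[0, 1000\], strand is ".".
#'
#' @param regions Region tibble from [segment_regions()] or
#'   [reconcile_pairs()].
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_regions_bed <- function(regions, path) {
  score <- pmin(pmax(round(abs(regions$region_z) * 100), 0), 1000)
  lines <- sprintf("%s\t%d\t%d\t%s\t%d\t.",
                   regions$chrom, as.integer(regions$start),
                   as.integer(regions$end), regions$direction, score)
  writeLines(lines, path)
  invisible(path)
}

#' Write / read a gene-by-sample count matrix TSV
#'
#' @param counts Tibble with `gene_id` plus one integer column per sample.
#' @param path File path.
#' @return `write_counts_tsv()` returns `path` invisibly;
#'   `read_counts_tsv()` returns the counts tibble.
#' @export
write_counts_tsv <- function(counts, path) {
  readr::write_tsv(counts, path)
  invisible(path)
}

#' @rdname write_counts_tsv
#' @export
read_counts_tsv <- function(path) {
  readr::read_tsv(path, show_col_types = FALSE, progress = FALSE)
}

#' Write the truth tables of a simulation
#'
#' @param truth A `truth_plan`.
#' @param dir Output directory; writes `truth_elements.tsv` and
#'   `truth_genes.tsv`.
#' @return Named vector of the two paths.
#' @export
write_truth_tables <- function(truth, dir) {
  stopifnot(inherits(truth, "truth_plan"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(elements = file.path(dir, "truth_elements.tsv"),
             genes = file.path(dir, "truth_genes.tsv"))
  readr::write_tsv(truth$elements, paths[["elements"]])
  readr::write_tsv(truth$genes, paths[["genes"]])
  paths
}
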