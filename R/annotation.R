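#' Load gene annotation from GFF3 or BED
#'
#' Reads gene intervals (via `rtracklayer`), normalises them to the
#' internal 0-based half-open convention (GFF3 is 1-based inclusive, BED
#' already 0-based half-open) and computes strand-aware TSS and promoter
#' windows of TSS +/- `flank` bp. The dialect is auto-detected from the
#' file extension and can be overridden. Records with an unknown strand
#' symbol are skipped with a warning.
#'
#' @param path Annotation file (`.gff3`/`.gff` or `.bed`).
#' @param flank Promoter half-width in bp; default 1000. With `flank = 0`
#'   the promoter is the single-position TSS window.
#' @param dialect `"auto"` (default), `"gff3"` or `"bed"`.
#' @return Gene tibble: `gene_id`, `chrom`, `start`, `end` (0-based
#'   half-open), `strand`, `tss`, `promoter_start`, `promoter_end`.
#' @export
load_annotation <- function(path, flank = 1000, dialect = c("auto", "gff3", "bed")) {
  dialect <- match.arg(dialect)
  if (dialect == "auto") {
    ext <- tolower(tools::file_ext(path))
    dialect <- if (ext %in% c("gff", "gff3")) "gff3"
               else if (ext == "bed") "bed"
               else abort(sprintf("cannot infer annotation dialect from '%s'; pass `dialect`", path))
  }
  gr <- tryCatch(
    rtracklayer::import(path, format = if (dialect == "gff3") "gff3" else "bed"),
    error = function(e) abort(sprintf("malformed %s annotation %s: %s",
                                      dialect, path, conditionMessage(e)))
  )
  if (dialect == "gff3") {
    keep <- as.character(gr$type) == "gene"
    if (any(keep)) gr <- gr[keep]
    ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$Name)
  } else {
    ids <- if (!is.null(gr$name)) as.character(gr$name)
           else sprintf("gene%05d", seq_along(gr))
  }
  strand <- as.character(GenomicRanges::strand(gr))
  bad <- !(strand %in% c("+", "-"))
  if (any(bad)) {
    warn(sprintf("skipping %d record(s) with unknown strand in %s",
                 sum(bad), path))
    gr <- gr[!bad]; ids <- ids[!bad]; strand <- strand[!bad]
  }
  genes <- tibble(
    gene_id = ids,
    chrom = as.character(GenomicRanges::seqnames(gr)),
    # GRanges is 1-based closed regardless of source dialect
    start = GenomicRanges::start(gr) - 1,
    end = as.numeric(GenomicRanges::end(gr)),
    strand = strand
  )
  if (any(duplicated(genes$gene_id)) || any(is.na(genes$gene_id))) {
    abort(sprintf("gene identifiers in %s are missing or duplicated", path))
  }
  add_promoters(genes, flank, chrom_length = Inf)
}

#' Assign consensus regions to promoters and gene bodies
#'
#' A hit is any interval intersection of at least 1 bp (half-open
#' semantics: a region ending where a feature starts does not hit). One
#' region may hit several genes, and both the promoter and the body of the
#' same gene. Regions on chromosomes absent from the annotation are
#' reported and left unassigned.
#'
#' @param consensus Consensus region tibble from [reconcile_pairs()].
#' @param genes Gene tibble from [load_annotation()] (or a `sim_genome`'s
#'   `genes`).
#' @return Hit tibble: `gene_id`, `feature` (promoter|body), `direction`,
#'   `region_id`, `chrom`, `region_start`, `region_end`.
#' @export
assign_regions <- function(consensus, genes) {
  stopifnot(all(c("chrom", "start", "end", "direction") %in% names(consensus)))
  missing_chrom <- setdiff(unique(consensus$chrom), unique(genes$chrom))
  if (length(missing_chrom) > 0) {
    inform(sprintf("%d region(s) on chromosome(s) %s have no annotation and stay unassigned",
                   sum(consensus$chrom %in% missing_chrom),
                   paste(missing_chrom, collapse = ", ")))
  }
  if (nrow(consensus) == 0 || nrow(genes) == 0) return(empty_hits())
  consensus <- consensus %>% mutate(region_id = sprintf("r%05d", row_number()))
  gr_regions <- regions_to_granges(consensus)
  feats <- bind_rows(
    genes %>% mutate(feature = "body") %>%
      select("gene_id", "feature", "chrom", "start", "end"),
    genes %>% mutate(feature = "promoter", start = .data$promoter_start,
                     end = .data$promoter_end) %>%
      select("gene_id", "feature", "chrom", "start", "end")
  )
  gr_feats <- regions_to_granges(feats)
  hits <- GenomicRanges::findOverlaps(gr_feats, gr_regions)
  fi <- S4Vectors::queryHits(hits)
  ri <- S4Vectors::subjectHits(hits)
  tibble(
    gene_id = feats$gene_id[fi],
    feature = feats$feature[fi],
    direction = consensus$direction[ri],
    region_id = consensus$region_id[ri],
    chrom = consensus$chrom[ri],
    region_start = consensus$start[ri],
    region_end = consensus$end[ri]
  ) %>% arrange(.data$gene_id, .data$feature, .data$region_start)
}

empty_hits <- function() {
  tibble(gene_id = character(), feature = character(), direction = character(),
         region_id = character(), chrom = character(),
         region_start = numeric(), region_end = numeric())
}

#' Classify each gene's methylation status
#'
#' Promoter status is hyper, hypo, both or none according to the
#' directions of consensus regions hitting the promoter window. Gene-body
#' status distinguishes unique signals from mixed ones: `unique_hyper` /
#' `unique_hypo` when regions of exactly one direction overlap the body,
#' `mixed` when both directions do. Mixed-body genes are excluded from the
#' downstream unique-set association.
#'
#' @param hits Hit tibble from [assign_regions()].
#' @param genes Gene tibble (defines the gene universe; genes without hits
#'   get status none/none).
#' @return Tibble: `gene_id`, `promoter_status`, `body_status`.
#' @export
classify_genes <- function(hits, genes) {
  prom <- hits %>%
    filter(.data$feature == "promoter") %>%
    group_by(.data$gene_id) %>%
    summarise(promoter_status = status_of(.data$direction), .groups = "drop")
  body <- hits %>%
    filter(.data$feature == "body") %>%
    group_by(.data$gene_id) %>%
    summarise(body_status = body_status_of(.data$direction), .groups = "drop")
  tibble(gene_id = genes$gene_id) %>%
    left_join(prom, by = "gene_id") %>%
    left_join(body, by = "gene_id") %>%
    mutate(promoter_status = .data$promoter_status %|NA|% "none",
           body_status = .data$body_status %|NA|% "none")
}

status_of <- function(direction) {
  has_hyper <- any(direction == "hyper")
  has_hypo <- any(direction == "hypo")
  if (has_hyper && has_hypo) "both"
  else if (has_hyper) "hyper"
  else if (has_hypo) "hypo"
  else "none"
}

body_status_of <- function(direction) {
  s <- status_of(direction)
  switch(s, both = "mixed", hyper = "unique_hyper", hypo = "unique_hypo",
         "none")
}

`%|NA|%` <- function(x, y) if_else(is.na(x), y, x)
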