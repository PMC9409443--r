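#' Pipeline configuration
#'
#' Collects file paths, sample labelling and every tunable parameter for an
#' end-to-end run. Exactly four pileup files are required, forming two
#' sex-matched pairs of one control and one case sample each. Expression
#' input is either a raw count matrix (analysed with the built-in test) or
#' a precomputed DE table (imported unchanged).
#'
#' @param pileups Named character vector of four cytosine-report paths with
#'   names `ctrl_male`, `as_male`, `ctrl_female`, `as_female`.
#' @param annotation Gene annotation path (GFF3 or BED).
#' @param counts Count-matrix TSV path, or `NULL` when `de_table` is given.
#' @param de_table Precomputed DE table TSV path, or `NULL`.
#' @param out_dir Output directory.
#' @param min_coverage,level,alpha,max_gap,min_sites,flank Stage parameters
#'   (see [site_contrasts()], [flag_sites()], [segment_regions()],
#'   [load_annotation()]).
#' @param dispersion,p_cutoff,fc_up,fc_down DE parameters (see
#'   [de_test()] / [classify_de()]).
#' @param call_convention Methylation-call convention for the importer.
#' @param logfc_base Base used to exponentiate an imported logFC column.
#' @param annotation_dialect `"auto"`, `"gff3"` or `"bed"`.
#' @return A validated list of class `pipeline_config`.
#' @export
pipeline_config <- function(pileups, annotation, counts = NULL,
                            de_table = NULL, out_dir,
                            min_coverage = 5, level = 0.95, alpha = 0.05,
                            max_gap = 500, min_sites = 3, flank = 1000,
                            dispersion = 0.1, p_cutoff = 0.005,
                            fc_up = 1.5, fc_down = 0.6,
                            call_convention = "as_printed", logfc_base = 2,
                            annotation_dialect = "auto") {
  cfg <- list(
    pileups = pileups, annotation = annotation, counts = counts,
    de_table = de_table, out_dir = out_dir, min_coverage = min_coverage,
    level = level, alpha = alpha, max_gap = max_gap, min_sites = min_sites,
    flank = flank, dispersion = dispersion, p_cutoff = p_cutoff,
    fc_up = fc_up, fc_down = fc_down, call_convention = call_convention,
    logfc_base = logfc_base, annotation_dialect = annotation_dialect
  )
  validate_pipeline_config(cfg)
  structure(cfg, class = "pipeline_config")
}

validate_pipeline_config <- function(cfg) {
  expected <- c("ctrl_male", "as_male", "ctrl_female", "as_female")
  if (!setequal(names(cfg$pileups), expected) || length(cfg$pileups) != 4) {
    abort(sprintf("`pileups` must be four paths named %s",
                  paste(expected, collapse = ", ")),
          class = "methexpr_validation_error")
  }
  for (p in c(cfg$pileups, cfg$annotation, cfg$counts, cfg$de_table)) {
    if (!file.exists(p)) {
      abort(sprintf("input file does not exist: %s", p),
            class = "methexpr_validation_error")
    }
  }
  if (is.null(cfg$counts) && is.null(cfg$de_table)) {
    abort("provide either `counts` or `de_table`",
          class = "methexpr_validation_error")
  }
  with(cfg, stopifnot(
    min_coverage >= 1, level > 0, level < 1, alpha > 0, alpha < 1,
    max_gap >= 0, min_sites >= 1, flank >= 0, dispersion >= 0,
    p_cutoff > 0, p_cutoff < 1, fc_up > 0, fc_down > 0, logfc_base > 1
  ))
  invisible(cfg)
}

#' Run the full methylation-expression association pipeline
#'
#' Reads the four pileups, computes per-site contrasts for both pairs,
#' flags and segments significant sites, reconciles the pairs into
#' consensus regions, assigns regions to promoters and gene bodies,
#' classifies genes, derives DE classes, and crosses the two. Writes the
#' per-site contrast TSV, one BED per pair plus the consensus BED, the
#' gene-status TSV, the DE TSV, the association JSON, the per-intersection
#' gene lists and a run manifest (parameters and input checksums).
#' Identical inputs and configuration give byte-identical outputs. Stage
#' progress is reported with per-stage record counts.
#'
#' @param config A [pipeline_config()].
#' @return The `assoc_report`, invisibly; its attribute `"paths"` names
#'   every artifact written.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  validate_pipeline_config(config)
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  stage <- function(...) inform(sprintf(...))

  meta <- tibble(
    sample = c("ctrl_male", "as_male", "ctrl_female", "as_female"),
    pair = c("male", "male", "female", "female"),
    group = c("ctrl", "as", "ctrl", "as")
  )
  pileups <- purrr::pmap_dfr(meta, function(sample, pair, group) {
    read_cytosine_report(config$pileups[[sample]], sample, pair, group,
                         call_convention = config$call_convention)
  })
  stage("read %d pileup rows from 4 samples", nrow(pileups))

  contrasts <- site_contrasts(pileups, min_coverage = config$min_coverage,
                              level = config$level)
  stage("retained %d sites per pair after the coverage filter (min %d)",
        nrow(contrasts) / 2, config$min_coverage)

  flagged <- flag_sites(contrasts, alpha = config$alpha)
  regions <- segment_regions(flagged, max_gap = config$max_gap,
                             min_sites = config$min_sites)
  consensus <- reconcile_pairs(regions)
  stage("%d pair regions, %d consensus regions",
        nrow(regions), nrow(consensus))

  genes <- load_annotation(config$annotation, flank = config$flank,
                           dialect = config$annotation_dialect)
  hits <- assign_regions(consensus, genes)
  status <- classify_genes(hits, genes)
  stage("%d genes annotated, %d feature hits", nrow(genes), nrow(hits))

  de <- if (!is.null(config$de_table)) {
    read_de_table(config$de_table, logfc_base = config$logfc_base,
                  p_cutoff = config$p_cutoff, fc_up = config$fc_up,
                  fc_down = config$fc_down)
  } else {
    counts <- read_counts_tsv(config$counts)
    samples <- setdiff(names(counts), "gene_id")
    groups <- setNames(ifelse(grepl("^ctrl", samples), "ctrl", "as"), samples)
    de_test(counts, groups, dispersion = config$dispersion,
            p_cutoff = config$p_cutoff, fc_up = config$fc_up,
            fc_down = config$fc_down)
  }
  stage("DE: %d genes, %d up, %d down", nrow(de$table),
        sum(de$table$de_class == "up"), sum(de$table$de_class == "down"))

  report <- cross_association(status, de, hits = hits)

  paths <- c(
    contrasts = file.path(config$out_dir, "site_contrasts.tsv"),
    regions_male = file.path(config$out_dir, "regions_male.bed"),
    regions_female = file.path(config$out_dir, "regions_female.bed"),
    consensus = file.path(config$out_dir, "consensus.bed"),
    gene_status = file.path(config$out_dir, "gene_status.tsv"),
    de = file.path(config$out_dir, "de_table.tsv"),
    association = file.path(config$out_dir, "association.json"),
    manifest = file.path(config$out_dir, "manifest.yaml")
  )
  readr::write_tsv(contrasts, paths[["contrasts"]])
  write_regions_bed(regions %>% filter(.data$pair == "male"),
                    paths[["regions_male"]])
  write_regions_bed(regions %>% filter(.data$pair == "female"),
                    paths[["regions_female"]])
  write_regions_bed(consensus, paths[["consensus"]])
  readr::write_tsv(status, paths[["gene_status"]])
  write_de_tsv(de, paths[["de"]])
  write_association_report(report, paths[["association"]])
  write_gene_lists(report, file.path(config$out_dir, "gene_lists"))

  inputs <- c(config$pileups, annotation = config$annotation,
              counts = config$counts, de_table = config$de_table)
  manifest <- list(
    parameters = unclass(config)[setdiff(names(config),
                                         c("pileups", "annotation", "counts",
                                           "de_table", "out_dir"))],
    inputs = as.list(setNames(unname(tools::md5sum(unlist(inputs))),
                              names(inputs)))
  )
  yaml::write_yaml(manifest, paths[["manifest"]])

  attr(report, "paths") <- paths
  invisible(report)
}
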