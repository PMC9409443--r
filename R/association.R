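#' Cross gene methylation status with differential expression
#'
#' Builds the per-gene joined record table and the association report:
#' category counts, the six Venn-style intersection gene lists
#' (promoter hyper/hypo against down/up, unique gene-body hyper/hypo
#' against up/down) and the derived summary identities. Counts follow the
#' mixed reporting convention in which promoter categories are counted as
#' consensus REGIONS (when `hits` is supplied; as genes otherwise, with the
#' unit labelled) while gene-body categories are counted as GENES with a
#' unique signal. Mixed-body genes are excluded from the body
#' intersections. Genes present in the DE table but absent from the
#' annotation are counted and reported, never fatal.
#'
#' @param status Gene-status tibble from [classify_genes()].
#' @param de A `de_fit` or its tidied DE tibble.
#' @param hits Optional hit tibble from [assign_regions()]; enables
#'   region-unit promoter counts.
#' @return An object of class `assoc_report` with elements `records`,
#'   `counts`, `intersections`, `identities`, `n_unmatched_de`.
#' @export
cross_association <- function(status, de, hits = NULL) {
  de_table <- if (inherits(de, "de_fit")) de$table else de
  stopifnot(all(c("gene_id", "de_class") %in% names(de_table)))

  unmatched <- setdiff(de_table$gene_id, status$gene_id)
  if (length(unmatched) > 0) {
    inform(sprintf("%d DE gene(s) absent from the annotation were left out of the association",
                   length(unmatched)))
  }
  records <- status %>%
    left_join(de_table %>% select("gene_id", "de_class",
                                  dplyr::any_of("exclusivity")),
              by = "gene_id") %>%
    mutate(de_class = .data$de_class %|NA|% "ns")
  if (!"exclusivity" %in% names(records)) records$exclusivity <- "none"
  records$exclusivity <- records$exclusivity %|NA|% "none"

  gene_set <- function(cond) sort(records$gene_id[cond])
  prom_hyper <- gene_set(records$promoter_status %in% c("hyper", "both"))
  prom_hypo <- gene_set(records$promoter_status %in% c("hypo", "both"))
  body_hyper <- gene_set(records$body_status == "unique_hyper")
  body_hypo <- gene_set(records$body_status == "unique_hypo")
  up <- gene_set(records$de_class == "up")
  down <- gene_set(records$de_class == "down")

  if (!is.null(hits)) {
    prom_hits <- hits %>% filter(.data$feature == "promoter")
    n_prom_hyper <- n_distinct(prom_hits$region_id[prom_hits$direction == "hyper"])
    n_prom_hypo <- n_distinct(prom_hits$region_id[prom_hits$direction == "hypo"])
    prom_unit <- "regions"
  } else {
    n_prom_hyper <- length(prom_hyper)
    n_prom_hypo <- length(prom_hypo)
    prom_unit <- "genes"
  }
  counts <- tibble(
    category = c("promoter_hyper", "promoter_hypo", "body_unique_hyper",
                 "body_unique_hypo", "body_mixed"),
    unit = c(prom_unit, prom_unit, "genes", "genes", "genes"),
    n = c(n_prom_hyper, n_prom_hypo, length(body_hyper), length(body_hypo),
          sum(records$body_status == "mixed"))
  )
  intersections <- list(
    promoter_hyper_down = intersect(prom_hyper, down),
    promoter_hypo_up = intersect(prom_hypo, up),
    body_hyper_down = intersect(body_hyper, down),
    body_hyper_up = intersect(body_hyper, up),
    body_hypo_up = intersect(body_hypo, up),
    body_hypo_down = intersect(body_hypo, down)
  )
  identities <- identity_check(
    promoter_hyper = n_prom_hyper, promoter_hypo = n_prom_hypo,
    body_hyper = length(body_hyper), body_hypo = length(body_hypo),
    n_up = length(up), n_down = length(down)
  )
  structure(
    list(records = records, counts = counts, intersections = intersections,
         identities = identities, n_unmatched_de = length(unmatched)),
    class = "assoc_report"
  )
}

#' Summary identities over the DM categories and DE counts
#'
#' The report's arithmetic: the total number of differentially methylated
#' elements is the sum of the four category counts (promoter hyper/hypo
#' regions plus unique-body hyper/hypo genes); the hypo share is the
#' hypo-methylated fraction of that total, in percent rounded to the
#' nearest integer; the up share is the upregulated percentage of all DE
#' genes. Inconsistent inputs (negative counts) are an error; a zero total
#' or zero DE genes yields NA shares with a warning rather than a silent
#' pass.
#'
#' @param promoter_hyper,promoter_hypo Promoter category counts.
#' @param body_hyper,body_hypo Unique gene-body category counts.
#' @param n_up,n_down Numbers of up- and downregulated genes.
#' @return One-row tibble: `total_dm`, `n_hypo`, `hypo_share_pct`,
#'   `n_de`, `up_share_pct`.
#' @export
#' @examples
#' identity_check(34, 625, 1257, 8772, n_up = 209, n_down = 31)
identity_check <- function(promoter_hyper, promoter_hypo, body_hyper,
                           body_hypo, n_up, n_down) {
  counts <- c(promoter_hyper, promoter_hypo, body_hyper, body_hypo,
              n_up, n_down)
  stopifnot(length(counts) == 6, all(!is.na(counts)))
  if (any(counts < 0)) abort("category counts must be non-negative")
  total <- promoter_hyper + promoter_hypo + body_hyper + body_hypo
  n_hypo <- promoter_hypo + body_hypo
  n_de <- n_up + n_down
  if (total == 0 || n_de == 0) {
    warn("empty category or DE counts; shares are NA")
  }
  tibble(
    total_dm = total,
    n_hypo = n_hypo,
    hypo_share_pct = if (total > 0) round(100 * n_hypo / total) else NA_real_,
    n_de = n_de,
    up_share_pct = if (n_de > 0) round(100 * n_up / n_de) else NA_real_
  )
}

#' @export
print.assoc_report <- function(x, ...) {
  cat("<assoc_report>\n")
  print(x$counts)
  cat("intersections:",
      paste(sprintf("%s=%d", names(x$intersections),
                    lengths(x$intersections)), collapse = ", "), "\n")
  print(x$identities)
  invisible(x)
}

#' @rdname cross_association
#' @param x An `assoc_report`.
#' @param ... Unused.
#' @export
tidy.assoc_report <- function(x, ...) x$counts

#' @rdname cross_association
#' @export
glance.assoc_report <- function(x, ...) {
  dplyr::bind_cols(
    x$identities,
    tibble(n_unmatched_de = x$n_unmatched_de,
           n_genes = nrow(x$records))
  )
}

#' @rdname cross_association
#' @param object An `assoc_report`.
#' @export
autoplot.assoc_report <- function(object, ...) {
  d <- object$counts %>%
    mutate(direction = if_else(grepl("hypo", .data$category), "hypo",
                               if_else(grepl("hyper", .data$category),
                                       "hyper", "mixed")))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$category, y = .data$n,
                                  fill = .data$direction)) +
    ggplot2::geom_col() +
    ggplot2::scale_fill_manual(values = c(hyper = "firebrick",
                                          hypo = "steelblue",
                                          mixed = "grey50")) +
    ggplot2::labs(x = NULL, y = "count", fill = NULL) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Serialise / deserialise an association report as JSON
#'
#' The round trip is lossless for counts, intersections, identities and
#' the per-gene records.
#'
#' @param report An `assoc_report`.
#' @param path JSON file path.
#' @return `write_association_report()` returns `path` invisibly;
#'   `read_association_report()` returns the `assoc_report`.
#' @export
write_association_report <- function(report, path) {
  stopifnot(inherits(report, "assoc_report"))
  payload <- list(
    counts = report$counts,
    intersections = report$intersections,
    identities = report$identities,
    n_unmatched_de = report$n_unmatched_de,
    records = report$records
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_association_report
#' @export
read_association_report <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  inter <- lapply(x$intersections, function(v) sort(as.character(unlist(v))))
  structure(
    list(records = as_tibble(x$records),
         counts = as_tibble(x$counts),
         intersections = inter,
         identities = as_tibble(x$identities),
         n_unmatched_de = x$n_unmatched_de),
    class = "assoc_report"
  )
}

#' Write the Venn-category gene lists as plain text
#'
#' One file per intersection, one gene per line, lexicographically sorted.
#'
#' @param report An `assoc_report`.
#' @param dir Output directory.
#' @return Named vector of paths.
#' @export
write_gene_lists <- function(report, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- setNames(
    file.path(dir, paste0(names(report$intersections), ".txt")),
    names(report$intersections)
  )
  for (nm in names(report$intersections)) {
    writeLines(report$intersections[[nm]], paths[[nm]])
  }
  paths
}
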