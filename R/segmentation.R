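#' Flag significant sites with their direction
#'
#' Applies the per-site significance threshold to the slope z-score:
#' a site is flagged hyper when z >= z_crit and hypo when z <= -z_crit,
#' with z_crit the two-sided normal quantile for `alpha`. Comparisons are
#' inclusive so boundary behaviour is deterministic. Input must already be
#' sorted by (pair, chrom, pos) — sorting is the importer's contract, and
#' unsorted input is an error rather than silently reordered.
#'
#' @param contrasts Output of [site_contrasts()].
#' @param alpha Two-sided significance level; default 0.05.
#' @return The input with an added `flag` column (`"hyper"`, `"hypo"` or
#'   `NA`).
#' @export
flag_sites <- function(contrasts, alpha = 0.05) {
  stopifnot(alpha > 0, alpha < 1)
  ord <- order(contrasts$pair, contrasts$chrom, contrasts$pos)
  if (!identical(ord, seq_len(nrow(contrasts)))) {
    abort("`contrasts` must be sorted by (pair, chrom, pos)",
          class = "methexpr_unsorted_input")
  }
  z_crit <- qnorm(1 - alpha / 2)
  contrasts %>% mutate(
    flag = case_when(.data$z >= z_crit ~ "hyper",
                     .data$z <= -z_crit ~ "hypo",
                     TRUE ~ NA_character_)
  )
}

#' Segment flagged sites into methylated regions
#'
#' Stand-in for published genome segmentation: within each pair,
#' chromosome and direction, maximal runs of same-direction flagged sites
#' in which consecutive flagged sites lie at most `max_gap` bp apart are
#' merged into one region; runs with fewer than `min_sites` sites are
#' dropped. The region interval spans the first through last contributing
#' site inclusive (emitted 0-based half-open), and the region score is the
#' Stouffer combination of the contributing z-scores,
#' sum(z) / sqrt(n_sites). Opposite-direction sites in between do not break
#' a run; only distance does.
#'
#' @param flagged Output of [flag_sites()].
#' @param max_gap Maximum distance (bp) between consecutive flagged sites
#'   of a run; default 500.
#' @param min_sites Minimum number of sites per region; default 3.
#' @return Tibble of regions: `pair`, `chrom`, `start`, `end` (0-based
#'   half-open), `direction`, `n_sites`, `region_z`, sorted and disjoint
#'   within each (pair, direction) track.
#' @export
segment_regions <- function(flagged, max_gap = 500, min_sites = 3) {
  stopifnot("flag" %in% names(flagged), max_gap >= 0, min_sites >= 1)
  sig <- flagged %>% filter(!is.na(.data$flag))
  if (nrow(sig) == 0) return(empty_regions())
  sig %>%
    group_by(.data$pair, .data$chrom, direction = .data$flag) %>%
    arrange(.data$pos, .by_group = TRUE) %>%
    mutate(run = cumsum(c(0, diff(.data$pos) > max_gap))) %>%
    group_by(.data$pair, .data$chrom, .data$direction, .data$run) %>%
    summarise(start = min(.data$pos) - 1, end = max(.data$pos),
              n_sites = dplyr::n(),
              region_z = sum(.data$z) / sqrt(dplyr::n()), .groups = "drop") %>%
    filter(.data$n_sites >= min_sites) %>%
    select("pair", "chrom", "start", "end", "direction", "n_sites",
           "region_z") %>%
    arrange(.data$pair, .data$chrom, .data$start)
}

empty_regions <- function() {
  tibble(pair = character(), chrom = character(), start = numeric(),
         end = numeric(), direction = character(), n_sites = integer(),
         region_z = numeric())
}

#' Reconcile the male and female pairs into consensus regions
#'
#' A genomic stretch counts as differentially methylated only when it is
#' called in the same direction in both sex-matched pairs: the consensus
#' track is the interval intersection of same-direction regions from the
#' two pairs. Opposite-direction overlaps are discarded. The consensus
#' interval is the overlap itself, its site support is the smaller of the
#' two parents' and its score the Stouffer combination of the two parent
#' scores.
#'
#' @param regions Region tibble from [segment_regions()] containing both
#'   pairs, or two tibbles via `regions` and `regions2`.
#' @param regions2 Optional second pair's regions (then `regions` holds the
#'   first pair's only).
#' @return Consensus region tibble with `pair = "consensus"`.
#' @export
reconcile_pairs <- function(regions, regions2 = NULL) {
  if (!is.null(regions2)) {
    regions <- bind_rows(
      regions %>% mutate(pair = "male"),
      regions2 %>% mutate(pair = "female")
    )
  }
  pairs <- setdiff(unique(regions$pair), "consensus")
  if (length(pairs) != 2) {
    abort(sprintf("expected regions from exactly two pairs, got: %s",
                  paste(pairs, collapse = ", ")))
  }
  a <- regions %>% filter(.data$pair == pairs[1])
  b <- regions %>% filter(.data$pair == pairs[2])
  if (nrow(a) == 0 || nrow(b) == 0) return(empty_regions())

  ga <- regions_to_granges(a)
  gb <- regions_to_granges(b)
  hits <- GenomicRanges::findOverlaps(ga, gb)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  same <- a$direction[qi] == b$direction[si]
  qi <- qi[same]; si <- si[same]
  if (length(qi) == 0) return(empty_regions())

  tibble(
    pair = "consensus",
    chrom = a$chrom[qi],
    start = pmax(a$start[qi], b$start[si]),
    end = pmin(a$end[qi], b$end[si]),
    direction = a$direction[qi],
    n_sites = pmin(a$n_sites[qi], b$n_sites[si]),
    region_z = (a$region_z[qi] + b$region_z[si]) / sqrt(2)
  ) %>%
    arrange(.data$chrom, .data$start, .data$direction)
}

# internal 0-based half-open -> GRanges (1-based closed)
regions_to_granges <- function(x) {
  GenomicRanges::GRanges(
    seqnames = x$chrom,
    ranges = IRanges::IRanges(start = x$start + 1, end = x$end)
  )
}

#' Sensitivity and precision of consensus regions against planted truth
#'
#' An element counts as recovered when a consensus region of the correct
#' direction overlaps it by at least 1 bp; a consensus region counts as a
#' true call when it overlaps a same-direction planted element.
#'
#' @param consensus Consensus regions from [reconcile_pairs()].
#' @param elements Planted-element tibble (the `elements` of a
#'   `truth_plan`): `chrom`, `start`, `end`, `direction`.
#' @return One-row tibble: `n_elements`, `n_regions`, `n_recovered`,
#'   `n_true_calls`, `sensitivity`, `precision`.
#' @export
evaluate_recovery <- function(consensus, elements) {
  if (nrow(elements) == 0 || nrow(consensus) == 0) {
    return(tibble(n_elements = nrow(elements), n_regions = nrow(consensus),
                  n_recovered = 0L, n_true_calls = 0L,
                  sensitivity = NA_real_, precision = NA_real_))
  }
  ge <- regions_to_granges(elements)
  gc <- regions_to_granges(consensus)
  hits <- GenomicRanges::findOverlaps(ge, gc)
  same <- elements$direction[S4Vectors::queryHits(hits)] ==
    consensus$direction[S4Vectors::subjectHits(hits)]
  rec <- unique(S4Vectors::queryHits(hits)[same])
  tru <- unique(S4Vectors::subjectHits(hits)[same])
  tibble(
    n_elements = nrow(elements), n_regions = nrow(consensus),
    n_recovered = length(rec), n_true_calls = length(tru),
    sensitivity = length(rec) / nrow(elements),
    precision = length(tru) / nrow(consensus)
  )
}
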