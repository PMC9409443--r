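#' Simulate a genome: site map and gene annotation
#'
#' Places assayed cytosine sites as a homogeneous Poisson process along each
#' chromosome and lays out non-overlapping genes with strand-aware TSS and
#' promoter windows. Coordinates are 0-based half-open for intervals and
#' 1-based for site positions (matching cytosine-report files).
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_genome` with elements
#'   * `sites`: tibble (`chrom`, `pos` 1-based, `strand`),
#'   * `genes`: tibble (`gene_id`, `chrom`, `start`, `end`, `strand`, `tss`,
#'     `promoter_start`, `promoter_end`),
#'   * `chrom_lengths`: named numeric vector.
#' @export
#' @examples
#' g <- simulate_genome(sim_config(n_genes = 4, chrom_length = 1e5, seed = 1))
#' g$genes
simulate_genome <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  chroms <- sprintf("chr%d", seq_len(config$n_chromosomes))
  chrom_lengths <- setNames(rep(config$chrom_length, length(chroms)), chroms)

  sites <- purrr::map_dfr(chroms, function(ch) {
    n <- rpois(1, config$site_density * config$chrom_length / 1000)
    n <- min(n, config$chrom_length)
    pos <- sort(sample.int(config$chrom_length, n))
    tibble(chrom = ch, pos = pos,
           strand = sample(c("+", "-"), n, replace = TRUE))
  })

  genes <- simulate_gene_layout(config, chroms)
  structure(list(sites = sites, genes = genes, chrom_lengths = chrom_lengths),
            class = "sim_genome")
}

simulate_gene_layout <- function(config, chroms) {
  empty <- tibble(gene_id = character(), chrom = character(),
                  start = numeric(), end = numeric(), strand = character(),
                  tss = numeric(), promoter_start = numeric(),
                  promoter_end = numeric())
  if (config$n_genes == 0) return(empty)
  per_chrom <- diff(round(seq(0, config$n_genes,
                              length.out = config$n_chromosomes + 1)))
  flank <- config$promoter_flank
  max_len <- config$gene_length_range[2]
  out <- vector("list", config$n_chromosomes)
  idx <- 0L
  for (ci in seq_along(chroms)) {
    k <- per_chrom[ci]
    if (k == 0) next
    slot <- floor(config$chrom_length / k)
    if (slot < max_len + 2 * flank + 2) {
      abort(sprintf(
        "chromosome %s (length %g) is too short to host %d genes of up to %d bp plus %d bp promoter flanks",
        chroms[ci], config$chrom_length, k, max_len, flank),
        class = "methexpr_config_error")
    }
    len <- sample(seq(config$gene_length_range[1], max_len), k, replace = TRUE)
    offset <- (seq_len(k) - 1) * slot
    room <- slot - len - 2 * flank - 1
    start <- offset + flank + floor(runif(k) * (room + 1))
    strand <- sample(c("+", "-"), k, replace = TRUE)
    g <- tibble(
      gene_id = sprintf("g%05d", idx + seq_len(k)),
      chrom = chroms[ci],
      start = start, end = start + len, strand = strand
    )
    idx <- idx + k
    out[[ci]] <- g
  }
  genes <- bind_rows(out)
  add_promoters(genes, flank, config$chrom_length)
}

# tss/promoter from 0-based half-open gene bodies; promoter = tss +/- flank,
# one position wide at flank = 0, clipped at chromosome bounds
add_promoters <- function(genes, flank, chrom_length) {
  genes %>%
    mutate(
      tss = if_else(.data$strand == "+", .data$start, .data$end - 1),
      promoter_start = pmax(0, .data$tss - flank),
      promoter_end = pmin(chrom_length, .data$tss + flank + 1)
    )
}

#' Plan the ground truth of a simulation
#'
#' Chooses which genes carry planted differential-methylation elements
#' (their promoter window or gene body, hyper or hypo) and which genes are
#' planted differentially expressed. With `coupling_prob`, promoter-hypo
#' genes are preferentially planted up-regulated. Directions are shared by
#' both sex-matched pairs by construction.
#'
#' @param genome A `sim_genome` from [simulate_genome()].
#' @param config The same [sim_config()].
#' @return A list of class `truth_plan`:
#'   * `elements`: tibble (`gene_id`, `kind` promoter|body, `direction`
#'     hyper|hypo, `chrom`, `start`, `end`) — empty when `effect_delta` is 0;
#'   * `genes`: tibble (`gene_id`, `de_class` up|down|ns, `fc`, `coupled`).
#' @export
plan_truth <- function(genome, config) {
  stopifnot(inherits(genome, "sim_genome"))
  set.seed(config$seed + 11L)
  genes <- genome$genes
  ng <- nrow(genes)

  n_hyper <- round(config$frac_hyper * ng)
  n_hypo <- round(config$frac_hypo * ng)
  if (config$effect_delta == 0) {
    n_hyper <- 0L
    n_hypo <- 0L
  }
  dm_ids <- if (n_hyper + n_hypo > 0) {
    sample(genes$gene_id, n_hyper + n_hypo)
  } else character()
  elements <- tibble(
    gene_id = dm_ids,
    kind = sample(c("promoter", "body"), length(dm_ids), replace = TRUE),
    direction = rep(c("hyper", "hypo"), c(n_hyper, n_hypo))
  ) %>%
    left_join(genes, by = "gene_id") %>%
    mutate(
      start = if_else(.data$kind == "promoter", .data$promoter_start, .data$start),
      end = if_else(.data$kind == "promoter", .data$promoter_end, .data$end)
    ) %>%
    select("gene_id", "kind", "direction", "chrom", "start", "end")

  # expression truth: coupled promoter-hypo genes fill the up quota first
  de <- tibble(gene_id = genes$gene_id, de_class = "ns", fc = 1,
               coupled = FALSE)
  if (config$planted_fc != 1 && ng > 0) {
    promoter_hypo <- elements$gene_id[elements$kind == "promoter" &
                                        elements$direction == "hypo"]
    coupled_ids <- promoter_hypo[runif(length(promoter_hypo)) < config$coupling_prob]
    n_up <- max(round(config$frac_up * ng), length(coupled_ids))
    pool_up <- setdiff(genes$gene_id, coupled_ids)
    extra_up <- if (n_up > length(coupled_ids)) {
      sample(pool_up, n_up - length(coupled_ids))
    } else character()
    up_ids <- c(coupled_ids, extra_up)
    n_down <- round(config$frac_down * ng)
    pool_down <- setdiff(genes$gene_id, up_ids)
    down_ids <- if (n_down > 0) {
      sample(pool_down, min(n_down, length(pool_down)))
    } else character()
    de <- de %>% mutate(
      de_class = case_when(.data$gene_id %in% .env$up_ids ~ "up",
                           .data$gene_id %in% .env$down_ids ~ "down",
                           TRUE ~ "ns"),
      fc = case_when(.data$de_class == "up" ~ config$planted_fc,
                     .data$de_class == "down" ~ 1 / config$planted_fc,
                     TRUE ~ 1),
      coupled = .data$gene_id %in% .env$coupled_ids
    )
  }
  structure(list(elements = elements, genes = de), class = "truth_plan")
}

#' Simulate bisulfite methylation count tracks for two sample pairs
#'
#' Draws, for each of the four samples (control/case in a male and a female
#' pair), per-site read coverage from Poisson(`coverage_mean`) and
#' methylated-call counts from Binomial(coverage, f). The per-site baseline
#' frequency f is Beta-distributed and shared by all samples; inside planted
#' elements the case samples' frequency is shifted by `effect_delta` on the
#' logit scale (up for hyper, down for hypo), identically in both pairs.
#' Sites with zero coverage are kept so that downstream filtering is
#' exercised. Each track draws from its own RNG stream derived from
#' (master seed, track index).
#'
#' @param genome A `sim_genome`.
#' @param truth A `truth_plan` from [plan_truth()].
#' @param config The same [sim_config()].
#' @return A long tibble with one row per site and sample: `sample`, `pair`
#'   (male|female), `group` (ctrl|as), `chrom`, `pos`, `strand`, `meth`,
#'   `cov`.
#' @export
simulate_methylation <- function(genome, truth, config) {
  stopifnot(inherits(genome, "sim_genome"), inherits(truth, "truth_plan"))
  validate_sim_config(config)
  sites <- genome$sites
  n <- nrow(sites)

  set.seed(config$seed + 22L)
  f_base <- rbeta(n, config$baseline_meth_alpha, config$baseline_meth_beta)
  f_base <- pmin(pmax(f_base, 1e-12), 1 - 1e-12)

  shift <- numeric(n)
  if (nrow(truth$elements) > 0) {
    for (ch in unique(truth$elements$chrom)) {
      el <- truth$elements[truth$elements$chrom == ch, ]
      in_ch <- which(sites$chrom == ch)
      pos <- sites$pos[in_ch]
      for (i in seq_len(nrow(el))) {
        # 1-based pos lies in 0-based half-open [start, end) iff start < pos <= end
        hit <- pos > el$start[i] & pos <= el$end[i]
        shift[in_ch[hit]] <- if (el$direction[i] == "hyper")
          config$effect_delta else -config$effect_delta
      }
    }
  }
  f_case <- plogis(qlogis(f_base) + shift)

  tracks <- tibble(
    track = 1:4,
    sample = c("ctrl_male", "as_male", "ctrl_female", "as_female"),
    pair = c("male", "male", "female", "female"),
    group = c("ctrl", "as", "ctrl", "as")
  )
  purrr::pmap_dfr(tracks, function(track, sample, pair, group) {
    set.seed(config$seed + 7919L * track)
    f <- if (group == "as") f_case else f_base
    cov <- rpois(n, config$coverage_mean)
    tibble(sample = sample, pair = pair, group = group,
           chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
           meth = rbinom(n, cov, f), cov = cov)
  })
}

#' Simulate a gene-by-sample expression count matrix
#'
#' Negative-binomial counts for two control and two case samples, with
#' baseline means drawn log-uniformly and planted fold changes taken from
#' the truth plan (`planted_fc` for up genes, its reciprocal for down).
#'
#' @param genes Gene annotation tibble (the `genes` element of a
#'   `sim_genome`).
#' @param truth A `truth_plan`.
#' @param config The same [sim_config()].
#' @return A tibble with `gene_id` and integer count columns `ctrl_1`,
#'   `ctrl_2`, `as_1`, `as_2`.
#' @export
simulate_expression <- function(genes, truth, config) {
  stopifnot(inherits(truth, "truth_plan"), nrow(genes) > 0)
  set.seed(config$seed + 33L)
  ng <- nrow(genes)
  mu0 <- exp(runif(ng, config$expr_mean_log_range[1],
                   config$expr_mean_log_range[2]))
  fc <- truth$genes$fc[match(genes$gene_id, truth$genes$gene_id)]
  fc[is.na(fc)] <- 1
  draw <- function(mu) {
    if (config$expr_dispersion > 0) {
      rnbinom(ng, mu = mu, size = 1 / config$expr_dispersion)
    } else {
      rpois(ng, mu)
    }
  }
  tibble(
    gene_id = genes$gene_id,
    ctrl_1 = draw(mu0), ctrl_2 = draw(mu0),
    as_1 = draw(mu0 * fc), as_2 = draw(mu0 * fc)
  )
}

#' Default sample-to-group map for simulated counts
#'
#' @return Named character vector mapping the count columns produced by
#'   [simulate_expression()] to their group labels.
#' @export
simulated_groups <- function() {
  c(ctrl_1 = "ctrl", ctrl_2 = "ctrl", as_1 = "as", as_2 = "as")
}
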