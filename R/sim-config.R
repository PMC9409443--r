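#' Simulation configuration
#'
#' Bundles every knob of the synthetic whole-genome bisulfite + expression
#' generator. Defaults describe the conditions the pipeline is exercised
#' under: a small two-chromosome genome, CpG-like sites at ~10 per kb,
#' Poisson read coverage, a Beta(2, 2) baseline methylation frequency per
#' site, and a strong planted effect (a shift of 2 on the logit of the
#' methylation frequency) in the case samples of both sex-matched pairs.
#'
#' @param n_chromosomes Number of chromosomes.
#' @param chrom_length Length of each chromosome in bp.
#' @param site_density Expected number of assayed cytosine sites per kb
#'   (sites are a homogeneous Poisson process along each chromosome).
#' @param n_genes Number of non-overlapping genes to place.
#' @param gene_length_range Length-2 integer vector, min/max gene length (bp).
#' @param promoter_flank Half-width of the promoter window around the
#'   strand-aware TSS, in bp (promoter = TSS +/- flank).
#' @param coverage_mean Poisson mean read coverage per site per sample.
#'   Must be > 0; individual sites may still draw coverage 0.
#' @param baseline_meth_alpha,baseline_meth_beta Beta shape parameters for
#'   the per-site baseline methylation frequency (shared by all samples).
#' @param effect_delta Additive shift applied on the logit of the baseline
#'   frequency inside planted elements of the case (AS) samples; >= 0.
#'   Hyper elements shift by +effect_delta, hypo by -effect_delta. 0 means
#'   no elements are planted.
#' @param frac_hyper,frac_hypo Fraction of genes planted with a
#'   hyper-/hypo-methylated element (each gene gets at most one element,
#'   randomly its promoter or its gene body).
#' @param frac_up,frac_down Fraction of genes planted as differentially
#'   expressed up/down (coupled promoter-hypo genes fill the up quota first).
#' @param expr_mean_log_range Length-2 numeric, range of log baseline
#'   expression means (means drawn log-uniformly).
#' @param expr_dispersion Negative-binomial dispersion (variance =
#'   mu + dispersion * mu^2); 0 gives Poisson counts.
#' @param planted_fc Linear fold change of planted up genes (down genes get
#'   1/planted_fc); 1 disables expression planting entirely.
#' @param coupling_prob Probability that a gene planted with a
#'   promoter-hypo element is also planted up-regulated.
#' @param seed Master RNG seed. Each of the four methylation tracks derives
#'   its own stream from (seed, track index), so adding samples never
#'   reshuffles existing ones.
#'
#' @return An object of class `sim_config` (a validated named list).
#' @export
#' @examples
#' cfg <- sim_config(n_genes = 10, chrom_length = 2e5, seed = 7)
#' cfg$coverage_mean
sim_config <- function(n_chromosomes = 2,
                       chrom_length = 2e6,
                       site_density = 10,
                       n_genes = 200,
                       gene_length_range = c(2000L, 8000L),
                       promoter_flank = 1000,
                       coverage_mean = 30,
                       baseline_meth_alpha = 2,
                       baseline_meth_beta = 2,
                       effect_delta = 2,
                       frac_hyper = 0.125,
                       frac_hypo = 0.125,
                       frac_up = 0.05,
                       frac_down = 0.05,
                       expr_mean_log_range = log(c(100, 400)),
                       expr_dispersion = 0.1,
                       planted_fc = 4,
                       coupling_prob = 0.5,
                       seed = 1L) {
  cfg <- list(
    n_chromosomes = as.integer(n_chromosomes),
    chrom_length = as.numeric(chrom_length),
    site_density = as.numeric(site_density),
    n_genes = as.integer(n_genes),
    gene_length_range = as.integer(gene_length_range),
    promoter_flank = as.integer(promoter_flank),
    coverage_mean = as.numeric(coverage_mean),
    baseline_meth_alpha = as.numeric(baseline_meth_alpha),
    baseline_meth_beta = as.numeric(baseline_meth_beta),
    effect_delta = as.numeric(effect_delta),
    frac_hyper = as.numeric(frac_hyper),
    frac_hypo = as.numeric(frac_hypo),
    frac_up = as.numeric(frac_up),
    frac_down = as.numeric(frac_down),
    expr_mean_log_range = as.numeric(expr_mean_log_range),
    expr_dispersion = as.numeric(expr_dispersion),
    planted_fc = as.numeric(planted_fc),
    coupling_prob = as.numeric(coupling_prob),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  stopifnot(
    cfg$n_chromosomes >= 1,
    cfg$chrom_length >= 1,
    cfg$site_density > 0,
    cfg$n_genes >= 0,
    length(cfg$gene_length_range) == 2,
    cfg$gene_length_range[1] >= 1,
    cfg$gene_length_range[1] <= cfg$gene_length_range[2],
    cfg$promoter_flank >= 0,
    cfg$baseline_meth_alpha > 0,
    cfg$baseline_meth_beta > 0,
    length(cfg$expr_mean_log_range) == 2,
    cfg$expr_mean_log_range[1] <= cfg$expr_mean_log_range[2],
    cfg$expr_dispersion >= 0,
    cfg$planted_fc > 0,
    !is.na(cfg$seed)
  )
  if (!(cfg$coverage_mean > 0)) {
    abort("`coverage_mean` must be > 0.", class = "methexpr_config_error")
  }
  if (cfg$effect_delta < 0) {
    abort("`effect_delta` must be >= 0.", class = "methexpr_config_error")
  }
  fracs <- c(cfg$frac_hyper, cfg$frac_hypo, cfg$frac_up, cfg$frac_down,
             cfg$coupling_prob)
  if (any(fracs < 0 | fracs > 1)) {
    abort("All fractions and probabilities must lie in [0, 1].",
          class = "methexpr_config_error")
  }
  if (cfg$frac_hyper + cfg$frac_hypo > 1) {
    abort("`frac_hyper + frac_hypo` must not exceed 1.",
          class = "methexpr_config_error")
  }
  invisible(cfg)
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  for (nm in names(x)) {
    cat(sprintf("  %-20s %s\n", nm, paste(format(x[[nm]]), collapse = ", ")))
  }
  invisible(x)
}

#' Write / read a simulation configuration as YAML
#'
#' @param config A [sim_config()] object.
#' @param path File path.
#' @return `write_sim_config()` returns `path` invisibly;
#'   `read_sim_config()` returns a `sim_config`.
#' @export
write_sim_config <- function(config, path) {
  stopifnot(inherits(config, "sim_config"))
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_sim_config
#' @export
read_sim_config <- function(path) {
  do.call(sim_config, yaml::read_yaml(path))
}
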