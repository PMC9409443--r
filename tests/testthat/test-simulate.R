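test_that("the generator is deterministic for a fixed seed", {
  cfg <- tiny_config()
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(g1, g2)
  t1 <- plan_truth(g1, cfg)
  expect_identical(t1, plan_truth(g2, cfg))
  expect_identical(simulate_methylation(g1, t1, cfg),
                   simulate_methylation(g1, t1, cfg))
  expect_identical(simulate_expression(g1$genes, t1, cfg),
                   simulate_expression(g1$genes, t1, cfg))
})

test_that("a genome without genes still has sites", {
  cfg <- tiny_config(n_genes = 0)
  g <- simulate_genome(cfg)
  expect_equal(nrow(g$genes), 0)
  expect_gt(nrow(g$sites), 0)
})

test_that("site counts follow the Poisson intensity", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e5, site_density = 1,
                    n_genes = 0, seed = 8)
  n <- nrow(simulate_genome(cfg)$sites)
  # mean 100, 3 sigma = 30
  expect_gt(n, 70)
  expect_lt(n, 130)
})

test_that("sites are strictly increasing and genes non-degenerate", {
  g <- simulate_genome(tiny_config())
  expect_true(all(diff(g$sites$pos) > 0))
  expect_true(all(g$genes$end > g$genes$start))
  # TSS sits at the strand-appropriate end
  plus <- g$genes$strand == "+"
  expect_true(all(g$genes$tss[plus] == g$genes$start[plus]))
  expect_true(all(g$genes$tss[!plus] == g$genes$end[!plus] - 1))
})

test_that("invalid configurations are rejected", {
  expect_error(sim_config(coverage_mean = 0), class = "methexpr_config_error")
  expect_error(sim_config(effect_delta = -1), class = "methexpr_config_error")
  expect_error(sim_config(frac_hyper = 1.2), class = "methexpr_config_error")
  expect_error(sim_config(frac_hyper = 0.7, frac_hypo = 0.7),
               class = "methexpr_config_error")
  # 20 genes of up to 6 kb + flanks cannot fit a 50 kb chromosome
  expect_error(simulate_genome(tiny_config(chrom_length = 5e4)),
               class = "methexpr_config_error")
})

test_that("a null simulation plants no elements and no DE truth", {
  cfg <- tiny_config(effect_delta = 0, planted_fc = 1)
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  expect_equal(nrow(tr$elements), 0)
  expect_true(all(tr$genes$de_class == "ns"))
  expect_true(all(tr$genes$fc == 1))
})

test_that("planted hyper elements raise the case frequency at most sites", {
  cfg <- tiny_config(effect_delta = 2, coverage_mean = 30, seed = 7)
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  pu <- simulate_methylation(g, tr, cfg)
  hyper <- tr$elements[tr$elements$direction == "hyper", ]
  skip_if(nrow(hyper) == 0)
  wide <- tidyr::pivot_wider(
    pu[pu$pair == "male", c("group", "pos", "meth", "cov")],
    names_from = "group", values_from = c("meth", "cov"))
  in_el <- rep(FALSE, nrow(wide))
  for (i in seq_len(nrow(hyper))) {
    in_el <- in_el | (wide$pos > hyper$start[i] & wide$pos <= hyper$end[i])
  }
  w <- wide[in_el & wide$cov_as > 0 & wide$cov_ctrl > 0, ]
  frac_up <- mean(w$meth_as / w$cov_as > w$meth_ctrl / w$cov_ctrl)
  expect_gte(frac_up, 0.9)
})

test_that("planted directions agree between the two pairs everywhere", {
  cfg <- tiny_config(effect_delta = 3, coverage_mean = 40, seed = 9)
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  pu <- simulate_methylation(g, tr, cfg)
  skip_if(nrow(tr$elements) == 0)
  agree <- vapply(seq_len(nrow(tr$elements)), function(i) {
    el <- tr$elements[i, ]
    sel <- pu$pos > el$start & pu$pos <= el$end & pu$chrom == el$chrom
    d <- dplyr::summarise(dplyr::group_by(pu[sel, ], pair, group),
                          f = sum(meth) / sum(cov), .groups = "drop")
    dm <- d$f[d$pair == "male" & d$group == "as"] -
      d$f[d$pair == "male" & d$group == "ctrl"]
    df <- d$f[d$pair == "female" & d$group == "as"] -
      d$f[d$pair == "female" & d$group == "ctrl"]
    sign(dm) == sign(df)
  }, logical(1))
  expect_true(all(agree))
})

test_that("marginal methylation level matches the Beta prior mean", {
  cfg <- sim_config(n_chromosomes = 1, chrom_length = 1e6, n_genes = 0,
                    baseline_meth_alpha = 2, baseline_meth_beta = 6,
                    coverage_mean = 30, seed = 12)
  g <- simulate_genome(cfg)
  pu <- simulate_methylation(g, plan_truth(g, cfg), cfg)
  one <- pu[pu$sample == "ctrl_male" & pu$cov > 0, ]
  f <- one$meth / one$cov
  mu <- 2 / 8
  se <- sd(f) / sqrt(length(f))
  expect_lt(abs(mean(f) - mu), 3 * se)
})

test_that("full coupling plants every promoter-hypo gene as upregulated", {
  cfg <- tiny_config(coupling_prob = 1, frac_hypo = 0.4, seed = 21)
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  ph <- tr$elements$gene_id[tr$elements$kind == "promoter" &
                              tr$elements$direction == "hypo"]
  skip_if(length(ph) == 0)
  cls <- tr$genes$de_class[match(ph, tr$genes$gene_id)]
  expect_true(all(cls == "up"))
  expect_true(all(tr$genes$coupled[match(ph, tr$genes$gene_id)]))
})

test_that("cytosine reports round-trip through disk", {
  cfg <- tiny_config()
  g <- simulate_genome(cfg)
  tr <- plan_truth(g, cfg)
  pu <- simulate_methylation(g, tr, cfg)
  dir <- withr::local_tempdir()
  paths <- write_cytosine_reports(pu, dir)
  expect_length(paths, 4)
  back <- read_cytosine_report(paths[["as_female"]], "as_female", "female", "as")
  orig <- pu[pu$sample == "as_female", ]
  expect_equal(back$meth, orig$meth)
  expect_equal(back$cov, orig$cov)
  expect_equal(attr(back, "call_convention"), "as_printed")
  # the inverted convention flips methylated and unmethylated calls
  inv <- read_cytosine_report(paths[["as_female"]], "as_female", "female",
                              "as", call_convention = "inverted")
  expect_equal(inv$meth, orig$cov - orig$meth)
})

test_that("sim_config round-trips through YAML", {
  cfg <- tiny_config(coverage_mean = 17.5)
  path <- withr::local_tempfile(fileext = ".yaml")
  write_sim_config(cfg, path)
  expect_equal(read_sim_config(path), cfg)
})
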