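test_that("site flagging is inclusive at the threshold and direction-aware", {
  ct <- make_contrasts(pos = c(100, 200, 300, 400),
                       z = c(0, 2.5, -qnorm(0.975), 1.9))
  fl <- flag_sites(ct, alpha = 0.05)
  expect_equal(fl$flag, c(NA, "hyper", "hypo", NA))
})

test_that("unsorted contrasts are rejected", {
  ct <- make_contrasts(pos = c(300, 100), z = c(1, 1))
  expect_error(flag_sites(ct), class = "methexpr_unsorted_input")
})

test_that("segmentation merges runs bounded by max_gap and min_sites", {
  # sites spanning coordinates 100 and 150; the distant one is dropped
  ct <- make_contrasts(pos = c(101, 151, 901), z = c(3, 3, 3))
  fl <- flag_sites(ct)
  rg <- segment_regions(fl, max_gap = 500, min_sites = 2)
  expect_equal(nrow(rg), 1)
  expect_equal(rg$start, 100)
  expect_equal(rg$end, 151)
  expect_equal(rg$n_sites, 2L)
  expect_equal(rg$region_z, (3 + 3) / sqrt(2))
  # nothing flagged -> nothing segmented
  expect_equal(nrow(segment_regions(flag_sites(make_contrasts(100, 0)))), 0)
  # everything flagged within gaps -> exactly one region
  ct2 <- make_contrasts(pos = seq(100, 1000, by = 100), z = 5)
  expect_equal(nrow(segment_regions(flag_sites(ct2), max_gap = 100)), 1)
})

test_that("segmentation agrees with the explicit run-enumeration oracle", {
  set.seed(5)
  for (rep in 1:20) {
    pos <- sort(sample.int(20000, 300))
    z <- rnorm(300, sd = 2)
    ct <- dplyr::bind_rows(
      make_contrasts(pos, z, pair = "male"),
      make_contrasts(sort(sample.int(20000, 200)), rnorm(200, sd = 2),
                     pair = "female", chrom = "chr2")
    ) |> dplyr::arrange(pair, chrom, pos)
    fl <- flag_sites(ct)
    got <- segment_regions(fl, max_gap = 400, min_sites = 2)
    ref <- segment_oracle(fl, max_gap = 400, min_sites = 2)
    if (is.null(ref)) {
      expect_equal(nrow(got), 0)
    } else {
      expect_equal(as.data.frame(got), ref, ignore_attr = TRUE)
    }
  }
})

test_that("segmentation does not depend on chromosome processing order", {
  set.seed(6)
  blocks <- lapply(c("chr1", "chr2", "chr3"), function(ch)
    make_contrasts(sort(sample.int(5000, 150)), rnorm(150, sd = 2), chrom = ch))
  a <- dplyr::arrange(dplyr::bind_rows(blocks), pair, chrom, pos)
  b <- dplyr::arrange(dplyr::bind_rows(rev(blocks)), pair, chrom, pos)
  expect_equal(segment_regions(flag_sites(a)), segment_regions(flag_sites(b)))
})

test_that("pair reconciliation keeps same-direction intersections only", {
  m <- tibble::tibble(pair = "male", chrom = "chr1", start = 0, end = 1000,
                      direction = "hyper", n_sites = 5L, region_z = 4)
  f <- m |> dplyr::mutate(pair = "female")
  # identical regions reconcile to themselves
  cons <- reconcile_pairs(dplyr::bind_rows(m, f))
  expect_equal(nrow(cons), 1)
  expect_equal(cons[, c("start", "end", "direction")],
               m[, c("start", "end", "direction")])
  expect_equal(cons$n_sites, 5L)
  # direction conflict yields nothing
  f2 <- f |> dplyr::mutate(direction = "hypo")
  expect_equal(nrow(reconcile_pairs(dplyr::bind_rows(m, f2))), 0)
  # partial overlap intersects
  f3 <- f |> dplyr::mutate(start = 500, end = 1500)
  cons3 <- reconcile_pairs(dplyr::bind_rows(m, f3))
  expect_equal(cons3$start, 500)
  expect_equal(cons3$end, 1000)
  expect_equal(cons3$direction, "hyper")
})

test_that("consensus regions are covered by both parents with direction kept", {
  set.seed(7)
  rand_regions <- function(pair) {
    start <- sort(sample.int(50000, 40)) * 10
    tibble::tibble(pair = pair, chrom = sample(c("chr1", "chr2"), 40, TRUE),
                   start = start, end = start + sample(200:2000, 40, TRUE),
                   direction = sample(c("hyper", "hypo"), 40, TRUE),
                   n_sites = sample(3:20, 40, TRUE), region_z = rnorm(40, sd = 3))
  }
  m <- rand_regions("male"); f <- rand_regions("female")
  cons <- reconcile_pairs(dplyr::bind_rows(m, f))
  for (i in seq_len(nrow(cons))) {
    covered <- function(p) any(
      p$chrom == cons$chrom[i] & p$direction == cons$direction[i] &
        p$start <= cons$start[i] & p$end >= cons$end[i])
    expect_true(covered(m))
    expect_true(covered(f))
    expect_lt(cons$start[i], cons$end[i])
  }
})

test_that("recovery evaluation scores overlaps direction-aware", {
  els <- tibble::tibble(gene_id = c("a", "b"), kind = "body",
                        direction = c("hyper", "hypo"), chrom = "chr1",
                        start = c(1000, 5000), end = c(2000, 6000))
  cons <- tibble::tibble(pair = "consensus", chrom = "chr1",
                         start = c(1500, 5200, 8000), end = c(1600, 5300, 9000),
                         direction = c("hyper", "hyper", "hypo"),
                         n_sites = 3L, region_z = 3)
  ev <- evaluate_recovery(cons, els)
  expect_equal(ev$n_recovered, 1L)   # only the hyper element matches in direction
  expect_equal(ev$n_true_calls, 1L)
  expect_equal(ev$sensitivity, 0.5)
  expect_equal(ev$precision, 1 / 3)
})
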