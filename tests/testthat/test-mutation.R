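test_that("summarize_mutations reproduces hand-counted fixtures", {
  # empty input -> all-zero summary
  empty <- summarize_mutations(table1_records()[0, ])
  expect_equal(empty$all, 0)
  # 5-record fixture counted by hand
  recs <- data.frame(
    lineage = "X",
    position = 1:5 * 100,
    class = c("SNP", "SNP", "SNP", "SNP", "indel"),
    context = c("genic", "genic", "genic", "intergenic", "genic"),
    effect = c("nonsynonymous", "nonsynonymous", "synonymous", NA, NA),
    gene = c("g1", "g2", "g3", NA, "g4"),
    essential = NA, stringsAsFactors = FALSE
  )
  s <- summarize_mutations(recs)
  row <- s[s$lineage == "X", ]
  expect_equal(unlist(row[c("all", "intergenic", "genic_indel", "genic_snp",
                            "N", "S")], use.names = FALSE),
               c(5, 1, 1, 3, 2, 1))
  expect_error(summarize_mutations(recs, lineages = "Y"), "unknown lineage")
})

test_that("summary satisfies its structural invariants on random inputs", {
  layout <- gen_genome_layout(sim_config(seed = 4, n_genes = 300,
                                         genome_length = 600000, n_scars = 6))
  for (seed in 1:5) {
    m <- gen_mutations(layout, 80, seed = seed, n_lineages = 5)
    s <- summarize_mutations(m)
    per <- s[s$lineage != "Sum", ]
    tot <- s[s$lineage == "Sum", ]
    expect_equal(per$N + per$S, per$genic_snp)
    expect_true(all(per$intergenic + per$genic_indel + per$genic_snp <=
                      per$all))
    expect_equal(unlist(tot[-1]), colSums(per[-1]))
    expect_equal(tot$all, 80)
  }
})

test_that("circular scar distance matches brute force", {
  ly <- tiny_layout(1000, scars = c(100, 900))
  expect_equal(distance_to_nearest_scar(100, ly), 0)
  expect_equal(distance_to_nearest_scar(1, ly), 99)   # wraps past the origin
  # antipode of a single scar
  ly1 <- genome_layout(1000, scars = 250)
  expect_equal(distance_to_nearest_scar(750, ly1), 500)
  # 1000 random instances against the oracle
  withr::with_seed(13, {
    for (i in 1:20) {
      L <- sample(1000:100000, 1)
      scars <- sort(sample(L, sample(1:12, 1)))
      ly2 <- genome_layout(L, scars)
      pos <- sample(L, 50)
      expect_equal(distance_to_nearest_scar(pos, ly2),
                   brute_scar_distance(pos, scars, L))
    }
  })
  expect_error(distance_to_nearest_scar(5, genome_layout(1000)), "no scars")
  # linear mode ignores the wrap-around arc
  expect_equal(distance_to_nearest_scar(1, ly, linear = TRUE), 99)
  expect_equal(distance_to_nearest_scar(999, ly, linear = TRUE), 99)
})

test_that("welch_t reproduces the textbook formulas and edge cases", {
  out <- welch_t(c(1, 2, 3, 4, 5), c(2, 3, 4, 5, 6))
  expect_equal(out$t, -1, tolerance = 1e-12)
  expect_equal(out$df, 8, tolerance = 1e-12)
  expect_equal(out$p, 2 * pt(-1, 8), tolerance = 1e-12)
  # agreement with the stats oracle on random inputs
  withr::with_seed(3, {
    for (i in 1:20) {
      a <- rnorm(sample(3:30, 1)); b <- rnorm(sample(3:30, 1), 0.3, 2)
      ref <- t.test(a, b)
      got <- welch_t(a, b)
      expect_equal(got$t, unname(ref$statistic), tolerance = 1e-10)
      expect_equal(got$df, unname(ref$parameter), tolerance = 1e-10)
      expect_equal(got$p, ref$p.value, tolerance = 1e-10)
    }
  })
  # identical samples -> t = 0, p = 1
  expect_equal(welch_t(c(1, 2, 3), c(1, 2, 3))$t, 0)
  # degenerate: zero variance
  expect_equal(welch_t(c(2, 2), c(2, 2))$p, 1)
  expect_equal(welch_t(c(2, 2), c(3, 3))$p, 0)
  # shift/scale invariances
  a <- c(1.2, 3.4, 2.2, 5.1); b <- c(2.0, 2.5, 4.4)
  expect_equal(welch_t(a + 10, b + 10)$p, welch_t(a, b)$p, tolerance = 1e-12)
  expect_equal(sign(welch_t(2 * a, 2 * b)$t), sign(welch_t(a, b)$t))
})

test_that("randomization test is reproducible and shaped as promised", {
  layout <- gen_genome_layout(sim_config(seed = 2, n_genes = 100,
                                         genome_length = 500000, n_scars = 8))
  m <- gen_mutations(layout, 30, seed = 5)
  r1 <- randomization_test(m, layout, n_replicates = 200, seed = 42)
  r2 <- randomization_test(m, layout, n_replicates = 200, seed = 42)
  expect_identical(r1, r2)
  expect_length(r1$p_values, 200)
  expect_true(all(r1$p_values >= 0 & r1$p_values <= 1))
  expect_true(r1$ci95[1] <= r1$mu_p && r1$mu_p <= r1$ci95[2])
  expect_error(randomization_test(m[1, ], layout), ">= 2")
})

test_that("mutations placed on scars are detected as biased", {
  layout <- genome_layout(3670000, scars = seq(1e5, 3.5e6, length.out = 10))
  on_scars <- data.frame(position = rep(layout$scars, length.out = 65))
  rr <- randomization_test(on_scars, layout, n_replicates = 300, seed = 7)
  expect_lt(rr$mu_p, 0.05)
  expect_equal(rr$verdict, "locational bias")
})

test_that("mu_p is invariant under coordinate rotation and scar relabeling", {
  L <- 800000
  scars <- c(120000, 300000, 650000)
  m_pos <- withr::with_seed(6, sample(L, 40))
  delta <- 250000
  rot <- function(p) ((p - 1 + delta) %% L) + 1
  ly_a <- genome_layout(L, scars)
  ly_b <- genome_layout(L, rev(rot(scars)))
  d_a <- distance_to_nearest_scar(m_pos, ly_a)
  d_b <- distance_to_nearest_scar(rot(m_pos), ly_b)
  expect_equal(sort(d_a), sort(d_b))
})

test_that("essentiality ratio test reports ratios and both chi2 variants", {
  out <- essentiality_ratio_test(11, 49, 286, 3290)
  expect_equal(out$ratio_mut, 100 * 11 / 49, tolerance = 1e-12)
  expect_equal(out$ratio_all, 100 * 286 / 3290, tolerance = 1e-12)
  expect_equal(round(out$ratio_mut), 22)
  expect_equal(round(out$ratio_all), 9)
  # against the stats oracle
  tab <- rbind(c(11, 38), c(275, 2966))
  expect_equal(out$chi2,
               unname(suppressWarnings(chisq.test(tab, correct = FALSE))$statistic),
               tolerance = 1e-10)
  expect_equal(out$p_corrected,
               suppressWarnings(chisq.test(tab, correct = TRUE))$p.value,
               tolerance = 1e-10)
  # proportional table -> chi2 = 0, p = 1
  prop <- essentiality_ratio_test(10, 100, 100, 1000)
  expect_equal(prop$chi2, 0, tolerance = 1e-12)
  expect_equal(prop$p, 1)
  # degenerate zero margin
  expect_warning(deg <- essentiality_ratio_test(0, 10, 0, 100), "degenerate")
  expect_equal(deg$p, 1)
})

test_that("normalized positions are fractions of the genome", {
  ly <- tiny_layout(1000)
  recs <- data.frame(position = c(1, 500, 1000))
  np <- normalized_positions(recs, ly)
  expect_equal(np, c(0, 0.499, 0.999))
  expect_true(all(np >= 0 & np < 1))
  fix <- table1_records()
  ly2 <- genome_layout(3670000, scars = 1e6)
  np2 <- normalized_positions(fix, ly2)
  expect_length(np2, 65)
  expect_true(all(np2 >= 0 & np2 < 1))
})

test_that("mutation TSV round-trips", {
  dir <- withr::local_tempdir()
  layout <- tiny_layout()
  m <- gen_mutations(layout, 25, seed = 3)
  path <- file.path(dir, "m.tsv")
  write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_mutations(path)
  expect_equal(back$position, m$position)
  expect_equal(back$effect, m$effect)
})
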