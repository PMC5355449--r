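test_that("codon-pair simulator honors t = 0 and omega = 0", {
  p0 <- simulate_codon_pair(50, omega = 0.5, t = 0, seed = 1)
  expect_identical(p0$seq_a, p0$seq_b)

  # omega = 0: every realized change is synonymous
  p <- simulate_codon_pair(400, omega = 0, t = 0.6, seed = 2)
  r <- kaks_ng86(p$seq_a, p$seq_b)
  expect_identical(r$nd, 0)
  expect_gt(r$sd, 0)
})

test_that("simulated pairs contain no stop codons and stay aligned", {
  code <- standard_genetic_code()
  for (seed in 1:3) {
    p <- simulate_codon_pair(100, omega = 0.8, t = 0.5, seed = seed)
    expect_identical(nchar(p$seq_a), nchar(p$seq_b))
    expect_identical(nchar(p$seq_a) %% 3L, 0L)
    for (s in c(p$seq_a, p$seq_b)) {
      codons <- substring(s, seq(1, nchar(s), 3), seq(3, nchar(s), 3))
      expect_false(any(code[codons] == "*"))
    }
  }
})

test_that("identical seeds reproduce byte-identical outputs", {
  a <- simulate_codon_pair(80, omega = 0.4, t = 0.3, seed = 77)
  b <- simulate_codon_pair(80, omega = 0.4, t = 0.3, seed = 77)
  expect_identical(a, b)
  g1 <- simulate_gene_table(seed = 77)
  g2 <- simulate_gene_table(seed = 77)
  expect_identical(g1, g2)
  e1 <- simulate_expression(seed = 77)
  e2 <- simulate_expression(seed = 77)
  expect_identical(e1, e2)
  p1 <- simulate_promoters(c("x", "y"), seed = 77)
  p2 <- simulate_promoters(c("x", "y"), seed = 77)
  expect_identical(p1, p2)
})

test_that("NG86 recovers the planted omega at 5000 codons (seeded)", {
  p <- simulate_codon_pair(5000, omega = 0.5, t = 0.3, seed = 1)
  r <- kaks_ng86(p$seq_a, p$seq_b)
  expect_gte(r$omega, 0.42)
  expect_lte(r$omega, 0.58)
})

test_that("planted gene-table layouts are recovered by detection", {
  sim <- simulate_gene_table(seed = 55)  # default: 11 arrays / 28 genes
  arr <- detect_tandem_arrays(sim$records, sim$genome_order)
  expect_identical(length(unique(arr$array_id)), 11L)
  expect_identical(nrow(arr), 28L)
  expect_identical(sort(arr$gene), sort(sim$true_arrays$gene))

  none <- simulate_gene_table(n_family = 20, array_sizes = integer(0),
                              genes_per_chromosome = 60, seed = 56)
  expect_identical(nrow(detect_tandem_arrays(none$records,
                                             none$genome_order)), 0L)
})

test_that("retention generator hits its rate extremes", {
  all1 <- simulate_retention_cohorts(n_focal = 40, n_background = 1,
                                     focal_rates = c(lf = 1, mf1 = 1,
                                                     mf2 = 1),
                                     seed = 4)
  r <- copy_number_retention(all1, "focal")
  expect_equal(unname(r$fraction_incl_zero), c(0, 0, 0, 1))
  all0 <- simulate_retention_cohorts(n_focal = 40, n_background = 1,
                                     focal_rates = c(lf = 0, mf1 = 0,
                                                     mf2 = 0),
                                     seed = 4)
  expect_identical(unname(copy_number_retention(all0, "focal")$counts[["0"]]),
                   40L)
})

test_that("expression generator plants recoverable structure", {
  sim <- simulate_expression(n_conserved = 1, n_neo = 0, n_pseudo = 1,
                             noise_sd = 0, seed = 9)
  mat <- sim$matrix
  conserved <- sim$pairs[sim$pairs$true_fate == "conserved_or_sub", ]
  expect_equal(pearson(mat[conserved$member_a, ], mat[conserved$member_b, ]),
               1)
  pseudo <- sim$pairs[sim$pairs$true_fate == "pseudogenization", ]
  expect_identical(classify_fate(mat[pseudo$member_a, ],
                                 mat[pseudo$member_b, ])$fate,
                   "pseudogenization")
  expect_true(all(mat >= 0))
})

test_that("promoter generator writes plants at the recorded offsets", {
  sim <- simulate_promoters("g1",
                            plant = data.frame(gene = "g1", signal = "GATA",
                                               offset = 10L),
                            length = 60, seed = 3)
  hits <- scan_motif(sim$promoters[["g1"]], "GATA", both_strands = FALSE)
  expect_true(10L %in% hits$offset)
  expect_identical(sim$plants$offset, 10L)
  expect_identical(substr(sim$promoters[["g1"]], 11, 14),
                   sim$plants$instance)

  # degenerate plants record their concrete instantiation
  sim2 <- simulate_promoters("g1",
                             plant = data.frame(gene = "g1",
                                                signal = "GRWAAW",
                                                offset = 0L),
                             length = 40, seed = 5)
  expect_identical(nchar(sim2$plants$instance), 6L)
  expect_identical(scan_motif(sim2$plants$instance, "GRWAAW",
                              both_strands = FALSE)$offset, 0L)
})

test_that("overlapping plant requests are shifted to free offsets", {
  sim <- simulate_promoters("g1",
                            plant = data.frame(gene = rep("g1", 2),
                                               signal = c("GATAGG", "TTCCAA"),
                                               offset = c(5L, 7L)),
                            length = 80, seed = 6)
  p <- sim$plants
  expect_identical(p$offset[1], 5L)
  expect_gte(p$offset[2], 11L)  # slid past the first plant
  expect_true(all(vapply(seq_len(2), function(i)
    substr(sim$promoters[["g1"]], p$offset[i] + 1,
           p$offset[i] + 6) == p$instance[i], logical(1))))
})
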