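toy_study <- function(n = 301, samples = 12, seed = 1) {
  set.seed(seed)
  expr <- matrix(rnorm(n * samples), n, samples,
                 dimnames = list(sprintf("T%04d", seq_len(n)),
                                 sprintf("S%02d", seq_len(samples))))
  expression_study(expr,
                   tibble::tibble(transcript_id = rownames(expr),
                                  gene = sub("T", "G", rownames(expr))),
                   tibble::tibble(sample_id = colnames(expr)))
}

test_that("seed neighborhoods take the ceiling of the top fraction plus the seed", {
  st <- toy_study(301)
  net <- seed_neighborhoods(st, "T0001", fraction = 0.01)
  expect_length(net$node_ids, 4) # ceiling(0.01 * 300) = 3 neighbors + seed
  all_net <- seed_neighborhoods(st, "T0001", fraction = 1)
  expect_length(all_net$node_ids, 301)
  expect_error(seed_neighborhoods(st, c("T0001", "nope")),
               class = "pathmod_missing_seeds")
})

test_that("a seed inside a planted module recruits its co-members", {
  st <- simulate_study(sim_config(seed = 23))
  seed_tx <- st$truth$seed_transcripts[1]
  net <- seed_neighborhoods(st$cns, seed_tx, fraction = 0.01)
  hood <- setdiff(net$node_ids, seed_tx)
  in_mod <- sum(hood %in% st$truth$seed_transcripts)
  # hypergeometric draw of |hood| from 59 co-members among 1999 transcripts
  p <- phyper(in_mod - 1, 59, 1940, length(hood), lower.tail = FALSE)
  expect_lt(p, 0.01)
})

test_that("topological overlap matches hand-computed values on a 3-node network", {
  cc <- matrix(c(1, 0.9, 0.8,
                 0.9, 1, 0,
                 0.8, 0, 1), 3, byrow = TRUE,
               dimnames = list(letters[1:3], letters[1:3]))
  tom <- topological_overlap(cc, beta = 2)
  # a12 = 0.81, a13 = 0.64, a23 = 0; k = (1.45, 0.81, 0.64)
  expect_equal(tom["a", "b"], 0.81 / (0.81 + 1 - 0.81))
  expect_equal(tom["a", "c"], 0.64 / (0.64 + 1 - 0.64))
  expect_equal(tom["b", "c"], (0.81 * 0.64) / (0.64 + 1))
  expect_equal(diag(tom), c(a = 1, b = 1, c = 1))
})

test_that("topological overlap hits its boundary cases", {
  set.seed(4)
  base <- rnorm(10)
  # third profile orthogonal to the identical pair, so the pair is isolated
  ortho <- residuals(lm(rnorm(10) ~ base))
  expr <- rbind(a = base, b = base, c = ortho)
  net <- structure(list(node_ids = c("a", "b", "c"),
                        seed_ids = "a", expr = expr),
                   class = "pm_seeded_network")
  tom <- topological_overlap(net, beta = 6)
  expect_equal(tom["a", "b"], 1, tolerance = 1e-9)

  cc <- diag(3)
  dimnames(cc) <- list(letters[1:3], letters[1:3])
  tom0 <- topological_overlap(cc, beta = 2)
  expect_equal(tom0[upper.tri(tom0)], rep(0, 3))
})

test_that("topological overlap equals the triple-loop oracle", {
  set.seed(9)
  expr <- matrix(rnorm(40 * 12), 40, 12,
                 dimnames = list(sprintf("T%02d", 1:40), NULL))
  cc <- cor(t(expr))
  for (beta in c(1, 3, 6)) {
    expect_lt(max(abs(topological_overlap(cc, beta) - oracle_tom(cc, beta))),
              1e-10)
  }
})

test_that("soft power selection warns on noise and fits modular networks", {
  st <- toy_study(200, seed = 31)
  net <- seed_neighborhoods(st, rownames(st$expr)[1:5], fraction = 1)
  expect_warning(scan <- select_soft_power(net), "no eligible power")
  expect_true(all(scan$scale_free_r2[scan$eligible] < 0.8))
  expect_equal(attr(scan, "chosen_power"),
               scan$power[scan$eligible][
                 which.max(scan$scale_free_r2[scan$eligible])])

  sim <- simulate_study(sim_config(seed = 1))
  sc <- screen_pathology_correlates(sim$cns)
  net2 <- seed_neighborhoods(sim$cns, sc$transcript_id[sc$selected])
  scan2 <- select_soft_power(net2)
  expect_true(attr(scan2, "reached_target"))
  expect_lte(attr(scan2, "chosen_power"), 12)
  expect_gte(max(scan2$scale_free_r2), 0.8)
  expect_true(all(diff(scan2$mean_connectivity) < 0))
})

test_that("module detection recovers planted modules and ignores noise", {
  st <- simulate_study(sim_config(seed = 6))
  planted <- st$truth$modules
  cc <- cor(t(st$cns$expr[planted$transcript_id, ]))
  # on a background-free network nearly every merge is within-module, so
  # the cut goes just below the final between-module joins
  part <- detect_modules(topological_overlap(cc, 6),
                         cut_height_quantile = 0.99)
  expect_gte(mclust::adjustedRandIndex(part$module, planted$module), 0.8)
  expect_equal(length(unique(part$module[part$module > 0])), 3)
  sizes <- module_sizes(part)
  expect_true(all(diff(sizes$size) <= 0)) # numbered by decreasing size

  set.seed(12)
  noise <- matrix(rnorm(200 * 12), 200,
                  dimnames = list(sprintf("N%03d", 1:200), NULL))
  pnoise <- detect_modules(topological_overlap(cor(t(noise)), 6))
  expect_gt(mean(pnoise$module == 0), 0.5)
})

test_that("tiny networks are left unassigned with a warning", {
  cc <- matrix(c(1, 0.5, 0.5, 1), 2,
               dimnames = list(c("a", "b"), c("a", "b")))
  expect_warning(part <- detect_modules(topological_overlap(cc, 2)),
                 "unassigned")
  expect_true(all(part$module == 0))
})

test_that("partitions are invariant to node input order up to renumbering", {
  st <- simulate_study(sim_config(seed = 13))
  planted <- st$truth$modules
  tom <- topological_overlap(cor(t(st$cns$expr[planted$transcript_id, ])), 6)
  part <- detect_modules(tom)
  set.seed(2)
  perm <- sample(nrow(tom))
  part_perm <- detect_modules(tom[perm, perm])
  merged <- merge(as.data.frame(part), as.data.frame(part_perm),
                  by = "transcript_id")
  expect_equal(mclust::adjustedRandIndex(merged$module.x, merged$module.y), 1)
})

test_that("seedless modules are discarded, seeded modules keep their numbers", {
  part <- pathmod:::new_partition(sprintf("T%02d", 1:50),
                                  rep(1:5, each = 10))
  filt <- filter_seeded_modules(part, c("T01", "T25"))
  expect_identical(attr(filt, "seeded_modules"), c(1L, 3L))
  expect_setequal(unique(filt$module), c(0L, 1L, 3L))
  expect_warning(empty <- filter_seeded_modules(part, "T99"),
                 "no module contains a seed")
  expect_true(all(empty$module == 0))
})

test_that("end to end, the pathology module survives and the control module does not", {
  st <- simulate_study(sim_config(seed = 7))
  sc <- screen_pathology_correlates(st$cns)
  seeds <- sc$transcript_id[sc$selected]
  net <- seed_neighborhoods(st$cns, seeds)
  scan <- select_soft_power(net)
  tom <- topological_overlap(net, attr(scan, "chosen_power"))
  part <- filter_seeded_modules(detect_modules(tom), seeds)
  surviving <- part$transcript_id[part$module > 0]
  expect_gte(sum(st$truth$seed_transcripts %in% surviving), 30)
  # the control module itself never survives; at most a few of its
  # transcripts hitch-hike into the disease module by sample correlation
  control_tx <- st$truth$modules$transcript_id[st$truth$modules$module ==
                                                 st$config$control_identity_module]
  expect_lt(sum(control_tx %in% surviving), length(control_tx) / 2)
})
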