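test_that("permutation ratio handles the structural extremes exactly", {
  p <- toy_pwm()
  # thresholds 0: every N-free window is a hit, so every shuffle hits
  r1 <- permutation_ratio(p, random_test_seq(100), n_shuffles = 50,
                          pwm_threshold = 0, core_threshold = 0, seed = 2)
  expect_equal(as.numeric(r1), 1)
  # the core consensus needs C/G but the sequence has none: no shuffle
  # can create a hit
  expect_true(grepl("[CG]", pwm_consensus(p)))
  r0 <- permutation_ratio(p, strrep("A", 200), n_shuffles = 50, seed = 2)
  expect_equal(as.numeric(r0), 0)
  # composition is preserved: hits-per-shuffle accounting is consistent
  expect_length(attr(r1, "hits_per_shuffle"), 50L)
  expect_true(all(attr(r1, "hits_per_shuffle") > 0))
})

test_that("permutation ratio matches a brute-force shuffle-and-rescan loop", {
  set.seed(13)
  p <- toy_pwm()
  seq <- paste0(random_test_seq(30), pwm_consensus(p), random_test_seq(30))
  ct <- 0.6; pt <- 0.75
  impl <- vapply(1:10, function(s) {
    as.numeric(permutation_ratio(p, seq, n_shuffles = 1000,
                                 pwm_threshold = pt, core_threshold = ct,
                                 seed = 1000 + s))
  }, numeric(1))
  oracle <- vapply(1:10, function(s) {
    set.seed(5000 + s)
    oracle_shuffle_ratio(p$weights, p$core, seq, 1000, ct, pt)
  }, numeric(1))
  # the true ratio is mid-range here; two independent estimates of it
  # must agree within binomial error at n = 1000 per seed
  expect_true(all(impl >= 0 & impl <= 1))
  p_bar <- mean(c(impl, oracle))
  expect_gt(p_bar, 0.02)
  expect_lt(p_bar, 0.98)
  se <- sqrt(p_bar * (1 - p_bar) / (10 * 1000))
  expect_lt(abs(mean(impl) - mean(oracle)), 5 * sqrt(2) * se)
})

test_that("identical seeds reproduce identical ratios; the caller RNG is untouched", {
  p <- toy_pwm()
  s <- random_test_seq(120)
  set.seed(1); ref <- runif(3)
  set.seed(1); runif(1)
  r1 <- permutation_ratio(p, s, n_shuffles = 200, seed = 42,
                          pwm_threshold = 0.6, core_threshold = 0.5)
  after <- runif(2)
  r2 <- permutation_ratio(p, s, n_shuffles = 200, seed = 42,
                          pwm_threshold = 0.6, core_threshold = 0.5)
  expect_identical(as.numeric(r1), as.numeric(r2))
  expect_identical(after, ref[2:3])   # caller's stream continued untouched
})

test_that("overlap Fisher test matches the hypergeometric tail oracle", {
  # identical sets: the most extreme table
  r <- overlap_fisher(sprintf("g%d", 1:10), sprintf("g%d", 1:10), 30000)
  expect_equal(r$overlap, 10L)
  expect_equal(r$p_value, oracle_fisher_tail(10, 10, 10, 30000),
               tolerance = 1e-12)
  # disjoint sets: overlap 0 is the minimum, tail is 1
  r0 <- overlap_fisher(c("a", "b"), c("c", "d"), 30000)
  expect_equal(r0$overlap, 0L)
  expect_equal(r0$p_value, 1, tolerance = 1e-12)
  # the worked 100/100/50 case
  a <- sprintf("x%03d", 1:100)
  b <- c(a[1:50], sprintf("y%03d", 1:50))
  r50 <- overlap_fisher(a, b, 30000)
  expect_equal(r50$overlap, 50L)
  expect_equal(r50$p_value, oracle_fisher_tail(50, 100, 100, 30000),
               tolerance = 1e-12)
  expect_error(overlap_fisher(sprintf("g%d", 1:10), "g1", 5), "universe")
})

test_that("the network recovers a planted edge and honours dual binding", {
  sim <- small_sim(seed = 63)
  net <- infer_network(sim$er_peaks, sim$pol_peaks, sim$genes,
                       sim$peak_seqs, sim$expression, sim$tf_universe,
                       sim$hub_pwms, n_shuffles = 300, seed = 63)
  expect_gt(nrow(sim$truth$edges), 0L)
  expect_equal(edge_key(net$edges), edge_key(sim$truth$edges))
  # planted targets carry their planted direction
  truth_dir <- setNames(sim$truth$direction$direction,
                        sim$truth$direction$gene_id)
  tg <- net$nodes[net$nodes$role == "target", ]
  expect_equal(tg$direction, unname(truth_dir[tg$gene_id]))

  # removing a target's Pol-II peak removes it from the network
  victim <- sim$truth$edges$gene_id[1]
  pol2 <- sim$pol_peaks[sim$pol_peaks$peak_id != paste0("POL_", victim), ]
  net2 <- infer_network(sim$er_peaks, pol2, sim$genes, sim$peak_seqs,
                        sim$expression, sim$tf_universe, sim$hub_pwms,
                        n_shuffles = 300, seed = 63)
  expect_false(victim %in% net2$nodes$gene_id)
  expect_false(victim %in% net2$edges$target)
})

test_that("composition-driven hits are pruned by the permutation cutoff", {
  sim <- small_sim(seed = 17)
  # permissive thresholds: background windows hit everywhere, so shuffles
  # hit just as often and every candidate edge has ratio near 1
  net <- infer_network(sim$er_peaks, sim$pol_peaks, sim$genes,
                       sim$peak_seqs, sim$expression, sim$tf_universe,
                       sim$hub_pwms, n_shuffles = 100,
                       pwm_threshold = 0.2, core_threshold = 0,
                       seed = 17)
  expect_gt(nrow(net$candidates), 0L)
  expect_true(all(net$candidates$best_ratio > 0.2))
  expect_equal(nrow(net$edges), 0L)
})

test_that("a missing peak sequence is reported with the gene name", {
  sim <- small_sim(seed = 5)
  g <- sim$truth$edges$gene_id[1]
  seqs <- sim$peak_seqs[names(sim$peak_seqs) != paste0("ER_", g)]
  expect_error(
    infer_network(sim$er_peaks, sim$pol_peaks, sim$genes, seqs,
                  sim$expression, sim$tf_universe, sim$hub_pwms,
                  n_shuffles = 10, seed = 5),
    g)
})

test_that("edge retention is monotone in the cutoffs", {
  sim <- small_sim(seed = 29)
  base <- list(sim$er_peaks, sim$pol_peaks, sim$genes, sim$peak_seqs,
               sim$expression, sim$tf_universe, sim$hub_pwms)
  run <- function(pt, cutoff) {
    do.call(infer_network, c(base, list(pwm_threshold = pt,
                                        n_shuffles = 200,
                                        ratio_cutoff = cutoff,
                                        seed = 29)))
  }
  lo <- run(0.95, 0.05); hi <- run(0.95, 0.5)
  expect_true(all(edge_key(lo$edges) %in% edge_key(hi$edges)))
  strict <- run(0.99, 0.2); loose <- run(0.9, 0.2)
  expect_true(all(edge_key(strict$candidates) %in%
                    edge_key(loose$candidates)))
})

test_that("network comparison counts common hubs, targets and edges", {
  net <- fixture_network()
  same <- compare_networks(net, net)
  expect_equal(same$pct_common_targets, 100)
  expect_equal(same$edge_jaccard, 1)
  expect_equal(same$common_hubs, c("FOXA1", "RORA"))

  other <- fixture_network(
    edges = data.frame(hub = "PITX2", target = "ESR1", n_peaks = 1L,
                       n_hit_peaks = 1L, n_hits = 1L, best_ratio = 0.02,
                       retained = TRUE, stringsAsFactors = FALSE),
    nodes = data.frame(gene_id = c("ESR1", "PITX2"),
                       role = c("target", "hub"),
                       direction = c("up", "none"),
                       stringsAsFactors = FALSE))
  disj <- compare_networks(net, other)
  expect_equal(disj$pct_common_targets, 0)
  expect_equal(disj$edge_jaccard, 0)
  expect_equal(disj$common_hubs, character())

  # hand-counted 5-node overlap: shared target MYC, shared hub FOXA1
  third <- fixture_network(
    edges = data.frame(hub = c("FOXA1", "FOXA1"),
                       target = c("MYC", "TFF1"),
                       n_peaks = 1L, n_hit_peaks = 1L, n_hits = 1L,
                       best_ratio = 0.01, retained = TRUE,
                       stringsAsFactors = FALSE),
    nodes = data.frame(gene_id = c("FOXA1", "MYC", "TFF1"),
                       role = c("hub", "target", "target"),
                       direction = c("none", "up", "up"),
                       stringsAsFactors = FALSE))
  mix <- compare_networks(net, third)
  expect_equal(mix$common_hubs, "FOXA1")
  expect_equal(mix$common_targets, "MYC")
  expect_equal(mix$pct_common_targets, 50)   # denominator: smaller set (2)
  expect_equal(mix$edge_jaccard, 1 / 3)      # FOXA1->MYC of 3 distinct
})

test_that("igraph conversion carries roles, directions and ratios", {
  net <- fixture_network()
  g <- as_igraph(net)
  expect_true(igraph::is_directed(g))
  expect_equal(igraph::gorder(g), 4L)
  expect_equal(igraph::gsize(g), 2L)
  expect_equal(sort(igraph::V(g)$direction), c("down", "none", "none", "up"))
  expect_equal(sort(igraph::E(g)$permutation_ratio), c(0.01, 0.1))
})
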