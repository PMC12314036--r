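test_that("effector distances follow edge direction", {
  net <- chain_net()
  effs <- effector_set("p", data.frame(protein = c("B", "C"), sign = 1))
  expect_equal(effector_distances(net, "A", effs), c(B = 1, C = 2))
  # the source itself sits at distance 0 (outside the scoring tiers)
  effs0 <- effector_set("p", data.frame(protein = c("A", "C"), sign = 1))
  d <- effector_distances(net, "A", effs0)
  expect_equal(d[["A"]], 0)
  # distance does not follow edges backwards: from C only C itself remains
  expect_equal(effector_distances(net, "C", effs0), c(C = 0))
  expect_false("B" %in% names(effector_distances(net, "C", effs)))
  expect_error(effector_distances(net, "Q", effs), "unknown source")
})

test_that("effector distances match exhaustive path enumeration on random graphs", {
  for (s in 1:6) {
    net <- random_net(10, p = 0.22, seed = 40 + s)
    effs <- effector_set("p", data.frame(
      protein = c("N03", "N06", "N09"), sign = c(1, -1, 1)))
    d <- effector_distances(net, "N01", effs)
    for (e in effs$effectors$protein) {
      bf <- bf_distance(net, "N01", e)
      if (is.finite(bf)) expect_equal(d[[e]], bf) else
        expect_false(e %in% names(d))
    }
  }
})

test_that("raw triggering score handles the trivial tiers", {
  # no effector within distance 3 -> 0
  long <- interactome(data.frame(from = c("A", "B", "C", "D"),
                                 to = c("B", "C", "D", "E"), sign = 1))
  ens <- random_ensemble(long, seeds = 1:2)
  effs_far <- effector_set("p", data.frame(protein = "E", sign = 1))
  expect_equal(raw_triggering_score(long, ens, "A", "inhibited", effs_far), 0)

  # one matching effector at distance 1, unanimous ensemble -> weight w1 = 1
  net1 <- interactome(data.frame(from = "A", to = "B", sign = 1))
  ens1 <- as_ensemble(list(model_params(net1, 0.9, 2),
                           model_params(net1, 0.6, 2)))
  effs1 <- effector_set("p", data.frame(protein = "B", sign = -1))
  expect_equal(raw_triggering_score(net1, ens1, "A", "inhibited", effs1), 1)
  # the same effector mismatches under activation
  expect_equal(raw_triggering_score(net1, ens1, "A", "activated", effs1), 0)

  expect_error(raw_triggering_score(net1, ens1, "A", "inhibited",
                                    structure(list(effectors = data.frame()),
                                              class = "effector_set")),
               "empty effector set")
})

test_that("raw triggering scores match the brute-force oracle on random graphs", {
  for (s in 1:8) {
    net <- random_net(4 + (s %% 7), p = 0.35, seed = 60 + s)
    ens <- random_ensemble(net, seeds = s * 3 + 1:3)
    prot <- net$proteins
    effs <- effector_set("p", data.frame(
      protein = prot[seq(2, length(prot), by = 2)],
      sign = rep_len(c(1, -1), length(seq(2, length(prot), by = 2)))))
    for (mode in c("inhibited", "activated")) {
      expect_equal(
        raw_triggering_score(net, ens, prot[1], mode, effs),
        bf_raw_score(net, ens, prot[1], mode, effs),
        tolerance = 1e-12)
    }
  }
})

test_that("adding a satisfied effector at distance 1 never lowers the raw score", {
  net <- interactome(data.frame(from = c("A", "A"), to = c("B", "C"),
                                sign = c(1, 1)))
  ens <- as_ensemble(model_params(net, c(0.9, 0.9), 2))
  base <- raw_triggering_score(net, ens, "A", "inhibited",
    effector_set("p", data.frame(protein = "B", sign = -1)))
  grown <- raw_triggering_score(net, ens, "A", "inhibited",
    effector_set("p", data.frame(protein = c("B", "C"), sign = c(-1, -1))))
  expect_gte(grown, base)
})

test_that("normalization divides by the per-process maximum over both modes", {
  tab <- data.frame(protein = c("X", "Y"), process = "p",
                    raw_inhibited = c(0.6, 0.3), raw_activated = c(0.2, 0.1))
  out <- normalize_scores(tab)
  expect_equal(out$score_inhibited, c(1, 0.5))
  expect_equal(out$score_activated, c(1 / 3, 1 / 6))

  zero <- data.frame(protein = "X", process = "q",
                     raw_inhibited = 0, raw_activated = 0)
  expect_equal(normalize_scores(zero)$score_inhibited, 0)

  # property: any table with a positive entry normalizes to max exactly 1,
  # everything within [0, 1]
  set.seed(99)
  for (i in 1:10) {
    r <- data.frame(protein = sprintf("P%d", 1:6),
                    process = rep(c("a", "b"), each = 3),
                    raw_inhibited = runif(6), raw_activated = runif(6))
    o <- normalize_scores(r)
    sc <- c(o$score_inhibited, o$score_activated)
    expect_true(all(sc >= 0 & sc <= 1))
    for (pn in c("a", "b"))
      expect_equal(max(o$score_inhibited[o$process == pn],
                       o$score_activated[o$process == pn]), 1)
  }
})

test_that("trigger classification uses a strict inequality at the threshold", {
  tab <- data.frame(protein = c("X", "Y", "Z"), process = "p",
                    difference = c(0.2, 0.2000001, -3))
  fl <- classify_triggers(tab, 0.2)
  expect_identical(fl$protein, "Y")
})

test_that("full triggering table flags exactly the planted inducers", {
  b <- small_bench()
  ens <- as_ensemble(b$planted$params)
  tab <- triggering_table(b$network, ens, b$drugs$drugA$targets$protein,
                          b$processes)
  expect_s3_class(tab, "triggering_table")
  expect_true(all(tab$raw_inhibited >= 0 & tab$raw_activated >= 0))
  fl <- classify_triggers(tab)
  expect_setequal(paste(fl$protein, fl$process),
                  paste(b$planted$inducers$protein,
                        b$planted$inducers$process))
})
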