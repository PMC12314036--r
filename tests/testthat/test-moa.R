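moa_fixture <- function() {
  net <- interactome(data.frame(
    from = c("T1", "T2", "M", "T1"), to = c("M", "M", "E", "E"),
    sign = c(-1, 1, 1, -1)))
  drug <- drug_profile("d", data.frame(protein = c("T1", "T2"),
                                       action = "inhibit"))
  effs <- effector_set("proc", data.frame(protein = "E", sign = 1))
  list(net = net, drug = drug, effs = effs)
}

test_that("MoA models clamp every drug target inhibited and average the ensemble", {
  fx <- moa_fixture()
  p1 <- model_params(fx$net, c(-0.9, 0.8, 0.7, -0.5), 3)
  p2 <- model_params(fx$net, c(-0.4, 0.3, 0.9, -0.2), 3)
  p3 <- model_params(fx$net, c(-0.7, 0.6, 0.2, -0.8), 3)
  ens <- as_ensemble(list(p1, p2, p3))

  m <- build_moa(fx$net, ens, fx$drug, flagged = "T1", effs = fx$effs)
  expect_identical(m$clamp, c(T1 = -1, T2 = -1))
  # ensemble mean equals the hand-average of per-solution propagations
  ys <- sapply(list(p1, p2, p3), function(p)
    propagate(fx$net, p, c(T1 = -1, T2 = -1)))
  expect_equal(m$mean_activity, rowMeans(ys))
  expect_true(all(m$mean_activity >= -1 & m$mean_activity <= 1))

  # single-solution ensemble: mean is that solution's activity
  m1 <- build_moa(fx$net, as_ensemble(p1), fx$drug, "T1", fx$effs)
  expect_equal(m1$mean_activity, propagate(fx$net, p1, c(T1 = -1, T2 = -1)))

  expect_error(build_moa(fx$net, ens, fx$drug, flagged = "E", fx$effs),
               "not drug targets")
})

test_that("pathway extraction returns unanimous chains and drops unreachable effectors", {
  net <- chain_net()
  drug <- drug_profile("d", data.frame(protein = "A", action = "inhibit"))
  ens <- as_ensemble(list(model_params(net, c(0.9, -0.8), 3),
                          model_params(net, c(0.5, -0.9), 3)))
  effs <- effector_set("proc", data.frame(protein = "C", sign = 1))
  m <- build_moa(net, ens, drug, "A", effs)
  pw <- extract_pathways(net, ens, m, max_len = 3, min_support = 1)
  expect_equal(pw$path, "A->B->C")
  expect_equal(pw$support, 1)
  expect_equal(pw$edge_signs, "+-")

  # effector unreachable within max_len -> absent
  pw1 <- extract_pathways(net, ens, m, max_len = 1, min_support = 0.1)
  expect_equal(nrow(pw1), 0)
})

test_that("pathway records match exhaustive per-solution path checking", {
  for (s in 1:4) {
    net <- random_net(10, p = 0.25, seed = 80 + s)
    ens <- random_ensemble(net, seeds = s * 5 + 1:3)
    drug <- drug_profile("d", data.frame(protein = c("N01", "N02"),
                                         action = "inhibit"))
    effs <- effector_set("p", data.frame(protein = c("N07", "N08"),
                                         sign = c(1, -1)))
    m <- build_moa(net, ens, drug, flagged = c("N01", "N02"), effs = effs)
    pw <- extract_pathways(net, ens, m, max_len = 3, min_support = 0.3)
    bf <- bf_pathway_records(net, ens, clamp = m$clamp,
                             stimuli = c("N01", "N02"),
                             effectors = c("N07", "N08"),
                             max_len = 3, min_support = 0.3)
    expect_setequal(pw$path, bf$path)
    expect_equal(pw$support[match(bf$path, pw$path)], bf$support,
                 tolerance = 1e-12)
  }
})

test_that("pathway sorting is by support, then length, then node order", {
  net <- interactome(data.frame(
    from = c("S", "S", "X"), to = c("E", "X", "E"), sign = c(1, 1, 1)))
  drug <- drug_profile("d", data.frame(protein = "S", action = "inhibit"))
  effs <- effector_set("p", data.frame(protein = "E", sign = -1))
  ens <- as_ensemble(model_params(net, c(0.9, 0.9, 0.9), 3))
  m <- build_moa(net, ens, drug, "S", effs)
  pw <- extract_pathways(net, ens, m, max_len = 3, min_support = 0.1)
  expect_equal(pw$path, c("S->E", "S->X->E"))
})

test_that("literature agreement scores only predicted (non-clamped) proteins", {
  fx <- moa_fixture()
  p1 <- model_params(fx$net, c(-0.9, 0.8, 0.7, -0.5), 3)
  ens <- as_ensemble(p1)
  m <- build_moa(fx$net, ens, fx$drug, "T1", fx$effs)
  y <- m$mean_activity

  lit_all <- literature_set("d", data.frame(
    protein = c("M", "E"), direction = sign(y[c("M", "E")])))
  expect_equal(as.numeric(literature_agreement(list(m), lit_all)), 100)

  lit_half <- literature_set("d", data.frame(
    protein = c("M", "E"), direction = c(sign(y[["M"]]), -sign(y[["E"]]))))
  expect_equal(as.numeric(literature_agreement(list(m), lit_half)), 50)

  # clamped stimulus proteins never count
  lit_clamped <- literature_set("d", data.frame(protein = "T1",
                                                direction = -1))
  res <- literature_agreement(list(m), lit_clamped)
  expect_true(is.na(res))
  expect_equal(attr(res, "n_present"), 0L)
})

test_that("agreement on a synthetic response set built from the model itself is 100%", {
  b <- small_bench()
  ens <- as_ensemble(b$planted$params)
  pn <- names(b$processes)[1]
  fl <- b$planted$inducers$protein[b$planted$inducers$process == pn]
  m <- build_moa(b$network, ens, b$drugs$drugA, fl, b$processes[[pn]])
  pres <- names(m$mean_activity)[abs(m$mean_activity) >= m$tau_act]
  pres <- setdiff(pres, names(m$clamp))[1:12]
  lit <- literature_set("drugA", data.frame(
    protein = pres, direction = sign(m$mean_activity[pres])))
  expect_equal(as.numeric(literature_agreement(list(m), lit)), 100)
})

test_that("two-drug asymmetry: outside drug-A-specific cones the models agree", {
  b <- small_bench()
  ens <- as_ensemble(b$planted$params)
  pn <- names(b$processes)[1]
  mA <- build_moa(b$network, ens, b$drugs$drugA,
                  b$drugs$drugA$targets$protein, b$processes[[pn]])
  mB <- build_moa(b$network, ens, b$drugs$drugB,
                  b$drugs$drugB$targets$protein, b$processes[[pn]])
  supA <- names(mA$mean_activity)[abs(mA$mean_activity) >= mA$tau_act]
  supB <- names(mB$mean_activity)[abs(mB$mean_activity) >= mB$tau_act]
  # the superset drug modulates at least as many proteins
  expect_gte(length(supA), length(supB))
  # outside the propagation cone of A-specific targets the activities are
  # identical, so B's suprathreshold set is contained in A's there
  extra <- setdiff(b$drugs$drugA$targets$protein,
                   b$drugs$drugB$targets$protein)
  g <- as_igraph(b$network)
  d <- igraph::distances(g, v = extra, to = b$network$proteins,
                         mode = "out", weights = NA)
  outside <- b$network$proteins[apply(d, 2, min) >
                                  b$planted$params$n_steps]
  expect_equal(mA$mean_activity[outside], mB$mean_activity[outside])
  expect_true(all(intersect(supB, outside) %in% supA))
})

test_that("DOT export is deterministic and parses back to the pathway union", {
  net <- chain_net()
  drug <- drug_profile("d", data.frame(protein = "A", action = "inhibit"))
  effs <- effector_set("proc", data.frame(protein = "C", sign = 1))
  ens <- as_ensemble(model_params(net, c(0.9, -0.8), 3))
  m <- build_moa(net, ens, drug, "A", effs)
  pw <- extract_pathways(net, ens, m, max_len = 3, min_support = 0.5)

  dot <- export_dot(m, pw)
  expect_identical(dot, export_dot(m, pw))
  # one DOT edge per pathway step, in path order
  edges <- regmatches(dot,
    gregexpr("\"[A-Z]\" -> \"[A-Z]\"", dot))[[1]]
  expect_identical(edges, c("\"A\" -> \"B\"", "\"B\" -> \"C\""))
  # inhibiting step drawn as a tee arrow
  expect_match(dot, "\"B\" -> \"C\" \\[arrowhead=tee\\]")

  # empty pathway list: stimulus and effector nodes only, no edges
  dot0 <- export_dot(m)
  expect_match(dot0, "\"A\"")
  expect_match(dot0, "\"C\"")
  expect_no_match(dot0, "->.*\\[arrowhead")
})
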