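test_that("pruning likelihood equals the dense multivariate-normal oracle", {
  for (s in 1:5) {
    tt <- gen_tree_with_trait(10, "brownian", sigma2 = 0.5,
                              root_value = 2, seed = s)
    mine <- fit_trait_model(tt$tree, tt$traits, "brownian")
    dense <- dense_bm_ml(tt$tree, tt$traits)
    expect_equal(mine$log_lik, dense$log_lik, tolerance = 1e-8)
    expect_equal(mine$sigma2, dense$sigma2, tolerance = 1e-8)
    expect_equal(mine$root, dense$root, tolerance = 1e-8)
  }
  # delta likelihood = Brownian likelihood on the transformed tree
  tt <- gen_tree_with_trait(12, "brownian", seed = 31)
  tr2 <- delta_transform(tt$tree, 2.2)
  expect_equal(fit_trait_model(tr2, tt$traits, "brownian")$log_lik,
               dense_bm_ml(tr2, tt$traits)$log_lik, tolerance = 1e-8)
})

test_that("delta transform is the documented depth-power map", {
  tr <- ape::read.tree(text = "((a:0.5,b:0.5):0.5,c:1);")
  t2 <- delta_transform(tr, 2)
  depths <- ape::node.depth.edgelength(t2)
  expect_equal(max(depths), 1)                   # total depth preserved
  expect_equal(depths[5], 0.25)                  # 0.5^2
  expect_equal(ape::node.depth.edgelength(delta_transform(tr, 1)),
               ape::node.depth.edgelength(tr))
  expect_identical(t2$tip.label, tr$tip.label)   # topology and tips kept
  expect_identical(t2$edge, tr$edge)
  expect_error(delta_transform(tr, 0), "> 0")
})

test_that("two-tip symmetry and star trees give the tip mean as root", {
  tr <- ape::read.tree(text = "(a:1,b:1);")
  anc2 <- ancestral_states(tr, c(a = 1, b = 3))
  expect_equal(anc2$state[1], 2)
  star <- ape::read.tree(text = "(a:1,b:1,c:1,d:1);")
  x <- c(a = 1, b = 2, c = 3, d = 10)
  anc <- ancestral_states(star, x)
  expect_equal(anc$state[1], mean(x))
})

test_that("reconstruction equals a dense GLS solve and tracks ape::ace", {
  tt <- gen_tree_with_trait(6, "brownian", seed = 17)
  anc <- ancestral_states(tt$tree, tt$traits)
  # dense GLS oracle at each internal node
  tree <- tt$tree; x <- tt$traits[tree$tip.label]
  n <- 6L
  depth <- ape::node.depth.edgelength(tree)
  mr <- ape::mrca(tree, full = TRUE)
  covm <- matrix(depth[mr], nrow = n + tree$Nnode)
  C <- covm[1:n, 1:n]
  Ci <- solve(C)
  one <- rep(1, n)
  mu <- drop(t(one) %*% Ci %*% x / (t(one) %*% Ci %*% one))
  for (i in seq_len(nrow(anc))) {
    nd <- anc$node[i]
    cvec <- covm[nd, 1:n]
    expect_equal(anc$state[i],
                 drop(mu + t(cvec) %*% Ci %*% (x - mu)),
                 tolerance = 1e-10)
  }
  # independent cross-check against ape's ML reconstruction
  ml <- ape::ace(x, tree, method = "ML")
  expect_equal(anc$state, unname(ml$ace), tolerance = 0.02)
  bad <- tt$traits[-1]
  expect_error(ancestral_states(tt$tree, bad), "missing trait")
})

test_that("Brownian fits on Brownian data keep delta near 1", {
  pv <- vapply(1:60, function(s) {
    tt <- gen_tree_with_trait(50, "brownian", sigma2 = 1, seed = s + 500)
    fit_trait_model(tt$tree, tt$traits, "delta")$lrt$p
  }, numeric(1))
  expect_gte(mean(pv > 0.05), 0.90)
})

test_that("the delta exponent is recovered from late-burst simulations", {
  dh <- vapply(1:50, function(s) {
    tt <- gen_tree_with_trait(102, "delta", sigma2 = 1, root_value = 1.36,
                              delta = 2.635, seed = s)
    fit_trait_model(tt$tree, tt$traits, "delta")$delta
  }, numeric(1))
  expect_lt(abs(mean(dh) - 2.635), 0.5)
})

test_that("the true root lies within 2 SE about 95% of the time", {
  cov95 <- vapply(1:200, function(s) {
    tt <- gen_tree_with_trait(50, "brownian", sigma2 = 1,
                              root_value = 1.36, seed = s + 900)
    a <- ancestral_states(tt$tree, tt$traits)
    abs(a$state[1] - 1.36) <= 2 * a$se[1]
  }, logical(1))
  expect_gt(mean(cov95), 0.88)
  expect_lt(mean(cov95), 0.995)
})

test_that("transition counting is directional and Monte-Carlo stable", {
  # trait increasing monotonically towards the nested clade of a
  # caterpillar (tips on short pendant branches, so node states track
  # their tip): every bin change along the tree is an increase
  txt <- "(((((a:0.1,b:0.1):5,c:0.1):5,d:0.1):5,e:0.1):5,f:0.1);"
  tr <- ape::read.tree(text = txt)
  x <- c(a = 50, b = 49, c = 40, d = 30, e = 20, f = 10)
  td <- transition_directions(tr, x, bin_edges = c(15, 25, 35, 45),
                              n_sim = 10, seed = 1, sample_se = FALSE)
  expect_equal(td$high_to_low, 0)
  expect_equal(td$low_to_high, 4)
  # symmetric data: directional counts agree within joint uncertainty
  tt <- gen_tree_with_trait(40, "brownian", sigma2 = 1, seed = 77)
  xs <- tt$traits - mean(tt$traits)
  td2 <- transition_directions(tt$tree, xs, bin_edges = 0, n_sim = 1000,
                               seed = 2)
  expect_lt(abs(td2$high_to_low - td2$low_to_high),
            6 * (td2$sem[1] + td2$sem[2]) +
              0.1 * (td2$high_to_low + td2$low_to_high))
  # doubling the simulation count moves means by at most a few SEM
  td3 <- transition_directions(tt$tree, xs, bin_edges = 0, n_sim = 2000,
                               seed = 2)
  expect_lt(abs(td3$high_to_low - td2$high_to_low),
            4 * (td2$sem[1] + td3$sem[1]))
  expect_error(transition_directions(tt$tree, xs, bin_edges = c(0, 99),
                                     n_sim = 10), "empty bin")
})

test_that("trees round-trip through Newick with traits intact", {
  tt <- gen_tree_with_trait(25, "brownian", seed = 13)
  tmp <- withr::local_tempfile(fileext = ".nwk")
  ape::write.tree(tt$tree, tmp)
  back <- ape::read.tree(tmp)
  expect_setequal(back$tip.label, tt$tree$tip.label)
  expect_equal(sum(back$edge.length), sum(tt$tree$edge.length),
               tolerance = 1e-6)
  fit1 <- fit_trait_model(tt$tree, tt$traits, "brownian")
  fit2 <- fit_trait_model(back, tt$traits, "brownian")
  expect_equal(fit2$log_lik, fit1$log_lik, tolerance = 1e-6)
})
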