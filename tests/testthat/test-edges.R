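test_that("log2 + gene-level z-scoring matches hand computation", {
  m <- matrix(c(0, 2), 1, 2, dimnames = list("g", c("s1", "s2")))
  z <- log2_zscore(m, pseudocount = 1)
  # log2(x + 1) -> [0, log2 3]; two symmetric points -> z = [-1, 1] (n-1 sd)
  expect_equal(unname(z[1, ]), c(-1, 1), tolerance = 1e-12)

  # constant gene dropped with a message
  m2 <- rbind(g1 = c(1, 1, 1), g2 = c(1, 2, 3))
  colnames(m2) <- paste0("s", 1:3)
  expect_message(z2 <- log2_zscore(m2, log2 = FALSE), "1 zero-variance")
  expect_equal(rownames(z2), "g2")

  # every output row has pooled mean 0 and unit uncorrected sd
  e <- random_ks_expr(15, 10, seed = 42)
  e$values <- abs(e$values)
  z3 <- log2_zscore(e)
  expect_lt(max(abs(rowMeans(z3$values))), 1e-9)
  expect_lt(max(abs(sqrt(rowMeans(z3$values^2)) - 1)), 1e-9)

  expect_error(log2_zscore(matrix(-1, 1, 2,
                                  dimnames = list("g", c("a", "b")))),
               "negative")
})

test_that("class parameters are the plain mean and uncorrected sd", {
  m <- matrix(c(1, 2, 3, 10, 20, 30), 1, 6,
              dimnames = list("g", paste0("s", 1:6)))
  e <- ks_expr(m, rep(c("A", "B"), each = 3))
  p <- class_params(e)
  expect_equal(p$mu["g", "A"], 2)
  expect_equal(p$sigma["g", "A"], sqrt(2 / 3), tolerance = 1e-12)
  expect_equal(p$n, c(A = 3L, B = 3L))

  # invariant to sample order
  perm <- c(4, 1, 6, 3, 2, 5)
  e2 <- ks_expr(m[, perm, drop = FALSE], e$class[perm])
  p2 <- class_params(e2)
  expect_equal(p2$mu, p$mu)
  expect_equal(p2$sigma, p$sigma)

  # constant gene within a class: sigma = 0, flagged out of edge building
  m3 <- rbind(g = c(5, 5, 5, 1, 2, 3), h = c(1, 2, 3, 4, 5, 6))
  colnames(m3) <- paste0("s", 1:6)
  e3 <- ks_expr(m3, rep(c("A", "B"), each = 3))
  expect_equal(class_params(e3)$sigma["g", "A"], 0)
  net <- ks_network("g", "h")
  expect_error(expect_message(edge_transform(e3, net), "zero within-class"),
               "no network pairs")

  expect_error(class_params(ks_expr(m[, 1:4, drop = FALSE],
                                    c("A", "A", "A", "B"))),
               "< 2 samples")
})

test_that("edge values follow the z-product formula on the worked example", {
  m <- rbind(u = c(1, 2, 3), v = c(3, 1, 2))
  colnames(m) <- paste0("s", 1:3)
  # two classes so that the container is valid; class B mirrors A
  m2 <- cbind(m, m)
  colnames(m2) <- paste0("s", 1:6)
  e <- ks_expr(m2, rep(c("A", "B"), each = 3))
  f <- edge_transform(e, ks_network("u", "v"))
  ed <- f$values["u-v", 1:3]
  expect_equal(unname(ed), c(-1.5, 0, 0), tolerance = 1e-9)
  # class mean of the edge equals the within-class Pearson correlation
  expect_equal(mean(ed), -0.5, tolerance = 1e-12)
  expect_equal(mean(ed), oracle_class_cor(m2, e$class, "u", "v", "A"),
               tolerance = 1e-12)
})

test_that("self-pairs give squared z-scores with class mean one, and perfect anticorrelation gives -1", {
  m <- rbind(u = c(1, 2, 3, 7, 8, 11), w = c(-1, -2, -3, 1, 2, 3))
  colnames(m) <- paste0("s", 1:6)
  e <- ks_expr(m, rep(c("A", "B"), each = 3))
  f <- edge_transform(e, ks_network(c("u", "u"), c("u", "w")))
  for (k in c("A", "B"))
    expect_equal(mean(f$values["u-u", e$class == k]), 1, tolerance = 1e-12)
  # u and w are exactly anticorrelated within class A
  expect_equal(unname(f$values["u-w", 1:3]),
               -unname(f$values["u-u", 1:3]), tolerance = 1e-12)
})

test_that("vectorized edge transform equals the scalar-loop oracle and the correlation identity", {
  for (seed in c(11, 12, 13)) {
    e <- random_ks_expr(20, 15, seed = seed)
    net <- withr::with_seed(seed, {
      g <- rownames(e$values)
      ks_network(sample(g, 8), sample(g, 8))
    })
    f <- edge_transform(e, net)
    ids <- edge_ids(net)
    loop <- oracle_edge_loop(e$values, e$class, net$kinase, net$substrate)
    expect_lt(max(abs(f$values[ids, ] - loop)), 1e-12)
    for (i in seq_len(nrow(net))) for (k in levels(e$class)) {
      expect_equal(mean(f$values[ids[i], e$class == k]),
                   oracle_class_cor(e$values, e$class,
                                    net$kinase[i], net$substrate[i], k),
                   tolerance = 1e-9)
    }
    # symmetry: swapping kinase and substrate leaves the values unchanged
    f_sw <- edge_transform(e, ks_network(net$substrate, net$kinase))
    expect_equal(unname(f_sw$values[edge_ids(ks_network(net$substrate,
                                                        net$kinase)), ]),
                 unname(f$values[ids, ]), tolerance = 1e-12)
  }
})

test_that("within-class z-scores have mean 0 and uncorrected sd 1", {
  e <- random_ks_expr(10, 20, seed = 99)
  p <- class_params(e)
  for (k in levels(e$class)) {
    idx <- e$class == k
    z <- (e$values[, idx] - p$mu[, k]) / p$sigma[, k]
    expect_lt(max(abs(rowMeans(z))), 1e-9)
    expect_lt(max(abs(sqrt(rowMeans(z^2)) - 1)), 1e-9)
  }
})

test_that("edge transform with training-only parameters marks provenance", {
  e <- random_ks_expr(10, 20, seed = 5)
  net <- ks_network("G001", "G002")
  tr_idx <- c(1:10, 21:30)  # both classes represented in the training half
  tr <- ks_expr(e$values[, tr_idx], e$class[tr_idx])
  f <- edge_transform(e, net, params = class_params(tr))
  expect_identical(f$provenance, "train")
  expect_identical(edge_transform(e, net)$provenance, "full")
  # missing parameters are reported by gene
  p_small <- class_params(ks_expr(e$values[3:10, ], e$class))
  expect_error(edge_transform(e, net, params = p_small), "G001")
})
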