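test_that("case-to-normal ratios follow the reference mean", {
  ref <- matrix(c(4, 6, 2, 2, 10, 30), 3, 2, byrow = TRUE,
                dimnames = list(c("A", "B", "C"), c("r1", "r2")))
  case <- c(A = 10, B = 2, C = 20)
  cnr <- compute_cnr(case, ref)
  expect_equal(cnr, c(A = 10 / 5, B = 2 / 2, C = 20 / 20))
  # geometric centering option
  cnr_g <- compute_cnr(case, ref, ref_center = "geometric")
  expect_equal(cnr_g[["A"]], 10 / sqrt(24))
  # genes missing from the reference are dropped with a warning
  expect_warning(cnr2 <- compute_cnr(c(A = 1, Z = 2), ref), "missing from reference")
  expect_named(cnr2, "A")
  expect_error(suppressWarnings(compute_cnr(c(Z = 1), ref)), "no genes shared")
  expect_error(compute_cnr(c(A = -1, B = 1, C = 1), ref), "strictly positive")
})

test_that("group-level differential testing matches stats::t.test and hand BH", {
  set.seed(21)
  G <- 40
  X <- matrix(2^(rnorm(G * 5, 8, 0.5)), G, 5,
              dimnames = list(sprintf("g%02d", 1:G), paste0("c", 1:5)))
  Y <- matrix(2^(rnorm(G * 4, 8, 0.5)), G, 4,
              dimnames = list(sprintf("g%02d", 1:G), paste0("r", 1:4)))
  de <- test_differential(X, Y)
  for (i in c(1, 7, 23, 40)) {
    p_ref <- t.test(log2(X[i, ]), log2(Y[i, ]), var.equal = TRUE)$p.value
    expect_equal(de$p[i], p_ref, tolerance = 1e-12)
  }
  expect_equal(de$q, bh_stepup(de$p), tolerance = 1e-12)
  # q is monotone in the raw-p rank and bounded
  o <- order(de$p)
  expect_true(all(diff(de$q[o]) >= -1e-15))
  expect_true(all(de$q <= 1 & de$q >= de$p - 1e-15))
  expect_equal(de$FC, rowMeans(X) / rowMeans(Y), ignore_attr = TRUE)
})

test_that("differential testing handles degenerate inputs", {
  V <- matrix(2, 3, 4, dimnames = list(c("A", "B", "C"), paste0("s", 1:4)))
  de <- test_differential(V[, 1:2], V[, 3:4])
  expect_true(all(de$p == 1) && all(de$FC == 1))
  # singleton group: all p = 1 with a warning
  expect_warning(de1 <- test_differential(V[, 1, drop = FALSE], V[, 2:4]),
                 "fewer than 2 samples")
  expect_true(all(de1$p == 1))
  # non-overlapping universes
  W <- V; rownames(W) <- c("X", "Y", "Z")
  expect_error(test_differential(V, W), "share no genes")
})

test_that("a strong shift at tight noise is reliably significant", {
  set.seed(31)
  G <- 200
  base <- runif(G, 6, 10)
  X <- matrix(2^(base + rnorm(G * 10, 0, 0.1)), G, 10,
              dimnames = list(sprintf("g%03d", 1:G), paste0("c", 1:10)))
  Y <- matrix(2^(base + rnorm(G * 10, 0, 0.1)), G, 10,
              dimnames = list(sprintf("g%03d", 1:G), paste0("r", 1:10)))
  X[1, ] <- X[1, ] * 4  # 4-fold shift on one gene
  de <- test_differential(X, Y)
  expect_lt(de$q[1], 0.05)
  expect_gt(de$FC[1], 1.5)
})

test_that("BTIF applies the fold-change and FDR gates", {
  expect_equal(compute_btif(1.6, 0.01, "filtered"), 1L)
  expect_equal(compute_btif(1.4, 0.001, "filtered"), 0L)   # fails FC gate
  expect_equal(compute_btif(1 / 1.6, 0.01, "filtered"), 1L) # down-regulation counts
  expect_equal(compute_btif(1.6, 0.05, "filtered"), 0L)    # q not < fdr
  expect_equal(compute_btif(1.0, 1.0, "unfiltered"), 1L)
  expect_equal(compute_btif(c(2, 1.1), c(0.2, 0.2), "filtered",
                            fc_threshold = 1.05, fdr = 0.25), c(1L, 1L))
  expect_error(compute_btif(-1, 0.5, "filtered"))
})

test_that("single-pathway PAS follows sum(ARR * BTIF * log10 CNR)", {
  pw <- pathway_definition("p", c(A = 1, B = -1))
  expect_equal(compute_pas(pw, c(A = 10, B = 3), c(A = 1, B = 0)), 1)
  # activator and repressor at the same ratio cancel
  expect_equal(compute_pas(pw, c(A = 4, B = 4), c(A = 1, B = 1)), 0)
  # all flags zero -> empty sum
  expect_equal(compute_pas(pw, c(A = 7, B = 9), c(A = 0, B = 0)), 0)
  # member genes absent from the matrix contribute 0, with a warning
  pw3 <- pathway_definition("p3", c(A = 1, Z = 1))
  expect_warning(v <- compute_pas(pw3, c(A = 100), c(A = 1)), "absent contribute 0")
  expect_equal(v, 2)
  # no member gene present -> NA, not 0
  pw4 <- pathway_definition("p4", c(Q = 1))
  expect_warning(v4 <- compute_pas(pw4, c(A = 1), c(A = 1)), "PAS undefined")
  expect_true(is.na(v4))
})

test_that("a reference group scored against itself is exactly zero when filtered", {
  st <- make_paper_like_study("aging4", seed = 3)
  age <- paste0("AGE", 1:4)
  pas <- suppressWarnings(compute_pas_matrix(
    st$matrices[age], st$groups, st$collection, st$reference_groups[age],
    mode = "filtered", score_groups = "Young", reference_scoring = "filtered"))
  expect_equal(ncol(pas$values), 15L)
  expect_true(all(pas$values == 0))
})

test_that("a case sample equal to the reference mean has zero PAS unfiltered", {
  set.seed(41)
  toy <- random_toy_study(n_genes = 6, n_ref = 4, n_case = 1)
  V <- toy$mat$values
  V[, 5] <- rowMeans(V[, 1:4])  # case column == reference mean
  mat <- expression_matrix(V, "TOY")
  pas <- compute_pas_matrix(list(TOY = mat), toy$groups, toy$collection,
                            c(TOY = "ref"), mode = "unfiltered",
                            score_groups = "case")
  expect_equal(max(abs(pas$values)), 0)
})

test_that("PAS is additive over disjoint pathway partitions", {
  set.seed(51)
  toy <- random_toy_study(n_genes = 10, n_ref = 3, n_case = 3, n_pathways = 1)
  genes <- rownames(toy$mat$values)
  arr <- stats::setNames(sample(c(-1, -0.5, 0.5, 1), 10, replace = TRUE), genes)
  whole <- pathway_collection(list(pathway_definition("whole", arr)))
  parts <- pathway_collection(list(
    pathway_definition("part1", arr[1:4]),
    pathway_definition("part2", arr[5:7]),
    pathway_definition("part3", arr[8:10])))
  for (mode in c("unfiltered", "filtered")) {
    p_whole <- compute_pas_matrix(list(TOY = toy$mat), toy$groups, whole,
                                  c(TOY = "ref"), mode = mode,
                                  score_groups = "case")
    p_parts <- compute_pas_matrix(list(TOY = toy$mat), toy$groups, parts,
                                  c(TOY = "ref"), mode = mode,
                                  score_groups = "case")
    expect_equal(colSums(p_parts$values), p_whole$values["whole", ],
                 tolerance = 1e-12)
  }
})

test_that("scaling a case sample shifts unfiltered PAS by the closed form", {
  set.seed(61)
  toy <- random_toy_study(n_genes = 8, n_ref = 3, n_case = 2)
  base <- compute_pas_matrix(list(TOY = toy$mat), toy$groups, toy$collection,
                             c(TOY = "ref"), mode = "unfiltered",
                             score_groups = "case")
  cc <- 3.7
  V <- toy$mat$values
  case_cols <- names(toy$groups)[toy$groups == "case"]
  V[, case_cols] <- V[, case_cols] * cc
  scaled <- compute_pas_matrix(list(TOY = expression_matrix(V, "TOY")),
                               toy$groups, toy$collection, c(TOY = "ref"),
                               mode = "unfiltered", score_groups = "case")
  shift <- vapply(toy$collection$pathways, function(p) sum(p$gene_roles),
                  numeric(1)) * log10(cc)
  for (s in case_cols)
    expect_equal(scaled$values[, s], base$values[, s] + shift,
                 tolerance = 1e-10)
})

test_that("filtered contributions are the BTIF-gated subset of unfiltered ones", {
  set.seed(71)
  toy <- random_toy_study(n_genes = 9, n_ref = 4, n_case = 4, n_pathways = 1)
  genes <- rownames(toy$mat$values)
  # per-gene single-gene pathways expose each contribution separately
  singles <- pathway_collection(lapply(genes, function(g)
    pathway_definition(paste0("s_", g), stats::setNames(1, g))))
  unf <- compute_pas_matrix(list(TOY = toy$mat), toy$groups, singles,
                            c(TOY = "ref"), mode = "unfiltered",
                            score_groups = "case")
  fil <- compute_pas_matrix(list(TOY = toy$mat), toy$groups, singles,
                            c(TOY = "ref"), mode = "filtered",
                            score_groups = "case")
  de <- test_differential(
    toy$mat$values[, toy$groups[colnames(toy$mat$values)] == "case"],
    toy$mat$values[, toy$groups[colnames(toy$mat$values)] == "ref"])
  btif <- compute_btif(de$FC, de$q, "filtered")
  expect_equal(fil$values, unf$values * btif, tolerance = 1e-12,
               ignore_attr = TRUE)
})

test_that("pipeline PAS matches the loop-based oracle on random toy studies", {
  set.seed(81)
  for (rep in 1:8) {
    toy <- random_toy_study(n_genes = sample(4:10, 1),
                            n_ref = sample(2:3, 1),
                            n_case = sample(2:3, 1),
                            n_pathways = sample(2:4, 1))
    for (mode in c("filtered", "unfiltered")) {
      pas <- compute_pas_matrix(list(TOY = toy$mat), toy$groups,
                                toy$collection, c(TOY = "ref"), mode = mode)
      oracle <- brute_pas_matrix(toy$mat, toy$groups, toy$collection, "ref",
                                 mode = mode)
      expect_equal(pas$values[, colnames(oracle)], oracle, tolerance = 1e-12)
    }
  }
})

test_that("PAS matrix bookkeeping and errors", {
  st <- make_paper_like_study("aging4", seed = 9)
  expect_error(compute_pas_matrix(st$matrices, st$groups, st$collection,
                                  c(AGE1 = "Young"), mode = "filtered"),
               "no designated reference group")
  bad_ref <- st$reference_groups
  bad_ref["AGE1"] <- "Old2"
  expect_error(compute_pas_matrix(st$matrices["AGE1"], st$groups,
                                  st$collection, bad_ref["AGE1"]),
               "has no samples")
  pas <- suppressWarnings(score_study(st))
  expect_equal(nrow(pas$sample_info), 82L)
  expect_equal(as.integer(table(pas$sample_info$group)[c("Young", "Middle", "Old", "HGPS")]),
               c(15L, 25L, 16L, 26L))
  # write/read round trip
  f <- tempfile(fileext = ".tsv")
  write_pas_matrix(pas, f)
  back <- read_pas_matrix(f)
  expect_equal(back$values, pas$values, tolerance = 1e-6)
  expect_equal(back$sample_info$group, pas$sample_info$group)
})
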