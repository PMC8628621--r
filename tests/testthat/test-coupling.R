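test_that("matching intersects tips and labels, reports drops", {
  tr <- parse_newick("((A:1,B:2):3,C:4);")
  d <- data.frame(species = c("A", "B", "D"), x = 1:3)
  td <- as_phylotable(tr, d)
  expect_coupled(td)
  expect_setequal(taxa(td), c("A", "B"))
  rpt <- td$report
  expect_identical(rpt$label_column, "species")
  expect_equal(rpt$n_matched, 2L)
  expect_equal(rpt$n_tips_dropped, 1L)
  expect_equal(rpt$n_rows_dropped, 1L)
  expect_equal(rpt$n_duplicate_rows_dropped, 0L)
})

test_that("the label column is chosen by maximum exact matches", {
  tr <- parse_newick("((A:1,B:2):3,C:4);")
  d <- data.frame(x = c("q", "r", "s"), sp = c("C", "B", "A"))
  td <- as_phylotable(tr, d)
  expect_identical(td$report$label_column, "sp")
  expect_equal(td$report$n_tips_dropped, 0L)
  expect_equal(td$report$n_rows_dropped, 0L)
  # rows reordered to the tree's tip order
  expect_identical(td$dat$sp, c("A", "B", "C"))

  # ties break to the leftmost column, with a warning
  d2 <- data.frame(s1 = c("A", "B", "x"), s2 = c("B", "C", "y"))
  expect_warning(td2 <- as_phylotable(tr, d2), "tie")
  expect_identical(td2$report$label_column, "s1")
})

test_that("matching failures raise validation errors", {
  tr <- parse_newick("((A:1,B:2):3,C:4);")
  expect_error(as_phylotable(tr, data.frame(x = c("q", "r"))),
               "no overlap", class = "ptb_validation_error")
  expect_error(as_phylotable(tr, data.frame(sp = c("A", "q", "r"))),
               "fewer than 2", class = "ptb_validation_error")
  expect_error(as_phylotable(tr, data.frame(x = 1:2), label_column = "nope"),
               "not found", class = "ptb_validation_error")
})

test_that("duplicate taxon rows keep the first occurrence and are counted", {
  tr <- parse_newick("((A:1,B:2):3,C:4);")
  d <- data.frame(species = c("A", "B", "A", "C"), x = c(10, 20, 99, 30))
  td <- as_phylotable(tr, d)
  expect_equal(td$report$n_duplicate_rows_dropped, 1L)
  expect_equal(extract_vector(td, "x")[["A"]], 10)
})

test_that("multi-tree sets are forced to the common tip sampling", {
  t1 <- parse_newick("((A:1,B:2):3,C:4);")
  t2 <- parse_newick("(((A:1,B:1):1,C:1):1,D:1);")
  trees <- structure(list(t1, t2), class = "multiPhylo")
  d <- data.frame(species = c("A", "B", "C", "D"), x = 1:4)
  td <- as_phylotable(trees, d)
  expect_coupled(td)
  expect_setequal(taxa(td), c("A", "B", "C"))
  expect_identical(td$report$per_tree_tips_dropped, c(0L, 1L))
  expect_equal(nrow(td$dat), 3L)
})

test_that("matching is idempotent on a coupled object's own parts", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  td2 <- as_phylotable(pull_phylotable(td, "trees"),
                       pull_phylotable(td, "table"))
  expect_equal(td2$report$n_tips_dropped, 0L)
  expect_equal(td2$report$n_rows_dropped, 0L)
  expect_equal(td2$report$n_duplicate_rows_dropped, 0L)
  expect_equal(td2$dat, td$dat)
})

test_that("drop_taxa removes rows and tips everywhere and counts", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  td2 <- drop_taxa(td, "sp6")
  expect_coupled(td2)
  expect_setequal(taxa(td2), paste0("sp", 1:5))
  expect_equal(td2$dropped_tips, 1L)
  expect_equal(td2$dropped_rows, 1L)
  expect_identical(drop_taxa(td, character(0)), td)
  expect_error(drop_taxa(td, "nope"), "'nope'",
               class = "ptb_validation_error")
  td3 <- as_phylotable(parse_newick("((A:1,B:2):3,C:4);"),
                       data.frame(species = c("A", "B", "C"), x = 1:3))
  expect_error(drop_taxa(td3, c("B", "C")), "below 2",
               class = "ptb_validation_error")
})

test_that("row filters stay coupled and prune every tree", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  out <- td[island == "Cuba"]
  expect_s3_class(out, "phylotable")
  expect_coupled(out)
  expect_setequal(taxa(out), c("sp1", "sp2", "sp5"))
  expect_equal(out$dropped_tips, 3L)
  # filters that would leave fewer than two taxa error out
  expect_error(td[island == "Jamaica"], "fewer than 2",
               class = "ptb_validation_error")
})

test_that("per-row derived columns keep the implicit label column", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  out <- td[island == "Cuba", .(Index = SVL + hostility)]
  expect_s3_class(out, "phylotable")
  expect_coupled(out)
  expect_identical(names(out$dat), c("species", "Index"))
  expect_equal(extract_vector(out, "Index"),
               c(sp1 = 51, sp2 = 62, sp5 = 60))
})

test_that("per-group head selections stay coupled", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  out <- td[, head(.SD, 1), by = "ecomorph"]
  expect_s3_class(out, "phylotable")
  expect_coupled(out)
  expect_setequal(taxa(out), c("sp1", "sp3", "sp5"))
  # retained tips keep their original root-to-tip depths
  for (tip in taxa(out)) {
    expect_equal(tip_depth(out$phy, tip), tip_depth(fx$tree, tip))
  }
})

test_that("aggregations detach the table with a warning and no trees", {
  fx <- aggregation_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  expect_warning(
    out <- td[Disc1 == "A", .(s = sum(Cont2), m = mean(Cont3)), by = Disc10],
    "detached"
  )
  expect_false(inherits(out, "phylotable"))
  expect_true(data.table::is.data.table(out))
  expect_identical(out$Disc10, c("X", "Y"))
  expect_equal(out$s, c(5, 8))
  expect_equal(out$m, c(5, 8))
})

test_that("filter composition matches a conjunctive filter", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  a <- td[island == "Cuba"][SVL > 50]
  b <- td[island == "Cuba" & SVL > 50]
  expect_equal(a$dat, b$dat)
  expect_true(isTRUE(ape::all.equal.phylo(a$phy, b$phy,
                                          use.edge.length = TRUE)))
})

test_that(":= updates keep all taxa coupled", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  out <- td[, logSVL := log(SVL)]
  expect_s3_class(out, "phylotable")
  expect_coupled(out)
  expect_equal(nrow(out$dat), 6L)
  expect_false("logSVL" %in% names(td$dat))  # original untouched
})

test_that("extract_vector returns named vectors in tip order", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  v <- extract_vector(td, "SVL")
  expect_identical(names(v), taxa(td))
  expect_equal(unname(v[taxa(td)]),
               fx$data$SVL[match(taxa(td), fx$data$species)])
  two <- extract_vector(td, "SVL", "ecomorph")
  expect_length(two, 2L)
  expect_named(two, c("SVL", "ecomorph"))
  expect_identical(td[["hostility"]], extract_vector(td, "hostility"))
  expect_error(extract_vector(td, "nope"), "'nope'",
               class = "ptb_validation_error")
  expect_error(extract_vector(td, "species"), "species",
               class = "ptb_validation_error")
  # cell-level agreement with the table
  for (tx in taxa(td)) {
    expect_equal(v[[tx]], td$dat[species == tx, SVL])
  }
})

test_that("pulled parts are independent copies", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  tab <- pull_phylotable(td, "table")
  tab[, SVL := 0]
  expect_equal(td$dat$SVL, fx$data$SVL[match(taxa(td), fx$data$species)])
  trs <- pull_phylotable(td, "trees")
  expect_s3_class(trs, "phylo")
  expect_error(pull_phylotable(td, "nope"))
})

test_that("external functions receive each tree with the shared table", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  expect_equal(apply_treedata(td, function(tree, data) ape::Ntip(tree)), 6L)

  trees <- structure(list(fx$tree, fx$tree), class = "multiPhylo")
  tdm <- as_phylotable(trees, fx$data)
  res <- apply_treedata(tdm, function(tree, data) ape::Ntip(tree))
  expect_identical(res, list(6L, 6L))
  expect_error(
    apply_treedata(tdm, function(tree, data) stop("boom")),
    "\\[tree 1\\] boom"
  )
})

test_that("summary counts characters, missing cells and drops", {
  fx <- worked_fixture()
  d <- fx$data
  d$SVL[2] <- NA
  td <- as_phylotable(fx$tree, d)
  s <- summary(td)
  expect_equal(s$n_taxa, 6L)
  expect_equal(s$n_trees, 1L)
  expect_equal(s$n_discrete, 2L)    # ecomorph, island
  expect_equal(s$n_continuous, 2L)  # SVL, hostility
  expect_equal(s$n_missing, 1L)
  expect_equal(s$dropped_tips_total, 0L)
  s2 <- summary(drop_taxa(td, "sp6"))
  expect_equal(s2$dropped_tips_total, 1L)
  expect_output(print(s), "2 discrete, 2 continuous")
})

test_that("head and tail render without mutating the object", {
  fx <- worked_fixture()
  td <- as_phylotable(fx$tree, fx$data)
  lines <- expect_output(head(td, 2), "sp1")
  expect_output(tail(td, 10), "sp6")
  expect_equal(nrow(td$dat), 6L)
  expect_coupled(td)
  expect_error(head(td, 0), ">= 1", class = "ptb_validation_error")
})

test_that("randomized operation chains preserve the coupling invariant", {
  set.seed(31)
  cfg <- benchmark_config(n_discrete = 3, n_continuous = 3, seed = 31)
  ok <- 0L
  n_seq <- 60L
  for (s in seq_len(n_seq)) {
    fx <- generate_benchmark_data(12, cfg, seed = 1000 + s)
    td <- as_phylotable(fx$tree, fx$data, label_column = "species")
    for (step in seq_len(sample(2:4, 1))) {
      op <- sample(c("drop", "filter", "head", "rebuild"), 1)
      td <- tryCatch(
        switch(op,
          drop = drop_taxa(td, sample(taxa(td), 1)),
          filter = {
            states <- sample(LETTERS[1:5], 3)
            td[Disc1 %in% states]
          },
          head = td[, head(.SD, 1), by = "Disc2"],
          rebuild = as_phylotable(pull_phylotable(td, "trees"),
                                  pull_phylotable(td, "table"))
        ),
        ptb_validation_error = function(e) td  # op would leave <2 taxa
      )
    }
    if (coupling_holds(td)) ok <- ok + 1L
  }
  expect_equal(ok, n_seq)
})
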