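test_that("matrix dialect parses labels and edges", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c(",a,b,c", "a,0,1,0", "b,0,0,1", "c,0,0,0"), f)
  g <- read_graph(f, format = "matrix")
  expect_s3_class(g, "hierord_graph")
  expect_identical(g$labels, c("a", "b", "c"))
  expect_equal(sum(g$W), 2)
  expect_equal(g$W["a", "b"], 1)
  expect_equal(g$W["b", "c"], 1)
})

test_that("edge list creates nodes in first-appearance order with weight 1", {
  f <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A B", "B C", "C A"), f)
  g <- read_graph(f, format = "edgelist")
  expect_identical(g$labels, c("A", "B", "C"))
  expect_equal(unname(diag(g$W[c(1, 2, 3), c(2, 3, 1)])), c(1, 1, 1))
  expect_equal(sum(g$W), 3)

  f3 <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("A\tB\t2.5", "B\tA"), f3)
  expect_warning(g3 <- read_graph(f3, format = "edgelist"), "nonbinary")
  expect_equal(g3$W["A", "B"], 2.5)
  expect_equal(g3$W["B", "A"], 1)
})

test_that("loader raises distinct labeled errors", {
  neg <- withr::local_tempfile()
  writeLines(c(",a,b", "a,0,-1", "b,0,0"), neg)
  expect_error(read_graph(neg), class = "hierord_error_negative_weight")

  nonsq <- withr::local_tempfile()
  writeLines(c(",a,b,c", "a,0,1,0", "b,0,0,1"), nonsq)
  expect_error(read_graph(nonsq), class = "hierord_error_nonsquare")

  dup <- withr::local_tempfile()
  writeLines(c("A B", "A B", "B A"), dup) # duplicate edge is fine ...
  expect_s3_class(read_graph(dup, format = "edgelist"), "hierord_graph")
  expect_error(
    directed_graph(matrix(0, 2, 2), labels = c("x", "x")),
    class = "hierord_error_duplicate_labels"
  )

  badline <- withr::local_tempfile()
  writeLines(c("A B", "C"), badline)
  expect_error(read_graph(badline, format = "edgelist"),
    class = "hierord_error_parse"
  )
})

test_that("matrix and edge-list serializations load to the same graph", {
  g <- cycle_graph(4L)
  fm <- withr::local_tempfile(fileext = ".tsv")
  write_graph(g, fm)
  fe <- withr::local_tempfile(fileext = ".tsv")
  el <- as_tibble(g)
  writeLines(paste(el$from, el$to, el$weight, sep = "\t"), fe)
  gm <- read_graph(fm, format = "matrix")
  ge <- read_graph(fe, format = "edgelist")
  # edge list may order labels differently; compare on a common order
  expect_setequal(gm$labels, ge$labels)
  expect_equal(gm$W[gm$labels, gm$labels], ge$W[gm$labels, gm$labels])
  expect_equal(gm$W, g$W)
})

test_that("induced subgraph takes the principal submatrix in keep order", {
  g <- cycle_graph(3L)
  sub <- induced_subgraph(g, c("A", "B"))
  expect_identical(sub$labels, c("A", "B"))
  expect_equal(sub$W["A", "B"], 1)
  expect_equal(sum(sub$W), 1)

  expect_equal(induced_subgraph(g, g$labels)$W, g$W)
  expect_error(induced_subgraph(g, c("A", "Z")),
    class = "hierord_error_unknown_label"
  )
})

test_that("level tables round-trip through write_levels/read_levels", {
  t1 <- tibble::tibble(label = c("V1", "V2"), level = c(0, 1))
  f <- withr::local_tempfile(fileext = ".tsv")
  write_levels(t1, f)
  expect_equal(as.data.frame(read_levels(f)), as.data.frame(t1))

  # empty table -> header-only file
  t0 <- tibble::tibble(label = character(), level = numeric())
  f0 <- withr::local_tempfile(fileext = ".tsv")
  write_levels(t0, f0)
  expect_identical(readLines(f0), "label\tlevel")

  # fractional levels survive
  t2 <- tibble::tibble(label = c("x", "y", "z"), level = c(4.5, 0.25, 9))
  f2 <- withr::local_tempfile(fileext = ".tsv")
  write_levels(t2, f2)
  expect_equal(read_levels(f2)$level, t2$level)
})

test_that("anchor validation enforces membership and range", {
  g <- cycle_graph(3L)
  ok <- validate_anchors("A=0,C=9", g, K = 9)
  expect_equal(ok$label, c("A", "C"))
  expect_equal(ok$level, c(0, 9))
  expect_error(validate_anchors("Z=0", g, K = 9),
    class = "hierord_error_unknown_label"
  )
  expect_error(validate_anchors("A=10", g, K = 9),
    class = "hierord_error_anchor_range"
  )
})

test_that("anchor_fraction counts relationships touching the anchors", {
  g <- cycle_graph(3L) # A->B->C->A: 3 directed, 3 pairs
  fr <- anchor_fraction(g, "A")
  expect_equal(fr$n_directed, 3)
  expect_equal(fr$n_pairs, 3)
  expect_equal(fr$n_pairs_anchored, 2) # {A,B} and {A,C}
  expect_equal(fr$frac_pairs, 100 * 2 / 3)
  expect_equal(fr$frac_directed, 100 * 2 / 3)
  expect_equal(anchor_fraction(g, c("A", "B", "C"))$frac_pairs, 100)
})

test_that("reference hierarchy tables ship with the package", {
  vis <- fv91_levels("vision")
  som <- fv91_levels("somatomotor")
  expect_equal(nrow(vis), 32)
  expect_equal(nrow(som), 16)
  expect_equal(sort(unique(vis$level)), 0:9)
  expect_equal(vis$level[vis$label == "V1"], 0)
  expect_equal(vis$level[vis$label == "46"], 9)
})
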