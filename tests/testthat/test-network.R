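test_that("Spearman rs handles perfect monotone series and small-n exact p", {
  e <- spearman_edge(c(1, 2, 3), c(10, 20, 30))
  expect_equal(e$rs, 1)
  expect_equal(e$p, 2 / 6)            # all 3! rank orders enumerated
  e2 <- spearman_edge(c(1, 2, 3), c(3, 2, 1))
  expect_equal(e2$rs, -1)
  expect_equal(e2$p, 2 / 6)
  e4 <- spearman_edge(1:4, 1:4)
  expect_equal(e4$p, 2 / 24)
  flat <- spearman_edge(c(1, 1, 1), c(1, 2, 3))
  expect_true(is.na(flat$rs))
})

test_that("exact path agrees with the permutation oracle for n <= 6", {
  set.seed(21)
  for (n in 3:6) {
    for (i in 1:4) {
      x <- rnorm(n)
      y <- rnorm(n)
      if (i %% 2 == 0) {            # inject ties
        x[1:2] <- x[2]
        y[n - 1] <- y[n]
      }
      want <- oracle_spearman(x, y)
      got <- spearman_edge(x, y)
      expect_equal(got$rs, want$rs, tolerance = 1e-12)
      expect_equal(got$p, want$p, tolerance = 1e-12)
    }
  }
})

test_that("rs agrees with cor.test on tie-free series and is invariant to monotone maps", {
  set.seed(31)
  x <- rnorm(8); y <- rnorm(8)
  got <- spearman_edge(x, y)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman"))
  expect_equal(got$rs, unname(ct$estimate), tolerance = 1e-12)
  expect_equal(spearman_edge(y, x)$rs, got$rs)
  expect_equal(spearman_edge(exp(x), y^3 + 5 * y)$rs, got$rs)
})

test_that("genus trajectories aggregate OTUs and order points by day", {
  rel <- matrix(c(0.1, 0.3, 0.5,
                  0.2, 0.2, 0.2,
                  0.7, 0.5, 0.3), nrow = 3, byrow = TRUE,
                dimnames = list(c("o1", "o2", "o3"),
                                c("late", "early", "mid")))
  tax <- data.frame(otu_id = c("o1", "o2", "o3"),
                    lineage = "x", genus = c("G1", "G1", "G2"),
                    stringsAsFactors = FALSE)
  meta <- data.frame(sample_id = c("late", "early", "mid"),
                     day = c(27, 3, 10), stringsAsFactors = FALSE)
  traj <- build_trajectories(rel, tax, meta)
  expect_equal(rownames(traj), c("G1", "G2"))
  expect_equal(attr(traj, "days"), c(3, 10, 27))
  expect_equal(unname(traj["G1", ]), c(0.5, 0.7, 0.3))  # 0.3+0.2 at day 3
  expect_error(build_trajectories(rel[, 1:2], tax, meta),
               class = "indigoferm_input_error")
})

test_that("identical short series fail the exact alpha gate, so no edges", {
  traj <- matrix(rep(c(0.1, 0.2, 0.3, 0.4), 3), nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:4)))
  net <- build_network(traj)           # rs = 1, exact p = 2/24 > 0.05
  expect_equal(nrow(net$edges), 0)
  single <- build_network(traj[1, , drop = FALSE])
  expect_equal(nrow(single$nodes), 1)
  expect_equal(nrow(single$edges), 0)
})

test_that("edge retention is monotone in rs threshold and alpha", {
  set.seed(13)
  traj <- matrix(runif(60), nrow = 6,
                 dimnames = list(paste0("g", 1:6), paste0("s", 1:10)))
  base <- build_network(traj, rs_threshold = 0.3, alpha = 0.3)
  tighter_rs <- build_network(traj, rs_threshold = 0.6, alpha = 0.3)
  tighter_a <- build_network(traj, rs_threshold = 0.3, alpha = 0.05)
  key <- function(n) paste(n$edges$genus_a, n$edges$genus_b)
  expect_true(all(key(tighter_rs) %in% key(base)))
  expect_true(all(key(tighter_a) %in% key(base)))
})

test_that("node weights accumulate abundance and components split cliques", {
  traj <- matrix(c(0.1, 0.2, 0.3, 0.4, 0.5,
                   0.2, 0.3, 0.4, 0.5, 0.6,
                   0.6, 0.5, 0.4, 0.3, 0.2,
                   0.5, 0.4, 0.3, 0.2, 0.1,
                   0.3, 0.1, 0.4, 0.2, 0.35), nrow = 5, byrow = TRUE,
                 dimnames = list(c("up1", "up2", "down1", "down2", "noise"),
                                 paste0("s", 1:5)))
  net <- build_network(traj, rs_threshold = 0.6, alpha = 0.05)
  expect_equal(unname(net$nodes$weight), unname(rowSums(traj)))
  # rising pair and falling pair are perfectly correlated (n=5, p=2/120);
  # cross edges are negative and equally strong
  key <- paste(net$edges$genus_a, net$edges$genus_b, net$edges$sign)
  expect_true("up1 up2 positive" %in% key)
  expect_true("down1 down2 positive" %in% key)
  expect_true(any(net$edges$sign == "negative"))
  comps <- network_components(net)
  expect_equal(sum(vapply(comps, function(cc) nrow(cc$nodes), numeric(1))),
               5)
  # an empty network decomposes into singletons
  empty <- build_network(traj, rs_threshold = 0.999, alpha = 1e-9)
  expect_equal(length(network_components(empty)), 5)
})

test_that("network outputs are written as edge list and GraphML", {
  traj <- matrix(c(1:6 / 10, 6:1 / 10, c(2, 1, 3, 2, 4, 3) / 10),
                 nrow = 3, byrow = TRUE,
                 dimnames = list(c("a", "b", "c"), paste0("s", 1:6)))
  net <- build_network(traj, rs_threshold = 0.5, alpha = 0.2)
  f <- tempfile(fileext = ".tsv")
  write_edge_list(net, f)
  back <- read.delim(f)
  expect_equal(nrow(back), nrow(net$edges))
  g <- tempfile(fileext = ".graphml")
  write_graphml(net, g)
  expect_true(file.size(g) > 0)
  expect_equal(igraph::vcount(as_igraph(net)), 3)
})
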