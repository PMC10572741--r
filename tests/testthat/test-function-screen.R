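make_hierarchy <- function(ids, subs) {
  data.frame(function_id = ids, subpathway = subs,
             superpathway = "sp", category = "cat", stringsAsFactors = FALSE)
}

test_that("subpathway percentages aggregate and sum to 100", {
  fx <- matrix(c(1, 3,
                 2, 2,
                 1, 1,
                 4, 2), nrow = 4, byrow = TRUE,
               dimnames = list(paste0("K", 1:4), c("s1", "s2")))
  h <- make_hierarchy(paste0("K", 1:4), c("A", "A", "B", "B"))
  p <- subpathway_percentages(fx, h)
  # hand sums: s1 A = 3/8, B = 5/8; s2 A = 5/8, B = 3/8
  expect_equal(p["A", "s1"], 37.5)
  expect_equal(p["B", "s1"], 62.5)
  expect_equal(p["A", "s2"], 62.5)
  expect_equal(unname(colSums(p)), c(100, 100))
  # single subpathway covers everything; unmapped functions go Unclassified
  p1 <- subpathway_percentages(fx, make_hierarchy(paste0("K", 1:4), "A"))
  expect_equal(as.numeric(p1), c(100, 100))
  p2 <- subpathway_percentages(fx, make_hierarchy("K1", "A"))
  expect_true("Unclassified" %in% rownames(p2))
  expect_equal(unname(colSums(p2)), c(100, 100))
})

test_that("day-pair ratio selection applies inclusive 1.05 and strict 1.4 rules", {
  profiles <- matrix(c(2.1, 2.1, 1.4,
                       1.0, 1.0, 1.0), nrow = 2, byrow = TRUE,
                     dimnames = list(c("A", "B"), c("s10a", "s10b", "s212")))
  days <- c(10, 10, 212)
  rs <- ratio_select(profiles, days, list(c(10, 212)))
  # A: replicate-averaged 2.1 / 1.4 = 1.5 -> selected and highlighted
  expect_equal(rs$`D10/D212`, c(1.5, 1.0))
  expect_equal(rs$selected, c(TRUE, FALSE))
  expect_equal(rs$highlighted, c(TRUE, FALSE))
  # identical profiles: every ratio 1, nothing selected at 1.05
  same <- matrix(c(5, 5, 95, 95), nrow = 2, byrow = TRUE,
                 dimnames = list(c("A", "B"), c("s1", "s2")))
  rs2 <- ratio_select(same, c(10, 212), list(c(10, 212)))
  expect_false(any(rs2$selected))
  # boundary threshold 1.0 selects every defined-ratio subpathway
  rs3 <- ratio_select(same, c(10, 212), list(c(10, 212)),
                      select_threshold = 1.0)
  expect_true(all(rs3$selected))
})

test_that("undefined ratios are excluded, and selection is threshold-monotone", {
  profiles <- matrix(c(60, 70, 40, 0,
                       0, 30), nrow = 3, byrow = TRUE,
                     dimnames = list(c("up", "gone", "new"), c("d10", "d212")))
  expect_warning(rs <- ratio_select(profiles, c(10, 212), list(c(10, 212))),
                 "undefined")
  expect_false(rs$selected[rs$subpathway == "gone"])
  expect_false(rs$defined[rs$subpathway == "gone"])
  # a zero numerator is a defined (zero) ratio, just never selected
  expect_true(rs$defined[rs$subpathway == "new"])
  expect_false(rs$selected[rs$subpathway == "new"])

  set.seed(7)
  prof <- matrix(runif(40, 1, 10), nrow = 10,
                 dimnames = list(paste0("sp", 1:10), paste0("s", 1:4)))
  prof <- sweep(prof, 2, colSums(prof), "/") * 100
  days <- c(10, 10, 212, 212)
  sel <- function(th) sum(ratio_select(prof, days, list(c(10, 212)),
                                       select_threshold = th)$selected)
  counts <- vapply(c(0.8, 1.0, 1.05, 1.2, 1.5), sel, numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("taxon contributions match the brute-force row oracle", {
  strat <- data.frame(
    Sample = "s1",
    Gene = c("K1", "K1", "K2", "K2", "K9"),
    OTU = c("o1", "o2", "o1", "o3", "o1"),
    GeneCountPerGenome = c(2, 1, 4, 4, 50),
    OTUAbundanceInSample = c(81, 162, 81, 88, 10),
    taxon = c("Alkalibacterium", "Alkalibacterium", "Alkalibacterium",
              "Amphibacillus", "Alkalibacterium"),
    stringsAsFactors = FALSE)
  strat$CountContributedByOTU <- strat$GeneCountPerGenome *
    strat$OTUAbundanceInSample
  # constructed so K1+K2 split 64.8% / 35.2%
  tc <- taxon_contribution(strat, c("K1", "K2"), "s1")
  expect_equal(tc$contribution_pct, c(64.8, 35.2), tolerance = 1e-9)
  expect_equal(sum(tc$contribution_pct), 100)
  expect_error(taxon_contribution(strat, character(0), "s1"),
               class = "indigoferm_input_error")
  expect_error(taxon_contribution(strat, "K1", "absent"),
               class = "indigoferm_input_error")

  # randomized tables vs the independent row-sum oracle
  set.seed(99)
  for (i in 1:5) {
    n <- sample(20:100, 1)
    tab <- data.frame(
      Sample = sample(c("s1", "s2"), n, replace = TRUE),
      Gene = sample(paste0("K", 1:6), n, replace = TRUE),
      OTU = paste0("o", seq_len(n)),
      GeneCountPerGenome = sample(0:5, n, replace = TRUE),
      OTUAbundanceInSample = sample(1:500, n),
      taxon = sample(c("A", "B", "C"), n, replace = TRUE),
      stringsAsFactors = FALSE)
    tab$CountContributedByOTU <- tab$GeneCountPerGenome *
      tab$OTUAbundanceInSample
    want <- oracle_contribution(tab, c("K1", "K2", "K3"), "s1")
    got <- taxon_contribution(tab, c("K1", "K2", "K3"), "s1")
    expect_equal(got$contribution_pct[match(names(want), got$taxon)],
                 unname(want), tolerance = 1e-9)
  }
})

test_that("single-function contributions cover the degenerate cases", {
  strat <- data.frame(
    Sample = "s1", Gene = "K7",
    OTU = c("o1", "o2", "o3"),
    GeneCountPerGenome = c(3, 1, 4),
    OTUAbundanceInSample = c(1, 1, 1),
    taxon = c("A", "A", "B"), stringsAsFactors = FALSE)
  strat$CountContributedByOTU <- strat$GeneCountPerGenome
  oc <- otu_contribution_for_function(strat, "K7", "s1")
  # two OTUs of taxon A contribute 3+1 = 4, taxon B contributes 4
  expect_equal(sort(oc$contribution_pct), c(50, 50))
  expect_equal(sum(oc$contribution_pct), 100)
  single <- strat[3, ]
  oc1 <- otu_contribution_for_function(single, "K7", "s1")
  expect_equal(oc1$contribution_pct, 100)
  expect_warning(empty <- otu_contribution_for_function(strat, "K404", "s1"),
                 "no stratified rows")
  expect_equal(nrow(empty), 0)
})

test_that("CLR matches hand-computed logs and centres every sample", {
  m <- matrix(c(2, 2, 2, 2, 1, 2, 4, 8), ncol = 2,
              dimnames = list(paste0("K", 1:4), c("flat", "geo")))
  clr <- clr_transform(m)
  expect_equal(unname(clr[, "flat"]), rep(0, 4))
  expect_equal(unname(clr[, "geo"]),
               c(-1.0397208, -0.3465736, 0.3465736, 1.0397208),
               tolerance = 1e-6)
  expect_equal(unname(colSums(clr)), c(0, 0), tolerance = 1e-9)
})

test_that("CLR is scale invariant, equivariant, and handles zeros", {
  set.seed(5)
  m <- matrix(rexp(60), nrow = 10,
              dimnames = list(paste0("K", 1:10), paste0("s", 1:6)))
  clr <- clr_transform(m)
  scaled <- sweep(m, 2, c(1, 10, 0.3, 2, 5, 100), "*")
  expect_equal(clr_transform(scaled), clr, tolerance = 1e-9)
  perm <- sample(10)
  expect_equal(clr_transform(m[perm, ]), clr[perm, ])
  mz <- m; mz[3, 2] <- 0
  clrz <- clr_transform(mz)
  expect_true(all(is.finite(clrz)))
  expect_equal(unname(colSums(clrz)), rep(0, 6), tolerance = 1e-9)
  expect_error(clr_transform(m[1, , drop = FALSE]),
               class = "indigoferm_input_error")
})

test_that("phenotype correlation flags perfect trackers and skips constants", {
  clr <- matrix(c(1, 2, 3, 4,
                  0, 0, 0, 0,
                  4, 3, 2, 1), nrow = 3, byrow = TRUE,
                dimnames = list(c("track", "flat", "anti"),
                                paste0("s", 1:4)))
  phen <- c(s1 = 1, s2 = 2, s3 = 3, s4 = 4)
  res <- correlate_with_phenotype(clr, phen, threshold = 0.9)
  expect_equal(res$r[res$function_id == "track"], 1)
  expect_true(res$selected[res$function_id == "track"])
  expect_true(is.na(res$r[res$function_id == "flat"]))
  expect_false(res$selected[res$function_id == "flat"])
  expect_equal(res$r[res$function_id == "anti"], -1)
  # name alignment: shuffled phenotype gives identical results
  res2 <- correlate_with_phenotype(clr, phen[c(3, 1, 4, 2)], threshold = 0.9)
  expect_equal(res2, res)
  # BH option adds p and q
  res3 <- correlate_with_phenotype(clr, phen, threshold = 0.9, adjust = "BH")
  expect_true(all(c("p", "q") %in% names(res3)))
})
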