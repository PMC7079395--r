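test_that("fraction categorization uses the 10%/80% thresholds", {
  expect_equal(categorize_site(c(0.05, 0.5, 0.95)), c("u", "p", "m"))
  expect_equal(categorize_site(c(0.1, 0.8)), c("p", "p")) # inclusive bounds
  expect_equal(categorize_site(c(0, 1)), c("u", "m"))
  expect_true(is.na(categorize_site(NA)))
  expect_error(categorize_site(1.2), "\\[0, 1\\]")
  # monotone: a higher fraction is never less methylated
  f <- sort(runif(50))
  lev <- match(categorize_site(f), methyl_states)
  expect_true(all(diff(lev) >= 0))
})

test_that("island-level classification needs a strict majority", {
  expect_equal(classify_island_state(rep(c("m", "u"), c(6, 4))), "m")
  expect_equal(classify_island_state(rep(c("u", "m"), c(5, 5))), "p")
  expect_equal(classify_island_state(rep("p", 7)), "p")
  expect_equal(classify_island_state(c("u", "u", "u", NA, NA)), "u")
  expect_error(classify_island_state(c(NA, NA)), "non-missing")
})

test_that("island transition summaries tabulate parent-to-child changes", {
  p <- c("u", "u", "m", "p"); ch <- c("u", "m", "m", "p")
  tab <- island_transition_summary(p, ch)
  expect_equal(unname(diag(tab)), c(1, 1, 1))
  expect_equal(tab["u", "m"], 1, ignore_attr = TRUE)
  expect_equal(unname(rowSums(tab)),
               unname(as.vector(table(factor(p, levels = methyl_states)))))
  # classification from site states against a hand count
  st_p <- c("u", "u", "u", "m", "m", "m", "m")
  st_c <- c("u", "u", "u", "u", "u", "u", "m")
  isl <- c(1, 1, 1, 2, 2, 2, 2)
  tab2 <- island_transition_summary(st_p, st_c, island = isl)
  expect_equal(tab2["u", "u"], 1, ignore_attr = TRUE)
  expect_equal(tab2["m", "u"], 1, ignore_attr = TRUE)
})

test_that("trees round-trip through Newick with full precision", {
  set.seed(51)
  tr <- balanced_tree(4, lengths = exp(rnorm(6, -2, 2)))
  path <- tempfile(fileext = ".nwk")
  write_tree(tr, path)
  tr2 <- read_tree(path)
  expect_identical(sort(tr$labels), sort(tr2$labels))
  m <- match(tr$labels, tr2$labels)
  expect_identical(tr$length, tr2$length[m]) # full precision, no rounding
  par_lab <- function(t) {
    out <- ifelse(is.na(t$parent), NA, t$labels[t$parent])
    setNames(out, t$labels)[sort(t$labels)]
  }
  expect_identical(par_lab(tr), par_lab(tr2))
  expect_error(read_tree(tempfile()), "not found")
})

test_that("state matrices and ground truths round-trip through text files", {
  des <- simulation_design(balanced_tree(4), n_islands = 3,
                           site_range = c(2, 5))
  sim <- simulate_dataset(des, seed = 52)
  sp <- tempfile(fileext = ".tsv")
  write_states(sim$data, sp)
  back <- read_states(sp, tree = sim$tree)
  expect_identical(back$states, sim$data$states)
  expect_identical(as.character(back$island), as.character(sim$data$island))
  # unknown node column is rejected by name
  df <- read.delim(sp, check.names = FALSE)
  names(df)[names(df) == "t1"] <- "bogus"
  sp2 <- tempfile(fileext = ".tsv")
  write.table(df, sp2, sep = "\t", quote = FALSE, row.names = FALSE)
  expect_error(read_states(sp2, tree = sim$tree), "bogus")
  gp <- tempfile(fileext = ".json")
  write_ground_truth(sim$truth, gp)
  tb <- read_ground_truth(gp)
  expect_equal(tb$theta, sim$truth$theta)
  expect_equal(tb$lengths, sim$truth$lengths)
  expect_equal(tb$configs[[1]]$events$pos, sim$truth$configs[[1]]$events$pos)
})

test_that("fraction tables are read and categorized per site", {
  fp <- tempfile(fileext = ".tsv")
  writeLines(c("island\tHSC\tMPP",
               "cgi1\t0.02\t0.95",
               "cgi1\t0.40\t0.80",
               "cgi2\t0.09\t0.10"), fp)
  d <- read_fractions(fp)
  expect_equal(unname(methyl_states[d$states[, "HSC"]]), c("u", "p", "u"))
  expect_equal(unname(methyl_states[d$states[, "MPP"]]), c("m", "p", "p"))
  expect_equal(as.character(d$island), c("cgi1", "cgi1", "cgi2"))
})

test_that("island maps follow BED conventions and reject stray sites", {
  bp <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\tislA", "chr1\t200\t300\tislB",
               "chr2\t50\t80\tislC"), bp)
  map <- read_island_map(bp)
  expect_equal(map$name, c("islA", "islB", "islC"))
  isl <- assign_sites_to_islands(map, c("chr1", "chr1", "chr2"),
                                 c(0, 250, 79))
  expect_equal(isl, c("islA", "islB", "islC"))
  expect_error(assign_sites_to_islands(map, "chr1", 150), "chr1:150")
  expect_error(assign_sites_to_islands(map, "chr1", 100), "chr1:100") # half-open
  bp2 <- tempfile(fileext = ".bed")
  writeLines(c("chr1\t0\t100\ta", "chr1\t50\t120\tb"), bp2)
  expect_error(read_island_map(bp2), "overlapping")
})

test_that("MCMC traces round-trip with their metadata sidecar", {
  tr <- cherry_tree()
  dat <- tiny_data(tr, list(i1 = c(1, 1, 1)))
  fit <- run_mcmc(tr, dat, n_sweeps = 100, burn_in = 50, thin = 10, seed = 53)
  tp <- tempfile(fileext = ".csv")
  write_trace(fit, tp, seed = 53)
  back <- read_trace(tp)
  expect_equal(as.data.frame(back), fit$trace, tolerance = 1e-12)
  meta <- jsonlite::read_json(paste0(tp, ".meta.json"))
  expect_equal(meta$seed, 53)
  expect_equal(meta$mode, "iwe-sse")
})
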