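scenario_state <- function(name, seed, dir, kw = keyword_set(tolerance = 100),
                           overrides = list()) {
  make_scenario(name, file.path(dir, "data"), seed = seed, overrides = overrides)
  mode_analysis(file.path(dir, "data"), kw, run_dir = dir, plot = FALSE)
}

test_that("keyword parsing covers the documented vocabulary", {
  kw <- parse_keywords(c("RESOLUTION HIGH 2.076", "TOLERANCE 100",
                         "RADFRAC 0.8", "ISIGI 2", "COMPLETENESS 90",
                         "MAXCYCLES 7", "PRUNEFRAC 0.2", "SEED 5"))
  expect_equal(kw$resolution_high, 2.076)
  expect_equal(kw$tolerance, 100)
  expect_equal(kw$radfrac, 0.8)
  expect_equal(kw$isigi, 2)
  expect_equal(kw$completeness_target, 90)
  expect_equal(kw$max_prune_cycles, 7L)
  expect_equal(kw$prune_fraction, 0.2)
  expect_equal(kw$seed, 5L)
  # empty stream = accept all defaults
  def <- parse_keywords(character(0))
  expect_equal(def$isigi, 1.5)
  expect_equal(def$tolerance, 2)
  expect_equal(def$completeness_target, 95)
  expect_equal(def$radfrac, 0.75)
  expect_warning(parse_keywords("FROBNICATE 3"), "unknown keyword")
})

test_that("dendrogram-only mode writes bookkeeping files and is reproducible", {
  dir <- withr::local_tempdir()
  make_scenario("two_group", file.path(dir, "data"), seed = 4)
  st <- mode_dendrogram_only(file.path(dir, "data"), run_dir = dir, plot = FALSE)
  expect_true(file.exists(file.path(dir, "mtz_names.dat")))
  expect_true(file.exists(file.path(dir, "CLUSTERS.txt")))
  expect_null(st$entries)
  expect_equal(nrow(st$dendrogram$nodes), 9)
  # re-running from the produced list file reproduces the tree
  st2 <- mode_dendrogram_only(file.path(dir, "mtz_names.dat"),
                              run_dir = withr::local_tempdir(), plot = FALSE)
  expect_equal(st2$dendrogram$nodes$height, st$dendrogram$nodes$height)
  expect_identical(st2$dendrogram$nodes$members, st$dendrogram$nodes$members)
  expect_error(mode_dendrogram_only(file.path(dir, "data", "sim_001.refl"),
                                    run_dir = withr::local_tempdir()),
               "at least 2")
})

test_that("analysis mode emits one final-list row per dataset", {
  dir <- withr::local_tempdir()
  st <- scenario_state("two_group", 4, dir)
  expect_equal(nrow(st$entries), length(st$datasets))
  expect_true(file.exists(file.path(dir, "FINAL_list_of_files.dat")))
  back <- read_final_list(file.path(dir, "FINAL_list_of_files.dat"))
  expect_equal(back$serial, seq_along(st$datasets))
})

test_that("synthesis merges the selected nodes and sorts by completeness", {
  dir <- withr::local_tempdir()
  st <- scenario_state("two_group", 4, dir)
  syn <- mode_synthesis(st, "height", max(st$dendrogram$nodes$height) + 1)
  expect_length(syn, nrow(st$dendrogram$nodes))
  tab <- attr(syn, "table")
  expect_equal(order(tab$completeness, decreasing = TRUE), seq_len(nrow(tab)))
  for (nid in names(syn)) {
    expect_true(file.exists(file.path(dir, "merged_files",
                                      sprintf("merged_%s.refl", nid))))
  }
  info <- readLines(file.path(dir, "MERGING_STATISTICS.info"))
  expect_length(info, nrow(tab) + 1)
  # aLCV cut selects exactly the qualifying nodes
  thr <- stats::median(st$dendrogram$nodes$alcv)
  syn2 <- mode_synthesis(st, "alcv", thr)
  want <- st$dendrogram$nodes$node_id[st$dendrogram$nodes$alcv <= thr]
  expect_equal(sort(as.integer(names(syn2))), sort(want))
  # empty selection warns and writes an empty table
  expect_warning(mode_synthesis(st, "height", 1e-6), "no dendrogram node")
})

test_that("combination syntax expands nodes and honours exclusions", {
  dir <- withr::local_tempdir()
  st <- scenario_state("two_group", 4, dir)
  d <- st$dendrogram
  root_id <- max(d$nodes$node_id)
  spec <- parse_combination(sprintf("[%d] [[%d]]", root_id, 3), d)
  expect_setequal(spec$serials, setdiff(1:10, 3))
  leaf <- parse_combination("[7]", d)
  expect_equal(leaf$serials, 7)
  multi <- parse_combination("[1,2] [[2]]", d)
  expect_equal(multi$serials, 1)
  expect_error(parse_combination("[999]", d), "unknown")
  expect_error(parse_combination(sprintf("[4] [[4]]"), d), "no datasets")
  expect_error(parse_combination("[[3]]", d), "no include")
})

test_that("a combination equal to a node reproduces that node's statistics", {
  dir <- withr::local_tempdir()
  st <- scenario_state("two_group", 4, dir)
  nd <- st$dendrogram$nodes
  node <- nd$node_id[which(lengths(nd$members) == 3)[1]]
  syn <- mode_synthesis(st, "height", max(nd$height) + 1)
  comb <- mode_combination(st, sprintf("[%d]", node))
  expect_equal(comb$stats$r_meas, syn[[as.character(node)]]$stats$r_meas,
               tolerance = 1e-12)
  expect_equal(comb$stats$completeness,
               syn[[as.character(node)]]$stats$completeness)
  expect_equal(comb$stats$cc_half, syn[[as.character(node)]]$stats$cc_half,
               tolerance = 1e-12)
  expect_equal(comb$label, "run1")
  comb2 <- mode_combination(st, sprintf("[%d]", node))
  expect_equal(comb2$label, "run2")  # sequential numbering across invocations
  expect_true(file.exists(file.path(dir, "combined_files", "merged_run1.refl")))
})

test_that("excluding the planted rogue improves R_meas", {
  dir <- withr::local_tempdir()
  st <- scenario_state("rogue", 8, dir)
  root_id <- max(st$dendrogram$nodes$node_id)
  man <- read_manifest(file.path(dir, "data"))
  rogue <- man$datasets$index[man$datasets$rogue][1]
  full <- mode_combination(st, sprintf("[%d]", root_id))
  filtered <- mode_combination(st, sprintf("[%d] [[%d]]", root_id, rogue))
  expect_lt(filtered$stats$r_meas, full$stats$r_meas)
})

test_that("pruning trims the damaged tail and respects its guarantees", {
  dir <- withr::local_tempdir()
  st <- scenario_state("damaged", 5, dir)
  root_id <- max(st$dendrogram$nodes$node_id)
  pr <- mode_pruning(st, sprintf("[%d]", root_id))
  man <- read_manifest(file.path(dir, "data"))
  damaged_serial <- man$datasets$index[man$datasets$damage_B > 0.5][1]
  # victim selection finds the damaged dataset from cycle 0 on
  expect_equal(pr$cycles$victim[1], damaged_serial)
  expect_gt(pr$best_cycle, 0)
  expect_lt(pr$best$stats$r_pim, pr$cycles$r_pim[1])
  expect_gte(pr$best$stats$completeness, st$keywords$completeness_target)
  # eligibility: every post-0 logged-eligible cycle meets the target
  post <- pr$cycles[pr$cycles$cycle > 0 & pr$cycles$eligible, ]
  expect_true(all(post$completeness >= st$keywords$completeness_target))
  # accepted ranges shrink monotonically; totals are additive
  expect_equal(pr$cycles$images_removed_total,
               cumsum(pr$cycles$images_removed))
  rng <- pr$ranges[[as.character(damaged_serial)]]
  expect_lt(rng[2], 60)
  expect_error(mode_pruning(st, "[1]"), "at least 2")
})

test_that("an unreachable completeness target stops pruning at cycle 0", {
  dir <- withr::local_tempdir()
  st <- scenario_state("two_group", 4, dir,
                       kw = keyword_set(tolerance = 100,
                                        completeness_target = 100))
  root_id <- max(st$dendrogram$nodes$node_id)
  pr <- mode_pruning(st, sprintf("[%d]", root_id))
  # partial wedges never reach 100 %: first pruned cycle is ineligible
  expect_equal(pr$best_cycle, 0)
  expect_lte(nrow(pr$cycles), 2)
})

test_that("the CLI dispatches modes and rejects unknown flags", {
  dir <- withr::local_tempdir()
  make_scenario("two_group", file.path(dir, "data"), seed = 4)
  expect_equal(cli(c("-aDO", file.path(dir, "data")), run_dir = dir,
                   keyword_lines = character(0)), 0L)
  expect_true(file.exists(file.path(dir, "CLUSTERS.txt")))
  expect_equal(cli(c("-a", file.path(dir, "data")), run_dir = dir,
                   keyword_lines = "TOLERANCE 100"), 0L)
  expect_true(file.exists(file.path(dir, "analysis_state.rds")))
  expect_equal(cli(c("-s", "1000"), run_dir = dir,
                   keyword_lines = "TOLERANCE 100"), 0L)
  expect_true(file.exists(file.path(dir, "MERGING_STATISTICS.info")))
  expect_equal(suppressMessages(cli("-bogus", run_dir = dir,
                                    keyword_lines = character(0))), 1L)
  expect_equal(suppressMessages(cli(character(0), run_dir = dir,
                                    keyword_lines = character(0))), 1L)
  # synthesis before analysis in a fresh dir fails cleanly
  expect_equal(suppressMessages(cli(c("-s", "10"),
                                    run_dir = withr::local_tempdir(),
                                    keyword_lines = character(0))), 1L)
})
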