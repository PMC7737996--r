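# build a small results table directly (bypassing chromatograms): one row
# per protein x timepoint with the given percent ratios
results_from <- function(ratios) {
  # ratios: named list protein -> c(`8` = ..., `16` = ..., `24` = ...)
  rows <- do.call(rbind, lapply(names(ratios), function(p) {
    r <- ratios[[p]]
    data.frame(protein = p, timepoint_h = as.numeric(names(r)),
               ratio_percent = unname(r), sd = 1, se = 0.5,
               n_replicates = 3L, converged = TRUE,
               change_bin = vapply(unname(r), function(x)
                 classify_change(x)$bin, character(1)),
               qc_pass = TRUE, stringsAsFactors = FALSE)
  }))
  rownames(rows) <- NULL
  rows
}

tp3 <- function(a, b, c) setNames(c(a, b, c), c("8", "16", "24"))

test_that("group summaries average extremum deltas and call activation", {
  reg <- mini_panel()
  res <- results_from(list(
    "Ki-67" = tp3(121.5, 113, 112.2),   # extremum +21.5
    "PCNA"  = tp3(113, 104, 100),       # extremum +13
    "cMyc"  = tp3(100, 100, 100),
    "p27"   = tp3(95, 80, 90)))         # extremum -20, overlap member
  gp <- group_profile(res, reg)

  prol <- gp[gp$group == "Proliferation", ]
  # members Ki-67 (+21.5), PCNA (+13), p27 (-20): mean +4.83 -> mixed
  expect_equal(prol$n_members, 3L)
  expect_equal(prol$mean_extremum_delta, (21.5 + 13 - 20) / 3)
  expect_equal(prol$call, "mixed")

  net <- gp[gp$group == "Network", ]   # cMyc (0), p27 (-20): mean -10
  expect_equal(net$n_members, 2L)
  expect_equal(net$call, "inactivated")

  # the overlap protein contributes to both of its groups
  members <- attr(gp, "members")
  expect_true("p27" %in% names(members$Proliferation))
  expect_true("p27" %in% names(members$Network))

  only_up <- results_from(list("Ki-67" = tp3(121.5, 113, 112.2),
                               "PCNA" = tp3(113, 104, 100)))
  expect_equal(group_profile(only_up, reg)$call[1], "activated")

  zeros <- results_from(list("Ki-67" = tp3(100, 100, 100)))
  expect_equal(group_profile(zeros, reg)$call[1], "mixed")

  expect_error(group_profile(res[0, ], reg), "empty")
  bad <- results_from(list("NotInPanel" = tp3(110, 100, 100)))
  expect_error(group_profile(bad, reg), "not in the registry")
})

test_that("star-plot specs order proteins by group and keep one axis each", {
  reg <- mini_panel()
  res <- results_from(list(
    "Ki-67" = tp3(110, 105, 100), "PCNA" = tp3(95, 90, 85),
    "cMyc" = tp3(100, 101, 102), "p27" = tp3(120, 110, 100)))
  spec <- star_plot_spec(res, reg, proteins = unique(res$protein))

  # registry order within groups; the overlap protein appears once, under
  # its first group
  expect_identical(spec$labels, c("Ki-67", "PCNA", "p27", "cMyc"))
  expect_equal(dim(spec$values), c(4L, 3L))
  expect_equal(spec$reference, 100)
  expect_equal(spec$rmax, 1.1 * 120)
  expect_identical(spec$series, c("8 h", "16 h", "24 h"))

  ext <- star_plot_spec(res, reg, proteins = unique(res$protein),
                        mode = "extremum")
  expect_equal(dim(ext$values), c(4L, 1L))
  expect_equal(unname(ext$values[1, 1]), 110)   # Ki-67 extremum +10

  expect_error(star_plot_spec(res[res$protein %in% c("Ki-67", "PCNA"), ],
                              reg, proteins = c("Ki-67", "PCNA")),
               ">= 3 proteins")
})

test_that("line graphs render with one polyline per protein plus the control line", {
  res <- results_from(list(
    "Ki-67" = tp3(110, 105, 100), "PCNA" = tp3(95, 90, 85),
    "cMyc" = tp3(100, 101, 102)))
  dir <- withr::local_tempdir()
  path <- file.path(dir, "group.svg")
  p <- render_line_graph(res, path, title = "demo")

  expect_true(file.exists(path))
  meta <- readLines(paste0(path, ".meta.txt"))
  expect_true("n_series: 3" %in% meta)

  single <- render_line_graph(res[res$protein == "Ki-67", ],
                              file.path(dir, "one.svg"))
  meta1 <- readLines(file.path(dir, "one.svg.meta.txt"))
  expect_true("n_series: 1" %in% meta1)
})

test_that("batch-rendered groups share one y scale", {
  reg <- mini_panel()
  res <- results_from(list(
    "Ki-67" = tp3(130, 105, 100), "PCNA" = tp3(95, 90, 85),
    "cMyc" = tp3(100, 70, 102), "p27" = tp3(120, 110, 100)))
  dir <- withr::local_tempdir()
  paths <- render_line_graphs(res, reg, dir)
  expect_length(paths, 2L)   # two pathway groups have members
  metas <- lapply(paste0(paths, ".meta.txt"), readLines)
  ylims <- vapply(metas, function(m)
    paste(grep("^ylim", m, value = TRUE), collapse = "|"), character(1))
  expect_equal(length(unique(ylims)), 1L)
  expect_match(ylims[1], "ylim_lo: 70")
  expect_match(ylims[1], "ylim_hi: 130")
})

test_that("star plots render deterministically with one axis per protein", {
  reg <- mini_panel()
  res <- results_from(list(
    "Ki-67" = tp3(110, 105, 100), "PCNA" = tp3(95, 90, 85),
    "cMyc" = tp3(100, 101, 102), "p27" = tp3(120, 110, 100)))
  spec <- star_plot_spec(res, reg, proteins = unique(res$protein))
  dir <- withr::local_tempdir()
  p1 <- file.path(dir, "star1.svg")
  p2 <- file.path(dir, "star2.svg")
  render_star_plot(spec, p1)
  render_star_plot(spec, p2)

  meta <- readLines(paste0(p1, ".meta.txt"))
  expect_true("n_axes: 4" %in% meta)
  expect_true(any(grepl("reference: 100", meta)))
  expect_identical(unname(tools::md5sum(p1)), unname(tools::md5sum(p2)))

  # an all-100 spec collapses onto the reference ring
  flat <- results_from(list(
    "Ki-67" = tp3(100, 100, 100), "PCNA" = tp3(100, 100, 100),
    "cMyc" = tp3(100, 100, 100)))
  fspec <- star_plot_spec(flat, reg, proteins = unique(flat$protein))
  expect_true(all(fspec$values == fspec$reference))

  two <- structure(list(labels = c("a", "b"),
                        values = matrix(100, 2, 1,
                                        dimnames = list(NULL, "8 h")),
                        series = "8 h", reference = 100, rmax = 110),
                   class = "star_plot_spec")
  expect_error(render_star_plot(two, file.path(dir, "two.svg")),
               ">= 3 proteins")
})

test_that("every profiled representative protein gets exactly one star axis", {
  reg <- quiet_panel()
  reps <- representative_proteins(reg)
  ratios <- setNames(lapply(seq_along(reps), function(i)
    tp3(100 + (i %% 7), 100 - (i %% 5), 100)), reps)
  res <- results_from(ratios)
  spec <- star_plot_spec(res, reg)
  expect_equal(length(spec$labels), 116L)
  expect_setequal(spec$labels, reps)
  expect_false(anyDuplicated(spec$labels) > 0)
})
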