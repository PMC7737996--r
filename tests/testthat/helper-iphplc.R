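# shared fixtures: the packaged panel is loaded once (its two documented
# count-column warnings are expected and silenced here), and small
# registries are built in code for error-path tests.

.panel_cache <- new.env(parent = emptyenv())

quiet_panel <- function() {
  if (is.null(.panel_cache$reg)) {
    .panel_cache$reg <- suppressWarnings(load_panel())
  }
  .panel_cache$reg
}

# write a minimal registry + category pair; `rows` are pre-formatted TSV
# body lines (after the header line)
write_mini_registry <- function(rows, categories,
                                dir = tempfile("registry")) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  reg_path <- file.path(dir, "panel.tsv")
  writeLines(c("name\tcategories\toverlap_in\thousekeeping\trepresentative\tvendor_code",
               rows), reg_path)
  cat_path <- file.path(dir, "categories.tsv")
  writeLines(c("category\tdeclared_count\tdeclared_overlap\tpathway_group",
               categories), cat_path)
  list(registry = reg_path, categories = cat_path)
}

# analytic Gaussian peak area in mAU*s for amplitude (mAU) and sigma (min)
gaussian_area <- function(amplitude_mAU, sigma_min) {
  amplitude_mAU * sigma_min * sqrt(2 * pi) * 60
}

# total rendered-trace area by trapezoid after removing the known baseline:
# an integration oracle independent of the peak-quantification module
whole_trace_area <- function(chrom, slope = 0, offset = 0) {
  t <- chrom$time_min
  y <- chrom$absorbance_mAU - (offset + slope * t)
  n <- length(t)
  60 * sum(diff(t) * (y[-1] + y[-n]) / 2)
}

# small self-consistent registry used by pipeline tests: two pathway
# groups plus the housekeeping controls
mini_panel <- function() {
  f <- write_mini_registry(
    rows = c(
      "Ki-67\tProliferation\t\t0\t1\t",
      "PCNA\tProliferation\t\t0\t1\t",
      "cMyc\tNetwork\t\t0\t1\t",
      "p27\tProliferation;Network\tNetwork\t0\t0\t",
      "alpha-tubulin\tControl housekeeping proteins\t\t1\t0\t",
      "beta-actin\tControl housekeeping proteins\t\t1\t0\t",
      "GAPDH\tControl housekeeping proteins\t\t1\t0\t"),
    categories = c(
      "Proliferation\t3\t0\t1",
      "Network\t2\t1\t1",
      "Control housekeeping proteins\t3\t0\t0"))
  load_panel(f$registry, f$categories)
}
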